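# Spectro-temporal Gabor filter bank (GBFB) linear baseline. Each filter is
# a complex exponential carrier under a raised-cosine (Hann) envelope on the
# mel-channel x time-frame plane; the modulation-frequency grids follow a
# geometric recurrence that bounds the correlation between neighboring
# filters.

#' Modulation-frequency grid by geometric recurrence
#'
#' Frequencies descend from `w_max` with ratio `(1 + c/2) / (1 - c/2)`,
#' `c = 8 d / nu`, and are truncated where the filter's Hann envelope extent
#' `b(w) = nu * pi / w` would exceed `size_max` samples (channels on the
#' spectral axis, frames on the temporal axis), i.e. at
#' `w_min = nu * pi / size_max`. The zero (DC) frequency is appended, and
#' the axis can be mirrored to negative frequencies to represent both
#' spectro-temporal sweep directions.
#'
#' @param d Per-axis spacing constant.
#' @param nu Semi-cycles under the envelope.
#' @param w_max Largest modulation frequency in rad/sample.
#' @param size_max Largest admissible envelope extent in samples; at the
#'   reference parameters this is the 64 mel channels on the spectral axis
#'   and 80 frames (1 s at the 12.5 ms hop) on the temporal axis.
#' @param mirror If `TRUE`, include sign-mirrored negative frequencies.
#' @return Numeric vector of frequencies in decreasing order (including 0
#'   and, when mirrored, the negative frequencies).
#' @export
modulation_grid <- function(d, nu, w_max, size_max = 64, mirror = FALSE) {
  if (d <= 0 || nu <= 0) stop("d and nu must be positive")
  if (w_max <= 0 || w_max > pi) stop("w_max must be in (0, pi]")
  c_ <- 8 * d / nu
  if (c_ >= 2) stop("spacing too large: c = 8 d / nu must be < 2")
  ratio <- (1 + c_ / 2) / (1 - c_ / 2)
  w_min <- nu * pi / size_max
  ws <- numeric(0)
  w <- w_max
  while (w >= w_min) {
    ws <- c(ws, w)
    w <- w / ratio
  }
  out <- c(ws, 0)
  if (mirror) out <- c(out, -ws)
  sort(out, decreasing = TRUE)
}

#' Grid of spectro-temporal modulation frequencies
#'
#' Builds both axes of the filter bank. The spectral axis is sign-mirrored
#' (upward and downward spectro-temporal sweeps) while the temporal axis is
#' non-negative; at the reference parameters (`d_k = 0.1`, `d_n = 0.045`,
#' `nu = 3.5`, `w_max = pi/4`) this yields 15 spectral and 18 temporal
#' modulation frequencies.
#'
#' @param d_k,d_n Spacing constants of the spectral and temporal axes.
#' @param nu_k,nu_n Semi-cycle counts.
#' @param w_max Largest modulation frequency (shared by both axes).
#' @param n_channels Number of mel channels (spectral extent bound).
#' @param max_frames Temporal extent bound in frames.
#' @return A list of class `gabor_grid` with `spectral`, `temporal` and the
#'   parameters.
#' @export
gabor_grid <- function(d_k = 0.1, d_n = 0.045, nu_k = 3.5, nu_n = 3.5,
                       w_max = pi / 4, n_channels = 64, max_frames = 80) {
  structure(list(
    spectral = modulation_grid(d_k, nu_k, w_max, n_channels, mirror = TRUE),
    temporal = modulation_grid(d_n, nu_n, w_max, max_frames, mirror = FALSE),
    d_k = d_k, d_n = d_n, nu_k = nu_k, nu_n = nu_n, w_max = w_max,
    n_channels = n_channels, max_frames = max_frames),
    class = "gabor_grid")
}

hann_envelope <- function(x, b) {
  ifelse(abs(x) < b / 2, 0.5 + 0.5 * cos(2 * pi * x / b), 0)
}

#' Construct a single complex 2-D Gabor filter
#'
#' The filter is the separable product of complex carriers
#' `exp(i w_k k) exp(i w_n n)` and raised-cosine envelopes peaked at the
#' filter center with extent `b = nu * pi / |w|` (the width holding `nu`
#' semi-cycles of the carrier); the envelope vanishes at the support edge.
#' For nonzero modulation frequencies the envelope-weighted mean is removed,
#' making the filter insensitive to constant offsets of the spectrogram.
#' Zero-frequency (DC) axes use a pure envelope with extent `dc_extent`.
#'
#' @param w_k Spectral modulation frequency (rad/channel); may be negative.
#' @param w_n Temporal modulation frequency (rad/frame), non-negative.
#' @param nu_k,nu_n Semi-cycle counts.
#' @param dc_extent_k,dc_extent_n Envelope extents used when the
#'   corresponding frequency is zero.
#' @return A list of class `gabor_filter` with the complex `values` matrix
#'   (channels x frames) and its parameters.
#' @export
make_gabor_filter <- function(w_k, w_n, nu_k = 3.5, nu_n = 3.5,
                              dc_extent_k = 23, dc_extent_n = 40) {
  b_k <- if (w_k == 0) dc_extent_k else nu_k * pi / abs(w_k)
  b_n <- if (w_n == 0) dc_extent_n else nu_n * pi / abs(w_n)
  if (b_k <= 0 || b_n <= 0) stop("zero-extent envelope")
  h_k <- ceiling(b_k / 2); h_n <- ceiling(b_n / 2)
  xk <- -h_k:h_k; xn <- -h_n:h_n
  env <- outer(hann_envelope(xk, b_k), hann_envelope(xn, b_n))
  carrier <- outer(exp(1i * w_k * xk), exp(1i * w_n * xn))
  g <- env * carrier
  if (w_k != 0 || w_n != 0) {
    g <- g - env * (sum(g) / sum(env))
  }
  nrm <- sqrt(sum(Mod(g)^2))
  if (nrm > 0) g <- g / nrm
  structure(list(values = g, w_k = w_k, w_n = w_n, nu_k = nu_k, nu_n = nu_n,
                 b_k = b_k, b_n = b_n),
            class = "gabor_filter")
}

#' Build the Gabor filter bank
#'
#' One filter per (spectral, temporal) frequency pair of the grid, with
#' redundant duplicates removed: a filter with negative spectral frequency
#' and zero temporal frequency is the complex conjugate of its positive
#' counterpart (identical real part), so those pairs are kept only once.
#' At the reference parameters this leaves 15 x 18 - 7 = 263 independent
#' filters.
#'
#' @param grid A [gabor_grid()].
#' @return A list of class `gabor_bank`: `filters` (list of
#'   [make_gabor_filter()] results), `size`, and the originating grid.
#' @export
build_filterbank <- function(grid = gabor_grid()) {
  stopifnot(inherits(grid, "gabor_grid"))
  pos_k <- grid$spectral[grid$spectral > 0]
  pos_n <- grid$temporal[grid$temporal > 0]
  dc_k <- if (length(pos_k)) grid$nu_k * pi / min(pos_k) else grid$n_channels
  dc_n <- if (length(pos_n)) grid$nu_n * pi / min(pos_n) else grid$max_frames
  filters <- list()
  for (wk in grid$spectral) {
    for (wn in grid$temporal) {
      if (wk < 0 && wn == 0) next  # conjugate duplicate of (+wk, 0)
      filters[[length(filters) + 1L]] <-
        make_gabor_filter(wk, wn, grid$nu_k, grid$nu_n, dc_k, dc_n)
    }
  }
  structure(list(filters = filters, size = length(filters), grid = grid),
            class = "gabor_bank")
}

#' @export
print.gabor_bank <- function(x, ...) {
  cat(sprintf("<gabor_bank: %d filters (%d spectral x %d temporal freqs)>\n",
              x$size, length(x$grid$spectral), length(x$grid$temporal)))
  invisible(x)
}

# Zero-padded "same" 2-D convolution of a real matrix with a (possibly
# complex) filter, via FFT. Filter dimensions must be odd.
conv2_same <- function(x, h) {
  nr <- nrow(x) + nrow(h) - 1L
  nc <- ncol(x) + ncol(h) - 1L
  pr <- stats::nextn(nr, c(2, 3, 5))
  pc <- stats::nextn(nc, c(2, 3, 5))
  X <- matrix(0, pr, pc); X[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  H <- matrix(0 + 0i, pr, pc); H[seq_len(nrow(h)), seq_len(ncol(h))] <- h
  full <- stats::fft(stats::fft(X) * stats::fft(H), inverse = TRUE) / (pr * pc)
  r0 <- (nrow(h) - 1L) / 2L
  c0 <- (ncol(h) - 1L) / 2L
  full[r0 + seq_len(nrow(x)), c0 + seq_len(ncol(x)), drop = FALSE]
}

#' GBFB feature vector of a log-Mel spectrogram
#'
#' Convolves the spectrogram with every filter of the bank (zero-padded
#' "same" convolution), takes the real part, applies a ReLU and averages
#' over time and frequency; one non-negative value per filter.
#'
#' @param spec A `log_mel` object or a numeric matrix (channels x frames).
#' @param bank A [build_filterbank()] result.
#' @return Numeric vector of length `bank$size`.
#' @export
gbfb_features <- function(spec, bank) {
  stopifnot(inherits(bank, "gabor_bank"))
  x <- if (inherits(spec, "log_mel")) spec$values else as.matrix(spec)
  if (length(x) == 0L) stop("empty spectrogram")
  vapply(bank$filters, function(f) {
    resp <- Re(conv2_same(x, f$values))
    mean(pmax(resp, 0))
  }, numeric(1))
}
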