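#' Log-Mel frontend configuration
#'
#' Settings for the time-frequency representation used by every downstream
#' stage: 64 mel bands spanning 0--8000 Hz, a 25 ms analysis window and a
#' 12.5 ms hop. Window and hop are converted to samples with `floor()`
#' (551 and 275 samples at 22,050 Hz), which makes a 10 s clip yield exactly
#' 800 frames under the left-aligned, no-padding framing used here.
#'
#' The mel scale is the HTK variant, `mel = 2595 log10(1 + f/700)`; the log
#' is natural and applied as `log(power + eps)` so digital silence maps to
#' the finite floor `log(eps)`.
#'
#' @param sample_rate Expected waveform rate in Hz.
#' @param n_mels Number of mel bands.
#' @param fmin,fmax Frequency range of the mel filter bank in Hz.
#' @param window_s Analysis window in seconds.
#' @param hop_s Hop between frames in seconds.
#' @param n_fft FFT length; defaults to the next power of two at or above the
#'   window length.
#' @param eps Additive offset on mel-band power before the log.
#' @return A list of class `frontend_config`.
#' @export
frontend_config <- function(sample_rate = 22050, n_mels = 64, fmin = 0,
                            fmax = 8000, window_s = 0.025, hop_s = 0.0125,
                            n_fft = NULL, eps = 1e-10) {
  win <- floor(window_s * sample_rate)
  if (is.null(n_fft)) n_fft <- 2^ceiling(log2(win))
  if (n_fft < win) stop("n_fft must be at least the window length")
  structure(list(sample_rate = sample_rate, n_mels = n_mels, fmin = fmin,
                 fmax = fmax, window_s = window_s, hop_s = hop_s,
                 window = win, hop = floor(hop_s * sample_rate),
                 n_fft = as.integer(n_fft), eps = eps, mel_variant = "htk"),
            class = "frontend_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Center frequencies of the mel filter bank
#'
#' @param config A [frontend_config()].
#' @return Numeric vector of `n_mels` center frequencies in Hz.
#' @export
mel_center_freqs <- function(config = frontend_config()) {
  edges <- mel_to_hz(seq(hz_to_mel(config$fmin), hz_to_mel(config$fmax),
                         length.out = config$n_mels + 2L))
  edges[2:(config$n_mels + 1L)]
}

# Triangular mel filter bank as a (n_mels x n_bins) matrix acting on the
# one-sided power spectrum.
mel_filterbank <- function(config = frontend_config()) {
  n_bins <- config$n_fft / 2L + 1L
  bin_freqs <- (seq_len(n_bins) - 1L) * config$sample_rate / config$n_fft
  edges <- mel_to_hz(seq(hz_to_mel(config$fmin), hz_to_mel(config$fmax),
                         length.out = config$n_mels + 2L))
  fb <- matrix(0, config$n_mels, n_bins)
  for (m in seq_len(config$n_mels)) {
    lo <- edges[m]; ce <- edges[m + 1L]; hi <- edges[m + 2L]
    up <- (bin_freqs - lo) / (ce - lo)
    dn <- (hi - bin_freqs) / (hi - ce)
    fb[m, ] <- pmax(0, pmin(up, dn))
  }
  fb
}

#' Convert a clip to a log-Mel spectrogram
#'
#' Frames the waveform left-aligned with no centering padding, so the frame
#' count is exactly `floor((N - window) / hop) + 1`. Each frame is Hann
#' windowed, zero padded to `n_fft`, and reduced to mel-band power; the
#' output is `log(power + eps)`.
#'
#' @param clip An [audio_clip()] at the configured sample rate (resample
#'   first with [resample_clip()] otherwise).
#' @param config A [frontend_config()].
#' @return An object of class `log_mel`: a list with `values` (a
#'   `n_mels x T` matrix), frame timing metadata and the originating config.
#' @export
to_log_mel <- function(clip, config = frontend_config()) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) == 0L) stop("empty waveform")
  if (abs(clip$sample_rate - config$sample_rate) > 1e-9)
    stop("clip sample rate (", clip$sample_rate, ") does not match config (",
         config$sample_rate, "); resample first")
  x <- clip$samples
  win <- config$window; hop <- config$hop
  if (length(x) < win) stop("waveform shorter than one analysis window")
  n_frames <- floor((length(x) - win) / hop) + 1L
  idx <- outer(seq_len(win), (seq_len(n_frames) - 1L) * hop, "+")
  frames <- matrix(x[idx], nrow = win)
  hann <- 0.5 - 0.5 * cos(2 * pi * (seq_len(win) - 1L) / win)
  frames <- frames * hann
  padded <- matrix(0, config$n_fft, n_frames)
  padded[seq_len(win), ] <- frames
  spec <- stats::mvfft(padded)
  power <- Mod(spec[seq_len(config$n_fft / 2L + 1L), , drop = FALSE])^2
  mel <- mel_filterbank(config) %*% power
  structure(list(values = log(mel + config$eps),
                 frame_hop = config$hop_s, window = config$window_s,
                 mel_range = c(config$fmin, config$fmax),
                 clip_id = clip$id, config = config),
            class = "log_mel")
}

#' @export
print.log_mel <- function(x, ...) {
  cat(sprintf("<log_mel %s: %d mel x %d frames, hop %.4g s>\n",
              x$clip_id, nrow(x$values), ncol(x$values), x$frame_hop))
  invisible(x)
}

#' Average-pool a log-Mel spectrogram along time
#'
#' Used to reduce the temporal resolution of network inputs at desk scale;
#' `factor` consecutive frames are averaged, trailing frames that do not fill
#' a full group are dropped.
#'
#' @param lm A `log_mel` object.
#' @param factor Integer pooling factor (1 = no pooling).
#' @return A `log_mel` object with `T %/% factor` frames.
#' @export
time_pool_log_mel <- function(lm, factor = 1L) {
  stopifnot(inherits(lm, "log_mel"), factor >= 1L)
  if (factor == 1L) return(lm)
  v <- lm$values
  n_keep <- (ncol(v) %/% factor) * factor
  v <- v[, seq_len(n_keep), drop = FALSE]
  dim(v) <- c(nrow(v), factor, n_keep %/% factor)
  pooled <- apply(v, c(1, 3), mean)
  lm$values <- pooled
  lm$frame_hop <- lm$frame_hop * factor
  lm
}

#' Root-mean-square amplitude of a clip
#' @param clip An [audio_clip()].
#' @return `sqrt(mean(x^2))` of the samples.
#' @export
rms <- function(clip) {
  stopifnot(inherits(clip, "audio_clip"))
  if (length(clip$samples) == 0L) stop("empty waveform")
  sqrt(mean(clip$samples^2))
}

#' Rescale a clip to a target RMS amplitude
#'
#' The waveform is multiplied by a single scalar so that its RMS equals
#' `target`; silent input cannot be normalized and raises an error.
#'
#' @param clip An [audio_clip()].
#' @param target Target RMS amplitude (> 0).
#' @return The rescaled clip.
#' @export
normalize_rms <- function(clip, target) {
  r <- rms(clip)
  if (r == 0) stop("cannot normalize a silent clip")
  if (target <= 0) stop("'target' must be positive")
  clip$samples <- clip$samples * (target / r)
  clip
}

#' Scale the power of a clip
#'
#' Multiplies the waveform by `sqrt(power_ratio)`, so mean-square power is
#' scaled by `power_ratio` and RMS amplitude by its square root (a power
#' ratio of 1/64 is an 8-fold RMS reduction).
#'
#' @param clip An [audio_clip()].
#' @param power_ratio Positive power scaling factor.
#' @return The scaled clip.
#' @export
scale_power <- function(clip, power_ratio) {
  stopifnot(inherits(clip, "audio_clip"))
  if (!is.numeric(power_ratio) || length(power_ratio) != 1L || power_ratio <= 0)
    stop("'power_ratio' must be a single positive number")
  clip$samples <- clip$samples * sqrt(power_ratio)
  clip
}
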