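# Per-unit selectivity statistics. The selectivity index of a unit is the
# Welch-style t statistic contrasting its mean response to a positive clip
# group (music, or speech for the speech analogue) against the negative
# group, normalized by the unpooled variances:
#   (m_pos - m_neg) / sqrt(s_pos^2 / n_pos + s_neg^2 / n_neg).
# Mixed clips belong to neither group and are always excluded.

#' Selectivity index per unit
#'
#' @param responses_pos Matrix of responses to positive-group clips
#'   (clips x units), e.g. music.
#' @param responses_neg Matrix of responses to negative-group clips with the
#'   same unit columns.
#' @return Numeric vector of per-unit indices. A unit with zero variance in
#'   both groups gets 0 when the means agree and a signed `Inf` (flagged via
#'   the `"degenerate"` attribute) otherwise.
#' @export
selectivity_index <- function(responses_pos, responses_neg) {
  responses_pos <- as.matrix(responses_pos)
  responses_neg <- as.matrix(responses_neg)
  if (ncol(responses_pos) != ncol(responses_neg))
    stop("unit dimensions differ between groups")
  if (nrow(responses_pos) < 2L || nrow(responses_neg) < 2L)
    stop("both groups need at least 2 clips")
  m_pos <- colMeans(responses_pos)
  m_neg <- colMeans(responses_neg)
  v_pos <- apply(responses_pos, 2, stats::var)
  v_neg <- apply(responses_neg, 2, stats::var)
  se <- sqrt(v_pos / nrow(responses_pos) + v_neg / nrow(responses_neg))
  idx <- (m_pos - m_neg) / se
  zero_se <- se == 0
  if (any(zero_se)) {
    idx[zero_se & m_pos == m_neg] <- 0
    deg <- zero_se & m_pos != m_neg
    idx[deg] <- sign(m_pos - m_neg)[deg] * Inf
    attr(idx, "degenerate") <- which(deg)
  }
  idx
}

#' Per-unit selectivity profile
#'
#' Computes group means, standard deviations, sizes and the selectivity
#' index for every unit, given the clip grouping of the manifest. Clips in
#' the `mixed` group are excluded. With `positive = "music"` this is the
#' music-selectivity index (MSI); passing a speech/non-speech grouping gives
#' the speech analogue (SSI) with the same machinery.
#'
#' @param features Feature matrix (clips x units).
#' @param groups Character vector per clip: `positive` group name,
#'   anything else non-positive, with `"mixed"` excluded.
#' @param positive Name of the positive group (default `"music"`).
#' @return A data frame of class `selectivity_profile` with columns `unit`,
#'   `m_pos`, `m_neg`, `s_pos`, `s_neg`, `n_pos`, `n_neg`, `index`.
#' @export
selectivity_profile <- function(features, groups, positive = "music") {
  features <- as.matrix(features)
  if (nrow(features) != length(groups))
    stop("one group label per clip is required")
  keep <- groups != "mixed"
  features <- features[keep, , drop = FALSE]
  groups <- groups[keep]
  pos <- features[groups == positive, , drop = FALSE]
  neg <- features[groups != positive, , drop = FALSE]
  if (nrow(pos) < 2L || nrow(neg) < 2L)
    stop("need at least 2 clips in each group")
  idx <- selectivity_index(pos, neg)
  out <- data.frame(unit = seq_len(ncol(features)),
                    m_pos = colMeans(pos), m_neg = colMeans(neg),
                    s_pos = apply(pos, 2, stats::sd),
                    s_neg = apply(neg, 2, stats::sd),
                    n_pos = nrow(pos), n_neg = nrow(neg),
                    index = as.numeric(idx))
  class(out) <- c("selectivity_profile", "data.frame")
  attr(out, "positive") <- positive
  out
}

#' Select a unit group by index rank
#'
#' Units are ranked by index in descending order (ties broken by unit
#' position) and a band of the ranking is selected with round-down
#' arithmetic: the top fraction `f` of `n` units is ranks
#' `1 .. max(1, floor(f n))`; a `band = c(lo, hi)` selects ranks
#' `floor(lo n) + 1 .. floor(hi n)` (the middle 43.75--56.25% of 256 units
#' is ranks 113--144).
#'
#' @param profile A [selectivity_profile()] (or any data frame with `unit`
#'   and `index` columns).
#' @param fraction Fraction of units for `which = "top"` or `"bottom"`.
#' @param which `"top"`, `"bottom"`, or `"band"`.
#' @param band Two-element rank-fraction interval when `which = "band"`.
#' @return An integer vector of unit indices of class `unit_group` with a
#'   `criterion` attribute.
#' @export
select_group <- function(profile, fraction = 0.125,
                         which = c("top", "bottom", "band"),
                         band = c(0.4375, 0.5625)) {
  which <- match.arg(which)
  if (nrow(profile) == 0L) stop("empty selectivity profile")
  if (which != "band" && (fraction <= 0 || fraction > 1))
    stop("fraction must be in (0, 1]")
  n <- nrow(profile)
  ord <- order(profile$index, profile$unit, decreasing = c(TRUE, FALSE),
               method = "radix")
  ranked <- profile$unit[ord]
  idx <- switch(which,
    top = ranked[seq_len(max(1L, floor(fraction * n)))],
    bottom = ranked[(n - max(1L, floor(fraction * n)) + 1L):n],
    band = {
      lo <- floor(band[1] * n) + 1L
      hi <- floor(band[2] * n)
      if (lo > hi) stop("band selects no units")
      ranked[lo:hi]
    })
  structure(as.integer(idx), class = "unit_group",
            criterion = if (which == "band")
              sprintf("band %.4f-%.4f", band[1], band[2])
            else sprintf("%s %.4f", which, fraction))
}

#' Select the units with the largest mean absolute response
#'
#' The L1-norm group: units with the strongest average response magnitude
#' over the evaluation clips, used as a contrast to index-based selection in
#' the ablation experiment.
#'
#' @param features Feature matrix (clips x units).
#' @param fraction Fraction of units to keep.
#' @return A `unit_group` of `max(1, floor(fraction * n_units))` units.
#' @export
select_group_l1 <- function(features, fraction = 0.125) {
  features <- as.matrix(features)
  n <- ncol(features)
  l1 <- colMeans(abs(features))
  ord <- order(l1, seq_len(n), decreasing = c(TRUE, FALSE), method = "radix")
  structure(as.integer(ord[seq_len(max(1L, floor(fraction * n)))]),
            class = "unit_group", criterion = sprintf("l1 %.4f", fraction))
}

#' Music/non-music response ratio of a unit group
#'
#' Mean over the group's units of (mean response to positive-group clips) /
#' (mean response to negative-group clips); mixed clips are excluded. Units
#' whose negative-group mean response is zero are excluded with a warning.
#'
#' @param features Feature matrix (clips x units).
#' @param group A `unit_group` (integer unit indices).
#' @param groups Clip grouping vector as in [selectivity_profile()].
#' @param positive Positive group name.
#' @return Scalar response ratio.
#' @export
response_ratio <- function(features, group, groups, positive = "music") {
  features <- as.matrix(features)
  keep <- groups != "mixed"
  features <- features[keep, , drop = FALSE]
  groups <- groups[keep]
  pos_mean <- colMeans(features[groups == positive, group, drop = FALSE])
  neg_mean <- colMeans(features[groups != positive, group, drop = FALSE])
  bad <- neg_mean == 0
  if (any(bad)) {
    warning(sum(bad), " unit(s) with zero non-", positive,
            " response excluded from the ratio")
    pos_mean <- pos_mean[!bad]; neg_mean <- neg_mean[!bad]
  }
  if (!length(pos_mean)) return(NA_real_)
  mean(pos_mean / neg_mean)
}

#' Response-ratio robustness to amplitude reduction
#'
#' Rescales the positive-group (music) clips by each power ratio, recomputes
#' the features and the group response ratio, keeping the unit group fixed
#' to the one identified on the unmanipulated data.
#'
#' @param model A `tagger_model`.
#' @param clips Named list of [audio_clip()]s (the evaluation clips).
#' @param groups Clip grouping vector aligned with `clips`.
#' @param group A `unit_group` identified beforehand on unmanipulated data.
#' @param power_ratios Power scaling factors for the positive clips (the
#'   RMS scales by their square roots).
#' @param positive Positive group name.
#' @param frontend A [frontend_config()].
#' @param time_pool Time-pooling factor matching the model's training
#'   inputs.
#' @return Data frame with columns `power_ratio`, `rms_ratio`,
#'   `response_ratio`.
#' @export
amplitude_robustness <- function(model, clips, groups, group,
                                 power_ratios = 1 / c(1, 2, 4, 8, 16, 32, 64),
                                 positive = "music",
                                 frontend = frontend_config(),
                                 time_pool = 1L) {
  stopifnot(length(clips) == length(groups))
  out <- lapply(power_ratios, function(pr) {
    scaled <- clips
    idx <- which(groups == positive)
    for (i in idx) scaled[[i]] <- scale_power(scaled[[i]], pr)
    x <- stack_spectrograms(lapply(scaled, to_log_mel, config = frontend),
                            time_pool = time_pool)
    feats <- extract_features(model, x)
    data.frame(power_ratio = pr, rms_ratio = sqrt(pr),
               response_ratio = response_ratio(feats, group, groups,
                                               positive = positive))
  })
  do.call(rbind, out)
}
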