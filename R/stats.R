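#' Average precision with tie averaging
#'
#' Area under the non-interpolated precision--recall step curve of a ranked
#' list. Items with exactly equal scores are processed as one block: every
#' positive in a tied block is credited the precision reached at the end of
#' the block, which is the average over the block of the linearly
#' interpolated precision and agrees with the expectation over random
#' tie-breaking up to `O(1/n)`. Under this convention a constant-score
#' ranking scores exactly the positive prevalence -- the chance level of
#' the metric.
#'
#' @param scores Numeric vector of ranking scores (higher = more positive).
#' @param labels Binary vector (0/1 or logical) of the same length.
#' @return The average precision in `[0, 1]`.
#' @export
average_precision <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  if (!all(labels %in% c(0, 1))) stop("labels must be binary")
  n_pos <- sum(labels)
  if (n_pos == 0) stop("average precision undefined: no positive labels")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- labels[o]
  blocks <- rle(s)
  ends <- cumsum(blocks$lengths)
  starts <- ends - blocks$lengths + 1L
  total <- 0
  for (b in seq_along(ends)) {
    m <- blocks$lengths[b]
    p <- sum(y[starts[b]:ends[b]])
    if (p == 0) next
    C <- if (b == 1L) 0 else sum(y[seq_len(starts[b] - 1L)])
    R <- starts[b] - 1L
    total <- total + p * (C + p) / (R + m)
  }
  total / n_pos
}

#' Macro-averaged mean average precision over categories
#'
#' @param scores Numeric matrix, clips x categories.
#' @param labels Binary matrix of the same shape.
#' @param exclude Character or integer vector of categories to drop from the
#'   macro average (e.g. music-related categories in the ablation analysis).
#' @return A list of class `metric_report` with `per_category` APs, the macro
#'   `map` over included categories, and the `included` mask. Categories
#'   without positives get `NA` and are excluded from the mean.
#' @export
map_score <- function(scores, labels, exclude = NULL) {
  stopifnot(is.matrix(scores), is.matrix(labels),
            all(dim(scores) == dim(labels)))
  cats <- colnames(scores)
  if (is.null(cats)) cats <- paste0("cat", seq_len(ncol(scores)))
  included <- rep(TRUE, ncol(scores))
  if (!is.null(exclude)) {
    if (is.character(exclude)) included[cats %in% exclude] <- FALSE
    else included[exclude] <- FALSE
  }
  ap <- vapply(seq_len(ncol(scores)), function(j) {
    if (sum(labels[, j]) == 0) return(NA_real_)
    average_precision(scores[, j], labels[, j])
  }, numeric(1))
  names(ap) <- cats
  use <- included & !is.na(ap)
  structure(list(per_category = ap, map = mean(ap[use]), included = included),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report: mAP = %.4f over %d categories>\n",
              x$map, sum(x$included & !is.na(x$per_category))))
  invisible(x)
}

#' Wilcoxon rank-sum and signed-rank tests
#'
#' Thin wrapper around [stats::wilcox.test()] that fixes the conventions
#' used throughout the analyses: the reported statistic `U` is the
#' Mann-Whitney U of the first sample (rank-sum of `a` minus
#' `n_a(n_a+1)/2`), so complete separation of two samples of five gives
#' `U = 25`; for the signed-rank mode it is the positive-rank sum `V`.
#' One-tailed tests are in the direction `a > b`. The exact null
#' distribution is used when both samples have at most `exact_n`
#' observations and no ties are present; otherwise the normal approximation
#' with continuity correction is used, and the `method` field records which.
#' The common-language effect size accompanies every outcome.
#'
#' @param a,b Numeric samples; for `signed-rank` they must be paired and of
#'   equal length (`b` may be a single reference value for a one-sample
#'   test).
#' @param mode `"rank-sum"` (independent samples) or `"signed-rank"`.
#' @param tail `"one"` (a greater than b) or `"two"`.
#' @param exact_n Largest per-group size for exact p-value computation.
#' @return A list of class `test_outcome`: `statistic`, `p.value`, `tail`,
#'   `mode`, `method`, `effect_size`, `n`, and a `degenerate` flag (set when
#'   all paired differences are zero, in which case `p.value` is `NA`).
#' @export
wilcoxon_tests <- function(a, b, mode = c("rank-sum", "signed-rank"),
                           tail = c("one", "two"), exact_n = 10L) {
  mode <- match.arg(mode); tail <- match.arg(tail)
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  alternative <- if (tail == "one") "greater" else "two.sided"
  if (mode == "rank-sum") {
    ranks <- rank(c(a, b))
    u <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
    ties <- any(duplicated(c(a, b)))
    use_exact <- length(a) <= exact_n && length(b) <= exact_n && !ties
    ht <- suppressWarnings(stats::wilcox.test(
      a, b, alternative = alternative, exact = use_exact, correct = TRUE))
    es <- common_language_es(a, b)
    structure(list(statistic = unname(u), p.value = ht$p.value, tail = tail,
                   mode = mode,
                   method = if (use_exact) "exact" else "normal-approximation",
                   effect_size = es, n = c(n_a = length(a), n_b = length(b)),
                   degenerate = FALSE),
              class = "test_outcome")
  } else {
    if (length(b) == 1L) b <- rep(b, length(a))
    if (length(a) != length(b)) stop("signed-rank requires paired samples")
    d <- a - b
    if (all(d == 0)) {
      return(structure(list(statistic = NA_real_, p.value = NA_real_,
                            tail = tail, mode = mode, method = "degenerate",
                            effect_size = 0.5,
                            n = c(n = length(a)), degenerate = TRUE),
                       class = "test_outcome"))
    }
    dz <- d[d != 0]
    v <- sum(rank(abs(dz))[dz > 0])
    ties <- any(duplicated(abs(dz)))
    use_exact <- length(dz) <= exact_n && !ties
    ht <- suppressWarnings(stats::wilcox.test(
      a, b, paired = TRUE, alternative = alternative, exact = use_exact,
      correct = TRUE))
    es <- mean(d > 0) + 0.5 * mean(d == 0)
    structure(list(statistic = unname(v), p.value = ht$p.value, tail = tail,
                   mode = mode,
                   method = if (use_exact) "exact" else "normal-approximation",
                   effect_size = es, n = c(n = length(a)),
                   degenerate = FALSE),
              class = "test_outcome")
  }
}

#' @export
print.test_outcome <- function(x, ...) {
  cat(sprintf("<%s Wilcoxon %s: U = %s, p = %s (%s), ES = %.3f>\n",
              x$tail, x$mode, format(x$statistic), format.pval(x$p.value),
              x$method, x$effect_size))
  invisible(x)
}

#' Common-language effect size
#'
#' The probability that a value sampled from `a` exceeds a value sampled
#' from `b`; ties count half. Computed from the joint ranking, so it is
#' `U / (n_a n_b)` with midranks and costs `O(n log n)`.
#'
#' @param a,b Numeric samples.
#' @return Effect size in `[0, 1]`; 0.5 means stochastically equal samples.
#' @export
common_language_es <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  ranks <- rank(c(a, b))
  u <- sum(ranks[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  u / (length(a) * length(b))
}
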