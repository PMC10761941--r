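# Linear read-outs of feature spaces and the unit-ablation experiment.

#' Linear classification probe
#'
#' Fits a least-squares linear score (optionally ridge-penalized) on 0/1
#' targets using the training features only, scores the held-out features,
#' and evaluates the ranking with average precision; no threshold is
#' involved. Feature sets can be concatenated by `cbind`-ing them before
#' the call.
#'
#' @param x_train,x_test Feature matrices (clips x features), clip-disjoint.
#' @param y_train,y_test Binary labels (0/1 or logical).
#' @param ridge Ridge penalty (default 0 = ordinary least squares).
#' @param intercept Include an intercept term.
#' @return A list of class `probe_result`: `ap`, `weights`, `scores`,
#'   `n_train`, `n_test`.
#' @export
linear_probe <- function(x_train, y_train, x_test, y_test, ridge = 0,
                         intercept = TRUE) {
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  y_train <- as.numeric(y_train); y_test <- as.numeric(y_test)
  stopifnot(nrow(x_train) == length(y_train),
            nrow(x_test) == length(y_test),
            ncol(x_train) == ncol(x_test))
  if (any(apply(x_train, 2, stats::sd) == 0))
    warning("constant feature column(s) in the probe design")
  X <- if (intercept) cbind(1, x_train) else x_train
  if (ridge > 0) {
    P <- diag(ncol(X)) * ridge
    if (intercept) P[1, 1] <- 0
    beta <- solve(crossprod(X) + P, crossprod(X, y_train))
  } else {
    fit <- stats::lm.fit(X, y_train)
    beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
  }
  Xt <- if (intercept) cbind(1, x_test) else x_test
  scores <- as.numeric(Xt %*% beta)
  structure(list(ap = average_precision(scores, y_test),
                 weights = as.numeric(beta), scores = scores,
                 n_train = nrow(x_train), n_test = nrow(x_test)),
            class = "probe_result")
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("<probe_result: AP = %.4f (%d train / %d test clips)>\n",
              x$ap, x$n_train, x$n_test))
  invisible(x)
}

#' t-SNE embedding of a feature matrix
#'
#' Seeded 2-D t-distributed stochastic neighbor embedding (via
#' [Rtsne::Rtsne()], exact mode). Duplicate feature rows are degenerate for
#' t-SNE; by default they raise an error, or are broken with tiny seeded
#' jitter when `jitter_duplicates = TRUE`.
#'
#' @param features Feature matrix (clips x units), at least 10 rows.
#' @param perplexity t-SNE perplexity.
#' @param seed Integer seed (same seed, same coordinates).
#' @param max_iter Gradient-descent iterations.
#' @param jitter_duplicates Jitter policy for duplicated rows.
#' @return Matrix `n x 2` of embedding coordinates.
#' @export
tsne_embed <- function(features, perplexity = 10, seed = 1L, max_iter = 500,
                       jitter_duplicates = FALSE) {
  features <- as.matrix(features)
  if (nrow(features) < 10L) stop("need at least 10 rows to embed")
  if (anyDuplicated(features)) {
    if (!jitter_duplicates)
      stop("duplicated feature rows; set jitter_duplicates = TRUE to ",
           "break them with seeded jitter")
    features <- with_seed(seed, features +
                            matrix(stats::rnorm(length(features), 0, 1e-8),
                                   nrow(features)))
  }
  coords <- with_seed(seed,
    Rtsne::Rtsne(features, dims = 2, perplexity = perplexity,
                 theta = 0, max_iter = max_iter, pca = FALSE,
                 check_duplicates = FALSE)$Y)
  coords
}

#' Silhouette separation of a labeled embedding
#'
#' Mean silhouette width (via [cluster::silhouette()]) of a binary clip
#' grouping in embedding space; the quantitative summary of cluster
#' separation used instead of visual inspection.
#'
#' @param coords Embedding coordinates (n x 2).
#' @param labels Binary or factor-like group labels, one per row.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
embedding_silhouette <- function(coords, labels) {
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) stop("need at least two groups")
  mean(cluster::silhouette(cl, stats::dist(coords))[, "sil_width"])
}

#' Ablate a unit group
#'
#' Returns a model whose pooled-feature outputs are zeroed at the group's
#' indices; every other computation is unchanged. Ablations compose: ablating
#' G then H equals ablating their union.
#'
#' @param model A `tagger_model`.
#' @param group A `unit_group` or integer vector of unit indices (may be
#'   empty).
#' @return The ablated `tagger_model`.
#' @export
ablate <- function(model, group) {
  stopifnot(inherits(model, "tagger_model"))
  idx <- as.integer(group)
  if (length(idx) && (min(idx) < 1L || max(idx) > model$arch$feature_dim))
    stop("unit indices out of range 1..", model$arch$feature_dim)
  model$ablated <- sort(unique(c(model$ablated, idx)))
  model
}

#' Detection performance after ablating unit groups
#'
#' Evaluates held-out detection mAP for the unablated baseline and for the
#' model with each unit group silenced. Music-related categories can be
#' excluded from the macro average (the convention of the ablation
#' analysis, which asks what the units contribute to *non-music*
#' detection). Per-category APs are retained for paired significance
#' testing.
#'
#' @param model A trained `tagger_model`.
#' @param x Evaluation input array (held-out split).
#' @param y Binary label matrix with category column names.
#' @param groups Named list of `unit_group`s (a `"none"` baseline row is
#'   always included first).
#' @param exclude Categories excluded from the macro average.
#' @param which Weight set, as in [extract_features()].
#' @return A data frame of class `ablation_result` with columns `group` and
#'   `map`, and attribute `per_category` (matrix groups x categories).
#' @export
ablation_experiment <- function(model, x, y, groups, exclude = NULL,
                                which = "best") {
  stopifnot(inherits(model, "tagger_model"), is.list(groups))
  feats <- extract_features(model, x, which = which)
  run <- c(list(none = integer(0)), groups)
  res <- lapply(run, function(g) {
    f <- feats
    if (length(g)) f[, as.integer(g)] <- 0
    scores <- detect(model, f, features = TRUE, which = which)
    colnames(scores) <- colnames(y)
    map_score(scores, y, exclude = exclude)
  })
  out <- data.frame(group = names(run),
                    map = vapply(res, `[[`, numeric(1), "map"))
  rownames(out) <- NULL
  attr(out, "per_category") <- do.call(rbind, lapply(res, `[[`,
                                                     "per_category"))
  class(out) <- c("ablation_result", "data.frame")
  out
}
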