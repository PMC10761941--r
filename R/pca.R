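#' PCA features of log-Mel spectrograms
#'
#' Fits a principal-component basis on the vectorized training spectrograms
#' only (via [stats::prcomp()]) and projects both training and test
#' spectrograms onto the same basis; the linear baseline corresponding to
#' the top principal components of the time-frequency representation.
#'
#' @param train List of `log_mel` objects (or matrices) used to fit the
#'   basis.
#' @param n_components Number of components requested; reduced with a
#'   warning if the training data have lower rank.
#' @param test Optional list of spectrograms to project with the fitted
#'   basis.
#' @return A list of class `pca_features`: `basis` (columns are
#'   orthonormal loadings), `center`, `train_scores`, `test_scores`,
#'   `explained_variance` (per-component fractions) and `n_components`.
#' @export
pca_features <- function(train, n_components = 256, test = NULL) {
  as_row <- function(s) as.vector(if (inherits(s, "log_mel")) s$values else s)
  x <- do.call(rbind, lapply(train, as_row))
  if (nrow(x) < 2L) stop("need at least 2 training spectrograms")
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n_components > max_rank) {
    warning("rank deficiency: reducing n_components from ", n_components,
            " to ", max_rank)
    n_components <- max_rank
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  out <- list(basis = pc$rotation, center = pc$center,
              train_scores = pc$x[, seq_len(n_components), drop = FALSE],
              test_scores = NULL,
              explained_variance = ev[seq_len(n_components)],
              n_components = n_components)
  if (!is.null(test)) {
    xt <- do.call(rbind, lapply(test, as_row))
    out$test_scores <- sweep(xt, 2, pc$center) %*% pc$rotation
  }
  structure(out, class = "pca_features")
}

#' @export
print.pca_features <- function(x, ...) {
  cat(sprintf("<pca_features: %d components, explained variance %.3f>\n",
              x$n_components, sum(x$explained_variance)))
  invisible(x)
}
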