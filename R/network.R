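#' Tagger architecture configuration
#'
#' Four convolutional blocks by default, each a 3x3 convolution followed by
#' batch normalization, ReLU, 2x2 max pooling and dropout; the channel count
#' of the final block is the feature dimension read out by global average
#' pooling, followed by two fully connected layers and per-category sigmoid
#' outputs. The default channel progression (64, 128, 256, 256) yields the
#' reference 256-dimensional pooled feature layer; smaller progressions are
#' used for desk-scale experiments.
#'
#' @param channels Integer vector of per-block output channels; the last
#'   entry is the pooled feature dimension.
#' @param pool Per-block max-pooling sizes: a list of `(rows, cols)` pairs
#'   (mel x time), recycled to the number of blocks. Time-preserving pools
#'   (`c(2, 1)`) in late blocks keep enough spatial cells under the global
#'   average for dropout noise to stay small and for temporal structure to
#'   reach the feature layer when inputs are short.
#' @param dropout Dropout proportion after each pooling layer.
#' @param fc_hidden Width of the hidden fully connected layer.
#' @param n_categories Number of output categories (sigmoid heads).
#' @param n_mels Input mel-band count.
#' @return A list of class `arch_config`.
#' @export
arch_config <- function(channels = c(64, 128, 256, 256),
                        pool = list(c(2, 2)), dropout = 0.2,
                        fc_hidden = 256, n_categories = 9, n_mels = 64) {
  if (length(channels) < 1L || any(channels < 1))
    stop("channels must be a positive integer vector")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  if (n_categories < 1) stop("n_categories must be at least 1")
  pool <- rep(pool, length.out = length(channels))
  pool_h <- vapply(pool, `[`, numeric(1), 1L)
  pool_w <- vapply(pool, `[`, numeric(1), 2L)
  if (any(pool_h < 1) || any(pool_w < 1)) stop("pool sizes must be >= 1")
  structure(list(channels = as.integer(channels),
                 pool_h = as.integer(pool_h), pool_w = as.integer(pool_w),
                 dropout = dropout,
                 fc_hidden = as.integer(fc_hidden),
                 n_categories = as.integer(n_categories),
                 n_mels = as.integer(n_mels),
                 feature_dim = as.integer(channels[length(channels)])),
            class = "arch_config")
}

#' Training configuration
#'
#' AdamW with decoupled weight decay and a one-cycle learning-rate schedule:
#' the rate is annealed linearly from the initial to the maximum value over
#' the warm-up epochs and then linearly down to the minimum over the
#' remaining epochs (interpolated per optimization step).
#'
#' @param epochs Training epochs (use ~2x for the randomized-label
#'   memorization control).
#' @param batch_size Mini-batch size.
#' @param lr_init,lr_max,lr_min One-cycle anchors: initial, maximum (reached
#'   at the end of warm-up) and final learning rate.
#' @param warmup_epochs Epochs of the rising phase.
#' @param weight_decay Decoupled weight decay on convolutional and fully
#'   connected weights.
#' @param val_fraction Fraction of the training clips held out for
#'   validation-based epoch selection, in (0, 1).
#' @param seed Integer seed controlling initialization, data order, the
#'   validation split and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 100, batch_size = 32, lr_init = 4e-5,
                         lr_max = 1e-3, lr_min = 4e-9, warmup_epochs = 30,
                         weight_decay = 0.01, val_fraction = 0.1, seed = 1L) {
  if (val_fraction <= 0 || val_fraction >= 1)
    stop("val_fraction must be in (0, 1)")
  if (warmup_epochs >= epochs) stop("warmup must be shorter than training")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 lr_init = lr_init, lr_max = lr_max, lr_min = lr_min,
                 warmup_epochs = warmup_epochs, weight_decay = weight_decay,
                 val_fraction = val_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' One-cycle learning rate at a given epoch
#'
#' Piecewise-linear schedule: `lr_init` at epoch 0, `lr_max` at the end of
#' warm-up, `lr_min` at the final epoch. Fractional epochs give the
#' per-step interpolation used during training.
#'
#' @param epoch Epoch index (0-based; may be fractional), in
#'   `[0, epochs - 1]`.
#' @param config A [train_config()].
#' @return Learning rate(s) at `epoch`.
#' @export
one_cycle_lr <- function(epoch, config = train_config()) {
  if (any(epoch < 0) || any(epoch > config$epochs - 1L))
    stop("epoch out of range [0, epochs - 1]")
  w <- config$warmup_epochs
  last <- config$epochs - 1L
  ifelse(epoch <= w,
         config$lr_init + (config$lr_max - config$lr_init) * epoch / w,
         config$lr_max + (config$lr_min - config$lr_max) *
           (epoch - w) / (last - w))
}

#' Binary cross-entropy loss
#'
#' `-[y log x + (1 - y) log(1 - x)]` per category, averaged over all
#' entries. Predictions are clamped to `[clamp, 1 - clamp]` before the
#' logarithm; values outside `[0, 1]` are a domain error.
#'
#' @param x Predicted probabilities in `[0, 1]`.
#' @param y Binary targets of the same shape.
#' @param clamp Clamping offset applied inside the unit interval.
#' @return Mean loss (non-negative scalar).
#' @export
bce_loss <- function(x, y, clamp = 1e-7) {
  if (any(x < 0) || any(x > 1))
    stop("predictions must lie in [0, 1]")
  if (!all(y %in% c(0, 1))) stop("targets must be binary")
  if (length(x) != length(y)) stop("shape mismatch")
  x <- pmin(1 - clamp, pmax(clamp, x))
  mean(-(y * log(x) + (1 - y) * log(1 - x)))
}

#' Build (and randomly initialize) a tagger network
#'
#' Returns an untrained model with He-initialized weights; usable directly
#' as the random-initialization baseline, or passed to [train_tagger()].
#'
#' @param arch An [arch_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `tagger_model`.
#' @export
build_tagger <- function(arch = arch_config(), seed = 1L) {
  stopifnot(inherits(arch, "arch_config"))
  w <- cnn_init(unclass(arch), as.integer(seed))
  structure(list(arch = arch, weights = w, trained = FALSE,
                 categories = NULL, history = NULL, best_epoch = NA_integer_,
                 ablated = integer(0), init_seed = as.integer(seed)),
            class = "tagger_model")
}

#' @export
print.tagger_model <- function(x, ...) {
  cat(sprintf("<tagger_model: %s channels, %d-d features, %s%s>\n",
              paste(x$arch$channels, collapse = "-"), x$arch$feature_dim,
              if (x$trained) "trained" else "untrained",
              if (length(x$ablated)) sprintf(", %d units ablated",
                                             length(x$ablated)) else ""))
  invisible(x)
}

#' Stack log-Mel spectrograms into a network input array
#'
#' @param specs List of `log_mel` objects (all with equal frame counts).
#' @param time_pool Optional time-pooling factor applied per spectrogram
#'   (see [time_pool_log_mel()]).
#' @return A numeric array `n_mels x T x n_clips`.
#' @export
stack_spectrograms <- function(specs, time_pool = 1L) {
  specs <- lapply(specs, time_pool_log_mel, factor = time_pool)
  dims <- vapply(specs, function(s) dim(s$values), integer(2))
  if (length(unique(dims[2, ])) != 1L)
    stop("all spectrograms must have the same number of frames")
  array(unlist(lapply(specs, `[[`, "values")),
        dim = c(dims[1, 1], dims[2, 1], length(specs)))
}

#' Train the tagger on a labeled spectrogram set
#'
#' Splits the clips into training and validation subsets (disjoint by clip,
#' seeded), runs AdamW with the one-cycle schedule, and records per-epoch
#' training loss, training mAP (accumulated over the training passes) and
#' validation mAP (clean forward passes). The returned model carries both
#' the weights of the epoch with the highest validation mAP (used by
#' default) and the final-epoch weights (used for the memorization control,
#' whose validation score is meaningless by construction).
#'
#' @param model A [build_tagger()] model.
#' @param x Input array `n_mels x T x n` from [stack_spectrograms()].
#' @param y Binary label matrix `n x n_categories` with category column
#'   names.
#' @param config A [train_config()].
#' @return The trained `tagger_model` with `history`, `best_epoch`,
#'   `weights` (best validation epoch) and `weights_final`.
#' @export
train_tagger <- function(model, x, y, config = train_config()) {
  stopifnot(inherits(model, "tagger_model"), inherits(config, "train_config"))
  if (!is.array(x) || length(dim(x)) != 3L) stop("x must be a 3-d array")
  n <- dim(x)[3]
  if (n == 0L || is.null(y) || nrow(y) != n)
    stop("labels must match the number of clips")
  if (ncol(y) != model$arch$n_categories)
    stop("label columns (", ncol(y), ") do not match n_categories (",
         model$arch$n_categories, ")")
  n_val <- max(1L, round(config$val_fraction * n))
  if (n_val >= n) stop("not enough clips for a validation split")
  val_idx <- with_seed(config$seed + 7L, sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  steps_per_epoch <- ceiling(length(tr_idx) / config$batch_size)
  total_steps <- steps_per_epoch * config$epochs
  frac_epoch <- pmin((seq_len(total_steps) - 1) / steps_per_epoch,
                     config$epochs - 1L)
  lr_steps <- one_cycle_lr(frac_epoch, config)
  fit <- cnn_train(x[, , tr_idx, drop = FALSE],
                   y[tr_idx, , drop = FALSE],
                   x[, , val_idx, drop = FALSE],
                   y[val_idx, , drop = FALSE],
                   unclass(model$arch), model$weights, lr_steps,
                   config$epochs, config$batch_size, config$weight_decay,
                   config$seed)
  model$weights <- fit$weights_best
  model$weights_final <- fit$weights_final
  model$history <- fit$history
  model$best_epoch <- fit$best_epoch
  model$trained <- TRUE
  model$categories <- colnames(y)
  model$train_config <- config
  model$val_idx <- val_idx
  model
}

#' Extract pooled feature vectors
#'
#' Responses of the global-average-pooling layer (post-ReLU averages, hence
#' non-negative) for every clip; the unit responses analyzed by the
#' selectivity machinery. Works identically for trained and untrained
#' (random-initialization) models. Ablated units, if any, are zeroed.
#'
#' @param model A `tagger_model`.
#' @param x Input array `n_mels x T x n`.
#' @param which `"best"` (validation-selected weights, the default) or
#'   `"final"` (last epoch; the memorization convention).
#' @return Matrix `n x feature_dim`.
#' @export
extract_features <- function(model, x, which = c("best", "final")) {
  stopifnot(inherits(model, "tagger_model"))
  which <- match.arg(which)
  w <- if (which == "final" && !is.null(model$weights_final))
    model$weights_final else model$weights
  f <- cnn_features(x, unclass(model$arch), w)
  if (length(model$ablated)) f[, model$ablated] <- 0
  f
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Per-category detection probabilities
#'
#' Applies the fully connected read-out to the pooled features; each
#' category gets an independent sigmoid probability (multi-label: the
#' outputs do not sum to 1). Respects ablation masks.
#'
#' @param model A `tagger_model`.
#' @param x Input array, or a feature matrix from [extract_features()]
#'   (`features = TRUE`).
#' @param features Set to `TRUE` when `x` is already a feature matrix.
#' @param which Weight set, as in [extract_features()].
#' @return Matrix `n x n_categories` of probabilities in (0, 1), with
#'   category column names when known.
#' @export
detect <- function(model, x, features = FALSE, which = c("best", "final")) {
  stopifnot(inherits(model, "tagger_model"))
  which <- match.arg(which)
  f <- if (features) {
    f0 <- as.matrix(x)
    if (ncol(f0) != model$arch$feature_dim)
      stop("feature matrix width does not match the model's feature_dim")
    if (length(model$ablated)) f0[, model$ablated] <- 0
    f0
  } else {
    extract_features(model, x, which = which)
  }
  w <- if (which == "final" && !is.null(model$weights_final))
    model$weights_final else model$weights
  h <- pmax(f %*% t(w$fc1_W) + rep(w$fc1_b[, 1], each = nrow(f)), 0)
  p <- sigmoid(h %*% t(w$fc2_W) + rep(w$fc2_b[, 1], each = nrow(f)))
  colnames(p) <- model$categories
  p
}
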