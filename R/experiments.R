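# Seeded end-to-end experiment runners reproducing the desk-scale analogues
# of the main analyses: emergence of music-selective units in a network
# trained without music, the randomized-label memorization control, sound-
# quilt response curves, and the unit-ablation comparison.

#' Default desk-scale study settings
#'
#' Problem sizes chosen so the full study (data synthesis, training of the
#' generalization and memorization networks, quilting and ablation) runs in
#' a few minutes on one CPU while preserving the structure of the original
#' analyses: 10 categories at 24 label appearances each (about 190 clips
#' including mixed and multi-event rows), a 4-block network with 128 pooled
#' feature units (top 12.5% = 16 units), 100-frame time-pooled inputs, 40
#' training epochs (200 for the memorization control, which fits random
#' labels and needs the longer budget).
#'
#' @param clips_per_category,mixed_fraction Passed to [synth_config()].
#' @param channels,pool,fc_hidden Passed to [arch_config()].
#' @param epochs,epochs_memorization Training epochs for the generalization
#'   and memorization networks.
#' @param warmup_fraction Fraction of epochs in the one-cycle rising phase.
#' @param batch_size Mini-batch size.
#' @param time_pool Spectrogram time-pooling factor (8: 100 input frames).
#' @param n_quilt_sources Music clips quilted per curve.
#' @param segment_lengths Quilt segment lengths in ms.
#' @return A list of class `study_config`.
#' @export
study_config <- function(clips_per_category = 24, mixed_fraction = 0.05,
                         channels = c(12, 32, 64, 128),
                         pool = list(c(2, 2), c(2, 2), c(2, 1), c(2, 1)),
                         fc_hidden = 128,
                         epochs = 40, epochs_memorization = 200,
                         warmup_fraction = 0.3, batch_size = 8,
                         time_pool = 8, n_quilt_sources = 8,
                         segment_lengths = c(50, 100, 200, 400, 800, 1600)) {
  structure(as.list(environment()), class = "study_config")
}

#' Generate the study dataset and network inputs
#'
#' @param seed Integer seed.
#' @param config A [study_config()].
#' @return A list with the `sound_dataset`, the input array `x`
#'   (time-pooled spectrograms), the full multi-hot label matrix `y`, the
#'   clip `groups`, `split` assignments, and the frontend used.
#' @export
prepare_study_data <- function(seed = 1L, config = study_config()) {
  sc <- synth_config(clips_per_category = config$clips_per_category,
                     mixed_fraction = config$mixed_fraction, seed = seed)
  dataset <- generate_dataset(sc)
  frontend <- frontend_config(sample_rate = sc$sample_rate)
  specs <- lapply(dataset$clips, to_log_mel, config = frontend)
  x <- stack_spectrograms(specs, time_pool = config$time_pool)
  cats <- sc$categories
  labs <- split_labels(dataset$manifest$labels)
  y <- t(vapply(labs, function(l) as.numeric(cats %in% l),
                numeric(length(cats))))
  colnames(y) <- cats
  list(dataset = dataset, x = x, y = y,
       groups = dataset$manifest$group,
       split = dataset$manifest$split,
       categories = cats, music_categories = sc$music_categories,
       frontend = frontend, synth = sc, config = config)
}

label_matrix <- function(manifest, categories) {
  labs <- split_labels(manifest$labels)
  y <- t(vapply(labs, function(l) as.numeric(categories %in% l),
                numeric(length(categories))))
  colnames(y) <- categories
  y
}

#' Train the generalization network (no music in training)
#'
#' Removes every music-related and mixed clip from the training split,
#' drops the music-related categories from the label space, and trains the
#' study network on what remains -- the "trained without music" condition.
#'
#' @param data From [prepare_study_data()].
#' @param seed Integer seed (initialization and training).
#' @return A trained `tagger_model` over the non-music categories.
#' @export
train_generalization_network <- function(data, seed = 1L) {
  cfg <- data$config
  nm_cats <- setdiff(data$categories, data$music_categories)
  tr <- data$split == "train" & data$groups == "non-music"
  y_tr <- data$y[tr, nm_cats, drop = FALSE]
  arch <- arch_config(channels = cfg$channels, pool = cfg$pool,
                      fc_hidden = cfg$fc_hidden,
                      n_categories = length(nm_cats))
  model <- build_tagger(arch, seed = seed)
  tc <- train_config(epochs = cfg$epochs, batch_size = cfg$batch_size,
                     warmup_epochs = round(cfg$warmup_fraction * cfg$epochs),
                     seed = seed)
  train_tagger(model, data$x[, , tr, drop = FALSE], y_tr, tc)
}

#' Train the memorization network (randomized labels)
#'
#' Randomly permutes the label sets within the training split (destroying
#' the sound-label association while preserving the label statistics) and
#' trains over the full category space for twice the usual epochs. The
#' final-epoch weights are the relevant ones: validation selection is
#' meaningless when held-out labels are noise.
#'
#' @param data From [prepare_study_data()].
#' @param seed Integer seed.
#' @return A list: `model`, the clean final `train_map` on the randomized
#'   training labels, `test_map` on the true held-out labels, and the
#'   held-out `chance` level (mean category prevalence).
#' @export
train_memorization_network <- function(data, seed = 1L) {
  cfg <- data$config
  ds_rand <- randomize_labels(data$dataset, seed = seed + 91L,
                              split = "train")
  tr <- data$split == "train"
  te <- data$split == "test"
  y_rand <- label_matrix(ds_rand$manifest[tr, , drop = FALSE],
                         data$categories)
  arch <- arch_config(channels = cfg$channels, pool = cfg$pool,
                      fc_hidden = cfg$fc_hidden,
                      n_categories = length(data$categories))
  model <- build_tagger(arch, seed = seed)
  ep <- cfg$epochs_memorization
  tc <- train_config(epochs = ep, batch_size = cfg$batch_size,
                     warmup_epochs = round(cfg$warmup_fraction * ep),
                     seed = seed)
  model <- train_tagger(model, data$x[, , tr, drop = FALSE], y_rand, tc)
  # training AP is measured on the clips actually optimized over; the
  # internal validation holdout carries randomized labels the network never
  # saw, which are unlearnable by construction
  fit_idx <- setdiff(seq_len(sum(tr)), model$val_idx)
  x_tr <- data$x[, , tr, drop = FALSE]
  train_scores <- detect(model, x_tr[, , fit_idx, drop = FALSE],
                         which = "final")
  test_scores <- detect(model, data$x[, , te, drop = FALSE],
                        which = "final")
  y_test <- data$y[te, , drop = FALSE]
  list(model = model,
       train_map = map_score(train_scores,
                             y_rand[fit_idx, , drop = FALSE])$map,
       test_map = map_score(test_scores, y_test)$map,
       chance = mean(colMeans(y_test)))
}

# Selectivity profile, unit groups, response ratio and probe APs for one
# model: identification on the test split, evaluation on the train split.
selectivity_summary <- function(model, data, which = "best",
                                fraction = 0.125) {
  te <- data$split == "test"
  tr <- data$split == "train"
  feats_te <- extract_features(model, data$x[, , te, drop = FALSE],
                               which = which)
  feats_tr <- extract_features(model, data$x[, , tr, drop = FALSE],
                               which = which)
  profile <- selectivity_profile(feats_te, data$groups[te],
                                 positive = "music")
  groups <- list(
    top = select_group(profile, fraction, "top"),
    mid = select_group(profile, which = "band",
                       band = c(0.5 - fraction / 2, 0.5 + fraction / 2)),
    bottom = select_group(profile, fraction, "bottom"),
    l1 = select_group_l1(feats_te, fraction))
  ratio_top <- response_ratio(feats_tr, groups$top, data$groups[tr])
  probe_ap <- function(units) {
    keep_tr <- data$groups[tr] != "mixed"
    keep_te <- data$groups[te] != "mixed"
    linear_probe(feats_tr[keep_tr, units, drop = FALSE],
                 (data$groups[tr] == "music")[keep_tr],
                 feats_te[keep_te, units, drop = FALSE],
                 (data$groups[te] == "music")[keep_te])$ap
  }
  list(profile = profile, groups = groups, ratio_top = ratio_top,
       probe_top_ap = probe_ap(groups$top),
       probe_mid_ap = probe_ap(groups$mid),
       features_train = feats_tr, features_test = feats_te)
}

# Quilt curves for several (model, group) conditions sharing the same
# rendered quilts, normalized within each condition by the response to the
# originals (truncated and padded like the quilts).
quilt_curves_shared <- function(conditions, sources, segment_lengths,
                                seed, frontend, time_pool,
                                content_s = 8, duration_s = 10) {
  originals <- lapply(sources, function(cl) {
    n_content <- round(content_s * cl$sample_rate)
    n_total <- round(duration_s * cl$sample_rate)
    x <- cl$samples[seq_len(min(n_content, length(cl$samples)))]
    audio_clip(c(x, numeric(n_total - length(x))), cl$sample_rate, cl$id)
  })
  x_orig <- stack_spectrograms(lapply(originals, to_log_mel,
                                      config = frontend), time_pool)
  x_quilt <- lapply(segment_lengths, function(ms) {
    quilts <- lapply(seq_along(sources), function(i)
      quilt_clip(sources[[i]], ms, seed = seed + i, frontend = frontend,
                 content_s = content_s, duration_s = duration_s))
    stack_spectrograms(lapply(quilts, to_log_mel, config = frontend),
                       time_pool)
  })
  out <- lapply(names(conditions), function(nm) {
    cond <- conditions[[nm]]
    which <- cond$which %||% "best"
    gmean <- function(x) {
      f <- extract_features(cond$model, x, which = which)
      rowMeans(f[, cond$group, drop = FALSE])
    }
    orig_resp <- gmean(x_orig)
    base <- mean(orig_resp)
    rows <- lapply(seq_along(segment_lengths), function(k) {
      r <- gmean(x_quilt[[k]]) / base
      data.frame(condition = nm, segment_ms = segment_lengths[k],
                 response = mean(r), sd = stats::sd(r))
    })
    rbind(do.call(rbind, rows),
          data.frame(condition = nm, segment_ms = NA_real_,
                     response = mean(orig_resp / base),
                     sd = stats::sd(orig_resp / base)))
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full desk-scale study for one seed
#'
#' Generates the dataset, trains the generalization network (without
#' music), builds the random-initialization baseline, optionally trains the
#' memorization network, computes selectivity profiles and unit groups
#' (identified on the test split), music/non-music response ratios and
#' probe APs (evaluated on the train split), quilt response curves (music
#' sources from the train split, independent of the identification data)
#' and the unit-ablation comparison (held-out split, music categories
#' excluded from the performance measure).
#'
#' @param seed Integer seed driving every stage.
#' @param config A [study_config()].
#' @param do_memorization,do_quilts,do_ablation Stage toggles.
#' @return A list of class `study_result` with elements `data`, `gen`,
#'   `rnd`, `mem`, `quilts`, `ablation`.
#' @export
run_study <- function(seed = 1L, config = study_config(),
                      do_memorization = TRUE, do_quilts = TRUE,
                      do_ablation = TRUE) {
  data <- prepare_study_data(seed, config)
  gen_model <- train_generalization_network(data, seed = seed)
  gen <- selectivity_summary(gen_model, data)
  gen$model <- gen_model
  rnd_model <- build_tagger(gen_model$arch, seed = seed + 1000L)
  rnd <- selectivity_summary(rnd_model, data)
  rnd$model <- rnd_model
  mem <- NULL
  if (do_memorization) {
    mem <- train_memorization_network(data, seed = seed)
    mem_sel <- selectivity_summary(mem$model, data, which = "final")
    mem$profile <- mem_sel$profile
    mem$groups <- mem_sel$groups
  }
  quilts <- NULL
  if (do_quilts) {
    tr_music <- which(data$split == "train" & data$groups == "music")
    take <- tr_music[seq_len(min(config$n_quilt_sources, length(tr_music)))]
    sources <- data$dataset$clips[take]
    conditions <- list(
      gen_ms = list(model = gen_model, group = gen$groups$top),
      gen_mid = list(model = gen_model, group = gen$groups$mid),
      rnd_ms = list(model = rnd_model, group = rnd$groups$top))
    if (do_memorization)
      conditions$mem_ms <- list(model = mem$model, group = mem$groups$top,
                                which = "final")
    quilts <- quilt_curves_shared(conditions, sources,
                                  config$segment_lengths, seed,
                                  data$frontend, config$time_pool)
  }
  ablation <- NULL
  if (do_ablation) {
    # evaluate on the held-out non-music clips: the ablation question is
    # what the units contribute to *natural-sound* detection, and at desk
    # scale music clips would otherwise make up ~20% of every category's
    # negatives, so the measure would be dominated by false-positive
    # relief on music rather than by information loss
    te <- data$split == "test" & data$groups == "non-music"
    ablation <- ablation_experiment(
      gen_model, data$x[, , te, drop = FALSE],
      data$y[te, setdiff(data$categories, data$music_categories),
             drop = FALSE],
      groups = list(msi_top = gen$groups$top, msi_mid = gen$groups$mid,
                    msi_bottom = gen$groups$bottom, l1_top = gen$groups$l1))
  }
  structure(list(seed = seed, config = config, data = data, gen = gen,
                 rnd = rnd, mem = mem, quilts = quilts,
                 ablation = ablation),
            class = "study_result")
}

#' @export
print.study_result <- function(x, ...) {
  cat("<study_result seed", x$seed, ">\n")
  cat(sprintf("  MS response ratio (trained without music): %.3f\n",
              x$gen$ratio_top))
  cat(sprintf("  MS response ratio (random init):           %.3f\n",
              x$rnd$ratio_top))
  cat(sprintf("  probe AP, MSI top vs middle units: %.3f vs %.3f\n",
              x$gen$probe_top_ap, x$gen$probe_mid_ap))
  if (!is.null(x$mem))
    cat(sprintf("  memorization: train mAP %.3f, held-out %.3f (chance %.3f)\n",
                x$mem$train_map, x$mem$test_map, x$mem$chance))
  if (!is.null(x$ablation)) {
    cat("  ablation mAP: ",
        paste(sprintf("%s %.3f", x$ablation$group, x$ablation$map),
              collapse = ", "), "\n")
  }
  invisible(x)
}
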