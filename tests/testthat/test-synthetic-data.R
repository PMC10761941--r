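test_that("generators are bit-deterministic given a seed", {
  a <- generate_music_clip(seed = 7L)
  b <- generate_music_clip(seed = 7L)
  expect_identical(a$samples, b$samples)
  w1 <- generate_nonmusic_clip("water", seed = 3L)
  w2 <- generate_nonmusic_clip("water", seed = 3L)
  expect_identical(w1$samples, w2$samples)
  expect_false(identical(generate_music_clip(seed = 8L)$samples, a$samples))
})

test_that("music clips sit on a beat grid with phrase-scale repetition", {
  # pure-tone pulse train: single partial, flat contour, fixed beat
  params <- music_params(beat_s = 0.5, n_partials = 1, partial_decay = 1,
                         scales = NULL, contour = "flat",
                         decay_frac = 0.2, percussion = 0)
  clip <- generate_music_clip(params, seed = 2L,
                              config = synth_config(noise_floor_db = Inf,
                                                    channel_eq_db = 0))
  # envelope autocorrelation (independent oracle) peaks at the beat period
  lags <- seq(0.15, 0.85, by = 0.05)
  ac <- vapply(lags, function(l)
    oracle_env_autocorr(clip$samples, clip$sample_rate, 0.05, l), numeric(1))
  expect_equal(lags[which.max(ac)], 0.5, tolerance = 1e-9)
  # energy present in at least 90% of 50 ms windows
  env <- clip_envelope(clip, 0.05)
  expect_gte(mean(env > 0.01 * max(env)), 0.9)
})

test_that("quilting destroys long-range structure of music", {
  for (s in 1:3) {
    clip <- generate_music_clip(seed = s)
    lri_orig <- oracle_env_autocorr(clip$samples, clip$sample_rate, 0.05, 2)
    quilt <- quilt_clip(clip, 50, seed = s)
    content <- quilt$samples[seq_len(8 * quilt$sample_rate)]
    lri_quilt <- oracle_env_autocorr(content, quilt$sample_rate, 0.05, 2)
    expect_lt(lri_quilt, lri_orig)
  }
})

test_that("music exceeds every non-music category in phrase-lag structure", {
  n <- 20
  lri_cat <- function(cat) {
    mean(vapply(seq_len(n), function(s) {
      clip <- if (cat %in% c("music", "singing"))
        generate_music_clip(seed = 100 + s)
      else generate_nonmusic_clip(cat, seed = 100 + s)
      long_range_index(clip)
    }, numeric(1)))
  }
  music <- lri_cat("music")
  for (cat in c("speech", "water", "wind", "barks", "ticks", "machinery",
                "chirps", "bells")) {
    expect_lt(lri_cat(cat), music)
  }
})

test_that("stationary noise texture survives 50 ms quilting spectrally", {
  clip <- generate_nonmusic_clip("water", seed = 5L)
  fe <- frontend_config()
  segs <- segment_clip(clip, 50)
  plan <- plan_quilt(segs, to_log_mel(clip, fe), seed = 1L)
  quilt <- render_quilt(segs, plan, junction_ms = 0, align_ms = 0,
                        content_s = 10, duration_s = 10)
  # segment-level mean mel spectrum: average of per-segment analyses
  seg_spectrum <- function(cl) {
    s <- segment_clip(cl, 50)
    rowMeans(vapply(s$segments, function(x)
      rowMeans(exp(to_log_mel(audio_clip(x, cl$sample_rate), fe)$values)),
      numeric(fe$n_mels)))
  }
  orig <- seg_spectrum(clip)
  quil <- seg_spectrum(quilt)
  expect_lt(max(abs(quil - orig) / orig), 0.01)
  # the re-analyzed whole quilt stays close in the occupied bands despite
  # junction-window effects
  po <- rowMeans(exp(to_log_mel(clip, fe)$values))
  pq <- rowMeans(exp(to_log_mel(quilt, fe)$values))
  occupied <- po > 0.05 * max(po)
  expect_lt(max(abs(pq - po)[occupied] / po[occupied]), 0.2)
})

test_that("impulsive trains have exactly rate x duration countable events", {
  clip <- generate_nonmusic_clip("barks", seed = 9L)
  # independent peak finder on the 10 ms envelope
  fn <- round(0.01 * clip$sample_rate)
  nf <- floor(length(clip$samples) / fn)
  env <- sqrt(colMeans(matrix(clip$samples[1:(nf * fn)], nrow = fn)^2))
  thr <- 0.5 * max(env)
  above <- env > thr
  onsets <- which(above & !c(FALSE, above[-length(above)]))
  # merge onsets closer than 100 ms
  events <- sum(diff(c(-100, onsets)) > 10)
  expect_equal(events, nonmusic_params("barks")$rate * 10)
})

test_that("speech-like clips are modulated at the syllable rate", {
  for (s in 1:3) {
    clip <- generate_nonmusic_clip("speech", seed = s)
    env <- clip_envelope(clip, 0.02)   # 50 Hz envelope sampling
    env <- env - mean(env)
    spec <- Mod(stats::fft(env))^2
    freqs <- (seq_along(env) - 1) / length(env) * 50
    band <- freqs > 0.8 & freqs < 12
    peak <- freqs[band][which.max(spec[band])]
    expect_gte(peak, 2)
    expect_lte(peak, 8)
  }
})

test_that("non-music categories are linearly identifiable from band means", {
  # generator-level contract, tested at a sample size adequate for a
  # 64-dimensional linear classifier (pure clips only)
  nm <- c("speech", "water", "wind", "barks", "ticks", "machinery",
          "chirps", "bells")
  sc <- synth_config(categories = c("music", nm),
                     music_categories = "music",
                     clips_per_category = 30, mixed_fraction = 0,
                     overlay_fraction = 0, seed = 7L)
  ds <- generate_dataset(sc)
  fe <- frontend_config()
  keep <- ds$manifest$group == "non-music"
  feat <- t(vapply(ds$clips[keep], function(cl)
    rowMeans(to_log_mel(cl, fe)$values), numeric(64)))
  lab <- factor(vapply(split_labels(ds$manifest$labels[keep]), `[`, "", 1L))
  tr <- ds$manifest$split[keep] == "train"
  fit <- glmnet::glmnet(feat[tr, ], lab[tr], family = "multinomial",
                        alpha = 0, lambda = 0.01)
  pred <- predict(fit, feat[!tr, ], type = "class")
  expect_gt(mean(pred == as.character(lab[!tr])), 0.9)
})

test_that("dataset bookkeeping matches the configuration", {
  base <- list(categories = c("music", "speech", "water", "barks"),
               music_categories = "music", speech_categories = "speech",
               clips_per_category = 10)
  sc0 <- do.call(synth_config, c(base, list(mixed_fraction = 0,
                                            overlay_fraction = 0, seed = 2L)))
  ds0 <- generate_dataset(sc0)
  expect_equal(nrow(ds0$manifest), 40L)
  expect_equal(sum(ds0$manifest$group == "mixed"), 0L)
  sc1 <- do.call(synth_config, c(base, list(mixed_fraction = 0.25,
                                            overlay_fraction = 0, seed = 2L)))
  ds1 <- suppressWarnings(generate_dataset(sc1))
  expect_equal(sum(ds1$manifest$group == "mixed"), 10L)
  # groups obey the label-set rule; ids unique; split disjoint
  labs <- split_labels(ds1$manifest$labels)
  expect_equal(ds1$manifest$group,
               vapply(labs, function(l) {
                 nm <- sum(l %in% "music")
                 if (nm == length(l)) "music"
                 else if (nm == 0) "non-music" else "mixed"
               }, character(1)))
  expect_false(any(duplicated(ds1$manifest$clip_id)))
  expect_setequal(unique(ds1$manifest$split), c("train", "test"))
})

test_that("the same configuration reproduces a byte-identical dataset", {
  # mixed and overlay rows included: their finalization must also be
  # seeded, independent of the session RNG state
  sc <- suppressWarnings(synth_config(
    categories = c("music", "water", "barks"),
    music_categories = "music",
    speech_categories = character(0),
    clips_per_category = 4, mixed_fraction = 0.1,
    overlay_fraction = 0.1, seed = 5L))
  d1 <- tempfile(); d2 <- tempfile()
  ds1 <- generate_dataset(sc, dir = d1)
  stats::runif(13)   # perturb the session RNG between the two builds
  ds2 <- generate_dataset(sc, dir = d2)
  for (f in list.files(d1, pattern = "\\.wav$")) {
    expect_identical(readBin(file.path(d1, f), "raw", 2e6),
                     readBin(file.path(d2, f), "raw", 2e6))
  }
  # manifests agree except for the output paths
  m1 <- ds1$manifest; m2 <- ds2$manifest
  m1$path <- m2$path <- NULL
  expect_identical(m1, m2)
})

test_that("generated clips respect amplitude bounds", {
  sc <- synth_config()
  for (s in 1:5) {
    clip <- generate_music_clip(seed = s, config = sc)
    expect_lte(max(abs(clip$samples)), 1)
    expect_gte(rms(clip), sc$rms_range[1] * 0.7)
    expect_lte(rms(clip), sc$rms_range[2] * 1.01)
  }
})

test_that("excluding music labels empties the training split of music", {
  st <- get_toy_fit()
  ds <- exclude_labels(st$dataset, c("music"))
  tr <- ds$manifest[ds$manifest$split == "train", ]
  expect_false(any(tr$group %in% c("music", "mixed")))
  te_before <- st$dataset$manifest[st$dataset$manifest$split == "test", ]
  te_after <- ds$manifest[ds$manifest$split == "test", ]
  expect_identical(te_before, te_after)
})

test_that("label randomization permutes label sets and is seeded", {
  st <- get_toy_fit()
  man <- st$dataset$manifest
  r1 <- randomize_labels(man, seed = 4L, music_categories = "music")
  r2 <- randomize_labels(man, seed = 4L, music_categories = "music")
  expect_identical(r1, r2)
  expect_setequal(r1$labels, man$labels)
  expect_equal(sort(table(r1$labels)), sort(table(man$labels)))
  one <- randomize_labels(man[1, , drop = FALSE], seed = 1L,
                          music_categories = "music")
  expect_identical(one$labels, man$labels[1])
})

test_that("fixed-point rate of label permutation matches uniform theory", {
  # for n distinct label sets the expected fixed-point count is 1 under a
  # uniform permutation; enumerate n = 4 exactly through many seeds
  man <- data.frame(clip_id = paste0("c", 1:4), path = NA,
                    labels = c("a", "b", "c", "d"),
                    group = "non-music", rms = 0.05,
                    split = "train", clip_seed = 1:4)
  fp <- vapply(1:400, function(s) {
    sum(randomize_labels(man, seed = s,
                         music_categories = "music")$labels == man$labels)
  }, numeric(1))
  expect_equal(mean(fp), 1, tolerance = 0.15)
})
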