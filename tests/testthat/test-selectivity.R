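test_that("the selectivity index is the Welch t statistic", {
  # hand-evaluated case: m_pos 2, m_neg 1, s = 1, n = 100 per group
  set.seed(1)
  pos <- matrix(stats::rnorm(100, 2), ncol = 1)
  neg <- matrix(stats::rnorm(100, 1), ncol = 1)
  pos <- (pos - mean(pos)) / stats::sd(pos) + 2
  neg <- (neg - mean(neg)) / stats::sd(neg) + 1
  expect_equal(selectivity_index(pos, neg)[1], 1 / sqrt(0.02),
               tolerance = 1e-10)
  expect_equal(1 / sqrt(0.02), 7.0711, tolerance = 1e-4)
  # oracle equivalence with t.test over 100 random instances
  for (i in 1:100) {
    a <- stats::rnorm(sample(5:30, 1), sd = stats::runif(1, 0.5, 2))
    b <- stats::rnorm(sample(5:30, 1), mean = stats::runif(1, -1, 1))
    got <- selectivity_index(matrix(a), matrix(b))[1]
    want <- unname(stats::t.test(a, b)$statistic)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("index edge cases follow the declared conventions", {
  same <- matrix(rep(1, 6), ncol = 1)
  expect_equal(selectivity_index(same, same)[1], 0)
  up <- matrix(rep(2, 6), ncol = 1)
  idx <- selectivity_index(up, same)
  expect_equal(idx[1], Inf)
  expect_equal(attr(idx, "degenerate"), 1L)
  expect_error(selectivity_index(matrix(1), matrix(1:3)), "at least 2")
})

test_that("the index is antisymmetric under group swap", {
  set.seed(2)
  a <- matrix(stats::rnorm(40), 10)
  b <- matrix(stats::rnorm(48, 0.5), 12)
  expect_equal(selectivity_index(a, b), -selectivity_index(b, a),
               tolerance = 1e-12)
})

test_that("group selection uses round-down rank arithmetic", {
  prof <- data.frame(unit = 1:256, index = seq(256, 1))  # unit i has rank i
  expect_equal(as.integer(select_group(prof, 0.125, "top")), 1:32)
  expect_equal(as.integer(select_group(prof, 0.125, "bottom")), 225:256)
  expect_equal(as.integer(select_group(prof, which = "band",
                                       band = c(0.4375, 0.5625))), 113:144)
  small <- data.frame(unit = 1:8, index = 8:1)
  expect_equal(as.integer(select_group(small, 0.125, "top")), 1L)
  expect_error(select_group(prof[0, ], 0.125), "empty")
})

test_that("selection is invariant to monotone transforms and breaks ties by position", {
  set.seed(3)
  prof <- data.frame(unit = 1:40, index = stats::rnorm(40))
  g1 <- select_group(prof, 0.25, "top")
  prof2 <- prof; prof2$index <- exp(3 * prof2$index) + 5
  expect_identical(as.integer(g1), as.integer(select_group(prof2, 0.25, "top")))
  tied <- data.frame(unit = 1:6, index = c(1, 2, 2, 2, 0, 3))
  expect_equal(as.integer(select_group(tied, 0.5, "top")), c(6L, 2L, 3L))
})

test_that("response ratios average per-unit group means", {
  feats <- rbind(c(2, 4), c(2, 4), c(1, 2), c(1, 2))
  groups <- c("music", "music", "non-music", "non-music")
  g <- structure(1:2, class = "unit_group")
  expect_equal(response_ratio(feats, g, groups), 2)
  feats_eq <- rbind(c(1, 3), c(1, 3), c(1, 3), c(1, 3))
  expect_equal(response_ratio(feats_eq, g, groups), 1)
  # hand-computed asymmetric case
  feats2 <- rbind(c(3, 1), c(1, 5), c(2, 2), c(2, 1))
  expect_equal(response_ratio(feats2, g, groups),
               mean(c(2 / 2, 3 / 1.5)))
  # zero denominator flags and excludes the unit
  feats3 <- rbind(c(2, 1), c(2, 1), c(0, 1), c(0, 1))
  expect_warning(r <- response_ratio(feats3, g, groups), "zero")
  expect_equal(r, 1)
  # mixed clips are excluded
  feats4 <- rbind(c(2, 4), c(2, 4), c(1, 2), c(1, 2), c(99, 99))
  expect_equal(response_ratio(feats4, g, c(groups, "mixed")), 2)
})

test_that("selectivity profiles exclude mixed clips and carry group stats", {
  set.seed(4)
  f <- matrix(stats::rnorm(60), 10, 6)
  groups <- c("music", "music", "music", "non-music", "non-music",
              "non-music", "non-music", "mixed", "mixed", "non-music")
  prof <- selectivity_profile(f, groups)
  expect_equal(prof$n_pos[1], 3)
  expect_equal(prof$n_neg[1], 5)
  expect_equal(prof$m_pos, colMeans(f[1:3, ]))
  expect_equal(prof$index,
               as.numeric(selectivity_index(f[1:3, ], f[c(4:7, 10), ])))
})

test_that("amplitude scaling of music weakens but preserves selectivity", {
  st <- get_study(1)
  data <- st$data
  tr <- which(data$split == "train")
  clips <- data$dataset$clips[tr]
  tab <- amplitude_robustness(st$gen$model, clips, data$groups[tr],
                              st$gen$groups$top,
                              power_ratios = c(1, 1 / 4, 1 / 64),
                              frontend = data$frontend,
                              time_pool = data$config$time_pool)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$rms_ratio, sqrt(tab$power_ratio))
  # unmanipulated row equals the plain response ratio
  expect_equal(tab$response_ratio[1], st$gen$ratio_top, tolerance = 1e-8)
  # music remains the stronger driver even at 1/64 power
  expect_gt(tab$response_ratio[3], 1)
})

test_that("RMS normalization leaves the selective group largely intact", {
  st <- get_study(1)
  data <- st$data
  te <- which(data$split == "test")
  target <- mean(vapply(data$dataset$clips, rms, numeric(1)))
  norm_clips <- lapply(data$dataset$clips[te], normalize_rms, target = target)
  x <- stack_spectrograms(lapply(norm_clips, to_log_mel,
                                 config = data$frontend),
                          time_pool = data$config$time_pool)
  feats <- extract_features(st$gen$model, x)
  prof <- selectivity_profile(feats, data$groups[te])
  top_norm <- select_group(prof, 0.125, "top")
  n_units <- st$gen$model$arch$feature_dim
  n_common <- length(intersect(top_norm, st$gen$groups$top))
  # per-unit membership agreement: units whose in/out-of-group status is
  # unchanged by the normalization
  agreement <- (n_units - 2 * (length(top_norm) - n_common)) / n_units
  expect_gte(agreement, 0.9)
  # and the set overlap itself is far above the 12.5% chance level
  expect_gte(n_common / length(top_norm), 0.6)
})
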