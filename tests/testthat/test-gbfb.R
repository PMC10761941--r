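test_that("modulation grid follows the geometric recurrence", {
  g <- modulation_grid(d = 0.1, nu = 3.5, w_max = pi / 4, size_max = 64)
  pos <- g[g > 0]
  expect_equal(pos[1], pi / 4)
  # ratio (1 + c/2)/(1 - c/2) with c = 8d/nu
  cc <- 8 * 0.1 / 3.5
  expect_equal(pos[1] / pos[2], (1 + cc / 2) / (1 - cc / 2),
               tolerance = 1e-12)
  expect_equal(pos[2], 0.6243, tolerance = 1e-4)
  expect_equal(pos[1] / pos[2], 1.2581, tolerance = 1e-4)
  # every adjacent nonzero pair keeps the exact ratio
  expect_equal(pos[-length(pos)] / pos[-1],
               rep((1 + cc / 2) / (1 - cc / 2), length(pos) - 1),
               tolerance = 1e-12)
  expect_true(0 %in% g)
  expect_error(modulation_grid(-1, 3.5, pi / 4), "positive")
})

test_that("reference parameters give the published grid sizes", {
  g <- gabor_grid()
  expect_equal(length(g$spectral), 15L)
  expect_equal(length(g$temporal), 18L)
  bank <- build_filterbank(g)
  expect_equal(bank$size, 263L)
  expect_equal(15L * 18L - bank$size, 7L)
})

test_that("single-pair grids collapse to one filter", {
  g <- gabor_grid()
  g$spectral <- 0; g$temporal <- 0
  expect_equal(build_filterbank(g)$size, 1L)
})

test_that("filters are raised-cosine enveloped complex carriers", {
  f <- make_gabor_filter(0.3, 0.2)
  # envelope vanishes at the support edge
  expect_equal(Mod(f$values[1, ]), rep(0, ncol(f$values)), tolerance = 1e-12)
  expect_equal(Mod(f$values[, 1]), rep(0, nrow(f$values)), tolerance = 1e-12)
  # DC-free after mean removal
  expect_equal(abs(sum(f$values)), 0, tolerance = 1e-10)
  # the all-DC filter is a real, non-negative low-pass
  dc <- make_gabor_filter(0, 0)
  expect_true(all(Im(dc$values) == 0))
  expect_true(all(Re(dc$values) >= 0))
})

test_that("sign reversal of both axes conjugates the filter", {
  f1 <- make_gabor_filter(0.35, 0.22)
  f2 <- make_gabor_filter(-0.35, -0.22)
  expect_equal(f2$values, Conj(f1$values), tolerance = 1e-12)
})

test_that("no two retained filters coincide up to conjugation", {
  g <- gabor_grid(n_channels = 16, max_frames = 16)  # small grid
  bank <- build_filterbank(g)
  keys <- vapply(bank$filters, function(f)
    paste(f$w_k, f$w_n), character(1))
  expect_false(any(duplicated(keys)))
  # conjugate pairs only arise at zero temporal frequency; there the
  # negative spectral twin must have been removed
  zero_t <- Filter(function(f) f$w_n == 0, bank$filters)
  expect_true(all(vapply(zero_t, function(f) f$w_k >= 0, logical(1))))
})

test_that("2-D convolution matches a direct loop oracle", {
  set.seed(3)
  x <- matrix(stats::rnorm(7 * 9), 7, 9)
  h <- matrix(stats::rnorm(3 * 5) + 1i * stats::rnorm(3 * 5), 3, 5)
  got <- musedetect:::conv2_same(x, h)
  # direct zero-padded same convolution
  want <- matrix(0 + 0i, 7, 9)
  for (i in 1:7) for (j in 1:9) {
    acc <- 0 + 0i
    for (a in 1:3) for (b in 1:5) {
      ii <- i - (a - 2); jj <- j - (b - 3)
      if (ii >= 1 && ii <= 7 && jj >= 1 && jj <= 9)
        acc <- acc + x[ii, jj] * h[a, b]
    }
    want[i, j] <- acc
  }
  expect_equal(got, want, tolerance = 1e-10)
})

test_that("GBFB features are non-negative and offset-insensitive", {
  g <- gabor_grid(n_channels = 16, max_frames = 16)
  bank <- build_filterbank(g)
  zero <- matrix(0, 16, 20)
  expect_equal(gbfb_features(zero, bank), rep(0, bank$size))
  set.seed(4)
  x <- matrix(stats::rnorm(16 * 20), 16, 20)
  v <- gbfb_features(x, bank)
  expect_true(all(v >= 0))
  # a DC-free filter ignores constant offsets (pre-ReLU linearity)
  f <- bank$filters[[which(vapply(bank$filters, function(f)
    f$w_k != 0, logical(1)))[1]]]
  r1 <- Re(musedetect:::conv2_same(x, f$values))
  r2 <- Re(musedetect:::conv2_same(x + 5, f$values))
  # fully interior cells only: zero padding makes borders see the offset
  hk <- (nrow(f$values) - 1) / 2; hn <- (ncol(f$values) - 1) / 2
  rows <- (hk + 1):(16 - hk); cols <- (hn + 1):(20 - hn)
  expect_equal(r1[rows, cols], r2[rows, cols], tolerance = 1e-8)
})

test_that("filters are matched to their own modulation frequency", {
  g <- gabor_grid()
  bank <- build_filterbank(g)
  picks <- c(30, 120, 200)
  K <- 64; T <- 100
  for (p in picks) {
    f <- bank$filters[[p]]
    if (f$w_k == 0 && f$w_n == 0) next
    # drifting ripple at each filter's frequency pair; the response of
    # filter p should peak at its own pair
    resp <- vapply(picks, function(q) {
      fq <- bank$filters[[q]]
      ripple <- outer(seq_len(K), seq_len(T), function(k, n)
        cos(fq$w_k * k + fq$w_n * n))
      sum(Mod(musedetect:::conv2_same(ripple, f$values)))
    }, numeric(1))
    expect_equal(which.max(resp), which(picks == p))
  }
})

test_that("PCA features fit on training data and report variance", {
  set.seed(9)
  base <- matrix(stats::rnorm(5 * 24), 5, 24)        # rank-5 subspace
  train <- lapply(1:12, function(i)
    matrix(as.numeric(stats::rnorm(5) %*% base), 4, 6))
  p <- pca_features(train, n_components = 5)
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
  # orthonormal basis
  expect_equal(crossprod(p$basis), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  # projection/reconstruction at least as good as any same-rank basis
  xt <- do.call(rbind, lapply(train, as.vector))
  xc <- sweep(xt, 2, colMeans(xt))
  recon <- p$train_scores %*% t(p$basis)
  err_pca <- sum((xc - recon)^2)
  ev <- eigen(crossprod(xc))$vectors[, 1:5]
  err_eig <- sum((xc - xc %*% ev %*% t(ev))^2)
  expect_lte(err_pca, err_eig + 1e-8)
  # rank deficiency triggers a warning and a reduced basis
  expect_warning(p2 <- pca_features(train[1:4], n_components = 10),
                 "rank")
  expect_equal(p2$n_components, 3)
  # test projection uses the training basis
  p3 <- pca_features(train, n_components = 3, test = train[1:2])
  expect_equal(p3$test_scores[, 1:3], p3$train_scores[1:2, 1:3],
               tolerance = 1e-9, ignore_attr = TRUE)
})
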