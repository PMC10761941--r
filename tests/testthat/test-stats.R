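test_that("average precision handles the canonical cases", {
  expect_equal(average_precision(c(5, 4, 3, 2, 1), c(1, 1, 0, 0, 0)), 1)
  expect_equal(average_precision(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  # untied step curve, hand-computed
  expect_equal(average_precision(c(4, 3, 2, 1), c(1, 0, 1, 0)),
               (1 + 2 / 3) / 2)
  # constant scores give exactly the prevalence
  expect_equal(average_precision(rep(0, 10), c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0)),
               0.3)
  expect_error(average_precision(1:3, c(0, 0, 0)), "no positive")
})

test_that("the chance level of the original class balance is 0.266", {
  labels <- c(rep(1, 3999), rep(0, 11010))
  ap <- average_precision(rep(0, length(labels)), labels)
  expect_equal(signif(ap, 3), 0.266)
})

test_that("tied blocks agree with brute-force tie-break expectation", {
  # at moderate n the block convention and the expectation over random
  # tie-breaks agree to within sampling error
  set.seed(42)
  n <- 2000
  n_pos <- 600
  labels <- as.numeric(seq_len(n) <= n_pos)
  ap_block <- average_precision(rep(1, n), labels)
  sim <- vapply(1:300, function(i) {
    o <- sample(n)
    tp <- cumsum(labels[o])
    sum((tp / seq_len(n))[labels[o] == 1]) / n_pos
  }, numeric(1))
  expect_equal(ap_block, mean(sim), tolerance = 0.02)
})

test_that("mAP is a mean over included categories", {
  scores <- cbind(a = c(3, 2, 1), b = c(1, 2, 3), c = c(2, 1, 3))
  labels <- cbind(a = c(1, 0, 0), b = c(0, 0, 1), c = c(1, 1, 0))
  r <- map_score(scores, labels)
  expect_equal(r$map, mean(r$per_category))
  r2 <- map_score(scores, labels, exclude = "a")
  expect_equal(r2$map, mean(r$per_category[c("b", "c")]))
  # a category without positives is dropped with NA
  labels[, "b"] <- 0
  r3 <- map_score(scores, labels)
  expect_true(is.na(r3$per_category["b"]))
  expect_equal(r3$map, mean(r3$per_category[c("a", "c")]))
})

test_that("rank-sum U follows the first-sample convention", {
  out <- wilcoxon_tests(6:10, 1:5, mode = "rank-sum", tail = "one")
  expect_equal(out$statistic, 25)
  expect_equal(out$effect_size, 1)
  expect_equal(out$method, "exact")
  # U + U(swapped) = n_a * n_b
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(0.4, 2.8, 3.9)
  u1 <- wilcoxon_tests(a, b)$statistic
  u2 <- wilcoxon_tests(b, a)$statistic
  expect_equal(u1 + u2, length(a) * length(b))
})

test_that("exact rank-sum p-values match permutation enumeration", {
  set.seed(7)
  for (i in 1:5) {
    a <- stats::rnorm(5); b <- stats::rnorm(4) + 0.5
    out <- wilcoxon_tests(a, b, mode = "rank-sum", tail = "one")
    # brute force: all assignments of the 9 values to group a
    pool <- c(a, b)
    combos <- utils::combn(9, 5)
    u_obs <- sum(rank(pool)[1:5]) - 5 * 6 / 2
    u_all <- apply(combos, 2, function(ix)
      sum(rank(pool)[ix]) - 5 * 6 / 2)
    expect_equal(out$p.value, mean(u_all >= u_obs), tolerance = 1e-12)
  }
})

test_that("exact signed-rank p-values match sign-flip enumeration", {
  set.seed(8)
  for (i in 1:5) {
    d <- stats::rnorm(7, 0.4)
    out <- wilcoxon_tests(d, rep(0, 7), mode = "signed-rank", tail = "one")
    r <- rank(abs(d))
    v_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 7)))
    v_all <- signs %*% r
    expect_equal(out$p.value, mean(v_all >= v_obs), tolerance = 1e-12)
  }
})

test_that("degenerate paired samples are flagged, not tested", {
  out <- wilcoxon_tests(c(1, 2, 3), c(1, 2, 3), mode = "signed-rank")
  expect_true(out$degenerate)
  expect_true(is.na(out$p.value))
  expect_equal(out$effect_size, 0.5)
})

test_that("complete separation at n = 5 reproduces the printed statistics", {
  out <- wilcoxon_tests(c(2.1, 2.5, 3.0, 2.2, 2.8),
                        c(1.0, 1.2, 0.9, 1.1, 1.3),
                        mode = "rank-sum", tail = "one")
  expect_equal(out$statistic, 25)
  expect_equal(out$effect_size, 1)
  v <- wilcoxon_tests(c(1, 2, 3, 4, 5), rep(0, 5), mode = "signed-rank",
                      tail = "one")
  expect_equal(v$statistic, 15)
  expect_equal(v$p.value, 1 / 32, tolerance = 1e-12)
})

test_that("common-language effect size counts cross pairs", {
  expect_equal(common_language_es(c(5, 6), c(1, 2)), 1)
  expect_equal(common_language_es(c(1, 2), c(3)), 0)
  expect_equal(common_language_es(c(1, 3), c(1, 3)), 0.5)
  # complementarity without ties
  a <- stats::rnorm(8); b <- stats::rnorm(6)
  expect_equal(common_language_es(a, b) + common_language_es(b, a), 1)
  # matches the direct cross-pair count
  expect_equal(common_language_es(a, b),
               mean(outer(a, b, ">") + 0.5 * outer(a, b, "==")))
})
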