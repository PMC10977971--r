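test_that("weighted stage means reduce to ordinary means under uniformity", {
  set.seed(23)
  J <- 40; K <- 5
  x <- rnorm(J)
  uni <- matrix(1 / K, J, K)
  tr <- weightedStageMean(x, uni)
  expect_equal(tr$mean, rep(mean(x), K), tolerance = 1e-12)
  expect_equal(tr$se, rep(sd(x) / sqrt(J), K), tolerance = 1e-12)
  # one-hot posterior: the single contributor's value, SE = sigma
  oh <- matrix(0, J, K)
  oh[7, 2] <- 1
  oh[-7, -2] <- 1 / (K - 1)
  tr2 <- weightedStageMean(x, oh)
  expect_equal(tr2$mean[2], x[7])
  expect_equal(tr2$se[2], sd(x))
  # plain arithmetic
  tr3 <- weightedStageMean(c(2, 4), cbind(c(0.25, 0.75)))
  expect_equal(tr3$mean, 3.5)
  # zero total weight at a stage is reported as missing
  z0 <- matrix(c(1, 1, 0, 0), 2, 2)
  tr4 <- weightedStageMean(c(1, 2), z0)
  expect_true(is.na(tr4$mean[2]) && is.na(tr4$se[2]))
})

test_that("SE lies between sigma/sqrt(J) and sigma", {
  set.seed(29)
  for (rep in 1:10) {
    J <- sample(5:60, 1); K <- sample(2:8, 1)
    x <- rnorm(J)
    p <- matrix(rexp(J * K), J, K)
    p <- p / rowSums(p)
    tr <- weightedStageMean(x, p)
    expect_true(all(tr$se >= sd(x) / sqrt(J) - 1e-12))
    expect_true(all(tr$se <= sd(x) + 1e-12))
  }
})

test_that("stage proportions form a simplex and recover prevalence", {
  set.seed(31)
  J <- 60; K <- 4
  labels <- sample(c("cdr0", "cdr0.5", "cdr1"), J, replace = TRUE)
  p <- matrix(rexp(J * K), J, K)
  p <- p / rowSums(p)
  pr <- stageProportions(labels, p)
  expect_equal(unname(rowSums(pr)), rep(1, K), tolerance = 1e-12)
  expect_true(all(pr >= 0))
  # all subjects one category
  pr1 <- stageProportions(rep("only", J), p)
  expect_equal(unname(pr1[, 1]), rep(1, K))
  # uniform posterior: fractions equal overall label prevalence
  prU <- stageProportions(labels, matrix(1 / K, J, K))
  expect_equal(unname(prU[1, ]),
               as.numeric(table(labels)[colnames(prU)] / J),
               tolerance = 1e-12)
})

test_that("bootstrap stage comparison behaves at the degenerate corners", {
  set.seed(37)
  J <- 30
  x <- rnorm(J)
  p <- matrix(rexp(J * 3), J, 3)
  p <- p / rowSums(p)
  same <- bootstrapStageDifference(x, p, 2, 2, B = 1000, seed = 1)
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)
  expect_warning(
    const <- bootstrapStageDifference(rep(1, J), p, 1, 2, B = 1000, seed = 1),
    "degenerate")
  expect_equal(const$p, 1)
  expect_error(bootstrapStageDifference(x, p, 1, 2, B = 10), "at least")
})

test_that("bootstrap comparison detects a planted 2-SD stage shift", {
  set.seed(41)
  n <- 50
  x <- c(rnorm(n, 0), rnorm(n, 2))          # 2-SD separation
  p <- rbind(cbind(1, 0), cbind(0, 1))[c(rep(1, n), rep(2, n)), ]
  p <- matrix(c(rep(c(1, 0), c(n, n)), rep(c(0, 1), c(n, n))), ncol = 2)
  cmp <- bootstrapStageDifference(x, p, 2, 1, B = 5000, seed = 2)
  expect_lt(cmp$p, 0.001)
  expect_gt(cmp$delta, 1.5)
  # deterministic given seed
  cmp2 <- bootstrapStageDifference(x, p, 2, 1, B = 5000, seed = 2)
  expect_identical(cmp, cmp2)
})

test_that("bootstrap type-I error is near nominal under the null", {
  # quick version: 200 exchangeable-null datasets (full calibration in
  # the acceptance suite)
  set.seed(43)
  n <- 40
  w <- matrix(c(rep(c(1, 0), c(n, n)), rep(c(0, 1), c(n, n))), ncol = 2)
  rej <- vapply(1:200, function(s) {
    x <- rnorm(2 * n)
    bootstrapStageDifference(x, w, 1, 2, B = 1000, seed = s)$p < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.12)
})

test_that("Benjamini-Hochberg adjustment follows the step-up definition", {
  expect_equal(bhFdr(0.03), 0.03)
  expect_equal(bhFdr(rep(1, 5)), rep(1, 5))
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  # permutation invariance
  set.seed(47)
  p <- runif(20)
  perm <- sample(20)
  expect_equal(bhFdr(p)[perm], bhFdr(p[perm]))
  expect_error(bhFdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # q >= p for every test under BH
  expect_true(all(bhFdr(p) >= p))
})

test_that("all-pairs comparison controls the FDR family per metric", {
  set.seed(53)
  J <- 45
  x <- rnorm(J) + rep(c(0, 0, 2), c(15, 15, 15))
  p <- matrix(0, J, 3)
  p[cbind(seq_len(J), rep(1:3, c(15, 15, 15)))] <- 1
  cmp <- compareAllStagePairs(x, p, B = 2000, seed = 7)
  expect_equal(nrow(cmp), choose(3, 2))
  expect_equal(cmp$q, bhFdr(cmp$p))
  sig <- cmp$q < 0.05
  expect_true(all(sig[cmp$stage_k == 3 | cmp$stage_kprime == 3]))
  expect_false(any(sig[cmp$stage_k != 3 & cmp$stage_kprime != 3]))
})
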