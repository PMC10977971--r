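test_that("valid-sequence counts equal the multinomial coefficient", {
  expect_equal(countValidSequences(c(3, 3)), 20)
  expect_equal(countValidSequences(c(3, 3, 3)), 1680)
  expect_equal(countValidSequences(5), 1)
  expect_equal(countValidSequences(c(2, 2)), 6)
  # matches full enumeration on random small cases
  set.seed(11)
  for (rep in 1:5) {
    counts <- sample(1:3, sample(2:3, 1), replace = TRUE)
    expect_equal(countValidSequences(counts),
                 length(enumerateSequences(counts)))
  }
})

test_that("stage z-scores interpolate events at half-integer midpoints", {
  # single metric, uniform spacing
  g <- eventGrid(rbind(c(0, 1, 2, 3, 4)), metricNames = "m")
  m <- stageZscores(g, eventSequence(c(1, 1, 1)))
  expect_equal(as.numeric(stageMu(m)), c(0.5, 1.5, 2.5, 3.5))
  # six events give seven stages, nine events ten stages
  p6 <- plantedProblem(I = 2, nEvents = 3)
  expect_equal(nStages(stageZscores(p6$grid, p6$sequence)), 7L)
  p9 <- plantedProblem(I = 3, nEvents = 3)
  expect_equal(nStages(stageZscores(p9$grid, p9$sequence)), 10L)
})

test_that("stage z-scores match an independent piecewise-linear oracle", {
  set.seed(21)
  for (rep in 1:20) {
    I <- sample(2:3, 1)
    nEvents <- sample(2:4, 1)
    z <- t(apply(matrix(rnorm(I * (nEvents + 2), sd = 2), I), 1, sort))
    rownames(z) <- paste0("m", seq_len(I))
    grid <- eventGrid(z)
    labels <- sample(rep(seq_len(I), nEvents))
    mu <- stageMu(stageZscores(grid, eventSequence(labels)))
    expect_equal(unname(mu), pwlStageOracle(z, labels), tolerance = 1e-12)
    # monotone non-decreasing per metric
    expect_true(all(apply(mu, 1, function(r) all(diff(r) >= -1e-12))))
  }
})

test_that("sequences with mismatched event counts are rejected", {
  g <- eventGrid(rbind(c(-2, 0, 2), c(-2, 0, 2)))
  expect_error(stageZscores(g, eventSequence(c(1, 1))), "ordering")
  expect_error(eventSequence(cbind(c(1, 1), c(2, 1))), "interleaving")
})

test_that("data log-likelihood matches closed forms and brute force", {
  # single subject at the stage mean: standard-normal density at its mode
  g <- eventGrid(rbind(c(-1, 0, 1)), metricNames = "m")
  model <- stageZscores(g, eventSequence(1L))
  # construct flat-mu model manually for the closed form
  flat <- new("StageModel", grid = g, sequence = eventSequence(1L),
              mu = matrix(0, 1, 2))
  expect_equal(dataLogLikelihood(matrix(0, 1, 1), flat),
               log(dnorm(0)), tolerance = 1e-12)
  # brute-force oracle on random instances
  set.seed(31)
  for (rep in 1:20) {
    I <- sample(1:3, 1)
    nEvents <- sample(1:3, 1)
    z <- matrix(rnorm(I * 5, sd = 2), I, 5)
    zg <- t(apply(matrix(rnorm(I * (nEvents + 2), sd = 2), I), 1, sort))
    rownames(zg) <- paste0("m", seq_len(I))
    grid <- eventGrid(zg)
    labels <- sample(rep(seq_len(I), nEvents))
    model <- stageZscores(grid, eventSequence(labels))
    expect_equal(dataLogLikelihood(z, model),
                 bruteLogLik(z, stageMu(model)), tolerance = 1e-12)
    # permuting subject columns leaves the product unchanged
    expect_equal(dataLogLikelihood(z[, sample(ncol(z)), drop = FALSE], model),
                 dataLogLikelihood(z, model), tolerance = 1e-12)
  }
})

test_that("stage posterior normalizes likelihoods over stages", {
  # flat stage means: uniform posterior
  g <- eventGrid(rbind(c(-1, 0, 1)), metricNames = "m")
  flat <- new("StageModel", grid = g, sequence = eventSequence(1L),
              mu = matrix(0, 1, 2))
  p <- stagePosterior(matrix(rnorm(5), 1, 5), flat)
  expect_equal(unname(p), matrix(0.5, 5, 2))
  # two-term hand computation: mu = (0, 2), z = 0
  m2 <- new("StageModel", grid = g, sequence = eventSequence(1L),
            mu = matrix(c(0, 2), 1, 2))
  p2 <- stagePosterior(matrix(0, 1, 1), m2)
  expect_equal(unname(p2[1, 1]), dnorm(0) / (dnorm(0) + dnorm(2)),
               tolerance = 1e-12)
  # rows sum to one even for extreme z (log-space, no NaN)
  pBig <- stagePosterior(matrix(c(500, -500), 1, 2), m2)
  expect_true(all(is.finite(pBig)))
  expect_equal(unname(rowSums(pBig)), c(1, 1), tolerance = 1e-12)
})

test_that("greedy ascent finds high-likelihood sequences", {
  # single-metric problems have exactly one valid sequence
  g1 <- eventGrid(rbind(c(-2, -1, 0, 1, 2)), metricNames = "m")
  s1 <- greedyAscentInit(matrix(rnorm(8), 1, 8), g1, nStarts = 2,
                         nIter = 10, seed = 1)
  expect_equal(s1@metricIndex, c(1L, 1L, 1L))
  # (3,3): result in the top of the 20-sequence likelihood landscape
  p <- plantedProblem()
  set.seed(42)
  model <- stageZscores(p$grid, p$sequence)
  z <- stageMu(model)[, sample.int(7, 60, replace = TRUE)] +
    matrix(rnorm(2 * 60), 2)
  best <- greedyAscentInit(z, p$grid, nStarts = 5, nIter = 300, seed = 7)
  ex <- exactSequenceWeights(z, p$grid)
  llBest <- dataLogLikelihood(z, stageZscores(p$grid, best))
  expect_gte(llBest, quantile(ex$logLik, 0.95))
  # zero noise: planted sequence recovered exactly
  z0 <- stageMu(model)[, rep(1:7, each = 10)]
  best0 <- greedyAscentInit(z0, p$grid, nStarts = 5, nIter = 500, seed = 3)
  expect_equal(best0@metricIndex, p$sequence@metricIndex)
})

test_that("MCMC respects the interleaving constraint and finds the argmax", {
  p <- plantedProblem()
  set.seed(5)
  model <- stageZscores(p$grid, p$sequence)
  z <- stageMu(model)[, sample.int(7, 80, replace = TRUE)] +
    matrix(rnorm(2 * 80), 2)
  run <- mcmcSequences(z, p$grid, nSamples = 4000, seed = 9)
  # every sample is a valid interleaving (same per-metric event counts)
  tab <- t(apply(run$samples, 1, tabulate, nbins = 2))
  expect_true(all(tab[, 1] == 3 & tab[, 2] == 3))
  # best of chain equals the exhaustive argmax over all 20 sequences
  ex <- exactSequenceWeights(z, p$grid)
  expect_equal(run$bestSequence@metricIndex,
               ex$sequences[[which.max(ex$logLik)]])
  expect_equal(run$bestLogLik, max(ex$logLik), tolerance = 1e-12)
  # the chain never visits more distinct sequences than exist
  visited <- unique(apply(run$samples, 1, paste, collapse = ""))
  expect_lte(length(visited), countValidSequences(c(3, 3)))
  # deterministic given the seed
  run2 <- mcmcSequences(z, p$grid, nSamples = 4000, seed = 9)
  expect_identical(run$samples, run2$samples)
})

test_that("MCMC visit frequencies track exact likelihood weights", {
  p <- plantedProblem(I = 2, nEvents = 2)
  set.seed(6)
  model <- stageZscores(p$grid, p$sequence)
  z <- stageMu(model)[, sample.int(5, 40, replace = TRUE)] +
    matrix(rnorm(2 * 40), 2)
  run <- mcmcSequences(z, p$grid, nSamples = 20000, seed = 4)
  ex <- exactSequenceWeights(z, p$grid)
  keys <- vapply(ex$sequences, paste, character(1), collapse = "")
  seen <- table(factor(apply(run$samples, 1, paste, collapse = ""),
                       levels = keys))
  freq <- as.numeric(seen) / nrow(run$samples)
  expect_gt(cor(freq, ex$weights, method = "spearman"), 0.9)
})

test_that("positional variance summarizes sequence uncertainty", {
  # chain that never moves: one-hot permutation matrix
  s <- c(1L, 2L, 1L, 2L)
  frozen <- matrix(rep(s, each = 10), nrow = 10)
  pv <- positionalVariance(frozen, nMetrics = 2)
  expect_equal(unname(pv[cbind(c(1, 3, 2, 4), 1:4)]), rep(1, 4))
  expect_equal(sum(pv), 4)
  # rows and columns sum to one for a real chain
  p <- plantedProblem(I = 2, nEvents = 2)
  set.seed(8)
  z <- matrix(rnorm(2 * 30), 2, 30)
  run <- mcmcSequences(z, p$grid, nSamples = 3000, seed = 2)
  pv2 <- positionalVariance(run)
  expect_equal(unname(rowSums(pv2)), rep(1, 4), tolerance = 1e-12)
  expect_equal(unname(colSums(pv2)), rep(1, 4), tolerance = 1e-12)
})

test_that("event-setting optimization matches brute force on tiny problems", {
  set.seed(12)
  g1 <- eventGrid(rbind(c(-2, -0.5, 0.5, 2), c(-2, -0.6, 0.6, 2)))
  g2 <- eventGrid(rbind(c(-2, -1.2, 1.2, 2), c(-2, -0.2, 0.2, 2)))
  z <- matrix(rnorm(2 * 50, mean = rep(c(0.4, -0.2), 25)), 2, 50)
  fit <- optimizeEventSettings(z, list(g1, g2), nStarts = 4,
                               ascentIter = 100, nSamples = 2000, seed = 5)
  # brute force over grids x all valid sequences
  bruteBest <- -Inf
  for (g in list(g1, g2)) {
    ex <- exactSequenceWeights(z, g)
    if (max(ex$logLik) > bruteBest) {
      bruteBest <- max(ex$logLik)
      bruteGrid <- g
      bruteSeq <- ex$sequences[[which.max(ex$logLik)]]
    }
  }
  expect_equal(bestLogLik(fit), bruteBest, tolerance = 1e-12)
  expect_equal(gridZ(bestModel(fit)@grid), gridZ(bruteGrid))
  expect_equal(bestModel(fit)@sequence@metricIndex, bruteSeq)
  # single-candidate list returns that grid
  fit1 <- optimizeEventSettings(z, list(g1), nStarts = 2,
                                ascentIter = 50, nSamples = 1000, seed = 3)
  expect_equal(fit1@nGrids, 1L)
  expect_equal(gridZ(bestModel(fit1)@grid), gridZ(g1))
  # reported log-likelihood equals recomputation from its stage model
  expect_equal(bestLogLik(fit), dataLogLikelihood(z, bestModel(fit)),
               tolerance = 1e-12)
})

test_that("planted sequences are recovered from realistic noise", {
  p <- plantedProblem(I = 2, nEvents = 3)
  model <- stageZscores(p$grid, p$sequence)
  set.seed(77)
  stage <- sample.int(7, 300, replace = TRUE)
  z <- stageMu(model)[, stage] + matrix(rnorm(2 * 300), 2)
  init <- greedyAscentInit(z, p$grid, nStarts = 5, nIter = 300, seed = 1)
  run <- mcmcSequences(z, p$grid, init = init, nSamples = 3000, seed = 1)
  expect_gte(sequenceTau(run$bestSequence, p$sequence), 0.8)
  # posterior concentrates on the true stage at zero noise once stage
  # mean vectors are well separated relative to the unit noise scale
  pw <- plantedProblem(I = 2, nEvents = 3, anchors = c(-12, 12))
  modelw <- stageZscores(pw$grid, pw$sequence)
  z0 <- stageMu(modelw)[, stage]
  post0 <- stagePosterior(z0, modelw)
  expect_gte(min(post0[cbind(seq_along(stage), stage)]), 0.99)
})
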