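makeCohort <- function(J = 200, seed = 1) {
  p <- plantedProblem()
  simulateCohort(J, p$grid, p$sequence, noiseSd = 1, seed = seed)
}

test_that("covariate adjustment removes planted slopes and nothing else", {
  p <- plantedProblem()
  # planted age slope of 0.5 raw units per year on metric 1
  eff <- matrix(0, 2, 1, dimnames = list(NULL, "age"))
  eff[1, 1] <- 0.5
  cohort <- simulateCohort(500, p$grid, p$sequence, noiseSd = 1,
                           covariateEffects = eff, seed = 3)
  adj <- adjustCovariates(cohort, covariates = "age")
  ctrl <- colData(cohort)$group == "control"
  expect_lt(abs(cor(assay(adj)[1, ctrl], colData(adj)$age[ctrl])), 0.01)
  # reference-group mean preserved
  expect_equal(mean(assay(adj)[1, ctrl]), mean(assay(cohort)[1, ctrl]),
               tolerance = 1e-10)
  # truly null slopes: constant reference values give an exactly flat
  # fitted slope, so adjustment is an exact no-op
  J0 <- 20
  raw0 <- rbind(m = c(rep(5, 10), rnorm(10, 8)))
  colnames(raw0) <- paste0("s", seq_len(J0))
  se0 <- SummarizedExperiment(
    assays = list(raw = raw0),
    colData = S4Vectors::DataFrame(
      group = rep(c("control", "patient"), each = 10),
      age = rnorm(J0, 70, 8), row.names = colnames(raw0)))
  adj0 <- adjustCovariates(se0, covariates = "age")
  expect_equal(assay(adj0), assay(se0), tolerance = 1e-10)
  # rank-deficient design is refused
  cd <- colData(cohort)
  cd$age2 <- cd$age
  colData(cohort) <- cd
  expect_error(adjustCovariates(cohort, covariates = c("age", "age2")),
               "collinear")
  expect_error(adjustCovariates(cohort, covariates = "not_a_column"),
               "missing covariate")
})

test_that("signed z-scoring follows the severity sign convention", {
  x <- rbind(up = c(10, 11, 12, 13, 14, 16), dn = c(5, 4, 3, 2, 1, 0))
  isControl <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  z <- zscoreMetrics(x, c(up = "increasing", dn = "decreasing"),
                     isControl = isControl)
  ctrMeanUp <- mean(x[1, 1:5]); ctrSdUp <- sd(x[1, 1:5])
  ctrMeanDn <- mean(x[2, 1:5]); ctrSdDn <- sd(x[2, 1:5])
  # control subject at the control mean scores zero
  expect_equal(unname(zValues(z)[1, 3]), (12 - ctrMeanUp) / ctrSdUp)
  # increasing metric one control-SD above the control mean: z = +1
  zi <- zscoreMetrics(rbind(m = c(0, 2, 1 + sd(c(0, 2)))),
                      c(m = "increasing"), isControl = c(TRUE, TRUE, FALSE))
  expect_equal(unname(zValues(zi)[1, 3]), 1, tolerance = 1e-12)
  # decreasing metric one control-SD below the control mean: z = +1
  zd <- zscoreMetrics(rbind(m = c(0, 2, 1 - sd(c(0, 2)))),
                      c(m = "decreasing"), isControl = c(TRUE, TRUE, FALSE))
  expect_equal(unname(zValues(zd)[1, 3]), 1, tolerance = 1e-12)
  # decreasing metric one control-SD below the mean: z = +1
  expect_equal(unname(zValues(z)[2, ])[6],
               unname((ctrMeanDn - x[2, 6]) / ctrSdDn))
  # z-scores of controls have mean 0 and SD 1 by construction (validity)
  expect_equal(unname(rowMeans(zValues(z)[, isControl])), c(0, 0),
               tolerance = 1e-12)
  expect_equal(unname(apply(zValues(z)[, isControl], 1, sd)), c(1, 1),
               tolerance = 1e-12)
  # degenerate control SD is refused
  expect_error(zscoreMetrics(rbind(m = c(1, 1, 5)), c(m = "increasing"),
                             isControl = c(TRUE, TRUE, FALSE)),
               "degenerate")
})

test_that("z-scoring is invertible back to the adjusted raw scale", {
  cohort <- makeCohort(J = 150, seed = 9)
  dirs <- setNames(c("increasing", "decreasing"), rownames(cohort))
  # flip sign of metric 2 on the raw scale so 'decreasing' is honest
  assay(cohort)[2, ] <- -assay(cohort)[2, ]
  z <- zscoreMetrics(cohort, dirs)
  expect_equal(unZscore(z), assay(cohort), tolerance = 1e-10)
})

test_that("anchor events are tail means of the z distribution", {
  expect_equal(unname(anchorEvents(rbind(m = 1:10), fraction = 0.1)[1, ]),
               c(1, 10))
  # median split
  expect_equal(unname(anchorEvents(rbind(m = 1:10), fraction = 0.5)[1, ]),
               c(mean(1:5), mean(6:10)))
  # matches the sort-based oracle on a large standard-normal sample
  set.seed(13)
  x <- rnorm(1e4)
  a <- anchorEvents(rbind(m = x), fraction = 0.1)
  expect_equal(unname(a[1, ]), tailMeansOracle(x, 0.1), tolerance = 1e-12)
  expect_equal(unname(a[1, 1]), -1.75, tolerance = 0.05)
  # monotone in the tail fraction
  fr <- c(0.05, 0.1, 0.2, 0.3, 0.5)
  anc <- t(vapply(fr, function(f)
    anchorEvents(rbind(m = x), fraction = f)[1, ], numeric(2)))
  expect_true(all(diff(anc[, 1]) >= 0))
  expect_true(all(diff(anc[, 2]) <= 0))
  expect_error(anchorEvents(rbind(m = rep(1, 10))), "degenerate")
})

test_that("quantile event grids enumerate level combinations per metric", {
  set.seed(17)
  z1 <- matrix(rnorm(500), 1, 500,
               dimnames = list("m1", NULL))
  g1 <- quantileEventGrid(z1)
  expect_length(g1, choose(7, 3))       # 35 per metric
  z2 <- rbind(m1 = rnorm(500), m2 = rnorm(500))
  g2 <- quantileEventGrid(z2)
  expect_length(g2, 35^2)               # 1225 for two metrics
  # every emitted grid is strictly monotone per metric
  mono <- vapply(g2[seq(1, length(g2), by = 37)], function(g)
    all(apply(gridZ(g), 1, function(r) all(diff(r) > 0))), logical(1))
  expect_true(all(mono))
  # tied quantiles are dropped, not perturbed
  zTied <- rbind(m1 = c(rep(0, 400), rnorm(100)))
  expect_message(gT <- quantileEventGrid(zTied), "dropped")
  expect_lt(length(gT), 35)
  expect_error(quantileEventGrid(z1, levels = numeric(0)), "empty level")
  expect_error(quantileEventGrid(z1, levels = c(0.5, 0.2)), "increasing")
})

test_that("property: emitted grids are monotone for random data", {
  set.seed(19)
  for (rep in 1:5) {
    z <- matrix(rnorm(2 * 120, sd = runif(1, 0.5, 3)), 2, 120,
                dimnames = list(c("a", "b"), NULL))
    grids <- quantileEventGrid(z, levels = c(0.25, 0.4, 0.6, 0.75),
                               nEvents = 3)
    ok <- vapply(grids, function(g)
      all(apply(gridZ(g), 1, function(r) all(diff(r) > 0))), logical(1))
    expect_true(all(ok))
  }
})
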