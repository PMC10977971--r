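#' Simulate a cross-sectional cohort under the linear z-score event model
#'
#' Generates subjects whose latent z-scores follow the generative
#' counterpart of the staging model: a true stage is drawn uniformly over
#' the N+1 stages (matching the model's uniform prior), the latent
#' z-vector is the stage z-score \eqn{\mu_i(k)} of the planted grid and
#' sequence (shared with [stageZscores()], so generator and model use one
#' definition) plus independent Gaussian noise. Latent z-scores are
#' mapped to the raw metric scale by a per-metric affine map with the
#' trend direction un-inverted, covariate effects (age, total
#' intracranial volume, scan-date offsets) are added, and clinical
#' ratings (CDR 0 / 0.5 / 1 / 2) are assigned by thresholding the true
#' stage with a configurable label-flip rate emulating imperfect
#' stage-to-rating alignment. Subjects rated CDR 0 form the control
#' group.
#'
#' Covariate distributions: age ~ uniform(49, 88) years, TIV ~
#' normal(1450, 120) ml, date offsets ~ normal(0, 1) years.
#'
#' @param nSubjects number of subjects J.
#' @param grid planted [EventGrid-class] (z units).
#' @param sequence planted [EventSequence-class].
#' @param noiseSd Gaussian noise SD in z units (model value 1; >= 0).
#' @param directions per-metric \code{"increasing"} / \code{"decreasing"}
#'   raw-scale trend (default all increasing).
#' @param rawMean,rawSd per-metric affine map from z to the raw scale
#'   (defaults 0 and 1: raw equals signed z).
#' @param covariateEffects metrics x covariates matrix of raw-scale
#'   slopes; columns named among \code{age}, \code{tiv},
#'   \code{date_offset_mri}, \code{date_offset_mmse}. Default all zero.
#' @param cdrStageBreaks stage thresholds mapping true stage to CDR
#'   categories: stages <= breaks[1] are CDR 0, then 0.5, 1, 2. Default
#'   splits the stage range as in a typical progression cohort.
#' @param labelFlip probability a subject's CDR is flipped to an adjacent
#'   category (default 0.1).
#' @param seed integer seed; generation is deterministic given it.
#' @return A \code{SummarizedExperiment}: assay \code{"raw"} (metrics x
#'   subjects), \code{colData} with \code{subject_id}, \code{group},
#'   \code{cdr}, \code{age}, \code{tiv}, \code{date_offset_mri},
#'   \code{date_offset_mmse}; \code{metadata()$groundTruth} holds the
#'   true stages, latent z-scores, planted grid/sequence and the affine
#'   map.
#' @export
simulateCohort <- function(nSubjects, grid, sequence, noiseSd = 1,
                           directions = NULL, rawMean = NULL, rawSd = NULL,
                           covariateEffects = NULL,
                           cdrStageBreaks = NULL, labelFlip = 0.1,
                           seed = 1) {
  stopifnot(is(grid, "EventGrid"), is(sequence, "EventSequence"))
  if (noiseSd < 0) stop("noiseSd must be nonnegative")
  model <- stageZscores(grid, sequence)   # validates the interleaving
  mu <- model@mu
  I <- nrow(mu)
  K <- ncol(mu)
  metricNames <- rownames(grid@z)
  if (is.null(directions)) directions <- rep("increasing", I)
  if (is.null(rawMean)) rawMean <- rep(0, I)
  if (is.null(rawSd)) rawSd <- rep(1, I)
  stopifnot(length(directions) == I, length(rawMean) == I,
            length(rawSd) == I, all(rawSd > 0))
  if (is.null(cdrStageBreaks))
    cdrStageBreaks <- round(K * c(0.45, 0.75, 0.9))
  .withSeed(seed, {
    stage <- sample.int(K, nSubjects, replace = TRUE)
    zLatent <- mu[, stage, drop = FALSE] +
      matrix(rnorm(I * nSubjects, sd = noiseSd), I, nSubjects)
    covs <- data.frame(
      age = runif(nSubjects, 49, 88),
      tiv = rnorm(nSubjects, 1450, 120),
      date_offset_mri = rnorm(nSubjects, 0, 1),
      date_offset_mmse = rnorm(nSubjects, 0, 1))
    sgn <- ifelse(directions == "decreasing", -1, 1)
    raw <- sweep(zLatent * sgn, 1, rawSd, "*")
    raw <- sweep(raw, 1, rawMean, "+")
    if (!is.null(covariateEffects)) {
      covariateEffects <- as.matrix(covariateEffects)
      if (is.null(colnames(covariateEffects)) ||
          !all(colnames(covariateEffects) %in% colnames(covs)))
        stop("covariateEffects columns must be named covariates")
      X <- as.matrix(covs[, colnames(covariateEffects), drop = FALSE])
      Xc <- sweep(X, 2, colMeans(X))
      raw <- raw + covariateEffects %*% t(Xc)
    }
    cdrLevels <- c(0, 0.5, 1, 2)
    cat0 <- findInterval(stage, c(-Inf, cdrStageBreaks + 0.5)) # 1..4
    flip <- runif(nSubjects) < labelFlip
    shift <- ifelse(rbinom(nSubjects, 1, 0.5) == 1, 1L, -1L)
    cat <- ifelse(flip, pmin(pmax(cat0 + shift, 1L), 4L), cat0)
    cdr <- cdrLevels[cat]
    group <- ifelse(cdr == 0, "control", "patient")
    if (sum(group == "control") < 2 || sum(group == "patient") < 1)
      warning("degenerate group split; consider different cdrStageBreaks")
    dimnames(raw) <- list(metricNames,
                          sprintf("subj_%03d", seq_len(nSubjects)))
    se <- SummarizedExperiment(
      assays = list(raw = raw),
      colData = S4Vectors::DataFrame(
        subject_id = colnames(raw), group = group, cdr = cdr, covs,
        row.names = colnames(raw)))
    S4Vectors::metadata(se)$groundTruth <- list(
      stage = stage, zLatent = zLatent, grid = grid, sequence = sequence,
      mu = mu, directions = directions, rawMean = rawMean, rawSd = rawSd,
      noiseSd = noiseSd, seed = seed)
    se
  })
}

#' Write / read a cohort as delimited text
#'
#' The cohort CSV has one row per subject with columns \code{subject_id},
#' \code{group}, \code{cdr}, \code{age}, \code{tiv},
#' \code{date_offset_mri}, \code{date_offset_mmse} followed by one column
#' per metric. Ground truth (when present) goes to a JSON sidecar.
#'
#' @param cohort a \code{SummarizedExperiment} as from
#'   [simulateCohort()].
#' @param path CSV file path.
#' @param truthPath optional JSON path for the ground-truth sidecar.
#' @return \code{path}, invisibly.
#' @export
writeCohortCSV <- function(cohort, path, truthPath = NULL) {
  x <- assay(cohort)
  cd <- as.data.frame(colData(cohort))
  df <- cbind(cd, as.data.frame(t(x)))
  write.csv(df, path, row.names = FALSE)
  gt <- S4Vectors::metadata(cohort)$groundTruth
  if (!is.null(truthPath) && !is.null(gt)) {
    jsonlite::write_json(list(
      stage = gt$stage,
      sequence = gt$sequence@metricIndex,
      metricNames = rownames(gt$grid@z),
      gridZ = gt$grid@z,
      directions = gt$directions,
      rawMean = gt$rawMean, rawSd = gt$rawSd,
      noiseSd = gt$noiseSd, seed = gt$seed),
      truthPath, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname writeCohortCSV
#' @param metricNames metric column names; by default every column after
#'   the seven standard subject columns.
#' @export
readCohortCSV <- function(path, metricNames = NULL) {
  df <- read.csv(path, check.names = FALSE)
  std <- c("subject_id", "group", "cdr", "age", "tiv",
           "date_offset_mri", "date_offset_mmse")
  missing <- setdiff(std, colnames(df))
  if (length(missing) > 0)
    stop("schema error: missing column(s) ", paste(missing, collapse = ", "))
  if (is.null(metricNames)) metricNames <- setdiff(colnames(df), std)
  x <- t(as.matrix(df[, metricNames, drop = FALSE]))
  colnames(x) <- df$subject_id
  SummarizedExperiment(
    assays = list(raw = x),
    colData = S4Vectors::DataFrame(df[, std], row.names = df$subject_id))
}
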