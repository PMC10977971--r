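#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<-
#'   colData colData<-
#' @importFrom S4Vectors DataFrame metadata
NULL

#' Adjust metrics for covariates by a normative linear model
#'
#' Fits, on the reference (control) group only, a linear model of the
#' metric on the named covariates, then removes the fitted covariate
#' effect from every subject:
#' \code{adjusted = observed - (X - meanRef(X)) \%*\% beta}. Centering the
#' design at the reference-group covariate means retains the intercept, so
#' the reference-group mean of the metric is unchanged. Fitting on
#' controls only avoids absorbing disease effects into the covariate
#' slopes.
#'
#' @param cohort a \code{SummarizedExperiment} (metrics x subjects assay,
#'   covariates and \code{group} in \code{colData}).
#' @param metrics metric names to adjust (default: all rows).
#' @param covariates character vector of covariate column names, or a
#'   named list mapping metric name -> covariate vector for per-metric
#'   covariate sets.
#' @param referenceGroup level of \code{colData(cohort)$group} defining
#'   the normative population.
#' @return the cohort with the adjusted assay (same shape).
#' @export
adjustCovariates <- function(cohort, metrics = NULL, covariates,
                             referenceGroup = "control") {
  x <- assay(cohort)
  cd <- as.data.frame(colData(cohort))
  if (is.null(metrics)) metrics <- rownames(x)
  if (!is.list(covariates))
    covariates <- setNames(rep(list(covariates), length(metrics)), metrics)
  ref <- cd$group == referenceGroup
  for (m in metrics) {
    covs <- covariates[[m]]
    if (is.null(covs)) next
    if (!all(covs %in% colnames(cd)))
      stop("missing covariate column(s): ",
           paste(setdiff(covs, colnames(cd)), collapse = ", "))
    X <- as.matrix(cd[, covs, drop = FALSE])
    if (!is.numeric(X)) stop("covariates must be numeric")
    if (sum(ref) <= ncol(X) + 1)
      stop("reference group too small to fit ", ncol(X), " covariates")
    Xr <- X[ref, , drop = FALSE]
    qrX <- qr(cbind(1, Xr))
    if (qrX$rank < ncol(Xr) + 1)
      stop("collinearity: rank-deficient covariate design for metric ", m)
    beta <- qr.coef(qrX, x[m, ref])[-1]
    x[m, ] <- x[m, ] - as.numeric(sweep(X, 2, colMeans(Xr)) %*% beta)
  }
  out <- cohort
  assay(out) <- x
  out
}

#' Signed z-scoring against the control group
#'
#' Standardizes each metric by the control-group mean and SD. Metrics that
#' decrease with disease progression are sign-inverted,
#' \eqn{z_{ij} = (\bar x_i^C - x_{ij}) / \sigma_i^C}, while increasing
#' metrics use the standard \eqn{z_{ij} = (x_{ij} - \bar x_i^C) /
#' \sigma_i^C}; either way a larger z-score means more severity, as the
#' linear z-score event model requires.
#'
#' @param cohort a \code{SummarizedExperiment} with a \code{group} column
#'   in \code{colData}, or a metrics x subjects matrix together with
#'   \code{isControl}.
#' @param directions named character vector, per metric
#'   \code{"increasing"} or \code{"decreasing"} (trend along disease
#'   progression on the raw scale).
#' @param isControl logical per subject; defaults to
#'   \code{group == "control"} for a SummarizedExperiment.
#' @return a [ZScoreMatrix-class].
#' @export
zscoreMetrics <- function(cohort, directions, isControl = NULL) {
  if (is(cohort, "SummarizedExperiment")) {
    x <- assay(cohort)
    if (is.null(isControl))
      isControl <- colData(cohort)$group == "control"
  } else {
    x <- as.matrix(cohort)
  }
  if (is.null(isControl) || length(isControl) != ncol(x))
    stop("isControl must flag every subject")
  if (sum(isControl) < 2) stop("need at least two control subjects")
  if (is.null(names(directions))) names(directions) <- rownames(x)
  directions <- directions[rownames(x)]
  if (any(is.na(directions)))
    stop("directions must be supplied for every metric")
  ctr <- rowMeans(x[, isControl, drop = FALSE])
  scl <- apply(x[, isControl, drop = FALSE], 1, sd)
  if (any(scl <= 0)) stop("degenerate metric: zero control SD")
  sgn <- ifelse(directions == "decreasing", -1, 1)
  z <- sweep(sweep(x, 1, ctr), 1, scl, "/") * sgn
  new("ZScoreMatrix", values = z, directions = as.character(directions),
      center = as.numeric(ctr), scale = as.numeric(scl),
      isControl = as.logical(isControl))
}

#' Invert z-scoring back to the (adjusted) raw scale
#'
#' @param z a [ZScoreMatrix-class].
#' @return metrics x subjects matrix on the raw scale.
#' @export
unZscore <- function(z) {
  stopifnot(is(z, "ZScoreMatrix"))
  sgn <- ifelse(z@directions == "decreasing", -1, 1)
  sweep(sweep(z@values, 1, sgn / z@scale, "/"), 1, z@center, "+")
}

#' Anchor events from distribution tails
#'
#' The initial and final event z-scores for each metric are the means of
#' the bottom and top \code{fraction} tails of that metric's z-score
#' distribution over the full cohort: all values at or below the
#' \code{fraction} sample quantile, and at or above the
#' \code{1 - fraction} quantile (type-7 quantiles).
#'
#' @param z a [ZScoreMatrix-class] or metrics x subjects matrix.
#' @param fraction tail fraction (default 0.1, i.e. bottom/top 10\%).
#' @return metrics x 2 matrix with columns \code{z_initial},
#'   \code{z_final}.
#' @export
anchorEvents <- function(z, fraction = 0.1) {
  v <- if (is(z, "ZScoreMatrix")) z@values else as.matrix(z)
  if (ncol(v) * fraction < 1)
    stop("tail fraction too small for ", ncol(v), " subjects")
  out <- t(apply(v, 1, function(r) {
    lo <- mean(r[r <= quantile(r, fraction, type = 7)])
    hi <- mean(r[r >= quantile(r, 1 - fraction, type = 7)])
    c(lo, hi)
  }))
  if (any(out[, 1] >= out[, 2]))
    stop("degenerate anchors: initial >= final for some metric")
  colnames(out) <- c("z_initial", "z_final")
  out
}

#' Candidate event grids from quantile combinations
#'
#' Builds every candidate [EventGrid-class] obtained by choosing
#' \code{nEvents} of the supplied quantile levels for each metric
#' (intermediate event z-scores = sample quantiles of that metric's
#' z-distribution) and crossing the per-metric choices. With the default
#' seven levels and three events this yields choose(7,3) = 35 candidate
#' triples per metric, hence 35^I grids for I metrics (1225 for two,
#' 42875 for three). Grids violating strict per-metric monotonicity
#' (including against the anchors) are dropped with a message.
#'
#' @param z a [ZScoreMatrix-class] or metrics x subjects matrix.
#' @param levels strictly increasing quantile levels in (0, 1); default
#'   \code{seq(0.2, 0.8, by = 0.1)}.
#' @param nEvents intermediate events per metric (default 3).
#' @param anchors metrics x 2 anchor matrix; default
#'   \code{anchorEvents(z)}.
#' @return list of [EventGrid-class] candidates.
#' @export
quantileEventGrid <- function(z, levels = seq(0.2, 0.8, by = 0.1),
                              nEvents = 3, anchors = anchorEvents(z)) {
  v <- if (is(z, "ZScoreMatrix")) z@values else as.matrix(z)
  if (length(levels) == 0) stop("configuration error: empty level set")
  if (any(levels <= 0) || any(levels >= 1) || any(diff(levels) <= 0))
    stop("levels must be strictly increasing in (0, 1)")
  if (nEvents > length(levels))
    stop("nEvents exceeds the number of levels")
  I <- nrow(v)
  metricNames <- rownames(v)
  if (is.null(metricNames)) metricNames <- paste0("metric_", seq_len(I))
  combos <- utils::combn(levels, nEvents)        # levels x nCombo
  perMetric <- vector("list", I)
  for (i in seq_len(I)) {
    qs <- quantile(v[i, ], probs = levels, type = 7, names = FALSE)
    names(qs) <- as.character(levels)
    perMetric[[i]] <- lapply(seq_len(ncol(combos)), function(cix) {
      lv <- combos[, cix]
      list(levels = lv, z = qs[as.character(lv)])
    })
  }
  idx <- expand.grid(lapply(perMetric, seq_along))
  grids <- vector("list", nrow(idx))
  nDropped <- 0L
  kept <- 0L
  for (g in seq_len(nrow(idx))) {
    zmat <- matrix(NA_real_, I, nEvents + 2L,
                   dimnames = list(metricNames, NULL))
    lmat <- matrix(NA_real_, I, nEvents)
    ok <- TRUE
    for (i in seq_len(I)) {
      cand <- perMetric[[i]][[idx[g, i]]]
      row <- c(anchors[i, 1], cand$z, anchors[i, 2])
      if (any(diff(row) <= 0)) { ok <- FALSE; break }
      zmat[i, ] <- row
      lmat[i, ] <- cand$levels
    }
    if (!ok) { nDropped <- nDropped + 1L; next }
    kept <- kept + 1L
    grids[[kept]] <- new("EventGrid", z = zmat, levels = lmat)
  }
  if (nDropped > 0)
    message(nDropped, " candidate grid(s) dropped for tied/non-monotone ",
            "event z-scores")
  grids[seq_len(kept)]
}
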