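#' @import methods
#' @importFrom stats approx cor fft lm median quantile rnorm runif sd var
#'   dnorm rbinom setNames p.adjust complete.cases coef
#' @importFrom utils read.csv write.csv head
NULL

#' Frequency band definition
#'
#' A named frequency band \code{[low, high]} in Hz used for band-pass
#' filtering, amplitude-envelope correlation and relative band power.
#'
#' @slot name character band name (e.g. \code{"alpha"}).
#' @slot low lower band edge in Hz.
#' @slot high upper band edge in Hz.
#'
#' @seealso [frequencyBand()], [defaultBands()]
#' @export
setClass("FrequencyBand",
  representation(name = "character", low = "numeric", high = "numeric"))

setValidity("FrequencyBand", function(object) {
  if (length(object@low) != 1L || length(object@high) != 1L)
    return("low/high must be scalars")
  if (!is.finite(object@low) || !is.finite(object@high))
    return("band edges must be finite")
  if (object@low <= 0) return("low must be > 0")
  if (object@high <= object@low) return("high must exceed low")
  TRUE
})

#' Regional time courses
#'
#' A regions-by-samples real matrix of source-level time courses with its
#' sampling rate and atlas region labels.
#'
#' @slot data numeric matrix, regions in rows, samples in columns.
#' @slot samplingRate sampling rate in Hz.
#' @slot regionLabels character vector of region names, one per row.
#'
#' @seealso [regionalTimeSeries()], [aecMatrix()], [welchPSD()]
#' @export
setClass("RegionalTimeSeries",
  representation(data = "matrix", samplingRate = "numeric",
                 regionLabels = "character"))

setValidity("RegionalTimeSeries", function(object) {
  if (!is.numeric(object@data)) return("data must be numeric")
  if (any(!is.finite(object@data))) return("data contains non-finite values")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    return("samplingRate must be a positive scalar")
  if (ncol(object@data) < 2 * object@samplingRate)
    return("record must be at least 2 s long (T >= 2 * samplingRate)")
  if (length(object@regionLabels) != nrow(object@data))
    return("one region label per row required")
  TRUE
})

#' Symmetric connectivity matrix
#'
#' Region-by-region amplitude-envelope correlations for one frequency band.
#' The diagonal is not defined for AEC and is stored as \code{NA}.
#'
#' @slot values symmetric numeric matrix, entries in \code{[-1, 1]},
#'   \code{NA} diagonal.
#' @slot band the [FrequencyBand-class] the matrix was computed in.
#'
#' @seealso [aecMatrix()], [regionalConnectivity()]
#' @export
setClass("ConnectivityMatrix",
  representation(values = "matrix", band = "FrequencyBand"))

setValidity("ConnectivityMatrix", function(object) {
  v <- object@values
  if (nrow(v) != ncol(v)) return("matrix must be square")
  off <- v[row(v) != col(v)]
  if (any(!is.finite(off))) return("off-diagonal entries must be finite")
  if (any(abs(off) > 1 + 1e-12)) return("correlations must lie in [-1, 1]")
  if (max(abs(v - t(v)), na.rm = TRUE) > 1e-10)
    return("matrix must be symmetric")
  TRUE
})

#' Welch power spectral densities
#'
#' One-sided power spectral densities for a set of regions on a common
#' frequency grid, in power per Hz (density scaling, so that
#' \code{sum(power) * resolution} approximates the signal variance).
#'
#' @slot frequencies frequency grid in Hz.
#' @slot power regions x frequencies matrix of nonnegative densities.
#' @slot resolution grid step in Hz, \code{samplingRate / segmentLength}.
#'
#' @seealso [welchPSD()], [relativeBandPower()]
#' @export
setClass("PSDSet",
  representation(frequencies = "numeric", power = "matrix",
                 resolution = "numeric"))

setValidity("PSDSet", function(object) {
  if (ncol(object@power) != length(object@frequencies))
    return("power columns must match the frequency grid")
  if (any(object@power < 0)) return("power must be nonnegative")
  if (length(object@resolution) != 1L || object@resolution <= 0)
    return("resolution must be a positive scalar")
  TRUE
})

#' Event threshold grid
#'
#' Per-metric event z-scores: the initial anchor, the intermediate event
#' thresholds, and the final anchor, strictly increasing within each metric.
#'
#' @slot z metrics x (events + 2) numeric matrix; column 1 is the initial
#'   anchor, the last column the final anchor.
#' @slot levels numeric matrix of the quantile levels that generated the
#'   intermediate events (zero rows when not quantile-derived).
#'
#' @seealso [eventGrid()], [quantileEventGrid()], [stageZscores()]
#' @export
setClass("EventGrid",
  representation(z = "matrix", levels = "matrix"))

setValidity("EventGrid", function(object) {
  z <- object@z
  if (ncol(z) < 3) return("need at least one event between the anchors")
  if (is.null(rownames(z))) return("metric names required as rownames")
  if (any(!is.finite(z))) return("event z-scores must be finite")
  if (any(apply(z, 1, function(r) any(diff(r) <= 0))))
    return("event z-scores must be strictly increasing within each metric")
  TRUE
})

#' Ordered event sequence
#'
#' A global ordering of all per-metric events. Within each metric, events
#' must occur in ascending z-score order, so a sequence is fully determined
#' by the order of metric labels; within-metric event indices follow by
#' cumulative count.
#'
#' @slot metricIndex integer vector of metric indices, one per sequence
#'   position.
#' @slot metricNames character vector naming the metrics.
#'
#' @seealso [eventSequence()], [sequenceEvents()], [mcmcSequences()]
#' @export
setClass("EventSequence",
  representation(metricIndex = "integer", metricNames = "character"))

setValidity("EventSequence", function(object) {
  if (length(object@metricIndex) < 1L) return("empty sequence")
  if (any(object@metricIndex < 1L |
          object@metricIndex > length(object@metricNames)))
    return("metric indices out of range")
  TRUE
})

#' Piecewise-linear stage model
#'
#' Stage z-scores \eqn{\mu_i(k)} implied by an event grid and a sequence:
#' event occurrence times sit on the integer grid (0 = initial anchor,
#' 1..N = ordered events, N+1 = final anchor), stages at the half-integer
#' midpoints, and each metric's z trajectory is linearly interpolated
#' through its own events.
#'
#' @slot grid the [EventGrid-class].
#' @slot sequence the [EventSequence-class].
#' @slot mu metrics x (N+1) matrix of stage z-scores.
#'
#' @seealso [stageZscores()], [dataLogLikelihood()], [stagePosterior()]
#' @export
setClass("StageModel",
  representation(grid = "EventGrid", sequence = "EventSequence",
                 mu = "matrix"))

setValidity("StageModel", function(object) {
  mu <- object@mu
  if (nrow(mu) != nrow(object@grid@z)) return("mu rows must match metrics")
  if (ncol(mu) != length(object@sequence@metricIndex) + 1L)
    return("mu must have N + 1 stages")
  if (any(apply(mu, 1, function(r) any(diff(r) < -1e-10))))
    return("stage z-scores must be non-decreasing within each metric")
  TRUE
})

#' Signed z-score matrix
#'
#' Metric-by-subject signed z-scores standardized against the control
#' group, with the affine map (center, scale, direction) retained so the
#' transformation is invertible. For metrics that decrease with disease
#' progression the sign is inverted so that larger z always means more
#' severe.
#'
#' @slot values metrics x subjects numeric z-score matrix.
#' @slot directions per-metric \code{"increasing"} or \code{"decreasing"}.
#' @slot center per-metric control mean on the raw scale.
#' @slot scale per-metric control SD on the raw scale.
#' @slot isControl logical per subject; the standardization population.
#'
#' @seealso [zscoreMetrics()], [unZscore()], [anchorEvents()]
#' @export
setClass("ZScoreMatrix",
  representation(values = "matrix", directions = "character",
                 center = "numeric", scale = "numeric",
                 isControl = "logical"))

setValidity("ZScoreMatrix", function(object) {
  v <- object@values
  if (any(!is.finite(v))) return("z-scores must be finite")
  if (length(object@directions) != nrow(v) ||
      length(object@center) != nrow(v) || length(object@scale) != nrow(v))
    return("per-metric slots must match the number of metrics")
  if (!all(object@directions %in% c("increasing", "decreasing")))
    return("directions must be 'increasing' or 'decreasing'")
  if (length(object@isControl) != ncol(v))
    return("isControl must flag every subject")
  if (sum(object@isControl) >= 2) {
    ctrl <- v[, object@isControl, drop = FALSE]
    if (max(abs(rowMeans(ctrl))) > 1e-8)
      return("control columns must have zero mean per metric")
    if (max(abs(apply(ctrl, 1, sd) - 1)) > 1e-8)
      return("control columns must have unit SD per metric")
  }
  TRUE
})

#' Fitted event-based model
#'
#' Result of the event-setting optimization: the winning stage model, its
#' log-likelihood, the MCMC sample record for the winning grid, and
#' bookkeeping for reproducibility.
#'
#' @slot model the best [StageModel-class].
#' @slot logLik best data log-likelihood.
#' @slot samples integer matrix (samples x N) of MCMC sequence samples
#'   (metric labels) for the winning grid.
#' @slot sampleLogLik per-sample log-likelihoods.
#' @slot seed integer seed that regenerates the fit.
#' @slot gridIndex index of the winning grid in the candidate list.
#' @slot nGrids number of candidate grids evaluated.
#' @slot nTies number of grids tying the best log-likelihood (ties broken
#'   by candidate order).
#'
#' @seealso [optimizeEventSettings()], [positionalVariance()]
#' @export
setClass("EbmFit",
  representation(model = "StageModel", logLik = "numeric",
                 samples = "matrix", sampleLogLik = "numeric",
                 seed = "integer", gridIndex = "integer",
                 nGrids = "integer", nTies = "integer"))

setValidity("EbmFit", function(object) {
  if (length(object@logLik) != 1L || !is.finite(object@logLik))
    return("logLik must be a finite scalar")
  if (ncol(object@samples) != length(object@model@sequence@metricIndex))
    return("sample columns must match the number of events")
  TRUE
})
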