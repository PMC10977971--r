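#' Create a frequency band
#'
#' @param name band name.
#' @param low,high band edges in Hz, \code{0 < low < high}.
#' @return A [FrequencyBand-class] object.
#' @examples
#' frequencyBand("alpha", 8, 12)
#' @export
frequencyBand <- function(name, low, high) {
  new("FrequencyBand", name = as.character(name),
      low = as.numeric(low), high = as.numeric(high))
}

#' Canonical frequency bands
#'
#' The three canonical resting-state bands used throughout: delta-theta
#' (2-7 Hz), alpha (8-12 Hz) and beta (15-29 Hz).
#'
#' @return Named list of [FrequencyBand-class] objects.
#' @export
defaultBands <- function() {
  list(delta_theta = frequencyBand("delta_theta", 2, 7),
       alpha       = frequencyBand("alpha", 8, 12),
       beta        = frequencyBand("beta", 15, 29))
}

#' Create a regional time-series object
#'
#' @param data regions x samples numeric matrix.
#' @param samplingRate sampling rate in Hz.
#' @param regionLabels optional region names (defaults to rownames or
#'   \code{region_1 ...}).
#' @return A [RegionalTimeSeries-class] object.
#' @export
regionalTimeSeries <- function(data, samplingRate, regionLabels = NULL) {
  data <- as.matrix(data)
  if (is.null(regionLabels))
    regionLabels <- if (!is.null(rownames(data))) rownames(data) else
      paste0("region_", seq_len(nrow(data)))
  rownames(data) <- regionLabels
  new("RegionalTimeSeries", data = data,
      samplingRate = as.numeric(samplingRate),
      regionLabels = as.character(regionLabels))
}

#' Create an event grid
#'
#' @param z metrics x (events + 2) matrix: initial anchor, intermediate
#'   event z-scores, final anchor, strictly increasing per row.
#' @param metricNames optional metric names (defaults to rownames).
#' @param levels optional matrix of quantile levels generating the
#'   intermediate events.
#' @return An [EventGrid-class] object.
#' @export
eventGrid <- function(z, metricNames = NULL, levels = NULL) {
  z <- as.matrix(z)
  if (!is.null(metricNames)) rownames(z) <- metricNames
  if (is.null(rownames(z)))
    rownames(z) <- paste0("metric_", seq_len(nrow(z)))
  if (is.null(levels)) levels <- matrix(numeric(0), nrow = 0, ncol = 0)
  new("EventGrid", z = z, levels = as.matrix(levels))
}

#' Create an event sequence
#'
#' A sequence is given either as a vector of metric labels (one per event
#' position; within-metric event indices follow in ascending order, which
#' is the only valid interleaving) or as a two-column matrix of
#' (metric index, within-metric event index) pairs, which is validated for
#' ascending within-metric order.
#'
#' @param metricIndex integer vector of metric indices, or a two-column
#'   matrix of (metric, event) pairs.
#' @param metricNames metric names.
#' @return An [EventSequence-class] object.
#' @export
eventSequence <- function(metricIndex, metricNames = NULL) {
  if (is.matrix(metricIndex)) {
    pairs <- metricIndex
    metricIndex <- as.integer(pairs[, 1])
    for (m in unique(metricIndex)) {
      ev <- pairs[pairs[, 1] == m, 2]
      if (any(diff(ev) <= 0) || any(ev != seq_along(ev)))
        stop("invalid interleaving: within-metric events of metric ", m,
             " must appear in ascending order 1, 2, ...")
    }
  }
  metricIndex <- as.integer(metricIndex)
  if (is.null(metricNames))
    metricNames <- paste0("metric_", seq_len(max(metricIndex)))
  new("EventSequence", metricIndex = metricIndex,
      metricNames = as.character(metricNames))
}

#' Events of a sequence as a table
#'
#' @param sequence an [EventSequence-class].
#' @return data.frame with columns \code{position}, \code{metric},
#'   \code{metricName}, \code{event} (within-metric event index).
#' @export
sequenceEvents <- function(sequence) {
  stopifnot(is(sequence, "EventSequence"))
  idx <- sequence@metricIndex
  cnt <- integer(length(sequence@metricNames))
  ev <- integer(length(idx))
  for (p in seq_along(idx)) {
    cnt[idx[p]] <- cnt[idx[p]] + 1L
    ev[p] <- cnt[idx[p]]
  }
  data.frame(position = seq_along(idx), metric = idx,
             metricName = sequence@metricNames[idx], event = ev)
}

# ---- accessors ------------------------------------------------------------

#' @describeIn regionalTimeSeries the data matrix.
#' @param x object.
#' @export
tsData <- function(x) x@data

#' @describeIn regionalTimeSeries sampling rate in Hz.
#' @export
samplingRate <- function(x) x@samplingRate

#' @describeIn regionalTimeSeries region labels.
#' @export
regionLabels <- function(x) x@regionLabels

#' @describeIn regionalTimeSeries number of regions.
#' @export
nRegions <- function(x) nrow(x@data)

#' Connectivity matrix values
#' @param x a [ConnectivityMatrix-class].
#' @export
connValues <- function(x) x@values

#' Event-grid z matrix
#' @param x an [EventGrid-class].
#' @export
gridZ <- function(x) x@z

#' Stage z-scores of a model
#' @param x a [StageModel-class].
#' @export
stageMu <- function(x) x@mu

#' Number of stages of a stage model (events + 1)
#' @param x a [StageModel-class].
#' @export
nStages <- function(x) ncol(x@mu)

#' Z-score values
#' @param x a [ZScoreMatrix-class].
#' @export
zValues <- function(x) x@values

#' Best stage model of a fit
#' @param x an [EbmFit-class].
#' @export
bestModel <- function(x) x@model

#' Best log-likelihood of a fit
#' @param x an [EbmFit-class].
#' @export
bestLogLik <- function(x) x@logLik

#' MCMC sequence samples of a fit
#' @param x an [EbmFit-class].
#' @export
mcmcSamples <- function(x) x@samples

# ---- show methods ---------------------------------------------------------

setMethod("show", "FrequencyBand", function(object) {
  cat(sprintf("FrequencyBand '%s': %.3g-%.3g Hz\n",
              object@name, object@low, object@high))
})

setMethod("show", "RegionalTimeSeries", function(object) {
  cat(sprintf("RegionalTimeSeries: %d regions x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@samplingRate,
              ncol(object@data) / object@samplingRate))
})

setMethod("show", "ConnectivityMatrix", function(object) {
  off <- object@values[row(object@values) != col(object@values)]
  cat(sprintf("ConnectivityMatrix (%s band): %d regions, mean AEC %.4f\n",
              object@band@name, nrow(object@values), mean(off)))
})

setMethod("show", "PSDSet", function(object) {
  cat(sprintf("PSDSet: %d regions, %d bins, resolution %.6g Hz\n",
              nrow(object@power), ncol(object@power), object@resolution))
})

setMethod("show", "EventGrid", function(object) {
  cat(sprintf("EventGrid: %d metrics x %d events (+2 anchors)\n",
              nrow(object@z), ncol(object@z) - 2L))
  print(round(object@z, 4))
})

setMethod("show", "EventSequence", function(object) {
  ev <- sequenceEvents(object)
  cat("EventSequence:",
      paste(sprintf("%s.%d", ev$metricName, ev$event), collapse = " -> "),
      "\n")
})

setMethod("show", "StageModel", function(object) {
  cat(sprintf("StageModel: %d metrics, %d events, %d stages\n",
              nrow(object@mu), ncol(object@mu) - 1L, ncol(object@mu)))
})

setMethod("show", "ZScoreMatrix", function(object) {
  cat(sprintf("ZScoreMatrix: %d metrics x %d subjects (%d controls)\n",
              nrow(object@values), ncol(object@values),
              sum(object@isControl)))
})

setMethod("show", "EbmFit", function(object) {
  cat(sprintf(paste0("EbmFit: best of %d grid(s), log-likelihood %.4f, ",
                     "%d MCMC samples\n"),
              object@nGrids, object@logLik, nrow(object@samples)))
  show(object@model@sequence)
})

#' @describeIn eventSequence number of events.
#' @param x an EventSequence.
#' @export
setMethod("length", "EventSequence", function(x) length(x@metricIndex))
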