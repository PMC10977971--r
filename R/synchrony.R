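#' Pairwise orthogonalization of two time courses
#'
#' Removes from \code{y} its least-squares projection on \code{x}
#' (intercept included), leaving a residual with exactly zero sample
#' correlation with \code{x}. Applied to band-limited regional signals
#' before envelope extraction, this discounts zero-lag leakage: any
#' instantaneously mixed copy of \code{x} inside \code{y} is removed.
#'
#' @param x seed time course (nonzero variance).
#' @param y target time course, same length.
#' @return the orthogonalized residual of \code{y}.
#' @examples
#' x <- sin(seq(0, 10, length.out = 500))
#' max(abs(pairwiseOrthogonalize(x, 2 * x)))  # collinear -> ~0
#' @export
pairwiseOrthogonalize <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  vx <- var(x)
  if (!is.finite(vx) || vx <= .Machine$double.eps)
    stop("degenerate seed: x has zero variance")
  beta <- cov(x, y) / vx
  y - mean(y) - beta * (x - mean(x))
}

#' Leakage-corrected amplitude-envelope correlation matrix
#'
#' For every ordered region pair the two signals are band-pass filtered,
#' the target is orthogonalized on the seed, amplitude envelopes are taken
#' as the modulus of the analytic signal, and the envelopes are Pearson
#' correlated. Orthogonalization is asymmetric, so the two directions are
#' averaged to produce a symmetric AEC matrix. With
#' \code{orthogonalize = FALSE} the uncorrected AEC is returned (useful to
#' demonstrate leakage).
#'
#' A zero-variance orthogonalized envelope (e.g. the target is an exact
#' scalar multiple of the seed) yields a flagged entry of 0 with a warning
#' rather than \code{NaN}.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param band a [FrequencyBand-class] valid for the sampling rate.
#' @param orthogonalize logical; apply pairwise leakage correction
#'   (default \code{TRUE}).
#' @return a [ConnectivityMatrix-class] with \code{NA} diagonal.
#' @references Hipp et al. (2012) Nat Neurosci; Brookes et al. (2012)
#'   NeuroImage (pairwise orthogonalization for envelope correlations).
#' @export
aecMatrix <- function(ts, band, orthogonalize = TRUE) {
  stopifnot(is(ts, "RegionalTimeSeries"), is(band, "FrequencyBand"))
  if (band@high >= ts@samplingRate / 2)
    stop("band exceeds the Nyquist frequency")
  x <- ts@data
  R <- nrow(x)
  if (R < 2) stop("need at least two regions")
  filt <- bandpassFilter(x, band, ts@samplingRate)
  env <- t(apply(filt, 1, amplitudeEnvelope))
  vals <- matrix(NA_real_, R, R, dimnames = list(ts@regionLabels,
                                                 ts@regionLabels))
  nDegenerate <- 0L
  for (s in seq_len(R - 1)) {
    for (t in (s + 1):R) {
      if (orthogonalize) {
        r1 <- .envCor(env[s, ], pairwiseOrthogonalize(filt[s, ], filt[t, ]))
        r2 <- .envCor(env[t, ], pairwiseOrthogonalize(filt[t, ], filt[s, ]))
      } else {
        r1 <- r2 <- cor(env[s, ], env[t, ])
      }
      if (is.na(r1) || is.na(r2)) {
        nDegenerate <- nDegenerate + 1L
        r1 <- ifelse(is.na(r1), 0, r1)
        r2 <- ifelse(is.na(r2), 0, r2)
      }
      vals[s, t] <- vals[t, s] <- (r1 + r2) / 2
    }
  }
  if (nDegenerate > 0)
    warning(nDegenerate, " degenerate (zero-variance) envelope pair(s) set to 0")
  new("ConnectivityMatrix", values = vals, band = band)
}

# correlation of a seed envelope with the envelope of a residual signal;
# NA when the residual envelope is (numerically) constant
.envCor <- function(seedEnv, resid) {
  e <- amplitudeEnvelope(resid)
  if (sd(e) <= sqrt(.Machine$double.eps) * (mean(e) + 1)) return(NA_real_)
  cor(seedEnv, e)
}

#' Regional connectivity strengths
#'
#' Reduces a symmetric connectivity matrix to one value per region: the
#' mean of that region's R - 1 off-diagonal entries (its row of the AEC
#' matrix).
#'
#' @param m a [ConnectivityMatrix-class] or symmetric matrix.
#' @return named numeric vector, one value per region.
#' @export
regionalConnectivity <- function(m) {
  v <- if (is(m, "ConnectivityMatrix")) m@values else as.matrix(m)
  if (nrow(v) < 2) stop("need at least two regions")
  diag(v) <- NA
  rowMeans(v, na.rm = TRUE)
}

#' Average a per-region metric over a region-of-interest
#'
#' Unweighted mean of a regional metric over a named set of regions.
#'
#' @param values named per-region numeric vector.
#' @param roi character vector of region names (nonempty, all present in
#'   \code{names(values)}).
#' @return scalar mean.
#' @export
roiAverage <- function(values, roi) {
  if (length(roi) == 0) stop("roi must be nonempty")
  if (is.null(names(values))) stop("values must be named by region")
  missing <- setdiff(roi, names(values))
  if (length(missing) > 0)
    stop("unknown region name(s): ", paste(missing, collapse = ", "))
  mean(values[roi])
}

#' Read region-of-interest definitions
#'
#' Reads a JSON (or YAML) file mapping ROI names to vectors of atlas
#' region names.
#'
#' @param path file path; format chosen by extension.
#' @return named list of character vectors.
#' @export
readROIs <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Default ROI sets for a given region labelling
#'
#' Ships a minimal convention: \code{whole_brain} (all regions), plus
#' \code{frontal} and \code{temporal} sets matched by label prefix when
#' the labels encode lobes (e.g. \code{"frontal_3"}); otherwise only
#' \code{whole_brain} is returned.
#'
#' @param regionLabels character vector of region names.
#' @return named list of character vectors.
#' @export
defaultROIs <- function(regionLabels) {
  rois <- list(whole_brain = regionLabels)
  for (lobe in c("frontal", "temporal")) {
    hit <- grep(paste0("^", lobe), regionLabels, value = TRUE)
    if (length(hit) > 0) rois[[lobe]] <- hit
  }
  rois
}

#' Scalar synchrony metrics from regional time courses
#'
#' Computes, for each frequency band, the leakage-corrected AEC
#' (long-range synchrony) and the relative spectral band power (local
#' synchrony) per region, then averages each over the requested ROIs.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param bands named list of [FrequencyBand-class] (default
#'   [defaultBands()]).
#' @param rois named list of ROI region-name vectors (default
#'   [defaultROIs()] on the labels).
#' @param totalBand total-power band for the relative power denominator.
#' @param segmentLength Welch segment length in samples.
#' @return data.frame with columns \code{metric} (e.g.
#'   \code{"aec_alpha_whole_brain"}) and \code{value}.
#' @export
scalarSynchronyMetrics <- function(ts, bands = defaultBands(),
                                   rois = defaultROIs(regionLabels(ts)),
                                   totalBand = frequencyBand("total", 0.5, 55),
                                   segmentLength = 2048) {
  segmentLength <- min(segmentLength, ncol(ts@data))
  psd <- welchPSD(ts, segmentLength = segmentLength)
  out <- list()
  for (bn in names(bands)) {
    aec <- regionalConnectivity(aecMatrix(ts, bands[[bn]]))
    rbp <- relativeBandPower(psd, bands[[bn]], totalBand)
    for (rn in names(rois)) {
      out[[length(out) + 1L]] <- data.frame(
        metric = c(sprintf("aec_%s_%s", bn, rn),
                   sprintf("power_%s_%s", bn, rn)),
        value = c(roiAverage(aec, rois[[rn]]),
                  roiAverage(rbp, rois[[rn]])))
    }
  }
  do.call(rbind, out)
}
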