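#' Simulate band-limited regional signals with controlled envelope coupling
#'
#' Generates per-region oscillatory sources as a sum over frequency
#' bands. Each band component is a band-limited constant-modulus carrier
#' (band-pass filtered Gaussian noise, iteratively modulus-normalized and
#' re-filtered so its Hilbert envelope is nearly flat and its power stays
#' in band) multiplied by a log-normal slow amplitude modulator: a
#' below-1-Hz low-pass filtered Gaussian process, standardized,
#' exponentiated with log-SD \code{modulationDepth}. Envelope coupling
#' between regions is imposed by correlating the slow modulators with a
#' latent correlation solved analytically from the log-normal envelope
#' correlation formula, so the unmixed sources achieve the requested
#' envelope correlations up to envelope-estimation attenuation. Source
#' leakage is emulated by an instantaneous linear mixing matrix applied
#' to the summed sources.
#'
#' Because the carriers are independent across regions, coupled sources
#' remain (near) uncorrelated at zero lag: the coupling survives pairwise
#' orthogonalization, while mixed-in leakage does not — the property the
#' leakage-corrected AEC is designed to exploit.
#'
#' @param nRegions number of regions R.
#' @param samplingRate sampling rate in Hz (default 600).
#' @param duration record length in seconds (default 60).
#' @param bands named list of [FrequencyBand-class]; default
#'   [defaultBands()]. The sampling rate must exceed twice the highest
#'   band edge.
#' @param bandWeights R x nBands matrix of per-region band amplitude
#'   weights (default all 1).
#' @param envelopeCoupling either one R x R target envelope-correlation
#'   matrix applied to every band, or a named list per band; symmetric
#'   with unit diagonal (default: identity, no coupling).
#' @param mixing R x R instantaneous mixing (leakage) matrix; must be
#'   invertible (default: identity, no leakage).
#' @param modulationDepth log-SD of the slow amplitude modulators
#'   (default 0.7).
#' @param regionLabels optional region names.
#' @param seed integer seed; generation is deterministic given it.
#' @return list with \code{mixed} and \code{sources}, both
#'   [RegionalTimeSeries-class] (R x T).
#' @export
simulateTimeSeries <- function(nRegions, samplingRate = 600, duration = 60,
                               bands = defaultBands(), bandWeights = NULL,
                               envelopeCoupling = NULL, mixing = NULL,
                               modulationDepth = 0.7, regionLabels = NULL,
                               seed = 1) {
  R <- as.integer(nRegions)
  maxEdge <- max(vapply(bands, function(b) b@high, numeric(1)))
  if (samplingRate <= 2 * maxEdge)
    stop("samplingRate must exceed twice the highest band edge")
  Tn <- as.integer(round(samplingRate * duration))
  if (is.null(bandWeights))
    bandWeights <- matrix(1, R, length(bands))
  bandWeights <- as.matrix(bandWeights)
  stopifnot(nrow(bandWeights) == R, ncol(bandWeights) == length(bands))
  if (is.null(mixing)) mixing <- diag(R)
  mixing <- as.matrix(mixing)
  if (nrow(mixing) != R || ncol(mixing) != R ||
      abs(det(mixing)) < .Machine$double.eps^0.5)
    stop("singular mixing: leakage matrix must be an invertible R x R matrix")
  if (is.null(regionLabels)) regionLabels <- paste0("region_", seq_len(R))
  couplingFor <- function(bn) {
    C <- if (is.null(envelopeCoupling)) diag(R)
         else if (is.list(envelopeCoupling)) envelopeCoupling[[bn]]
         else envelopeCoupling
    if (is.null(C)) C <- diag(R)
    C <- as.matrix(C)
    if (max(abs(C - t(C))) > 1e-10 || any(abs(diag(C) - 1) > 1e-10))
      stop("envelopeCoupling must be symmetric with unit diagonal")
    C
  }
  .withSeed(seed, {
    sources <- matrix(0, R, Tn)
    for (b in seq_along(bands)) {
      bn <- names(bands)[b]
      band <- bands[[b]]
      mod <- .slowModulators(R, Tn, samplingRate,
                             couplingFor(bn), modulationDepth)
      for (r in seq_len(R)) {
        if (bandWeights[r, b] == 0) next
        carrier <- .constantModulusCarrier(Tn, band, samplingRate)
        sources[r, ] <- sources[r, ] +
          bandWeights[r, b] * mod[r, ] * carrier
      }
    }
    mixed <- mixing %*% sources
    list(mixed = regionalTimeSeries(mixed, samplingRate, regionLabels),
         sources = regionalTimeSeries(sources, samplingRate, regionLabels))
  })
}

# band-limited carrier with near-constant Hilbert envelope: filtered noise,
# modulus-normalized and re-filtered (2 rounds), unit variance
.constantModulusCarrier <- function(Tn, band, fs, rounds = 2) {
  v <- bandpassFilter(rnorm(Tn), band, fs)
  for (i in seq_len(rounds)) {
    a <- analyticSignal(v)
    v <- bandpassFilter(Re(a / Mod(a)), band, fs)
  }
  v / sd(v)
}

# correlated log-normal slow modulators (R x T). The latent Gaussian
# correlation rho_u reproducing a target envelope correlation rho_e of
# exp(s u) is rho_u = log(1 + rho_e (e^{s^2} - 1)) / s^2.
.slowModulators <- function(R, Tn, fs, targetCor, logSd) {
  s2 <- logSd^2
  latent <- log(1 + targetCor * (exp(s2) - 1)) / s2
  diag(latent) <- 1
  ch <- tryCatch(chol(latent), error = function(e)
    stop("envelopeCoupling is not achievable (latent correlation not ",
         "positive definite)"))
  lowBand <- frequencyBand("slow", 0.001, 1)
  u <- matrix(rnorm(R * Tn), Tn, R)
  u <- apply(u, 2, function(v)
    bandpassFilter(v, lowBand, fs, order = 2, type = "low"))
  u <- scale(u)
  t(exp(logSd * (u %*% ch)))
}

#' Write / read regional time series as delimited text with a sidecar
#'
#' The matrix goes to a (gzip-compressible) CSV of regions x samples and
#' the metadata (region labels, sampling rate) to a JSON sidecar at
#' \code{<path>.json}.
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param path CSV path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
writeRegionalTimeSeries <- function(ts, path) {
  write.csv(as.data.frame(ts@data), path, row.names = FALSE)
  jsonlite::write_json(
    list(regionLabels = ts@regionLabels, samplingRate = ts@samplingRate),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRegionalTimeSeries
#' @export
readRegionalTimeSeries <- function(path) {
  meta <- jsonlite::fromJSON(paste0(path, ".json"))
  x <- as.matrix(read.csv(path, check.names = FALSE))
  regionalTimeSeries(x, meta$samplingRate, meta$regionLabels)
}
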