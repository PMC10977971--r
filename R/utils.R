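# internal numerical helpers

# log(sum(exp(x))) without overflow; x a vector or matrix rows
.logSumExp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

.rowLogSumExp <- function(x) {
  m <- apply(x, 1, max)
  m + log(rowSums(exp(x - m)))
}

#' Analytic signal via the FFT
#'
#' Computes the discrete analytic signal (Hilbert transform companion) of a
#' real vector: negative frequencies are zeroed, positive doubled. The
#' modulus of the result is the amplitude envelope.
#'
#' @param x real numeric vector.
#' @return complex vector of the same length.
#' @export
analyticSignal <- function(x) {
  n <- length(x)
  stopifnot(n > 1)
  h <- numeric(n)
  h[1] <- 1
  if (n %% 2 == 0) {
    h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[2:((n + 1) / 2)] <- 2
  }
  fft(fft(x) * h, inverse = TRUE) / n
}

#' Amplitude envelope of a signal
#'
#' @param x real numeric vector.
#' @return nonnegative envelope, \code{Mod(analyticSignal(x))}.
#' @export
amplitudeEnvelope <- function(x) Mod(analyticSignal(x))

#' Zero-phase Butterworth band-pass filter
#'
#' Fourth-order Butterworth applied forward and backward
#' (\code{signal::filtfilt}), giving an effective zero-phase 8th-order
#' response that preserves envelope timing.
#'
#' @param x numeric vector or regions x samples matrix (filtered per row).
#' @param band a [FrequencyBand-class].
#' @param samplingRate sampling rate in Hz.
#' @param order per-pass filter order.
#' @param type \code{"pass"}, \code{"low"} or \code{"high"}; for
#'   \code{"low"}/\code{"high"} only the relevant edge of \code{band} is
#'   used.
#' @return filtered data with the shape of \code{x}.
#' @export
bandpassFilter <- function(x, band, samplingRate, order = 4, type = "pass") {
  nyq <- samplingRate / 2
  w <- switch(type,
              pass = c(band@low, band@high) / nyq,
              low  = band@high / nyq,
              high = band@low / nyq,
              stop("unknown filter type"))
  if (any(w <= 0) || any(w >= 1))
    stop("band edges must lie strictly inside (0, Nyquist)")
  bf <- signal::butter(order, w, type = type)
  f <- function(v) as.numeric(signal::filtfilt(bf, v))
  if (is.matrix(x)) t(apply(x, 1, f)) else f(x)
}

# deterministic child seeds below 2^31 derived from a user seed
.childSeed <- function(seed, stream) {
  (as.numeric(seed) * 1103515245 + 12345 * as.numeric(stream)) %% 2147483647
}

.withSeed <- function(seed, expr) {
  if (!is.null(seed)) set.seed(as.integer(seed %% 2147483647))
  expr
}
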