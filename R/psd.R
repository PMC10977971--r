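#' Welch power spectral density
#'
#' Averaged modified periodogram with Hann-windowed segments and 50\%
#' overlap by default. One-sided density scaling: the PSD integrates
#' (\code{sum(power) * resolution}) to the signal variance, and the
#' frequency resolution is exactly \code{samplingRate / segmentLength}
#' (0.293 Hz for a 600-Hz record with 2048-sample segments).
#'
#' @param ts a [RegionalTimeSeries-class].
#' @param segmentLength segment length in samples (\code{<=} record
#'   length).
#' @param overlap fractional overlap between consecutive segments in
#'   \code{[0, 1)}.
#' @return a [PSDSet-class].
#' @export
welchPSD <- function(ts, segmentLength = 2048, overlap = 0.5) {
  stopifnot(is(ts, "RegionalTimeSeries"))
  x <- ts@data
  fs <- ts@samplingRate
  Tn <- ncol(x)
  segmentLength <- as.integer(segmentLength)
  if (segmentLength > Tn)
    stop("segmentation error: segment (", segmentLength,
         ") longer than record (", Tn, ")")
  if (overlap < 0 || overlap >= 1) stop("overlap must be in [0, 1)")
  step <- max(1L, as.integer(round(segmentLength * (1 - overlap))))
  starts <- seq(1L, Tn - segmentLength + 1L, by = step)
  w <- .hann(segmentLength)
  u <- sum(w^2)                       # window power normalization
  nf <- segmentLength %/% 2 + 1L
  freqs <- (seq_len(nf) - 1L) * fs / segmentLength
  pow <- matrix(0, nrow(x), nf,
                dimnames = list(ts@regionLabels, NULL))
  for (r in seq_len(nrow(x))) {
    acc <- numeric(nf)
    for (s in starts) {
      seg <- x[r, s:(s + segmentLength - 1L)]
      seg <- (seg - mean(seg)) * w
      sp <- Mod(fft(seg)[seq_len(nf)])^2 / (fs * u)
      sp[2:(nf - 1L)] <- 2 * sp[2:(nf - 1L)]   # one-sided
      acc <- acc + sp
    }
    pow[r, ] <- acc / length(starts)
  }
  new("PSDSet", frequencies = freqs, power = pow,
      resolution = fs / segmentLength)
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * seq_len(n) / (n + 1))

#' Relative spectral band power
#'
#' Per region, the PSD integrated over a band divided by the integral over
#' the total band — the local-synchrony metric. Values lie in
#' \code{[0, 1]} when the band is inside the total band.
#'
#' @param psd a [PSDSet-class].
#' @param band numerator [FrequencyBand-class].
#' @param totalBand denominator band; default 0.5-55 Hz, the conventional
#'   broadband pre-processing range.
#' @return named per-region numeric vector of power ratios.
#' @export
relativeBandPower <- function(psd, band,
                              totalBand = frequencyBand("total", 0.5, 55)) {
  stopifnot(is(psd, "PSDSet"), is(band, "FrequencyBand"))
  if (band@low < totalBand@low || band@high > totalBand@high)
    stop("band must lie within the total band")
  f <- psd@frequencies
  inBand <- f >= band@low & f <= band@high
  inTotal <- f >= totalBand@low & f <= totalBand@high
  tot <- rowSums(psd@power[, inTotal, drop = FALSE])
  if (any(tot <= 0)) stop("degenerate signal: zero total power")
  rowSums(psd@power[, inBand, drop = FALSE]) / tot
}
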