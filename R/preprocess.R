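#' Gaussian low-pass filter
#'
#' Zero-phase digital Gaussian low-pass filtering of a trace, the standard
#' software filter applied to single-channel recordings before event
#' analysis. The cutoff is defined at the -3 dB point; for a Gaussian
#' kernel this fixes the temporal standard deviation at
#' `sigma_t = 0.1325 / cutoffHz` (since `|H(f)| = exp(-2 pi^2 sigma_t^2
#' f^2)` equals `1/sqrt(2)` at `f = cutoffHz`). The kernel is truncated at
#' +-4 sigma (amplitude error < 1e-4), normalized to unit DC gain, and
#' applied by reflect-padded convolution so the output has the same length
#' as the input.
#'
#' @param trace A [Trace-class].
#' @param cutoffHz -3 dB cutoff frequency in Hz; must be below the Nyquist
#'   frequency.
#' @return A filtered [Trace-class]; metadata records the cutoff.
#' @examples
#' tr <- Trace(rep(80, 1000), samplingRate = 5e4)
#' all.equal(samples(gaussianLowpass(tr, 2000)), samples(tr))
#' @export
gaussianLowpass <- function(trace, cutoffHz) {
  rate <- samplingRate(trace)
  if (!is.finite(cutoffHz) || cutoffHz <= 0 || cutoffHz >= rate / 2)
    stop("cutoffHz must lie in (0, samplingRate/2)")
  sigmaT <- 0.1325 / cutoffHz
  kernel <- .gaussKernel(sigmaT * rate)
  y <- .convReflect(samples(trace), kernel)
  md <- traceMetadata(trace)
  md$gaussian_lowpass_hz <- cutoffHz
  Trace(samples = y, samplingRate = rate, protocol = protocol(trace),
        metadata = md)
}

#' Normalize trace polarity
#'
#' Recordings at negative applied potential carry negative currents; all
#' downstream statistics (open-pore current, blockade depths, excluded
#' current) are defined on magnitudes. This flips the sign of every segment
#' recorded at negative voltage, using the attached protocol, so that
#' currents are positive throughout. Gap-free traces are flipped according
#' to their single segment voltage.
#'
#' @param trace A [Trace-class] with a protocol attached.
#' @return A [Trace-class] with positive current magnitudes; metadata
#'   records the flip (`polarity_normalized = TRUE`).
#' @examples
#' tr <- Trace(rnorm(100, -80, 2), samplingRate = 5e4,
#'             protocol = gapFreeProtocol(-75, 100 / 5e4))
#' mean(samples(normalizePolarity(tr)))   # ~ +80 pA
#' @export
normalizePolarity <- function(trace) {
  pr <- protocol(trace)
  if (is.null(pr))
    stop("polarity unknown: trace has no voltage protocol")
  if (any(pr@voltageMV == 0))
    stop("zero analysis voltage: polarity undefined")
  x <- samples(trace)
  if (pr@mode == "gap-free") {
    if (pr@voltageMV < 0) x <- -x
  } else {
    segs <- .protocolSegments(pr, samplingRate(trace))
    for (i in which(segs$voltage_mV < 0)) {
      lo <- segs$start_sample[i] + 1L
      hi <- min(segs$end_sample[i], length(x))
      if (lo <= hi) x[lo:hi] <- -x[lo:hi]
    }
    ## remainder samples beyond the last full sweep follow the last segment
    last <- segs$end_sample[nrow(segs)]
    if (last < length(x) && segs$voltage_mV[nrow(segs)] < 0)
      x[(last + 1L):length(x)] <- -x[(last + 1L):length(x)]
  }
  md <- traceMetadata(trace)
  md$polarity_normalized <- TRUE
  Trace(samples = x, samplingRate = samplingRate(trace), protocol = pr,
        metadata = md)
}
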