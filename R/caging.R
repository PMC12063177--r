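#' All-point histogram of a blockade window on the excluded-current axis
#'
#' Builds the all-point amplitude histogram (default bin width 0.1 pA) of a
#' trace window -- canonically exactly 60 s of a caged blockade -- and
#' converts it bin-by-bin from blocked current to excluded current,
#' `I_EX = (I_O - I_B)/I_O * 100`, using the open-pore current measured on
#' the pre-capture blank.
#'
#' @param trace A polarity-normalized, filtered [Trace-class].
#' @param iO Open-pore current magnitude in pA (from the blank).
#' @param binPA Histogram bin width in pA.
#' @param windowS Window length in seconds.
#' @param startS Window start within the trace, seconds.
#' @param strict Error when fewer than `windowS` seconds are available
#'   (default); with `strict = FALSE` the available span is used and
#'   recorded.
#' @return A [LevelProfile-class] with the histogram filled in and peak
#'   statistics unset (see [fitOuterPeaks()], [countLevels()]).
#' @examples
#' x <- rep(c(80, 48), each = 500)           # two-level square wave
#' tr <- Trace(rep(x, 60), samplingRate = 1000)
#' pf <- allpointProfile(tr, iO = 100, windowS = 60)
#' @export
allpointProfile <- function(trace, iO, binPA = 0.1, windowS = 60,
                            startS = 0, strict = TRUE) {
  if (!is.finite(iO) || iO <= 0) stop("iO must be known and > 0")
  rate <- samplingRate(trace)
  x <- samples(trace)
  i0 <- floor(startS * rate) + 1L
  i1 <- min(length(x), floor((startS + windowS) * rate))
  if (i1 - i0 + 1L < round(windowS * rate)) {
    if (strict)
      stop(sprintf("window shorter than %g s", windowS))
    windowS <- (i1 - i0 + 1L) / rate
  }
  if (i1 < i0) stop("empty window")
  idx <- i0:i1
  ## for sweep protocols only measuring-voltage samples enter the
  ## histogram; flip segments sit on a different baseline
  pr <- protocol(trace)
  if (!is.null(pr) && pr@mode == "sweeps") {
    segs <- .protocolSegments(pr, rate)
    ana <- segs[segs$analysis, , drop = FALSE]
    keep <- logical(length(x))
    for (k in seq_len(nrow(ana))) {
      lo <- ana$start_sample[k] + 1L
      hi <- min(ana$end_sample[k], length(x))
      if (lo <= hi) keep[lo:hi] <- TRUE
    }
    idx <- idx[keep[idx]]
    if (!length(idx)) stop("window contains no measuring-voltage samples")
  }
  x <- x[idx]
  breaks <- seq(min(x) - binPA, max(x) + binPA, by = binPA)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  iex <- excludedCurrent(iO, h$mids)
  ord <- order(iex)
  new("LevelProfile", binCenters = iex[ord], counts = h$counts[ord],
      binPA = binPA, iO = iO, windowS = windowS)
}

## detect blockade modes on a profile; flags the open-pore mode (any mode
## whose fitted mean lies within baselineExcludeSD of I_EX = 0, in units of
## its own sd)
.profilePeaks <- function(profile, promFrac = 0.05, smoothSDbins = 3,
                          baselineExcludeSD = 3) {
  pk <- .histogramPeaks(profile@binCenters, profile@counts,
                        smoothSDbins = smoothSDbins, promFrac = promFrac)
  if (!nrow(pk)) return(cbind(pk, baseline = logical()))
  pk$baseline <- abs(pk$mean) <= baselineExcludeSD * pmax(pk$sd, 1e-6)
  pk
}

#' Fit Gaussians to the outer blockade peaks
#'
#' Locates the modes of an all-point excluded-current profile, discards the
#' open-pore mode (any mode within `baselineExcludeSD` standard deviations
#' of `I_EX = 0`), fits local Gaussians to the shallowest and deepest
#' remaining modes, and reports their means as `I_EX,min` and `I_EX,max`
#' together with the blockade bandwidth `Delta I_EX = I_EX,max - I_EX,min`.
#' With fewer than two blockade modes the profile is flagged degenerate and
#' `Delta I_EX = 0`.
#'
#' @param profile A [LevelProfile-class] from [allpointProfile()].
#' @param promFrac Minimum relative prominence of a mode (fraction of the
#'   tallest non-baseline mode of the smoothed histogram). The default is
#'   deliberately lower than in [countLevels()]: the extreme occupancy
#'   states are the least-populated ends of the level ladder, so the outer
#'   modes are real but small.
#' @param smoothSDbins Gaussian smoothing sd for peak *finding*, in bins
#'   (fits use the raw histogram).
#' @param baselineExcludeSD Open-pore exclusion width.
#' @return The [LevelProfile-class] with `iexMin()`, `iexMax()`,
#'   `deltaIEX()` and the `peaks` table filled in.
#' @seealso [countLevels()]
#' @export
fitOuterPeaks <- function(profile, promFrac = 0.02, smoothSDbins = 3,
                          baselineExcludeSD = 3) {
  pk <- .profilePeaks(profile, promFrac, smoothSDbins, baselineExcludeSD)
  blk <- pk[!pk$baseline, , drop = FALSE]
  if (nrow(blk) == 0L) stop("only the open-pore mode is present")
  profile@peaks <- pk
  if (nrow(blk) < 2L) {
    profile@iexMinPct <- profile@iexMaxPct <- blk$mean[1L]
    profile@deltaPct <- 0
    profile@degenerate <- TRUE
    return(profile)
  }
  profile@iexMinPct <- min(blk$mean)
  profile@iexMaxPct <- max(blk$mean)
  profile@deltaPct <- profile@iexMaxPct - profile@iexMinPct
  profile@degenerate <- FALSE
  profile
}

#' Count discrete blockade levels
#'
#' Census of discrete current levels in an all-point excluded-current
#' profile: the number of local maxima of the smoothed histogram with
#' relative prominence at least `promFrac`, excluding the open-pore mode.
#' For a multivalent analyte this is the experimental counterpart of
#' [predictedLevelCount()].
#'
#' @inheritParams fitOuterPeaks
#' @return Integer level count (0 for a flat/empty profile).
#' @examples
#' ## see predictedLevelCount() for the model expectation
#' @export
countLevels <- function(profile, promFrac = 0.05, smoothSDbins = 3,
                        baselineExcludeSD = 3) {
  pk <- .profilePeaks(profile, promFrac, smoothSDbins, baselineExcludeSD)
  as.integer(sum(!pk$baseline))
}

#' Expected level count of a multivalent blockade
#'
#' An analyte with `nSites` binding pockets trapped over a multi-tag pore
#' visits occupancy states `0..nSites`, hence shows `nSites + 1` discrete
#' current levels: five for a tetravalent analyte (streptavidin), two for
#' monovalent binding.
#'
#' @param nSites Number of binding pockets (>= 0).
#' @return `nSites + 1`.
#' @examples
#' predictedLevelCount(4)   # 5
#' predictedLevelCount(1)   # 2
#' @export
predictedLevelCount <- function(nSites) {
  if (any(!is.finite(nSites)) || any(nSites < 0))
    stop("nSites must be >= 0")
  as.integer(nSites) + 1L
}

#' Per-event level metrics for fingerprint classification
#'
#' For each event computes, from its own trace window (up to `maxWindowS`
#' seconds from event start), the outer-peak statistics and level census of
#' its all-point profile: `iex_max_pct`, `delta_iex_pct`, `n_levels`,
#' alongside the event duration. These are the inputs of
#' [classifyFingerprints()].
#'
#' @param trace The polarity-normalized, filtered [Trace-class] the events
#'   were detected in.
#' @param events An [EventTable-class].
#' @param iO Open-pore current magnitude, pA.
#' @param binPA Histogram bin width, pA.
#' @param maxWindowS Per-event window cap in seconds.
#' @param promFrac Mode prominence threshold.
#' @return A `data.frame` with one row per event: `start_s`, `duration_s`,
#'   `iex_max_pct`, `delta_iex_pct`, `n_levels`.
#' @export
eventLevelMetrics <- function(trace, events, iO, binPA = 0.1,
                              maxWindowS = 60, promFrac = 0.05) {
  df <- eventData(events)
  out <- lapply(seq_len(nrow(df)), function(i) {
    win <- min(df$dwell_s[i], maxWindowS)
    res <- tryCatch({
      pf <- allpointProfile(trace, iO, binPA = binPA, windowS = win,
                            startS = df$start_s[i], strict = FALSE)
      pf <- fitOuterPeaks(pf, promFrac = promFrac)
      c(iexMax = iexMax(pf), delta = deltaIEX(pf),
        levels = countLevels(pf, promFrac = promFrac))
    }, error = function(e) c(iexMax = df$I_EX_pct[i], delta = 0,
                             levels = 1))
    data.frame(start_s = df$start_s[i], duration_s = df$dwell_s[i],
               iex_max_pct = res[["iexMax"]],
               delta_iex_pct = res[["delta"]],
               n_levels = as.integer(res[["levels"]]))
  })
  if (!length(out))
    return(data.frame(start_s = numeric(), duration_s = numeric(),
                      iex_max_pct = numeric(), delta_iex_pct = numeric(),
                      n_levels = integer()))
  do.call(rbind, out)
}
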