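#' Detector settings
#'
#' Two-threshold (hysteresis) idealization parameters. An event opens when
#' the current falls below `openFraction * I_O` and closes when it rises
#' back above `closeFraction * I_O` (`openFraction <= closeFraction`, both
#' in (0, 1)); the hysteresis band prevents noise from splitting one
#' blockade into many. Events shorter than `minDwellS` are discarded
#' (default: 5 samples at the trace sampling rate, resolved at detection
#' time when `NULL`). The defaults are chosen so that even shallow
#' (< 10% excluded current) linker blockades remain detectable after 2 kHz
#' filtering.
#'
#' @param openFraction Fraction of the open-pore current below which an
#'   event opens.
#' @param closeFraction Fraction above which an event closes.
#' @param minDwellS Minimum dwell in seconds, or `NULL` for 5 samples.
#' @param minSeparationS Events closer than this are merged.
#' @return A validated settings list.
#' @examples
#' detectorSettings()
#' @export
detectorSettings <- function(openFraction = 0.90, closeFraction = 0.95,
                             minDwellS = NULL, minSeparationS = 0) {
  if (!(openFraction > 0 && openFraction <= closeFraction &&
        closeFraction < 1))
    stop("need 0 < openFraction <= closeFraction < 1")
  if (!is.null(minDwellS) && minDwellS < 0)
    stop("minDwellS must be >= 0")
  if (minSeparationS < 0)
    stop("minSeparationS must be >= 0")
  structure(list(openFraction = openFraction,
                 closeFraction = closeFraction,
                 minDwellS = minDwellS,
                 minSeparationS = minSeparationS),
            class = "detectorSettings")
}

#' Estimate the open-pore current from an all-point histogram
#'
#' Builds an all-point amplitude histogram (default bin width 0.5 pA) of a
#' polarity-normalized trace and fits a Gaussian to its highest-current
#' mode, which is the open-pore level whenever the pore is not blocked the
#' entire time. For sweep protocols only measuring-voltage segments enter
#' the histogram.
#'
#' @param trace A polarity-normalized [Trace-class].
#' @param binPA Histogram bin width in pA.
#' @param promFrac Minimum relative prominence for a histogram mode.
#' @return A list of class `"BaselineEstimate"` with elements `iO` (pA),
#'   `sd` (pA), `binPA`, and `degenerate` (TRUE for a constant trace).
#' @examples
#' tr <- Trace(rnorm(1e4, 80, 2), samplingRate = 5e4)
#' estimateBaseline(tr)$iO
#' @export
estimateBaseline <- function(trace, binPA = 0.5, promFrac = 0.05) {
  x <- samples(trace)
  pr <- protocol(trace)
  if (!is.null(pr) && pr@mode == "sweeps") {
    segs <- .protocolSegments(pr, samplingRate(trace))
    keep <- segs[segs$analysis, , drop = FALSE]
    idx <- unlist(lapply(seq_len(nrow(keep)), function(i)
      seq.int(keep$start_sample[i] + 1L, keep$end_sample[i])))
    x <- x[idx[idx <= length(x)]]
  }
  if (!length(x)) stop("no samples available for baseline estimation")
  if (stats::sd(x) < binPA / 10) {
    return(structure(list(iO = mean(x), sd = stats::sd(x), binPA = binPA,
                          degenerate = TRUE), class = "BaselineEstimate"))
  }
  breaks <- seq(min(x) - binPA, max(x) + binPA, by = binPA)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  pk <- .histogramPeaks(h$mids, h$counts, smoothSDbins = 3,
                        promFrac = promFrac)
  if (!nrow(pk)) stop("no histogram mode found")
  top <- pk[which.max(pk$mean), ]           # highest-current mode
  if (top$mean <= 0)
    stop("open-pore mode non-positive; is the trace polarity-normalized?")
  structure(list(iO = top$mean, sd = top$sd, binPA = binPA,
                 degenerate = FALSE), class = "BaselineEstimate")
}

#' Per-event excluded current
#'
#' The excluded current of a blockade, `((I_O - I_B) / I_O) * 100` percent:
#' the fraction of the open-pore current displaced by the analyte, a
#' size/shape fingerprint independent of the absolute current scale.
#'
#' @param iO Open-pore current magnitude, pA (> 0).
#' @param iB Blocked current magnitude, pA; vectorized.
#' @return Excluded current in percent.
#' @examples
#' excludedCurrent(100, 54.6)   # 45.4
#' @export
excludedCurrent <- function(iO, iB) {
  if (!is.finite(iO) || iO <= 0) stop("iO must be > 0")
  (iO - iB) / iO * 100
}

## two-threshold idealization of one contiguous sample window.
## Returns 0-based local sample indices [start, end) per event plus
## boundary-touch flags.
.idealizeWindow <- function(x, thOpen, thClose) {
  below <- x < thClose
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  k <- 0L
  for (i in which(r$values)) {
    lo <- starts[i]
    hi <- ends[i]
    opened <- which(x[lo:hi] < thOpen)
    if (!length(opened)) next
    s <- lo + opened[1L] - 1L
    k <- k + 1L
    out[[k]] <- c(start = s - 1L, end = hi,
                  atStart = as.integer(lo == 1L),
                  atEnd = as.integer(hi == length(x)))
  }
  if (!k)
    return(data.frame(start = integer(), end = integer(),
                      atStart = integer(), atEnd = integer()))
  as.data.frame(do.call(rbind, out))
}

#' Detect blockade events by threshold crossing with hysteresis
#'
#' Idealizes a polarity-normalized trace into blockade events: an event
#' opens when the current drops below `openFraction * I_O` and closes when
#' it recovers above `closeFraction * I_O`. Per event the mean blocked
#' current `I_B`, dwell, interevent gap and excluded current are computed.
#' Events shorter than the minimum dwell are discarded. For sweep
#' protocols, detection runs per measuring segment; events abutting a
#' segment boundary are flagged `truncated`, and blockades that continue
#' through a voltage flip into the next sweep (caged analytes) are merged
#' into single wall-clock events when `mergeAcrossSweeps` is `TRUE`.
#'
#' @param trace A polarity-normalized (and typically low-pass filtered)
#'   [Trace-class].
#' @param baseline A `"BaselineEstimate"` (see [estimateBaseline()]) or a
#'   single open-pore current magnitude in pA.
#' @param settings A [detectorSettings()] list.
#' @param mergeAcrossSweeps Merge blockades continuing across consecutive
#'   measuring segments.
#' @return An [EventTable-class] with an extra `n_sweeps_spanned` column.
#' @examples
#' x <- rep(100, 3000); x[1001:1250] <- 55        # one 250-sample blockade
#' tr <- Trace(x + rnorm(3000, 0, 1), samplingRate = 5000)
#' ev <- detectEvents(tr, baseline = 100)
#' nEvents(ev)
#' @export
detectEvents <- function(trace, baseline, settings = detectorSettings(),
                         mergeAcrossSweeps = TRUE) {
  iO <- if (inherits(baseline, "BaselineEstimate")) baseline$iO
  else as.numeric(baseline)
  if (!is.finite(iO) || iO <= 0) stop("invalid baseline")
  if (inherits(baseline, "BaselineEstimate") && baseline$degenerate)
    stop("degenerate baseline (zero spread); cannot detect events")
  rate <- samplingRate(trace)
  minDwell <- if (is.null(settings$minDwellS)) 5 / rate else
    settings$minDwellS
  thOpen <- settings$openFraction * iO
  thClose <- settings$closeFraction * iO
  x <- samples(trace)
  pr <- protocol(trace)

  if (!is.null(pr) && pr@mode == "sweeps") {
    segs <- .protocolSegments(pr, rate)
    wins <- segs[segs$analysis, , drop = FALSE]
  } else {
    wins <- data.frame(sweep_index = NA_integer_, start_sample = 0L,
                       end_sample = length(x))
  }

  rows <- list()
  for (w in seq_len(nrow(wins))) {
    lo <- wins$start_sample[w]
    hi <- min(wins$end_sample[w], length(x))
    if (hi - lo < 2L) next
    seg <- x[(lo + 1L):hi]
    id <- .idealizeWindow(seg, thOpen, thClose)
    if (!nrow(id)) next
    id$gstart <- id$start + lo
    id$gend <- id$end + lo
    id$sweep <- wins$sweep_index[w]
    id$win <- w
    rows[[length(rows) + 1L]] <- id
  }
  if (!length(rows)) return(EventTable())
  ev <- do.call(rbind, rows)

  ## merge blockades continuing across consecutive measuring segments
  if (mergeAcrossSweeps && nrow(ev) > 1L) {
    grp <- cumsum(c(1L, !(ev$atStart[-1L] == 1L &
                            ev$atEnd[-nrow(ev)] == 1L &
                            ev$win[-1L] == ev$win[-nrow(ev)] + 1L)))
  } else {
    grp <- seq_len(nrow(ev))
  }
  agg <- lapply(split(seq_len(nrow(ev)), grp), function(ii) {
    first <- ii[1L]
    last <- ii[length(ii)]
    nsamp <- sum(ev$gend[ii] - ev$gstart[ii])
    ib <- sum(vapply(ii, function(i)
      sum(x[(ev$gstart[i] + 1L):ev$gend[i]]), numeric(1))) / nsamp
    data.frame(start_s = ev$gstart[first] / rate,
               end_s = ev$gend[last] / rate,
               I_B_pA = ib,
               sweep_index = ev$sweep[first],
               n_sweeps_spanned = length(ii),
               truncated = ev$atStart[first] == 1L ||
                 ev$atEnd[last] == 1L)
  })
  df <- do.call(rbind, agg)
  df <- df[order(df$start_s), , drop = FALSE]
  df$dwell_s <- df$end_s - df$start_s
  keep <- df$dwell_s >= minDwell - 1e-12
  df <- df[keep, , drop = FALSE]
  if (!nrow(df)) return(EventTable())
  df$interevent_s <- c(NA_real_, df$start_s[-1L] -
                         df$end_s[-nrow(df)])
  df$I_EX_pct <- excludedCurrent(iO, df$I_B_pA)
  df$label <- NA_character_
  df$end_s <- NULL
  EventTable(df)
}

#' Classify a pore by its single-channel conductance
#'
#' Assigns the conductance class from the open-pore current measured at
#' 35 mV magnitude: conductance `G = I_O / 35` nS, labelled by the nearest
#' of the reference classes 1.94 +/- 0.09 nS (`"1.9*"`), 2.29 +/- 0.23 nS
#' (`"2.3*"`) and 2.63 +/- 0.09 nS (`"2.6*"`) when within two standard
#' deviations of that class, else `"other"`.
#'
#' @param ioPA Open-pore current magnitude(s) at 35 mV, pA; vectorized.
#' @param voltageMV Measurement voltage magnitude, mV.
#' @return A `data.frame` with `conductance_nS` and `class`.
#' @examples
#' classifyPore(80.15)   # 2.29 nS -> "2.3*"
#' @export
classifyPore <- function(ioPA, voltageMV = 35) {
  g <- abs(ioPA) / abs(voltageMV)
  centers <- c(1.94, 2.29, 2.63)
  sds <- c(0.09, 0.23, 0.09)
  labels <- c("1.9*", "2.3*", "2.6*")
  cls <- vapply(g, function(gi) {
    k <- which.min(abs(gi - centers))
    if (abs(gi - centers[k]) <= 2 * sds[k]) labels[k] else "other"
  }, character(1))
  data.frame(conductance_nS = g, class = cls)
}

#' Calibrate and apply a two-parameter event gate
#'
#' `calibrateGate()` summarizes a calibration event population by the mean
#' and sd of its excluded current and of its log dwell time.
#' `gateEvents()` then selects events whose excluded current lies within
#' `mu +/- 2 sigma` of the calibrated I_EX *and* whose dwell lies within
#' `mu +/- 2 sigma` on the log scale -- dwell distributions are
#' exponential-tailed, so gating on log dwell rather than raw dwell keeps
#' the two-sided window meaningful.
#'
#' @param events An [EventTable-class].
#' @param gate A gate list from `calibrateGate()` (fields `iexMean`,
#'   `iexSD`, `logDwellMean`, `logDwellSD`).
#' @param nSigma Half-width of the acceptance window in standard
#'   deviations.
#' @param label Label assigned to selected events.
#' @return `calibrateGate()`: the gate list. `gateEvents()`: the selected
#'   subset as an [EventTable-class], labelled.
#' @examples
#' df <- data.frame(start_s = 1:100, dwell_s = rlnorm(100, -3, 0.5),
#'                  I_EX_pct = rnorm(100, 45, 1))
#' df$I_B_pA <- 100 * (1 - df$I_EX_pct / 100)
#' gate <- calibrateGate(EventTable(df))
#' nEvents(gateEvents(EventTable(df), gate))
#' @export
calibrateGate <- function(events) {
  df <- eventData(events)
  if (!nrow(df)) stop("no events to calibrate on")
  if (any(df$dwell_s <= 0)) stop("dwells must be > 0")
  list(iexMean = mean(df$I_EX_pct), iexSD = stats::sd(df$I_EX_pct),
       logDwellMean = mean(log(df$dwell_s)),
       logDwellSD = stats::sd(log(df$dwell_s)))
}

#' @rdname calibrateGate
#' @export
gateEvents <- function(events, gate, nSigma = 2, label = "SA") {
  stopifnot(all(c("iexMean", "iexSD", "logDwellMean", "logDwellSD") %in%
                  names(gate)))
  if (gate$iexSD <= 0 || gate$logDwellSD <= 0)
    stop("gate standard deviations must be > 0")
  df <- eventData(events)
  sel <- abs(df$I_EX_pct - gate$iexMean) <= nSigma * gate$iexSD &
    abs(log(df$dwell_s) - gate$logDwellMean) <= nSigma * gate$logDwellSD
  sel[is.na(sel)] <- FALSE
  out <- df[sel, , drop = FALSE]
  if (nrow(out)) out$label <- label
  EventTable(out)
}
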