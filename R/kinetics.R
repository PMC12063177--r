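#' Fit an exponential to a cumulative event-time histogram
#'
#' The classic single-channel estimate of a mean dwell or interevent time:
#' the durations (at least `minN` of them) are accumulated into an
#' empirical cumulative count over the edge window (default 0-500 ms) and
#' `N(t) = N_total (1 - exp(-t / tau))` is fitted by least squares.
#'
#' @param durations Event durations in seconds.
#' @param edges Two-element numeric, the fit window in seconds.
#' @param minN Minimum number of usable durations.
#' @return List with `tau` (s), `se`, `nTotal` (fitted amplitude) and `n`
#'   (durations used).
#' @examples
#' set.seed(1)
#' fitExponentialCumulative(rexp(1000, 1 / 0.0657))$tau   # ~ 0.0657
#' @export
fitExponentialCumulative <- function(durations, edges = c(0, 0.5),
                                     minN = 150) {
  d <- durations[is.finite(durations) & durations > edges[1] &
                   durations <= edges[2]]
  if (length(d) < minN)
    stop(sprintf("insufficient events: %d < %d within the edge window",
                 length(d), minN))
  if (stats::sd(d) < .Machine$double.eps^0.5 * mean(d))
    stop("degenerate durations: no spread to fit")
  t <- sort(d)
  N <- seq_along(t)
  start <- list(Ntot = length(t), tau = mean(t))
  fit <- minpack.lm::nlsLM(N ~ Ntot * (1 - exp(-t / tau)),
                           start = start,
                           lower = c(Ntot = 1, tau = 1e-9),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- summary(fit)$coefficients
  list(tau = unname(cf["tau", "Estimate"]),
       se = unname(cf["tau", "Std. Error"]),
       nTotal = unname(cf["Ntot", "Estimate"]),
       n = length(t))
}

#' Geometric-mean dwell time
#'
#' Back-transformed mean of log dwell times, `exp(mean(log(dwell)))` -- a
#' robust location estimate for small, skewed dwell samples. Note that for
#' exponentially distributed dwells the geometric mean underestimates the
#' distribution mean by the factor `exp(-0.5772)` (Euler-Mascheroni), so it
#' is a descriptive statistic rather than an unbiased rate estimator; see
#' the methods vignette.
#'
#' @param dwells Dwell times in seconds, all > 0.
#' @return The geometric mean, seconds.
#' @examples
#' logMeanDwell(c(0.001, 0.01, 0.1))   # 0.01
#' @export
logMeanDwell <- function(dwells) {
  if (!length(dwells)) stop("need at least one dwell")
  if (any(!is.finite(dwells)) || any(dwells <= 0))
    stop("dwells must be > 0")
  exp(mean(log(dwells)))
}

#' Capture frequency from a gap-free recording
#'
#' Number of target events divided by the recording time not occupied by
#' the target: `n / (analyzedDurationS - targetOccupiedTimeS)`, in 1/s.
#' This is the exact "recording time excluding target time" normalization;
#' it equals the plain event rate when the occupied time is negligible.
#'
#' @param nEvents Number of target events.
#' @param analyzedDurationS Analyzed recording time, s.
#' @param targetOccupiedTimeS Time the target occupied the pore, s.
#' @return Capture frequency in 1/s.
#' @examples
#' captureFrequencyGapfree(30, 600, 100)   # 0.06
#' @export
captureFrequencyGapfree <- function(nEvents, analyzedDurationS,
                                    targetOccupiedTimeS = 0) {
  if (!.isCount(nEvents)) stop("nEvents must be a non-negative count")
  denom <- analyzedDurationS - targetOccupiedTimeS
  if (!is.finite(denom) || denom <= 0)
    stop("no target-free recording time in denominator")
  nEvents / denom
}

#' Capture frequency from a sweep protocol (sweep-counting form)
#'
#' Sweep-normalized capture frequency: target events divided by the
#' measuring time of sweeps that contained no target,
#' `n / (nSweepsWithoutTarget * tSweepS)`. Each multi-sweep event counts
#' once; every sweep it touches is excluded from the denominator. This
#' discretizes "recording time excluding target time" at sweep resolution:
#' free measuring time inside partially occupied sweeps is dropped from the
#' denominator, which biases the estimate upward once the pore is occupied
#' an appreciable fraction of the time (see the methods vignette); the
#' pipeline therefore uses the exact excluded-time form
#' ([captureFrequencyGapfree()] on measuring-segment time) for rate
#' estimation.
#'
#' @param nEvents Number of target events (counted once each).
#' @param nSweepsWithoutTarget Number of sweeps containing no target event.
#' @param tSweepS Measuring time per sweep, seconds.
#' @return Capture frequency in 1/s.
#' @examples
#' captureFrequencySweeps(6, 240)   # 0.0125
#' @export
captureFrequencySweeps <- function(nEvents, nSweepsWithoutTarget,
                                   tSweepS = 2) {
  if (!.isCount(nEvents)) stop("nEvents must be a non-negative count")
  if (!.isCount(nSweepsWithoutTarget) || nSweepsWithoutTarget < 1)
    stop("need at least one target-free sweep")
  nEvents / (nSweepsWithoutTarget * tSweepS)
}

#' Sweep occupancy bookkeeping for a target event population
#'
#' For a sweeps-mode recording, determines which sweeps' measuring segments
#' overlap target events, the target-occupied measuring time, and the total
#' measuring time -- the quantities entering both capture-frequency
#' estimators.
#'
#' @param events An [EventTable-class] of target events (times in trace
#'   wall-clock seconds).
#' @param protocol The [VoltageProtocol-class] (mode `"sweeps"`).
#' @return A list: `nSweeps`, `occupied` (logical per sweep),
#'   `nSweepsWithoutTarget`, `measuringTimeS` (total), and
#'   `occupiedMeasuringTimeS`.
#' @export
sweepOccupancy <- function(events, protocol) {
  if (protocol@mode != "sweeps") stop("protocol is not in sweeps mode")
  segs <- .protocolSegments(protocol, rate = 1e6)  # times only
  ana <- segs[segs$analysis, , drop = FALSE]
  df <- eventData(events)
  starts <- df$start_s
  ends <- df$start_s + df$dwell_s
  occupied <- logical(protocol@repeatCount)
  occTime <- 0
  for (i in seq_len(nrow(ana))) {
    ov <- pmin(ends, ana$end_s[i]) - pmax(starts, ana$start_s[i])
    ov <- ov[ov > 0]
    if (length(ov)) {
      occupied[ana$sweep_index[i]] <- TRUE
      occTime <- occTime + sum(ov)
    }
  }
  list(nSweeps = protocol@repeatCount,
       occupied = occupied,
       nSweepsWithoutTarget = sum(!occupied),
       measuringTimeS = sum(ana$end_s - ana$start_s),
       occupiedMeasuringTimeS = occTime)
}

#' Titration regression of the apparent on-rate
#'
#' Least-squares fit of capture frequency against concentration through
#' the origin, `f_C = k_on [POI]`. The default is the ordinary (unweighted)
#' straight-line fit with zero intercept; `weights = "invvar"` uses inverse
#' replicate variances instead, which is only advisable when the
#' per-concentration standard deviations rest on many replicates.
#'
#' @param series A titration `data.frame` with columns `conc_nM`,
#'   `fC_per_s`, and (for `weights = "invvar"`) `fC_sd`.
#' @param weights `"none"` (default) or `"invvar"`.
#' @return List with `kOn` (1/uM/s) and `se`.
#' @examples
#' s <- data.frame(conc_nM = c(1, 5, 10, 25),
#'                 fC_per_s = 8.77 * c(1, 5, 10, 25) / 1000)
#' fitKon(s)$kOn    # 8.77
#' @export
fitKon <- function(series, weights = c("none", "invvar")) {
  weights <- match.arg(weights)
  if (nrow(series) < 2L) stop("need at least two concentrations")
  if (any(duplicated(series$conc_nM)) || any(series$conc_nM <= 0))
    stop("concentrations must be distinct and > 0")
  concUM <- series$conc_nM / 1000
  w <- rep(1, nrow(series))
  if (weights == "invvar") {
    if (!"fC_sd" %in% names(series) || !all(is.finite(series$fC_sd)) ||
        any(series$fC_sd <= 0))
      stop("invvar weighting needs positive fC_sd values")
    w <- 1 / series$fC_sd^2
  }
  fit <- stats::lm(fC_per_s ~ 0 + concUM,
                   data = cbind(series, concUM = concUM), weights = w)
  cf <- summary(fit)$coefficients
  list(kOn = unname(cf[1, "Estimate"]),
       se = if (nrow(series) > 1) unname(cf[1, "Std. Error"]) else NA_real_)
}

#' Concentration-independent apparent off-rate
#'
#' The release frequency `f_R = 1 / mean dwell` is independent of analyte
#' concentration, so the apparent off-rate is the (inverse-variance
#' weighted) mean of the per-concentration release frequencies -- the
#' "slope constrained to zero" regression.
#'
#' @param series A titration `data.frame` with columns `dwell_s` (mean
#'   dwell per concentration) and optionally `dwell_sd` and `n_events`, or
#'   a precomputed `fR_per_s` column.
#' @return List with `kOff` (1/s) and `se`.
#' @examples
#' fitKoff(data.frame(fR_per_s = c(0.19, 0.20, 0.21)))$kOff   # 0.2
#' @export
fitKoff <- function(series) {
  fR <- if ("fR_per_s" %in% names(series)) series$fR_per_s
  else {
    if (!"dwell_s" %in% names(series)) stop("missing dwell data")
    1 / series$dwell_s
  }
  ok <- is.finite(fR)
  if (!any(ok)) stop("missing dwell data")
  fR <- fR[ok]
  w <- rep(1, length(fR))
  if (all(c("dwell_s", "dwell_sd", "n_events") %in% names(series))) {
    sdfR <- (series$dwell_sd / series$dwell_s^2 /
               sqrt(pmax(series$n_events, 1)))[ok]
    if (all(is.finite(sdfR)) && all(sdfR > 0)) w <- 1 / sdfR^2
  }
  kOff <- sum(w * fR) / sum(w)
  se <- if (length(fR) > 1)
    sqrt(sum(w * (fR - kOff)^2) / ((length(fR) - 1) * sum(w)))
  else NA_real_
  list(kOff = kOff, se = se)
}

#' Apparent binding constant
#'
#' `K_D = k_off / k_on`, converted to nM when `k_on` is in 1/uM/s
#' (multiply by 1000).
#'
#' @param kOff Apparent off-rate, 1/s.
#' @param kOn Apparent on-rate, 1/uM/s (> 0).
#' @return `K_D` in nM.
#' @examples
#' bindingConstant(0.20, 8.77)   # 22.8 nM
#' @export
bindingConstant <- function(kOff, kOn) {
  if (!is.finite(kOn) || kOn <= 0) stop("kOn must be > 0")
  if (!is.finite(kOff) || kOff < 0) stop("kOff must be >= 0")
  kOff / kOn * 1000
}

## per-run dwell estimate: cumulative exponential fit when enough events,
## else the arithmetic mean of uncensored dwells (the exponential MLE)
.dwellEstimate <- function(dwells, edges = c(0, 0.5), minN = 150) {
  if (!length(dwells)) return(list(tau = NA_real_, n = 0L, method = "none"))
  if (length(dwells) >= minN &&
      mean(dwells > edges[1] & dwells <= edges[2]) > 0.95) {
    fit <- tryCatch(fitExponentialCumulative(dwells, edges, minN),
                    error = function(e) NULL)
    if (!is.null(fit))
      return(list(tau = fit$tau, n = fit$n, method = "cumulative-fit"))
  }
  list(tau = mean(dwells), n = length(dwells), method = "mle-mean")
}

#' Kinetics from a titration of detected event tables
#'
#' Computes per-run capture frequencies (exact excluded-time
#' normalization over measuring segments for sweep protocols, or over the
#' full trace for gap-free runs) and mean dwells (cumulative exponential
#' fit when at least `minN` uncensored events lie in the edge window, else
#' the arithmetic-mean MLE; truncated events are excluded from dwell
#' estimates but counted for capture), aggregates them per concentration,
#' and extracts `k_on`, `k_off` and `K_D`.
#'
#' @param runs A list of runs, each a list with elements `conc_nM`,
#'   `events` (an [EventTable-class]) and `protocol` (a
#'   [VoltageProtocol-class]).
#' @param edges,minN Passed to the dwell estimator.
#' @return A list with `series` (per-concentration `data.frame`), `perRun`
#'   (per-run `data.frame`) and `result` (a [KineticsResult-class]).
#' @export
analyzeTitration <- function(runs, edges = c(0, 0.5), minN = 150) {
  perRun <- lapply(runs, function(r) {
    df <- eventData(r$events)
    pr <- r$protocol
    if (pr@mode == "sweeps") {
      occ <- sweepOccupancy(r$events, pr)
      fC <- captureFrequencyGapfree(nrow(df), occ$measuringTimeS,
                                    occ$occupiedMeasuringTimeS)
    } else {
      dur <- protocolDuration(pr)
      occT <- sum(df$dwell_s)
      fC <- captureFrequencyGapfree(nrow(df), dur, occT)
    }
    dw <- df$dwell_s[!df$truncated]
    data.frame(conc_nM = r$conc_nM, fC_per_s = fC,
               n_events = nrow(df), n_uncensored = length(dw),
               dwell_sum_s = sum(dw))
  })
  perRun <- do.call(rbind, perRun)
  concs <- sort(unique(perRun$conc_nM))
  series <- do.call(rbind, lapply(concs, function(cc) {
    sub <- perRun[perRun$conc_nM == cc, , drop = FALSE]
    ## pool uncensored dwells across replicate runs at this concentration
    dwells <- unlist(lapply(runs, function(r) {
      if (r$conc_nM != cc) return(numeric())
      df <- eventData(r$events)
      df$dwell_s[!df$truncated]
    }))
    est <- .dwellEstimate(dwells, edges, minN)
    data.frame(conc_nM = cc,
               fC_per_s = mean(sub$fC_per_s),
               fC_sd = if (nrow(sub) > 1) stats::sd(sub$fC_per_s)
               else NA_real_,
               dwell_s = est$tau,
               dwell_sd = if (length(dwells) > 1) stats::sd(dwells)
               else NA_real_,
               n_pores = nrow(sub),
               n_events = sum(sub$n_events),
               dwell_method = est$method)
  }))
  konFit <- fitKon(series)
  koffFit <- fitKoff(series)
  res <- .kineticsResult(
    tauOffS = 1 / koffFit$kOff,
    tauOffSE = if (is.finite(koffFit$se)) koffFit$se / koffFit$kOff^2
    else NA_real_,
    kOff = koffFit$kOff, kOffSE = koffFit$se,
    kOn = konFit$kOn, kOnSE = konFit$se,
    nEventsTotal = sum(series$n_events),
    method = paste0("fC: excluded-time; dwell: ",
                    paste(unique(series$dwell_method), collapse = "/")))
  list(series = series, perRun = perRun, result = res)
}
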