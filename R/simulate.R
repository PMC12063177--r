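## Synthetic single-channel trace generator. Captures arrive as a Poisson
## process (thinned to single pore occupancy) during measuring-voltage
## segments; non-caged species produce square blockades with exponential
## dwell that are ejected at voltage flips, caged species follow the
## multivalent birth-death occupancy model and persist across flips.

## map analysis intervals to an "analysis clock": given wall time t and an
## increment w of analysis time, return the wall time at which the
## accumulated analysis time since t reaches w (Inf when past the end)
.analysisClock <- function(intervals) {
  a0 <- intervals$start_s
  a1 <- intervals$end_s
  force(a0); force(a1)
  list(
    advance = function(t, w) {
      for (i in seq_along(a0)) {
        if (a1[i] <= t) next
        lo <- max(a0[i], t)
        avail <- a1[i] - lo
        if (w < avail) return(lo + w)
        w <- w - avail
      }
      Inf
    }
  )
}

## continuous-time birth-death occupancy path; state entered at each time.
## Returns transition times/states plus how the excursion ended.
.simulateOccupancyPath <- function(model, t0, tMax) {
  kb <- model@kBind
  ku <- model@kUnbind * model@competitorFactor
  n <- model@nSites
  Tt <- model@nTags
  kesc <- model@kEscape
  times <- t0
  states <- 0L
  t <- t0
  m <- 0L
  escaped <- FALSE
  repeat {
    birth <- kb * (n - m) * (Tt - m)
    death <- ku * m
    esc <- if (m == 0L) kesc else 0
    tot <- birth + death + esc
    if (tot <= 0) { t <- tMax; break }          # absorbing (e.g. kb = 0, kesc = 0)
    dt <- stats::rexp(1, tot)
    if (t + dt >= tMax) { t <- tMax; break }
    t <- t + dt
    u <- stats::runif(1) * tot
    if (u < birth) {
      m <- m + 1L
    } else if (u < birth + death) {
      m <- m - 1L
    } else {
      escaped <- TRUE
      break
    }
    times <- c(times, t)
    states <- c(states, m)
  }
  list(times = times, states = states, endTime = t, escaped = escaped)
}

#' Stationary occupancy distribution of the multivalent binding model
#'
#' Exact stationary distribution of the birth-death occupancy chain over
#' `m = 0..nSites` bound tags (escape ignored, i.e. conditional on the
#' analyte residing in the pore):
#' `pi(m)` proportional to the product over `j < m` of
#' `kBind (nSites - j)(nTags - j) / (kUnbind competitorFactor (j + 1))`.
#'
#' @param model An [OccupancyModel-class].
#' @return Named numeric vector of probabilities over states `0..nSites`.
#' @details With `kUnbind = 0` and `kBind > 0` the chain is absorbed at full
#'   occupancy and a point mass at `m = nSites` is returned; with
#'   `kBind = 0` all mass sits at `m = 0`.
#' @examples
#' stationaryOccupancy(OccupancyModel(nSites = 1, nTags = 10,
#'                                    kBind = 0.1, kUnbind = 1))
#' @export
stationaryOccupancy <- function(model) {
  stopifnot(is(model, "OccupancyModel"))
  n <- model@nSites
  pi <- numeric(n + 1L)
  names(pi) <- as.character(0:n)
  if (model@kBind == 0) { pi[1] <- 1; return(pi) }
  if (model@kUnbind == 0) {
    pi[n + 1L] <- 1
    return(pi)
  }
  ku <- model@kUnbind * model@competitorFactor
  j <- 0:(n - 1)
  logRatio <- log(model@kBind * (n - j) * (model@nTags - j)) -
    log(ku * (j + 1))
  logpi <- c(0, cumsum(logRatio))
  pi[] <- exp(logpi - max(logpi))
  pi / sum(pi)
}

#' Contour length of a polypeptide
#'
#' Maximum end-to-end length of a fully extended chain of `nResidues`
#' residues at the standard intra-C-alpha spacing of 3.8 Angstrom per
#' residue, returned in nm. The 8-residue strepII tag, for instance,
#' spans 3.04 nm.
#'
#' @param nResidues Residue count (>= 0); vectorized.
#' @param perResidueA C-alpha to C-alpha distance in Angstrom.
#' @return Contour length(s) in nm.
#' @examples
#' contourLength(8)    # 3.04
#' contourLength(70)   # 26.6
#' @export
contourLength <- function(nResidues, perResidueA = 3.8) {
  if (any(!is.finite(nResidues)) || any(nResidues < 0))
    stop("nResidues must be >= 0")
  nResidues * perResidueA / 10
}

#' Simulate a single-channel current trace with ground truth
#'
#' Generates a synthetic recording under a [SimulationConfig-class]: a
#' conductance-determined signed baseline per voltage segment, white
#' Gaussian noise, Poisson-arriving analyte captures during
#' measuring-voltage segments (thinned so that at most one analyte occupies
#' the pore), square blockades with exponential dwell for non-caged
#' species (ejected at voltage flips), and multilevel caged blockades that
#' follow the birth-death occupancy model and survive voltage flips. The
#' entropic gate enters as a per-species multiplicative attenuation of the
#' capture rate.
#'
#' @param config A [SimulationConfig-class]; `config@seed` seeds all
#'   randomness.
#' @return A list with elements `trace` (a [Trace-class]), `events` (the
#'   ground-truth [EventTable-class], with extra columns `species`,
#'   `depth_max_pct`, `depth_min_pct`, `n_levels_visited`) and `occupancy`
#'   (a `data.frame` of the per-event occupancy path: `event`, `time_s`,
#'   `state`, `depth_pct`).
#' @examples
#' cfg <- SimulationConfig(seed = 7, samplingRate = 2000,
#'                         protocol = gapFreeProtocol(-75, 30),
#'                         species = list(SpeciesSpec("SA", 20, 8.77,
#'                                        dwellMeanS = 0.0657,
#'                                        depthPct = 45.4)))
#' sim <- simulateTrace(cfg)
#' nEvents(sim$events)
#' @export
simulateTrace <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  set.seed(config@seed)
  rate <- config@samplingRate
  pr <- config@protocol
  segs <- .protocolSegments(pr, rate)
  nTotal <- segs$end_sample[nrow(segs)]
  tEnd <- segs$end_s[nrow(segs)]
  analysisIv <- segs[segs$analysis, c("start_s", "end_s")]

  ## per-species effective capture rates (1/s of free analysis time)
  lam <- vapply(config@species, function(s) {
    att <- if (s@name %in% names(config@gateAttenuation))
      config@gateAttenuation[[s@name]] else 1
    s@kOn * s@concentrationNM / 1000 * att
  }, numeric(1))
  lamTot <- sum(lam)

  clock <- .analysisClock(analysisIv)
  evs <- list()
  occ <- list()
  t <- 0
  eid <- 0L
  while (lamTot > 0 && nrow(analysisIv) > 0) {
    tc <- clock$advance(t, stats::rexp(1, lamTot))
    if (!is.finite(tc) || tc >= tEnd) break
    sp <- config@species[[sample.int(length(lam), 1L, prob = lam)]]
    eid <- eid + 1L
    if (is.null(sp@occupancy)) {
      ## square blockade; ejected at the end of its measuring segment
      segEnd <- analysisIv$end_s[findInterval(tc, analysisIv$start_s)]
      d <- stats::rexp(1, 1 / sp@dwellMeanS)
      end <- min(tc + d, segEnd, tEnd)
      depth <- sp@depthPct +
        if (sp@depthJitterSD > 0) stats::rnorm(1, 0, sp@depthJitterSD) else 0
      depth <- min(max(depth, 0.1), 100)
      evs[[eid]] <- data.frame(
        start_s = tc, dwell_s = end - tc, I_EX_pct = depth,
        truncated = end < tc + d, species = sp@name,
        depth_max_pct = depth, depth_min_pct = depth,
        n_levels_visited = 1L)
      occ[[eid]] <- data.frame(event = eid, time_s = tc, state = NA_integer_,
                               depth_pct = depth)
    } else {
      path <- .simulateOccupancyPath(sp@occupancy, tc, tEnd)
      end <- path$endTime
      depths <- sp@occupancy@levelDepths[path$states + 1L]
      segDur <- diff(c(path$times, end))
      meanDepth <- sum(depths * segDur) / sum(segDur)
      evs[[eid]] <- data.frame(
        start_s = tc, dwell_s = end - tc, I_EX_pct = meanDepth,
        truncated = !path$escaped, species = sp@name,
        depth_max_pct = max(depths), depth_min_pct = min(depths),
        n_levels_visited = length(unique(path$states)))
      occ[[eid]] <- data.frame(event = eid, time_s = path$times,
                               state = path$states, depth_pct = depths)
    }
    t <- end
  }

  ## render: signed conductance baseline, blockades as fractional
  ## magnitude reductions (applied at any voltage), then white noise
  volts <- numeric(nTotal)
  for (i in seq_len(nrow(segs))) {
    lo <- segs$start_sample[i] + 1L
    hi <- segs$end_sample[i]
    if (lo <= hi) volts[lo:hi] <- segs$voltage_mV[i]
  }
  frac <- rep(1, nTotal)
  for (i in seq_along(evs)) {
    p <- occ[[i]]
    e <- evs[[i]]
    bounds <- c(p$time_s, e$start_s + e$dwell_s)
    for (j in seq_len(nrow(p))) {
      lo <- floor(bounds[j] * rate) + 1L
      hi <- min(floor(bounds[j + 1L] * rate), nTotal)
      if (lo <= hi) frac[lo:hi] <- 1 - p$depth_pct[j] / 100
    }
  }
  x <- config@conductanceNS * volts * frac +
    stats::rnorm(nTotal, 0, config@noiseSD)

  truth <- if (length(evs)) do.call(rbind, evs) else data.frame()
  if (nrow(truth)) {
    ends <- truth$start_s + truth$dwell_s
    truth$interevent_s <- c(NA_real_, truth$start_s[-1] -
                              ends[-length(ends)])
    iAna <- abs(config@conductanceNS * analysisVoltage(pr))
    truth$I_B_pA <- iAna * (1 - truth$I_EX_pct / 100)
    truth$label <- truth$species
    truth$sweep_index <- if (pr@mode == "sweeps")
      segs$sweep_index[findInterval(truth$start_s, segs$start_s)]
    else rep(NA_integer_, nrow(truth))
  }
  tr <- Trace(samples = x, samplingRate = rate, protocol = pr,
              metadata = list(simulated = TRUE, seed = config@seed,
                              conductance_nS = config@conductanceNS,
                              noise_sd_pA = config@noiseSD))
  list(trace = tr, events = EventTable(truth),
       occupancy = if (length(occ)) do.call(rbind, occ)
       else data.frame(event = integer(), time_s = numeric(),
                       state = integer(), depth_pct = numeric()))
}
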