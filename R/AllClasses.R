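#' @name poreCage-methods
#' @title Internal method registrations
#' @description S4 method exports for the package's own generics.
#' @keywords internal
#' @exportMethod show
#' @exportMethod samples
#' @exportMethod samplingRate
#' @exportMethod protocol
#' @exportMethod traceMetadata
#' @exportMethod eventData
#' @exportMethod nEvents
#' @exportMethod iexMin
#' @exportMethod iexMax
#' @exportMethod deltaIEX
#' @exportMethod levelCount
NULL

## Central S4 containers: voltage protocols, current traces, event tables,
## the multivalent occupancy model, simulation configuration, all-point
## level profiles and kinetics results. Units throughout: seconds, pA, mV,
## Hz; sample indices are 0-based with half-open ranges.

#' Voltage protocol of a recording
#'
#' Ordered voltage segments applied cyclically during a recording. A
#' `"gap-free"` protocol has a single segment applied once; a `"sweeps"`
#' protocol repeats its segment list `repeatCount` times (e.g. a brief
#' positive ejection pulse followed by a long measuring segment at negative
#' potential).
#'
#' @slot voltageMV Numeric vector, segment voltages in mV.
#' @slot durationS Numeric vector, segment durations in seconds (all > 0).
#' @slot repeatCount Integer >= 1, number of sweep repeats.
#' @slot mode `"gap-free"` (one segment, one repeat) or `"sweeps"`.
#'
#' @param voltageMV,durationS,repeatCount,mode See slots.
#' @return A `VoltageProtocol` object.
#' @examples
#' sweepProtocol(totalS = 600)          # +100 mV 200 ms / -75 mV 2 s cycles
#' gapFreeProtocol(-75, durationS = 60)
#' @aliases VoltageProtocol
#' @export VoltageProtocol
#' @exportClass VoltageProtocol
setClass(
  "VoltageProtocol",
  slots = c(
    voltageMV   = "numeric",
    durationS   = "numeric",
    repeatCount = "integer",
    mode        = "character"
  )
)

setValidity("VoltageProtocol", function(object) {
  msg <- character()
  if (length(object@voltageMV) != length(object@durationS))
    msg <- c(msg, "voltageMV and durationS must have equal length")
  if (length(object@durationS) == 0L)
    msg <- c(msg, "protocol needs at least one segment")
  if (any(!is.finite(object@durationS)) || any(object@durationS <= 0))
    msg <- c(msg, "segment durations must be finite and > 0")
  if (length(object@repeatCount) != 1L || is.na(object@repeatCount) ||
      object@repeatCount < 1L)
    msg <- c(msg, "repeatCount must be a single integer >= 1")
  if (length(object@mode) != 1L || !object@mode %in% c("gap-free", "sweeps"))
    msg <- c(msg, "mode must be 'gap-free' or 'sweeps'")
  if (identical(object@mode, "gap-free") &&
      (length(object@voltageMV) != 1L || object@repeatCount != 1L))
    msg <- c(msg, "gap-free mode has exactly one segment with repeatCount 1")
  if (length(msg)) msg else TRUE
})

setClassUnion("VoltageProtocolOrNULL", c("VoltageProtocol", "NULL"))

VoltageProtocol <- function(voltageMV, durationS, repeatCount = 1L,
                            mode = c("sweeps", "gap-free")) {
  if (missing(mode))
    mode <- if (length(voltageMV) == 1L && repeatCount == 1L)
      "gap-free" else "sweeps"
  else mode <- match.arg(mode)
  new("VoltageProtocol", voltageMV = as.numeric(voltageMV),
      durationS = as.numeric(durationS),
      repeatCount = as.integer(repeatCount), mode = mode)
}

#' @describeIn VoltageProtocol construct a single-segment gap-free protocol.
#' @param totalS Total protocol duration in seconds (sweeps: truncated to an
#'   integer number of full sweep periods).
#' @export
gapFreeProtocol <- function(voltageMV = -75, durationS) {
  VoltageProtocol(voltageMV = voltageMV, durationS = durationS,
                  repeatCount = 1L, mode = "gap-free")
}

#' @describeIn VoltageProtocol construct a cyclic flip/measure sweep
#'   protocol; defaults are a +100 mV, 200 ms ejection pulse followed by a
#'   -75 mV, 2 s measuring segment, repeated to fill `totalS`.
#' @param flipMV,flipS Voltage (mV) and duration (s) of the ejection pulse.
#' @param measureMV,measureS Voltage (mV) and duration (s) of the measuring
#'   segment.
#' @export
sweepProtocol <- function(totalS = 600, flipMV = 100, flipS = 0.2,
                          measureMV = -75, measureS = 2) {
  period <- flipS + measureS
  reps <- as.integer(floor(totalS / period))
  if (reps < 1L)
    stop("totalS shorter than one sweep period")
  VoltageProtocol(voltageMV = c(flipMV, measureMV),
                  durationS = c(flipS, measureS),
                  repeatCount = reps, mode = "sweeps")
}

#' @describeIn VoltageProtocol duration of one sweep period in seconds.
#' @param object,x A `VoltageProtocol`.
#' @export
sweepPeriod <- function(object) sum(object@durationS)

#' @describeIn VoltageProtocol total protocol duration in seconds.
#' @export
protocolDuration <- function(object) {
  sum(object@durationS) * object@repeatCount
}

#' @describeIn VoltageProtocol the measuring ("analysis") voltage, taken as
#'   the voltage of the longest segment within one sweep.
#' @export
analysisVoltage <- function(object) {
  object@voltageMV[which.max(object@durationS)]
}

setMethod("show", "VoltageProtocol", function(object) {
  cat(sprintf("VoltageProtocol [%s]: %d segment(s) x %d repeat(s), %.3f s total\n",
              object@mode, length(object@voltageMV), object@repeatCount,
              protocolDuration(object)))
  for (i in seq_along(object@voltageMV))
    cat(sprintf("  segment %d: %+g mV for %g s\n", i,
                object@voltageMV[i], object@durationS[i]))
  invisible(NULL)
})

#' Single-channel current trace
#'
#' A sampled ionic-current recording. Currents are stored signed, exactly as
#' recorded (negative at negative applied potential); analyses operate on
#' magnitudes after [normalizePolarity()].
#'
#' @slot samples Numeric vector of currents in pA.
#' @slot samplingRate Sampling frequency in Hz (> 0).
#' @slot protocol A [VoltageProtocol-class] or `NULL` when unknown.
#' @slot metadata Free-form named list (source file, pore class, filters
#'   applied, polarity flag, ...).
#'
#' @param samples,samplingRate,protocol,metadata See slots.
#' @return A `Trace` object.
#' @examples
#' tr <- Trace(rnorm(5000, -171.75, 2), samplingRate = 5e4,
#'             protocol = gapFreeProtocol(-75, durationS = 0.1))
#' tr
#' @aliases Trace
#' @export Trace
#' @exportClass Trace
setClass(
  "Trace",
  slots = c(
    samples      = "numeric",
    samplingRate = "numeric",
    protocol     = "VoltageProtocolOrNULL",
    metadata     = "list"
  ),
  prototype = list(protocol = NULL, metadata = list())
)

setValidity("Trace", function(object) {
  msg <- character()
  if (length(object@samplingRate) != 1L || !is.finite(object@samplingRate) ||
      object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (!is.null(object@protocol)) {
    expected <- protocolDuration(object@protocol) * object@samplingRate
    nseg <- length(object@protocol@voltageMV) * object@protocol@repeatCount
    ## +-1 sample per segment boundary; a recording may additionally run
    ## on for less than one sweep period beyond the last full repeat
    remainder <- sum(object@protocol@durationS) * object@samplingRate
    n <- length(object@samples)
    if (n < expected - (nseg + 1) || n >= expected + remainder + nseg + 1)
      msg <- c(msg, sprintf(
        "sample count %d inconsistent with protocol duration (expected ~%d)",
        n, round(expected)))
  }
  if (length(msg)) msg else TRUE
})

Trace <- function(samples, samplingRate, protocol = NULL,
                  metadata = list()) {
  new("Trace", samples = as.numeric(samples),
      samplingRate = as.numeric(samplingRate), protocol = protocol,
      metadata = metadata)
}

setMethod("samples", "Trace", function(object) object@samples)
setMethod("samplingRate", "Trace", function(object) object@samplingRate)
setMethod("protocol", "Trace", function(object) object@protocol)
setMethod("traceMetadata", "Trace", function(object) object@metadata)

setMethod("show", "Trace", function(object) {
  n <- length(object@samples)
  cat(sprintf("Trace: %d samples at %g Hz (%.3f s)\n",
              n, object@samplingRate, n / object@samplingRate))
  if (n)
    cat(sprintf("  current range: [%.2f, %.2f] pA\n",
                min(object@samples), max(object@samples)))
  if (!is.null(object@protocol))
    cat(sprintf("  protocol: %s, %d segment(s) x %d repeat(s)\n",
                object@protocol@mode, length(object@protocol@voltageMV),
                object@protocol@repeatCount))
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
  invisible(NULL)
})

## required event-table columns, in canonical (file) order
.EVENT_COLUMNS <- c("start_s", "dwell_s", "interevent_s", "I_B_pA",
                    "I_EX_pct", "sweep_index", "label", "truncated")

#' Idealized blockade events
#'
#' One row per blockade: onset time (`start_s`, s), dwell (`dwell_s`, s),
#' gap since the previous event's end (`interevent_s`, s; `NA` for the
#' first event), mean blocked current (`I_B_pA`), excluded current
#' (`I_EX_pct`, percent of the open-pore current), the sweep in which the
#' event started (`sweep_index`, `NA` for gap-free recordings), a free-text
#' `label`, and a `truncated` flag for events cut by a sweep boundary or the
#' recording edge. Extra columns (e.g. ground-truth species) are preserved.
#'
#' Events must be time-ordered and non-overlapping with positive dwells.
#'
#' @slot events The underlying `data.frame`.
#'
#' @param events A `data.frame`; missing canonical columns are added
#'   (`NA`-filled, `truncated` defaults to `FALSE`).
#' @return An `EventTable`.
#' @examples
#' ev <- EventTable(data.frame(start_s = c(1, 2), dwell_s = c(0.05, 0.1),
#'                             I_B_pA = c(90, 85), I_EX_pct = c(45, 48)))
#' nEvents(ev)
#' @aliases EventTable
#' @export EventTable
#' @exportClass EventTable
setClass("EventTable", slots = c(events = "data.frame"))

setValidity("EventTable", function(object) {
  df <- object@events
  msg <- character()
  missing <- setdiff(.EVENT_COLUMNS, names(df))
  if (length(missing))
    msg <- c(msg, paste("missing columns:", paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(df)) {
    if (any(!is.finite(df$dwell_s)) || any(df$dwell_s <= 0))
      msg <- c(msg, "dwell_s must be finite and > 0")
    if (is.unsorted(df$start_s, strictly = FALSE))
      msg <- c(msg, "events must be ordered by start_s")
    if (nrow(df) > 1) {
      ends <- df$start_s + df$dwell_s
      if (any(df$start_s[-1] < ends[-nrow(df)] - 1e-9))
        msg <- c(msg, "events must not overlap")
    }
  }
  if (length(msg)) msg else TRUE
})

.asEventTable <- function(df) {
  if (is.null(df)) df <- data.frame()
  if (!nrow(df) && !length(names(df)))
    df <- data.frame(start_s = numeric(), dwell_s = numeric())
  for (col in .EVENT_COLUMNS) {
    if (!col %in% names(df)) {
      df[[col]] <- switch(col,
        truncated   = logical(nrow(df)),
        label       = rep(NA_character_, nrow(df)),
        sweep_index = rep(NA_integer_, nrow(df)),
        rep(NA_real_, nrow(df)))
    }
  }
  extra <- setdiff(names(df), .EVENT_COLUMNS)
  df <- df[, c(.EVENT_COLUMNS, extra), drop = FALSE]
  rownames(df) <- NULL
  new("EventTable", events = df)
}

## user-facing constructor normalizes columns
EventTable <- function(events = data.frame()) .asEventTable(events)

setMethod("eventData", "EventTable", function(object) object@events)
setMethod("nEvents", "EventTable", function(object) nrow(object@events))

setMethod("show", "EventTable", function(object) {
  df <- object@events
  cat(sprintf("EventTable: %d event(s)\n", nrow(df)))
  if (nrow(df)) {
    cat(sprintf("  time span: %.4f - %.4f s; median dwell %.4g s\n",
                min(df$start_s), max(df$start_s + df$dwell_s),
                stats::median(df$dwell_s)))
    cat(sprintf("  median I_EX: %.1f %%; truncated: %d\n",
                stats::median(df$I_EX_pct), sum(df$truncated, na.rm = TRUE)))
  }
  invisible(NULL)
})

#' @describeIn EventTable subset an event table (rows), returning an
#'   `EventTable`.
#' @param x An `EventTable`.
#' @param i Row index.
#' @export
setMethod("[", "EventTable", function(x, i) .asEventTable(x@events[i, ,
                                                                   drop = FALSE]))

#' @describeIn EventTable coerce to `data.frame`.
#' @param row.names,optional,... Passed on for S3 compatibility (unused).
#' @export
as.data.frame.EventTable <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  x@events
}

#' Multivalent occupancy model of a caged blockade
#'
#' Birth-death Markov model of the number of pore tags simultaneously bound
#' to a multivalent analyte trapped in the pore. From occupancy state
#' `m` (0..`nSites` bound), a new bond forms at rate
#' `kBind * (nSites - m) * (nTags - m)` (mass-action over free analyte
#' pockets and free pore tags) and an existing bond breaks at rate
#' `kUnbind * competitorFactor * m`; a trans-side competitor (e.g. biotin)
#' raises the unbinding rate by `competitorFactor`. The analyte can escape
#' the pore only from the fully unbound state `m = 0`, at rate `kEscape`.
#' Each state has its own excluded-current level: `levelDepths[1]` (state 0,
#' analyte deepest in the pore) is the maximum depth and depths decrease
#' monotonically as more tags hold the analyte higher in the vestibule.
#'
#' The default geometry is the tetravalent streptavidin / didecameric pore
#' case: 4 binding pockets against 10 tags (one tag per pore subunit).
#'
#' @slot nSites Integer >= 1, binding pockets on the analyte (4 for SA).
#' @slot nTags Integer >= 1, tags displayed by the pore (10 for a didecamer).
#' @slot kBind Per site-tag pair binding rate, 1/s.
#' @slot kUnbind Per-bond unbinding rate, 1/s.
#' @slot competitorFactor Multiplier >= 1 on `kUnbind`.
#' @slot kEscape Escape rate from state 0, 1/s.
#' @slot levelDepths Numeric, length `nSites + 1`, excluded-current percent
#'   per state, non-increasing from state 0.
#'
#' @param nSites,nTags,kBind,kUnbind,competitorFactor,kEscape See slots.
#' @param depthMaxPct,depthMinPct Extremes of the level ladder (state 0 and
#'   state `nSites`); used to build a linear ladder when `levelDepths` is
#'   not given. Defaults match a deep ~48% unbound level with a 15.4
#'   Delta-percent band.
#' @param levelDepths Explicit per-state depths overriding the ladder.
#' @return An `OccupancyModel`.
#' @examples
#' m <- OccupancyModel(nSites = 4, nTags = 10)
#' stationaryOccupancy(m)
#' @aliases OccupancyModel
#' @export OccupancyModel
#' @exportClass OccupancyModel
setClass(
  "OccupancyModel",
  slots = c(
    nSites           = "integer",
    nTags            = "integer",
    kBind            = "numeric",
    kUnbind          = "numeric",
    competitorFactor = "numeric",
    kEscape          = "numeric",
    levelDepths      = "numeric"
  )
)

setValidity("OccupancyModel", function(object) {
  msg <- character()
  if (object@nSites < 1L) msg <- c(msg, "nSites must be >= 1")
  if (object@nTags < 1L) msg <- c(msg, "nTags must be >= 1")
  if (object@nTags < object@nSites)
    msg <- c(msg, "nTags must be >= nSites for full occupancy to be reachable")
  if (object@kBind < 0 || object@kUnbind < 0 || object@kEscape < 0)
    msg <- c(msg, "rates must be >= 0")
  if (object@competitorFactor < 1)
    msg <- c(msg, "competitorFactor must be >= 1")
  if (length(object@levelDepths) != object@nSites + 1L)
    msg <- c(msg, "levelDepths must have length nSites + 1")
  else {
    if (any(diff(object@levelDepths) > 1e-9))
      msg <- c(msg, "levelDepths must be non-increasing from state 0")
    if (which.max(object@levelDepths) != 1L)
      msg <- c(msg, "state 0 must carry the maximum depth")
  }
  if (length(msg)) msg else TRUE
})

setClassUnion("OccupancyModelOrNULL", c("OccupancyModel", "NULL"))

OccupancyModel <- function(nSites = 4L, nTags = 10L, kBind = 0.12,
                           kUnbind = 1.0, competitorFactor = 1,
                           kEscape = 0.01, depthMaxPct = 48.0,
                           depthMinPct = 32.6, levelDepths = NULL) {
  nSites <- as.integer(nSites)
  nTags <- as.integer(nTags)
  if (is.null(levelDepths))
    levelDepths <- seq(depthMaxPct, depthMinPct, length.out = nSites + 1L)
  new("OccupancyModel", nSites = nSites, nTags = nTags, kBind = kBind,
      kUnbind = kUnbind, competitorFactor = competitorFactor,
      kEscape = kEscape, levelDepths = as.numeric(levelDepths))
}

setMethod("show", "OccupancyModel", function(object) {
  cat(sprintf(
    "OccupancyModel: %d pockets x %d tags; kBind %g /s, kUnbind %g /s%s, kEscape %g /s\n",
    object@nSites, object@nTags, object@kBind, object@kUnbind,
    if (object@competitorFactor != 1)
      sprintf(" (x%g competitor)", object@competitorFactor) else "",
    object@kEscape))
  cat("  level depths (% I_EX):",
      paste(sprintf("%.1f", object@levelDepths), collapse = ", "), "\n")
  invisible(NULL)
})

#' Analyte species specification for simulation
#'
#' Captures arrive as a Poisson process at rate
#' `kOn (1/uM/s) * concentration (nM) / 1000`, optionally attenuated by the
#' entropic gate (see [SimulationConfig-class]). A species is either
#' *non-caged* -- square blockades with exponentially distributed dwell
#' (`dwellMeanS`) at depth `depthPct` (per-event Gaussian jitter
#' `depthJitterSD`), ejected by voltage flips -- or *caged* -- a
#' multivalent [OccupancyModel-class] blockade that persists across voltage
#' flips and terminates only by escape from the unbound state.
#'
#' @slot name Species label used in ground-truth tables.
#' @slot concentrationNM Concentration in nM.
#' @slot kOn Capture on-rate in 1/uM/s.
#' @slot dwellMeanS Mean dwell in s (non-caged), `NA` for caged species.
#' @slot depthPct Blockade depth in % excluded current (non-caged).
#' @slot depthJitterSD Per-event depth jitter sd, in Delta-percent.
#' @slot occupancy An [OccupancyModel-class] (caged), or `NULL`.
#'
#' @param name,concentrationNM,kOn,dwellMeanS,depthPct,depthJitterSD,occupancy
#'   See slots.
#' @return A `SpeciesSpec`.
#' @examples
#' SpeciesSpec("BT", concentrationNM = 50, kOn = 2,
#'             dwellMeanS = 0.05, depthPct = 75.9)
#' @aliases SpeciesSpec
#' @export SpeciesSpec
#' @exportClass SpeciesSpec
setClass(
  "SpeciesSpec",
  slots = c(
    name            = "character",
    concentrationNM = "numeric",
    kOn             = "numeric",
    dwellMeanS      = "numeric",
    depthPct        = "numeric",
    depthJitterSD   = "numeric",
    occupancy       = "OccupancyModelOrNULL"
  )
)

setValidity("SpeciesSpec", function(object) {
  msg <- character()
  if (object@concentrationNM < 0 || object@kOn < 0)
    msg <- c(msg, "concentration and kOn must be >= 0")
  caged <- !is.null(object@occupancy)
  if (caged && !is.na(object@dwellMeanS))
    msg <- c(msg, "exactly one of dwellMeanS / occupancy may be set")
  if (!caged) {
    if (is.na(object@dwellMeanS) || object@dwellMeanS <= 0)
      msg <- c(msg, "non-caged species need dwellMeanS > 0")
    if (is.na(object@depthPct) || object@depthPct <= 0 ||
        object@depthPct > 100)
      msg <- c(msg, "non-caged species need depthPct in (0, 100]")
    if (object@depthJitterSD < 0)
      msg <- c(msg, "depthJitterSD must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

SpeciesSpec <- function(name, concentrationNM, kOn, dwellMeanS = NA_real_,
                        depthPct = NA_real_, depthJitterSD = 0,
                        occupancy = NULL) {
  new("SpeciesSpec", name = name, concentrationNM = concentrationNM,
      kOn = kOn, dwellMeanS = dwellMeanS, depthPct = depthPct,
      depthJitterSD = depthJitterSD, occupancy = occupancy)
}

setMethod("show", "SpeciesSpec", function(object) {
  kind <- if (is.null(object@occupancy)) {
    sprintf("square blockade %.1f%% (jitter %.2g), dwell %g s",
            object@depthPct, object@depthJitterSD, object@dwellMeanS)
  } else {
    sprintf("caged, %d-site occupancy model", object@occupancy@nSites)
  }
  cat(sprintf("SpeciesSpec '%s': %g nM, kOn %g /uM/s -> lambda %.4g /s; %s\n",
              object@name, object@concentrationNM, object@kOn,
              object@kOn * object@concentrationNM / 1000, kind))
  invisible(NULL)
})

#' Simulation configuration
#'
#' Full parameterization of a synthetic single-channel recording: sampling,
#' voltage protocol, pore conductance (the signed open-pore baseline is
#' `conductanceNS * voltageMV` pA per segment), white Gaussian current
#' noise, the analyte species present, and optional per-species capture
#' attenuation factors in (0, 1] modelling the entropic gate.
#'
#' @slot seed Integer RNG seed; all randomness flows from it.
#' @slot samplingRate Hz.
#' @slot protocol A [VoltageProtocol-class].
#' @slot conductanceNS Pore conductance in nS.
#' @slot noiseSD Gaussian current noise sd in pA (> 0).
#' @slot species List of [SpeciesSpec-class].
#' @slot gateAttenuation Named numeric, per-species multiplicative capture
#'   attenuation in (0, 1]; species absent from the vector are unattenuated.
#'
#' @param seed,samplingRate,protocol,conductanceNS,noiseSD,species,gateAttenuation
#'   See slots.
#' @return A `SimulationConfig`.
#' @examples
#' cfg <- SimulationConfig(seed = 1, samplingRate = 5000,
#'                         protocol = gapFreeProtocol(-75, 10),
#'                         species = list(SpeciesSpec("SA", 20, 8.77,
#'                                        dwellMeanS = 0.0657,
#'                                        depthPct = 45.4)))
#' @aliases SimulationConfig
#' @export SimulationConfig
#' @exportClass SimulationConfig
setClass(
  "SimulationConfig",
  slots = c(
    seed            = "integer",
    samplingRate    = "numeric",
    protocol        = "VoltageProtocol",
    conductanceNS   = "numeric",
    noiseSD         = "numeric",
    species         = "list",
    gateAttenuation = "numeric"
  )
)

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be > 0")
  if (object@conductanceNS <= 0)
    msg <- c(msg, "conductanceNS must be > 0")
  if (object@noiseSD <= 0)
    msg <- c(msg, "noiseSD must be > 0")
  if (length(object@species) &&
      !all(vapply(object@species, is, logical(1), "SpeciesSpec")))
    msg <- c(msg, "species must be a list of SpeciesSpec")
  if (length(object@gateAttenuation)) {
    if (any(object@gateAttenuation <= 0 | object@gateAttenuation > 1))
      msg <- c(msg, "gateAttenuation factors must be in (0, 1]")
    spnames <- vapply(object@species, function(s) s@name, character(1))
    if (!all(names(object@gateAttenuation) %in% spnames))
      msg <- c(msg, "gateAttenuation names must match species names")
  }
  if (length(msg)) msg else TRUE
})

SimulationConfig <- function(seed = 1L, samplingRate = 5e4,
                             protocol = sweepProtocol(),
                             conductanceNS = 2.29, noiseSD = 2,
                             species = list(),
                             gateAttenuation = numeric()) {
  new("SimulationConfig", seed = as.integer(seed),
      samplingRate = samplingRate, protocol = protocol,
      conductanceNS = conductanceNS, noiseSD = noiseSD,
      species = species, gateAttenuation = gateAttenuation)
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: seed %d, %g Hz, G = %.2f nS, noise sd %.2g pA\n",
    object@seed, object@samplingRate, object@conductanceNS, object@noiseSD))
  cat(sprintf("  protocol: %s, %.1f s total; %d species\n",
              object@protocol@mode, protocolDuration(object@protocol),
              length(object@species)))
  for (s in object@species) {
    att <- if (s@name %in% names(object@gateAttenuation))
      object@gateAttenuation[[s@name]] else 1
    cat(sprintf("   - %s (gate attenuation %.3g)\n", s@name, att))
  }
  invisible(NULL)
})

#' All-point amplitude profile of a blockade window
#'
#' All-point histogram of a trace window on the excluded-current axis
#' (percent of the open-pore current), with, after fitting, the outer-peak
#' Gaussian means `iexMin`/`iexMax`, their difference `deltaIEX` (the
#' blockade bandwidth in Delta-percent) and the discrete level census.
#'
#' @slot binCenters Bin centers on the I_EX axis (%), increasing.
#' @slot counts Per-bin sample counts.
#' @slot binPA Histogram bin width in pA (before conversion to I_EX).
#' @slot iO Open-pore current magnitude used for the conversion, pA.
#' @slot windowS Window length in seconds.
#' @slot peaks `data.frame` of detected/fitted peaks (`mean_iex`, `sd`,
#'   `height`, `baseline` flag).
#' @slot iexMinPct,iexMaxPct,deltaPct Outer-peak summary (% / Delta-%).
#' @slot nLevels Discrete level count (excluding the open-pore mode).
#' @slot degenerate TRUE when fewer than two blockade modes were found.
#' @aliases LevelProfile
#' @exportClass LevelProfile
setClass(
  "LevelProfile",
  slots = c(
    binCenters = "numeric",
    counts     = "numeric",
    binPA      = "numeric",
    iO         = "numeric",
    windowS    = "numeric",
    peaks      = "data.frame",
    iexMinPct  = "numeric",
    iexMaxPct  = "numeric",
    deltaPct   = "numeric",
    nLevels    = "integer",
    degenerate = "logical"
  ),
  prototype = list(peaks = data.frame(), iexMinPct = NA_real_,
                   iexMaxPct = NA_real_, deltaPct = NA_real_,
                   nLevels = NA_integer_, degenerate = FALSE)
)

setValidity("LevelProfile", function(object) {
  msg <- character()
  if (length(object@binCenters) != length(object@counts))
    msg <- c(msg, "binCenters and counts must have equal length")
  if (length(object@iO) != 1L || object@iO <= 0)
    msg <- c(msg, "iO must be a single positive number")
  if (!is.na(object@deltaPct) && object@deltaPct < -1e-9)
    msg <- c(msg, "deltaPct must be >= 0")
  if (!is.na(object@iexMinPct) && !is.na(object@iexMaxPct) &&
      object@iexMaxPct < object@iexMinPct - 1e-9)
    msg <- c(msg, "iexMaxPct must be >= iexMinPct")
  if (length(msg)) msg else TRUE
})

setMethod("iexMin", "LevelProfile", function(object) object@iexMinPct)
setMethod("iexMax", "LevelProfile", function(object) object@iexMaxPct)
setMethod("deltaIEX", "LevelProfile", function(object) object@deltaPct)
setMethod("levelCount", "LevelProfile", function(object) object@nLevels)

setMethod("show", "LevelProfile", function(object) {
  cat(sprintf("LevelProfile: %d bins (%.2g pA), %.1f s window, I_O = %.2f pA\n",
              length(object@counts), object@binPA, object@windowS, object@iO))
  if (!is.na(object@deltaPct))
    cat(sprintf("  I_EX,min %.2f%%  I_EX,max %.2f%%  Delta I_EX %.2f Delta-%%%s\n",
                object@iexMinPct, object@iexMaxPct, object@deltaPct,
                if (object@degenerate) " [degenerate]" else ""))
  if (!is.na(object@nLevels))
    cat(sprintf("  discrete levels: %d\n", object@nLevels))
  invisible(NULL)
})

#' Kinetics summary of a recording or titration
#'
#' Rates and affinities from dwell/interevent analysis: mean dwell
#' `tauOff` (s) and interevent `tauOn` (s), release frequency
#' `fR = 1/tauOff` (1/s), capture frequency `fC = 1/tauOn` (1/s), the
#' apparent rates `kOff` (1/s) and `kOn` (1/uM/s), and the apparent binding
#' constant `kD = kOff/kOn` in nM with first-order propagated uncertainty.
#' Fields not determined by the analysis that produced the object are `NA`.
#'
#' @slot tauOffS,tauOffSE,tauOnS,tauOnSE Dwell/interevent means and their
#'   standard errors, s.
#' @slot fR,fC Release and capture frequencies, 1/s.
#' @slot kOff,kOffSE Apparent off-rate and se, 1/s.
#' @slot kOn,kOnSE Apparent on-rate and se, 1/uM/s.
#' @slot kDnM,kDnMSE Apparent binding constant and se, nM.
#' @slot nEventsTotal Number of events used.
#' @slot method Short tag describing the estimators used.
#' @aliases KineticsResult
#' @exportClass KineticsResult
setClass(
  "KineticsResult",
  slots = c(
    tauOffS = "numeric", tauOffSE = "numeric",
    tauOnS = "numeric", tauOnSE = "numeric",
    fR = "numeric", fC = "numeric",
    kOff = "numeric", kOffSE = "numeric",
    kOn = "numeric", kOnSE = "numeric",
    kDnM = "numeric", kDnMSE = "numeric",
    nEventsTotal = "integer",
    method = "character"
  )
)

setValidity("KineticsResult", function(object) {
  msg <- character()
  rates <- c(object@fR, object@fC, object@kOff, object@kOn)
  if (any(rates[!is.na(rates)] < 0))
    msg <- c(msg, "rates must be >= 0")
  if (!is.na(object@kDnM) && !is.na(object@kOff) && !is.na(object@kOn) &&
      object@kOn > 0 &&
      abs(object@kDnM - 1000 * object@kOff / object@kOn) >
        1e-6 * max(1, object@kDnM))
    msg <- c(msg, "kDnM must equal kOff/kOn (in nM)")
  if (length(msg)) msg else TRUE
})

.kineticsResult <- function(tauOffS = NA_real_, tauOffSE = NA_real_,
                            tauOnS = NA_real_, tauOnSE = NA_real_,
                            kOff = NA_real_, kOffSE = NA_real_,
                            kOn = NA_real_, kOnSE = NA_real_,
                            nEventsTotal = NA_integer_, method = "") {
  kD <- if (!is.na(kOff) && !is.na(kOn) && kOn > 0)
    1000 * kOff / kOn else NA_real_
  kDSE <- if (!is.na(kD) && !is.na(kOffSE) && !is.na(kOnSE) && kOff > 0)
    kD * sqrt((kOffSE / kOff)^2 + (kOnSE / kOn)^2) else NA_real_
  new("KineticsResult",
      tauOffS = tauOffS, tauOffSE = tauOffSE,
      tauOnS = tauOnS, tauOnSE = tauOnSE,
      fR = if (!is.na(tauOffS) && tauOffS > 0) 1 / tauOffS else NA_real_,
      fC = if (!is.na(tauOnS) && tauOnS > 0) 1 / tauOnS else NA_real_,
      kOff = kOff, kOffSE = kOffSE, kOn = kOn, kOnSE = kOnSE,
      kDnM = kD, kDnMSE = kDSE,
      nEventsTotal = as.integer(nEventsTotal), method = method)
}

setMethod("show", "KineticsResult", function(object) {
  cat("KineticsResult", if (nzchar(object@method))
    sprintf("[%s]", object@method) else "", "\n")
  if (!is.na(object@kOff))
    cat(sprintf("  kOff = %.4g +/- %.2g /s\n", object@kOff, object@kOffSE))
  if (!is.na(object@kOn))
    cat(sprintf("  kOn  = %.4g +/- %.2g /uM/s\n", object@kOn, object@kOnSE))
  if (!is.na(object@kDnM))
    cat(sprintf("  K_D  = %.3g +/- %.2g nM\n", object@kDnM, object@kDnMSE))
  if (!is.na(object@tauOffS))
    cat(sprintf("  tauOff = %.4g s (n = %d)\n", object@tauOffS,
                object@nEventsTotal))
  invisible(NULL)
})
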