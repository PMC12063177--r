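#' Read a pipeline run configuration
#'
#' Loads a YAML or JSON run configuration. A configuration names exactly
#' one input source -- a `simulation` block (see
#' [simulationConfigFromList()]) or an `input` block pointing at a trace
#' file -- plus optional `filter_hz`, `detector`, `baseline`, `caging`,
#' `selectivity` blocks, the list of `analyses` to run (`"caging"`,
#' `"kinetics"`, `"selectivity"`), an `output_dir` and a `seed`. See the
#' packaged example: `system.file("extdata", "example-config.yaml",
#' package = "poreCage")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return The configuration as a named list (class `"runConfig"`).
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::fromJSON(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext)
  .validateRunConfig(cfg)
}

.validateRunConfig <- function(cfg) {
  nsrc <- sum(c("simulation", "input") %in% names(cfg))
  if (nsrc != 1L)
    stop("config must name exactly one input source ",
         "('simulation' or 'input')")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  if (is.null(cfg$filter_hz)) cfg$filter_hz <- 500
  if (is.null(cfg$analyses)) cfg$analyses <- character()
  bad <- setdiff(cfg$analyses, c("caging", "kinetics", "selectivity"))
  if (length(bad)) stop("unknown analyses: ", paste(bad, collapse = ", "))
  class(cfg) <- c("runConfig", class(cfg))
  cfg
}

#' Build a SimulationConfig from a plain list
#'
#' Maps the `simulation` block of a run configuration (snake_case keys, as
#' serialized to YAML/JSON) onto a [SimulationConfig-class]. The protocol
#' block is either `mode: sweeps` with `total_s`, `flip_mV`, `flip_s`,
#' `measure_mV`, `measure_s`, or `mode: gap-free` with `voltage_mV` and
#' `duration_s`. Each species carries `name`, `concentration_nM`,
#' `k_on_per_uM_s` and either `dwell_mean_s` + `depth_pct`
#' (+ `depth_jitter_sd`) or an `occupancy` block with the
#' [OccupancyModel-class] parameters.
#'
#' @param sim The simulation block as a named list.
#' @param seed Integer seed.
#' @return A [SimulationConfig-class].
#' @export
simulationConfigFromList <- function(sim, seed = 1L) {
  pr <- .protocolFromList(sim$protocol) %||% sweepProtocol()
  species <- lapply(sim$species, function(s) {
    occ <- NULL
    if (!is.null(s$occupancy)) {
      o <- s$occupancy
      occ <- OccupancyModel(
        nSites = o$n_sites %||% 4L, nTags = o$n_tags %||% 10L,
        kBind = o$k_bind %||% 0.12, kUnbind = o$k_unbind %||% 1.0,
        competitorFactor = o$competitor_factor %||% 1,
        kEscape = o$k_escape %||% 0.01,
        depthMaxPct = o$depth_max_pct %||% 48.0,
        depthMinPct = o$depth_min_pct %||% 32.6,
        levelDepths = o$level_depths)
    }
    SpeciesSpec(name = s$name,
                concentrationNM = s$concentration_nM,
                kOn = s$k_on_per_uM_s,
                dwellMeanS = if (is.null(occ)) s$dwell_mean_s else NA_real_,
                depthPct = if (is.null(occ)) s$depth_pct else NA_real_,
                depthJitterSD = s$depth_jitter_sd %||% 0,
                occupancy = occ)
  })
  gate <- unlist(sim$gate_attenuation %||% list())
  SimulationConfig(seed = seed,
                   samplingRate = sim$sampling_rate_hz %||% 5e4,
                   protocol = pr,
                   conductanceNS = sim$conductance_nS %||% 2.29,
                   noiseSD = sim$noise_sd_pA %||% 2,
                   species = species,
                   gateAttenuation = if (length(gate)) gate else numeric())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## protocol block (snake_case list) -> VoltageProtocol, or NULL
.protocolFromList <- function(prl) {
  if (is.null(prl)) return(NULL)
  if (is.null(prl$mode) || identical(prl$mode, "sweeps")) {
    sweepProtocol(totalS = prl$total_s %||% 600,
                  flipMV = prl$flip_mV %||% 100,
                  flipS = prl$flip_s %||% 0.2,
                  measureMV = prl$measure_mV %||% -75,
                  measureS = prl$measure_s %||% 2)
  } else {
    gapFreeProtocol(voltageMV = prl$voltage_mV %||% -75,
                    durationS = prl$duration_s)
  }
}

#' Run the analysis pipeline from a configuration
#'
#' Config-driven orchestration of simulate/load, polarity normalization,
#' Gaussian filtering, baseline estimation, event detection, and the
#' requested analyses (caged-level profiling, kinetics, fingerprint
#' selectivity). All outputs are deterministic given the seed and are
#' written to the output directory: `params.json` (every parameter actually
#' used), `events.tsv`, `ground_truth.tsv` (simulated input only),
#' `level_profile.tsv` + `caging.json`, `kinetics.json`,
#' `selectivity.json` + `events_annotated.tsv`, and `summary.txt`.
#'
#' @param config A configuration list from [readRunConfig()], or a path to
#'   one.
#' @param outputDir Output directory, overriding `config$output_dir`.
#' @return Invisibly, a list with the computed objects (`trace`, `events`,
#'   and per-analysis results).
#' @export
runPipeline <- function(config, outputDir = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- .validateRunConfig(unclass(config))
  out <- outputDir %||% config$output_dir %||% stop("no output directory")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  used <- list(seed = config$seed, filter_hz = config$filter_hz,
               analyses = config$analyses)

  truth <- NULL
  if (!is.null(config$simulation)) {
    simCfg <- simulationConfigFromList(config$simulation,
                                       seed = config$seed)
    sim <- simulateTrace(simCfg)
    trace <- sim$trace
    truth <- sim$events
    writeEvents(truth, file.path(out, "ground_truth.tsv"))
    used$simulation <- config$simulation
  } else {
    trace <- readTrace(config$input$path,
                       samplingRate = config$input$sampling_rate_hz,
                       protocol = .protocolFromList(config$input$protocol))
    used$input <- config$input
  }

  trace <- normalizePolarity(trace)
  trace <- gaussianLowpass(trace, config$filter_hz)

  det <- config$detector %||% list()
  settings <- detectorSettings(
    openFraction = det$open_fraction %||% 0.90,
    closeFraction = det$close_fraction %||% 0.95,
    minDwellS = det$min_dwell_s)
  used$detector <- settings

  iO <- config$baseline$i_o_pA
  if (is.null(iO)) {
    bl <- estimateBaseline(trace, binPA = config$baseline$bin_pA %||% 0.5)
    iO <- bl$iO
  } else bl <- iO
  used$baseline_i_o_pA <- iO

  events <- detectEvents(trace, bl, settings)
  writeEvents(events, file.path(out, "events.tsv"))
  results <- list(trace = trace, events = events, truth = truth,
                  baseline = iO)

  .stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE))
  }

  if ("caging" %in% config$analyses) {
    cg <- config$caging %||% list()
    pf <- .stage("caging", allpointProfile(trace, iO,
                          binPA = cg$bin_pA %||% 0.1,
                          windowS = cg$window_s %||% 60,
                          startS = cg$window_start_s %||% 0,
                          strict = isTRUE(cg$strict)))
    pf <- .stage("caging", fitOuterPeaks(pf))
    nl <- countLevels(pf)
    utils::write.table(
      data.frame(bin_center_iex_pct = .fmtNum(pf@binCenters),
                 count = pf@counts),
      file.path(out, "level_profile.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    jsonlite::write_json(
      list(iex_min_pct = iexMin(pf), iex_max_pct = iexMax(pf),
           delta_iex_pct = deltaIEX(pf), n_levels = nl,
           degenerate = pf@degenerate),
      file.path(out, "caging.json"), auto_unbox = TRUE, digits = NA)
    used$caging <- cg
    results$caging <- pf
    results$nLevels <- nl
  }

  if ("kinetics" %in% config$analyses) {
    pr <- protocol(trace)
    df <- eventData(events)
    if (!is.null(pr) && pr@mode == "sweeps") {
      occ <- sweepOccupancy(events, pr)
      fC <- captureFrequencyGapfree(nrow(df), occ$measuringTimeS,
                                    occ$occupiedMeasuringTimeS)
      fCsweeps <- if (occ$nSweepsWithoutTarget >= 1)
        captureFrequencySweeps(nrow(df), occ$nSweepsWithoutTarget,
                               tSweepS = occ$measuringTimeS / occ$nSweeps)
      else NA_real_
    } else {
      dur <- length(samples(trace)) / samplingRate(trace)
      fC <- captureFrequencyGapfree(nrow(df), dur, sum(df$dwell_s))
      fCsweeps <- NA_real_
    }
    est <- .dwellEstimate(df$dwell_s[!df$truncated])
    kin <- list(fC_per_s = fC, fC_sweepcount_per_s = fCsweeps,
                tau_off_s = est$tau,
                k_off_per_s = if (is.finite(est$tau) && est$tau > 0)
                  1 / est$tau else NA_real_,
                n_events = nrow(df), n_uncensored = est$n,
                dwell_method = est$method)
    jsonlite::write_json(kin, file.path(out, "kinetics.json"),
                         auto_unbox = TRUE, digits = NA)
    results$kinetics <- kin
  }

  if ("selectivity" %in% config$analyses) {
    sel <- config$selectivity %||% list()
    crit <- if (!is.null(sel$criteria)) {
      list(iexMaxRange = sel$criteria$iex_max_range,
           deltaRange = sel$criteria$delta_range,
           minDurationS = sel$criteria$min_duration_s,
           minLevels = sel$criteria$min_levels)
    } else defaultFingerprintCriteria()
    metrics <- eventLevelMetrics(trace, events, iO)
    cls <- classifyFingerprints(metrics, crit)
    ann <- eventData(events)
    ann$label <- cls$label
    writeEvents(EventTable(ann), file.path(out, "events_annotated.tsv"))
    jsonlite::write_json(
      list(criteria = crit, n_target = sum(cls$label == "target"),
           n_background = sum(cls$label == "background")),
      file.path(out, "selectivity.json"), auto_unbox = TRUE, digits = NA)
    used$selectivity_criteria <- crit
    results$selectivity <- cls
  }

  jsonlite::write_json(used, file.path(out, "params.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  summaryLines <- c(
    sprintf("poreCage run (seed %d)", config$seed),
    sprintf("trace: %d samples at %g Hz", length(samples(trace)),
            samplingRate(trace)),
    sprintf("baseline I_O: %.3f pA", iO),
    sprintf("events detected: %d", nEvents(events)),
    if (!is.null(results$nLevels))
      sprintf("caging: %d levels, delta I_EX %.2f Delta-%%",
              results$nLevels, deltaIEX(results$caging)),
    if (!is.null(results$kinetics))
      sprintf("kinetics: fC %.4g /s, tau_off %.4g s",
              results$kinetics$fC_per_s, results$kinetics$tau_off_s),
    if (!is.null(results$selectivity))
      sprintf("selectivity: %d target / %d background",
              sum(results$selectivity$label == "target"),
              sum(results$selectivity$label == "background")))
  writeLines(summaryLines, file.path(out, "summary.txt"))
  invisible(results)
}
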