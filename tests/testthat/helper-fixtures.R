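# Shared fixtures: all synthetic inputs are built in code at test time.

# hand-built square-blockade trace on a constant baseline (no protocol)
squareTrace <- function(iO = 100, rate = 5000, totalS = 60,
                        starts = numeric(), dursS = numeric(),
                        depthPct = numeric(), noiseSD = 1, seed = 42) {
  set.seed(seed)
  n <- round(totalS * rate)
  x <- rep(iO, n)
  for (i in seq_along(starts)) {
    lo <- floor(starts[i] * rate) + 1L
    hi <- min(floor((starts[i] + dursS[i]) * rate), n)
    x[lo:hi] <- iO * (1 - depthPct[i] / 100)
  }
  Trace(x + rnorm(n, 0, noiseSD), samplingRate = rate)
}

# non-caged streptavidin-like species at the buffer-condition statistics
saSpecies <- function(concentrationNM = 20, kOn = 8.77,
                      dwellMeanS = 0.0657, depthPct = 45.4,
                      depthJitterSD = 0.9) {
  SpeciesSpec("SA", concentrationNM = concentrationNM, kOn = kOn,
              dwellMeanS = dwellMeanS, depthPct = depthPct,
              depthJitterSD = depthJitterSD)
}

# caged occupancy model in the long-linker (70 aa) regime:
# extremes 48.0 / 32.6 % excluded current
cagedModel <- function(nSites = 4, nTags = 10, kBind = 0.12, kUnbind = 1,
                       competitorFactor = 1, kEscape = 0.01,
                       depthMaxPct = 48.0, depthMinPct = 32.6) {
  OccupancyModel(nSites = nSites, nTags = nTags, kBind = kBind,
                 kUnbind = kUnbind, competitorFactor = competitorFactor,
                 kEscape = kEscape, depthMaxPct = depthMaxPct,
                 depthMinPct = depthMinPct)
}

# a single long caged blockade rendered gap-free at the measuring voltage
cagedSim <- function(seed = 5, totalS = 65, nSites = 4, samplingRate = 5000,
                     conductanceNS = 2.29, noiseSD = 2, ...) {
  cfg <- SimulationConfig(
    seed = seed, samplingRate = samplingRate,
    protocol = gapFreeProtocol(-75, totalS),
    conductanceNS = conductanceNS, noiseSD = noiseSD,
    species = list(SpeciesSpec("SAc", concentrationNM = 2000, kOn = 50,
                               occupancy = cagedModel(nSites = nSites, ...))))
  simulateTrace(cfg)
}

# preprocess exactly as the pipeline would
prepTrace <- function(trace, cutoffHz = 500) {
  gaussianLowpass(normalizePolarity(trace), cutoffHz)
}

# detected-vs-truth matching by interval overlap; returns per-truth-event
# hit flags and the count of detected events with no truth overlap
matchEvents <- function(truth, detected, tol = 0) {
  td <- eventData(truth)
  dd <- eventData(detected)
  t0 <- td$start_s - tol
  t1 <- td$start_s + td$dwell_s + tol
  d0 <- dd$start_s
  d1 <- dd$start_s + dd$dwell_s
  hit <- vapply(seq_len(nrow(td)), function(i)
    any(d1 > t0[i] & d0 < t1[i]), logical(1))
  spurious <- vapply(seq_len(nrow(dd)), function(j)
    !any(t1 > d0[j] & t0 < d1[j]), logical(1))
  list(hit = hit, nSpurious = sum(spurious))
}
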