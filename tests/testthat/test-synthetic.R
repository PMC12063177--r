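test_that("zero species yields baseline plus noise only", {
  cfg <- SimulationConfig(seed = 2, samplingRate = 2000,
                          protocol = gapFreeProtocol(-75, 10),
                          conductanceNS = 2.29, noiseSD = 2)
  sim <- simulateTrace(cfg)
  expect_identical(nEvents(sim$events), 0L)
  x <- samples(sim$trace)
  expect_equal(length(x), 20000L)
  expect_lt(abs(mean(x) - 2.29 * -75), 0.2)
  expect_equal(sd(x), 2, tolerance = 0.1)
})

test_that("capture counts follow the configured Poisson rate", {
  ## lambda = 0.2/s for 600 s gap-free -> ~120 events, within 3*sqrt(120);
  ## dwells kept short so occupancy thinning is negligible
  cfg <- SimulationConfig(seed = 8, samplingRate = 1000,
                          protocol = gapFreeProtocol(-75, 600),
                          conductanceNS = 2.29, noiseSD = 2,
                          species = list(SpeciesSpec(
                            "X", concentrationNM = 20, kOn = 10,
                            dwellMeanS = 0.01, depthPct = 45)))
  sim <- simulateTrace(cfg)
  expect_lt(abs(nEvents(sim$events) - 120), 3 * sqrt(120))
})

test_that("gate attenuation scales the realized capture rate", {
  mk <- function(att, seed) {
    cfg <- SimulationConfig(seed = seed, samplingRate = 1000,
                            protocol = gapFreeProtocol(-75, 500),
                            conductanceNS = 2.29, noiseSD = 2,
                            species = list(SpeciesSpec(
                              "X", 20, 10, dwellMeanS = 0.005,
                              depthPct = 45)),
                            gateAttenuation = c(X = att))
    nEvents(simulateTrace(cfg)$events)
  }
  nFull <- mk(1, 21)       # lambda = 0.2
  nGated <- mk(0.25, 22)   # lambda = 0.05
  ## each count within 3 SE of its own expectation
  expect_lt(abs(nFull - 100), 3 * sqrt(100))
  expect_lt(abs(nGated - 25), 3 * sqrt(25))
})

test_that("ground-truth dwells are exponential (KS at alpha 0.01)", {
  cfg <- SimulationConfig(seed = 9, samplingRate = 1000,
                          protocol = gapFreeProtocol(-75, 2500),
                          conductanceNS = 2.29, noiseSD = 2,
                          species = list(SpeciesSpec(
                            "X", 100, 50, dwellMeanS = 0.01,
                            depthPct = 50)))
  sim <- simulateTrace(cfg)
  d <- eventData(sim$events)
  d <- d$dwell_s[!d$truncated]
  expect_gt(length(d), 1e4)
  p <- suppressWarnings(ks.test(d, "pexp", rate = 1 / 0.01))$p.value
  expect_gt(p, 0.01)
})

test_that("degenerate occupancy chains behave as closed forms predict", {
  ## kBind = 0: the blockade never leaves the unbound (deepest) level
  sim <- cagedSim(seed = 5, totalS = 20, kBind = 0, kEscape = 0.001)
  expect_identical(nEvents(sim$events), 1L)
  expect_identical(eventData(sim$events)$n_levels_visited, 1L)
  expect_equal(eventData(sim$events)$depth_max_pct, 48.0)
  ## stationary closed forms
  m0 <- cagedModel(kBind = 0)
  expect_equal(unname(stationaryOccupancy(m0)), c(1, 0, 0, 0, 0))
  ## monovalent: Bernoulli with odds kBind*nTags : kUnbind
  m1 <- cagedModel(nSites = 1, kBind = 0.3, kUnbind = 2)
  pi1 <- stationaryOccupancy(m1)
  odds <- 0.3 * 10 / 2
  expect_equal(unname(pi1), c(1, odds) / (1 + odds), tolerance = 1e-12)
  ## absorbing at full occupancy when unbinding is off
  mAbs <- cagedModel(kBind = 0.5, kUnbind = 0)
  expect_equal(unname(stationaryOccupancy(mAbs)), c(0, 0, 0, 0, 1))
})

test_that("stationary distribution matches long-run chain occupancy within 1%", {
  model <- cagedModel(kBind = 1, kUnbind = 1, kEscape = 0)
  set.seed(123)
  path <- poreCage:::.simulateOccupancyPath(model, 0, 2e4)
  durs <- diff(c(path$times, path$endTime))
  expect_gt(length(path$states), 1e5)
  emp <- vapply(0:4, function(m) sum(durs[path$states == m]), numeric(1))
  emp <- emp / sum(emp)
  expect_lt(max(abs(emp - stationaryOccupancy(model))), 0.01)
})

test_that("competitor saturation empties the bound states", {
  ## competitorFactor >> 1: occupancy concentrates at m = 0 and events
  ## terminate by escape
  mComp <- cagedModel(kBind = 0.5, kUnbind = 1, competitorFactor = 1e6,
                      kEscape = 2)
  pi <- stationaryOccupancy(mComp)
  expect_gt(pi[["0"]], 0.999)
  sim <- cagedSim(seed = 31, totalS = 30, kBind = 0.5,
                  competitorFactor = 1e6, kEscape = 2)
  df <- eventData(sim$events)
  expect_gt(nrow(df), 3)
  expect_lt(mean(df$truncated), 0.5)
  expect_equal(median(df$depth_max_pct), 48, tolerance = 1e-6)
})

test_that("occupancy ladder exposes nSites + 1 ideal levels", {
  for (ns in c(1L, 4L)) {
    m <- cagedModel(nSites = ns)
    expect_identical(length(m@levelDepths), ns + 1L)
    expect_identical(length(unique(m@levelDepths)), ns + 1L)
    expect_true(all(diff(m@levelDepths) < 0))
  }
  expect_error(OccupancyModel(nSites = 4, levelDepths = c(40, 45, 30, 20, 10)),
               "non-increasing|maximum")
})

test_that("contour length follows the 3.8 Angstrom per-residue convention", {
  expect_equal(contourLength(8), 3.04)
  expect_equal(contourLength(0), 0)
  expect_equal(contourLength(70), 26.6)
  expect_equal(contourLength(10, perResidueA = 4), 4)
  expect_error(contourLength(-1), ">= 0")
})

test_that("simulation is reproducible from its seed", {
  cfg <- SimulationConfig(seed = 77, samplingRate = 1000,
                          protocol = sweepProtocol(30),
                          conductanceNS = 1.94, noiseSD = 2,
                          species = list(saSpecies(concentrationNM = 100)))
  a <- simulateTrace(cfg)
  b <- simulateTrace(cfg)
  expect_identical(samples(a$trace), samples(b$trace))
  expect_identical(eventData(a$events), eventData(b$events))
})
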