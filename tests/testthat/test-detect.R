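test_that("baseline estimation finds the open-pore mode", {
  set.seed(14)
  ## pure Gaussian: sample-mean oracle within 0.1 pA
  x <- rnorm(1e5, 80, 2)
  bl <- estimateBaseline(Trace(x, 5e4))
  expect_lt(abs(bl$iO - mean(x)), 0.1)
  expect_equal(bl$sd, 2, tolerance = 0.2)
  expect_false(bl$degenerate)

  ## bimodal 50/50: the highest-current mode wins, not the global mean
  y <- c(rnorm(5e4, 40, 2), rnorm(5e4, 80, 2))
  bl2 <- estimateBaseline(Trace(y, 5e4))
  expect_lt(abs(bl2$iO - 80), 0.2)

  ## constant trace is flagged degenerate
  bl3 <- estimateBaseline(Trace(rep(55, 1000), 5e4))
  expect_true(bl3$degenerate)
  expect_equal(bl3$iO, 55)
})

test_that("square blockades are detected with correct dwell and depth", {
  tr <- squareTrace(iO = 100, rate = 5000, totalS = 60,
                    starts = c(10, 25, 40), dursS = rep(0.05, 3),
                    depthPct = rep(45, 3), noiseSD = 1, seed = 15)
  ev <- detectEvents(tr, estimateBaseline(tr))
  expect_identical(nEvents(ev), 3L)
  df <- eventData(ev)
  expect_equal(df$dwell_s, rep(0.05, 3), tolerance = 0.02)  # 50 +/- 1 ms
  expect_equal(df$I_EX_pct, rep(45, 3), tolerance = 0.05)
  expect_equal(df$start_s, c(10, 25, 40), tolerance = 1e-3)
  expect_equal(df$interevent_s[-1], c(14.95, 14.95), tolerance = 0.01)
})

test_that("blank traces and sub-threshold dwells give no events", {
  blank <- squareTrace(iO = 100, rate = 5000, totalS = 10, noiseSD = 1,
                       seed = 16)
  expect_identical(nEvents(detectEvents(blank, 100)), 0L)
  ## a blockade of half the minimum dwell is discarded
  st <- detectorSettings(minDwellS = 0.01)
  short <- squareTrace(iO = 100, rate = 5000, totalS = 10, starts = 5,
                       dursS = 0.005, depthPct = 45, noiseSD = 1, seed = 17)
  expect_identical(nEvents(detectEvents(short, 100, st)), 0L)
})

test_that("excluded current matches its defining ratio", {
  expect_equal(excludedCurrent(100, 54.6), 45.4)
  expect_equal(excludedCurrent(100, 100), 0)
  expect_equal(excludedCurrent(100, 0), 100)
  expect_equal(excludedCurrent(171.75, c(171.75, 0)), c(0, 100))
  expect_error(excludedCurrent(0, 1), "> 0")
})

test_that("I_EX is invariant under trace rescaling", {
  tr <- squareTrace(iO = 100, rate = 5000, totalS = 20,
                    starts = c(5, 12), dursS = c(0.1, 0.2),
                    depthPct = c(30, 60), noiseSD = 0.5, seed = 18)
  ev1 <- eventData(detectEvents(tr, 100))
  sc <- Trace(samples(tr) * 3.7, samplingRate = samplingRate(tr))
  ev2 <- eventData(detectEvents(sc, 370))
  expect_identical(nrow(ev1), nrow(ev2))
  expect_equal(ev1$I_EX_pct, ev2$I_EX_pct, tolerance = 1e-9)
})

test_that("dwell, interevent and margins conserve the analyzed duration", {
  tr <- squareTrace(iO = 100, rate = 5000, totalS = 30,
                    starts = c(4, 11, 22), dursS = c(0.5, 1, 2),
                    depthPct = rep(50, 3), noiseSD = 1, seed = 19)
  df <- eventData(detectEvents(tr, 100))
  total <- sum(df$dwell_s) + sum(df$interevent_s, na.rm = TRUE) +
    df$start_s[1] + (30 - (df$start_s[3] + df$dwell_s[3]))
  expect_equal(total, 30, tolerance = 1e-9)
})

test_that("detector recovers nearly all resolvable simulated events", {
  ## amplitude >= 5 noise sd, dwell >= 10 samples post-filter
  cfg <- SimulationConfig(seed = 20, samplingRate = 5000,
                          protocol = gapFreeProtocol(-75, 120),
                          conductanceNS = 2.29, noiseSD = 5,
                          species = list(saSpecies(concentrationNM = 50)))
  sim <- simulateTrace(cfg)
  tr <- prepTrace(sim$trace, 2000)
  ev <- detectEvents(tr, estimateBaseline(tr))
  truth <- sim$events
  resolvable <- eventData(truth)$dwell_s >= 10 / 5000
  m <- matchEvents(truth, ev, tol = 2 / 5000)
  expect_gte(mean(m$hit[resolvable]), 0.99)
  expect_lte(m$nSpurious, ceiling(0.01 * sum(resolvable)))
})

test_that("caged blockades are merged across sweep boundaries", {
  occ <- cagedModel(kBind = 0, kEscape = 0.1)
  cfg <- SimulationConfig(seed = 23, samplingRate = 5000,
                          protocol = sweepProtocol(120),
                          conductanceNS = 1.94, noiseSD = 2,
                          species = list(SpeciesSpec("SA", 50, 8.77,
                                                     occupancy = occ)))
  sim <- simulateTrace(cfg)
  tr <- prepTrace(sim$trace)
  ev <- detectEvents(tr, estimateBaseline(tr))
  df <- eventData(ev)
  td <- eventData(sim$events)
  long <- td$dwell_s > 5          # spans > 2 sweeps
  expect_gt(sum(long), 0)
  ## every long truth event has a matching merged detection spanning sweeps
  m <- matchEvents(sim$events, ev)
  expect_true(all(m$hit[long]))
  expect_gt(max(df$n_sweeps_spanned), 2)
  ## without merging the same trace yields more, shorter events
  evNo <- detectEvents(tr, estimateBaseline(tr), mergeAcrossSweeps = FALSE)
  expect_gt(nEvents(evNo), nEvents(ev))
})

test_that("pore classification follows nearest conductance class", {
  expect_identical(classifyPore(80.15)$class, "2.3*")
  expect_equal(classifyPore(80.15)$conductance_nS, 2.29, tolerance = 1e-9)
  expect_identical(classifyPore(67.9)$class, "1.9*")
  expect_identical(classifyPore(35)$class, "other")
  expect_identical(classifyPore(c(67.9, 92.05, 35))$class,
                   c("1.9*", "2.6*", "other"))
})

test_that("two-parameter gate selects the calibrated population", {
  gate <- list(iexMean = 45.4, iexSD = 0.9, logDwellMean = log(0.0657),
               logDwellSD = 0.6)
  mk <- function(iex, dwell) EventTable(data.frame(
    start_s = 10 * seq_along(iex), dwell_s = dwell, I_B_pA = 100 - iex,
    I_EX_pct = iex))
  ## event exactly at the gate center is selected
  expect_identical(nEvents(gateEvents(mk(45.4, 0.0657), gate)), 1L)
  ## 3 sigma outlier in I_EX is rejected
  expect_identical(nEvents(gateEvents(mk(45.4 + 3 * 0.9, 0.0657), gate)), 0L)
  ## Monte-Carlo acceptance under independent Gaussians: 0.954^2
  set.seed(24)
  n <- 1e4
  ev <- mk(rnorm(n, 45.4, 0.9), exp(rnorm(n, log(0.0657), 0.6)))
  frac <- nEvents(gateEvents(ev, gate)) / n
  expect_equal(frac, 0.954^2, tolerance = 0.01)
  expect_error(gateEvents(ev, list(iexMean = 1, iexSD = 0,
                                   logDwellMean = 0, logDwellSD = 1)),
               "> 0")
})

test_that("detector settings are validated", {
  expect_error(detectorSettings(openFraction = 0.95, closeFraction = 0.9),
               "openFraction")
  expect_error(detectorSettings(openFraction = 0), "openFraction")
  tr <- squareTrace(totalS = 1, noiseSD = 1)
  degen <- structure(list(iO = 100, sd = 0, binPA = 0.5, degenerate = TRUE),
                     class = "BaselineEstimate")
  expect_error(detectEvents(tr, degen), "degenerate")
})
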