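test_that("mixture peaks recover per-species abundances within 10%", {
  set.seed(70)
  n <- c(400, 300, 350)
  iex <- c(rnorm(n[1], 35, 2), rnorm(n[2], 55, 2), rnorm(n[3], 75.9, 2))
  df <- data.frame(start_s = 0.1 * seq_along(iex), dwell_s = 0.01,
                   I_B_pA = 100 - iex, I_EX_pct = iex)
  mp <- fitMixturePeaks(EventTable(df), expectedMeans = c(35, 55, 75.9))
  expect_identical(nrow(mp), 3L)
  expect_lt(max(abs(mp$mean_iex_pct - c(35, 55, 75.9))), 0.5)
  expect_true(all(abs(mp$auc_events - n) / n < 0.10))
  ## AUC conservation within fit tolerance
  expect_lte(sum(mp$auc_events), sum(n) * 1.1)
})

test_that("single-species histograms integrate to the event count", {
  set.seed(71)
  iex <- rnorm(500, 45.4, 1.5)
  df <- data.frame(start_s = seq_along(iex), dwell_s = 0.05,
                   I_B_pA = 100 - iex, I_EX_pct = iex)
  mp <- fitMixturePeaks(EventTable(df), nComponents = 1)
  expect_equal(mp$auc_events, 500, tolerance = 0.05)
  expect_error(fitMixturePeaks(EventTable(), nComponents = 1), "empty")
  expect_error(fitMixturePeaks(EventTable(df[1:10, ]), nComponents = 1),
               "too few")
})

test_that("fold reduction and background fraction follow their ratios", {
  expect_equal(foldReduction(1400, 100), 14)
  expect_equal(foldReduction(100, 100), 1)
  expect_warning(fr <- foldReduction(100, 0), "lower bound")
  expect_identical(fr, Inf)
  ## symmetric under common rescaling of both recordings
  expect_equal(foldReduction(1400 * 0.5, 100 * 0.5), 14)

  expect_equal(backgroundFraction(0.06, 0.27), 0.2222, tolerance = 1e-3)
  expect_equal(backgroundFraction(0, 0.27), 0)
  expect_equal(backgroundFraction(0.27, 0.27), 1)
  expect_error(backgroundFraction(0.3, 0.27), "fBackground")
  expect_error(backgroundFraction(0.1, 0), "fTotal")
  set.seed(72)
  for (i in 1:20) {
    f <- sort(runif(2))
    expect_gte(backgroundFraction(f[1], f[2]), 0)
    expect_lte(backgroundFraction(f[1], f[2]), 1)
  }
})

test_that("entropic-gate attenuation is recovered as a fold reduction", {
  ## same large species measured with and without a 1/14 gate over 519 s
  mk <- function(att, seed) {
    cfg <- SimulationConfig(seed = seed, samplingRate = 2000,
                            protocol = gapFreeProtocol(-75, 519),
                            conductanceNS = 2.29, noiseSD = 2,
                            species = list(SpeciesSpec(
                              "CRP", 20, 60, dwellMeanS = 0.05,
                              depthPct = 65, depthJitterSD = 2)),
                            gateAttenuation = c(CRP = att))
    sim <- simulateTrace(cfg)
    tr <- prepTrace(sim$trace, 500)
    ev <- detectEvents(tr, estimateBaseline(tr))
    mp <- fitMixturePeaks(ev, expectedMeans = 65, minEvents = 10)
    mp$auc_events[1]
  }
  ref <- mk(1, 80)
  gated <- mk(1 / 14, 81)
  expect_equal(foldReduction(ref, gated), 14, tolerance = 0.25)
})

test_that("fingerprint classifier applies all criteria jointly", {
  crit <- defaultFingerprintCriteria()
  m <- data.frame(
    start_s = 1:4, duration_s = c(30, 0.1, 30, 30),
    iex_max_pct = c(48, 75.9, 48, 48),
    delta_iex_pct = c(15.4, 0, 15.4, 2),
    n_levels = c(5L, 1L, 1L, 4L))
  cls <- classifyFingerprints(m, crit)
  ## caged 5-level event -> target; short square -> background;
  ## right depth but single level -> background; band too narrow -> background
  expect_identical(cls$label, c("target", "background", "background",
                                "background"))
  expect_error(classifyFingerprints(m, modifyList(crit, list(
    iexMaxRange = c(50, 41)))), "empty")
})

test_that("classifier separates a caged target from a blood-like background", {
  ## internal benchmark: 4 fast background species + caged target, sweeps
  occ <- cagedModel(kEscape = 0.5)
  runOne <- function(seed) {
    cfg <- SimulationConfig(
      seed = seed, samplingRate = 5000,
      protocol = sweepProtocol(480), conductanceNS = 1.94, noiseSD = 2,
      species = list(
        SpeciesSpec("BSA", 2000, 1.0, dwellMeanS = 0.02, depthPct = 35,
                    depthJitterSD = 2),
        SpeciesSpec("HTf", 300, 1.0, dwellMeanS = 0.05, depthPct = 55,
                    depthJitterSD = 2),
        SpeciesSpec("CRP", 100, 1.0, dwellMeanS = 0.2, depthPct = 65,
                    depthJitterSD = 2),
        SpeciesSpec("BT", 100, 2.0, dwellMeanS = 0.05, depthPct = 75.9,
                    depthJitterSD = 2),
        SpeciesSpec("SA", 25, 8.0, occupancy = occ)),
      gateAttenuation = c(BSA = 0.3, HTf = 1 / 14, CRP = 1 / 14,
                          BT = 1 / 4))
    sim <- simulateTrace(cfg)
    tr <- prepTrace(sim$trace, 500)
    bl <- estimateBaseline(tr)
    ev <- detectEvents(tr, bl)
    cls <- classifyFingerprints(eventLevelMetrics(tr, ev, bl$iO))
    dd <- eventData(ev)
    td <- eventData(sim$events)
    sa <- td[td$species == "SA" & td$dwell_s >= 10, ]
    others <- td[td$species != "SA", ]
    hitSA <- vapply(seq_len(nrow(sa)), function(i) {
      j <- which(dd$start_s < sa$start_s[i] + sa$dwell_s[i] &
                   dd$start_s + dd$dwell_s > sa$start_s[i])
      length(j) > 0 && any(cls$label[j] == "target")
    }, logical(1))
    isBg <- vapply(seq_len(nrow(dd)), function(j) {
      !any(sa$start_s < dd$start_s[j] + dd$dwell_s[j] &
             sa$start_s + sa$dwell_s > dd$start_s[j])
    }, logical(1))
    c(saFound = sum(hitSA), saTotal = nrow(sa),
      bgCalledTarget = sum(cls$label[isBg] == "target"),
      bgTotal = sum(isBg))
  }
  tot <- runOne(90) + runOne(91)
  expect_gte(tot[["saFound"]] / tot[["saTotal"]], 0.90)      # sensitivity
  expect_gte(1 - tot[["bgCalledTarget"]] / max(tot[["bgTotal"]], 1),
             0.95)                                           # specificity
})
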