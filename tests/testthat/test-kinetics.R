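test_that("cumulative exponential fit recovers the dwell constant", {
  set.seed(50)
  d <- rexp(1e4, 1 / 0.0657)
  fit <- fitExponentialCumulative(d)
  expect_equal(fit$tau, 0.0657, tolerance = 0.002 / 0.0657)  # +/- 2 ms
  expect_lt(fit$se, 0.002)
  ## agreement with the maximum-likelihood mean within 3%
  set.seed(51)
  d2 <- rexp(1e4, 1 / 0.1)
  fit2 <- fitExponentialCumulative(d2)
  mle <- mean(d2[d2 <= 0.5])          # same support as the fit window
  expect_equal(fit2$tau, mean(d2), tolerance = 0.03)
  expect_equal(fit2$tau, mle, tolerance = 0.05)
})

test_that("cumulative fit enforces its preconditions", {
  expect_error(fitExponentialCumulative(rexp(100, 10)), "insufficient")
  expect_error(fitExponentialCumulative(rep(0.1, 200)), "degenerate")
  expect_error(fitExponentialCumulative(rexp(200, 10), edges = c(0, 0.5),
                                        minN = 500), "insufficient")
})

test_that("cumulative fit is consistent as n grows", {
  bias <- vapply(c(150, 1e3, 1e4), function(n) {
    set.seed(n)
    mean(vapply(1:5, function(r) {
      fitExponentialCumulative(rexp(n, 1 / 0.05))$tau
    }, numeric(1))) - 0.05
  }, numeric(1))
  expect_lt(abs(bias[3]), abs(bias[1]) + 0.001)
  expect_lt(abs(bias[3] / 0.05), 0.01)
})

test_that("log-mean dwell is the geometric mean and respects AM-GM", {
  expect_equal(logMeanDwell(c(0.001, 0.01, 0.1)), 0.01)
  expect_equal(logMeanDwell(0.37), 0.37)
  expect_equal(logMeanDwell(c(2, 8)), 4)
  expect_error(logMeanDwell(c(1, 0)), "> 0")
  expect_error(logMeanDwell(numeric()), "at least one")
  set.seed(52)
  for (i in 1:20) {
    d <- rexp(50, 5)
    expect_lte(logMeanDwell(d), mean(d))
  }
  expect_equal(logMeanDwell(rep(0.2, 10)), mean(rep(0.2, 10)))
})

test_that("capture-frequency estimators implement their normalizations", {
  expect_equal(captureFrequencyGapfree(30, 600, 100), 0.06)
  expect_equal(captureFrequencyGapfree(0, 600, 100), 0)
  expect_equal(captureFrequencyGapfree(12, 600), 0.02)
  expect_error(captureFrequencyGapfree(10, 100, 100), "denominator")
  expect_equal(captureFrequencySweeps(6, 240), 0.0125)
  expect_equal(captureFrequencySweeps(0, 240), 0)
  ## invariant to sweep relabelling: depends only on counts
  expect_equal(captureFrequencySweeps(7, 100), captureFrequencySweeps(7, 100))
  expect_error(captureFrequencySweeps(1, 0), "sweep")
})

test_that("sweep occupancy bookkeeping counts occupied sweeps and time", {
  pr <- sweepProtocol(totalS = 22)      # 10 sweeps of 2.2 s
  ## one event inside sweep 2's measuring window, one spanning sweeps 5-6
  df <- data.frame(start_s = c(2.5, 9.5), dwell_s = c(0.5, 2.0),
                   I_B_pA = 50, I_EX_pct = 50)
  occ <- sweepOccupancy(EventTable(df), pr)
  expect_identical(occ$nSweeps, 10L)
  expect_identical(which(occ$occupied), c(2L, 5L, 6L))
  expect_identical(occ$nSweepsWithoutTarget, 7L)
  expect_equal(occ$measuringTimeS, 20)
  ## 0.5 s in sweep 2; 9.5-11.0 in sweep 5; 11.2-11.5 in sweep 6
  expect_equal(occ$occupiedMeasuringTimeS, 0.5 + 1.5 + 0.3,
               tolerance = 1e-9)
})

test_that("on-rate regression through the origin recovers the slope", {
  s <- data.frame(conc_nM = c(1, 5, 10, 25),
                  fC_per_s = 8.77 * c(1, 5, 10, 25) / 1000)
  ## noiseless line: lm warns that the fit is exact, which is the point
  expect_equal(suppressWarnings(fitKon(s)$kOn), 8.77, tolerance = 1e-9)
  sz <- data.frame(conc_nM = c(1, 5), fC_per_s = c(0, 0))
  expect_equal(suppressWarnings(fitKon(sz)$kOn), 0)
  expect_error(fitKon(s[1, , drop = FALSE]), "two concentrations")
  expect_error(fitKon(data.frame(conc_nM = c(1, 1), fC_per_s = c(1, 2))),
               "distinct")
  ## noisy line: slope within 2 se of truth
  set.seed(53)
  conc <- rep(c(1, 5, 10, 25), each = 3)
  fc <- 8.77 * conc / 1000 * (1 + rnorm(12, 0, 0.1))
  fit <- fitKon(data.frame(conc_nM = conc + rep(c(0, 1e-9, 2e-9), 4),
                           fC_per_s = fc))
  expect_lt(abs(fit$kOn - 8.77), 2 * fit$se + 1e-9)
})

test_that("off-rate is the weighted mean release frequency", {
  expect_equal(fitKoff(data.frame(fR_per_s = c(0.19, 0.20, 0.21)))$kOff, 0.20)
  expect_equal(fitKoff(data.frame(fR_per_s = 0.2))$kOff, 0.2)
  expect_equal(fitKoff(data.frame(dwell_s = c(5, 5, 5)))$kOff, 0.2)
  expect_error(fitKoff(data.frame(conc_nM = 1)), "dwell")
})

test_that("binding constant composes the rates with unit conversion", {
  expect_equal(bindingConstant(0.20, 8.77), 22.8, tolerance = 0.01)
  expect_equal(bindingConstant(0, 8.77), 0)
  ## units: K_D in uM times 1000 is K_D in nM
  expect_equal(bindingConstant(0.5, 2), 0.5 / 2 * 1000)
  expect_error(bindingConstant(0.2, 0), "kOn")
})

test_that("titration analysis assembles a consistent kinetics result", {
  ## event-level construction: two concentrations, gap-free protocols
  mkRun <- function(conc, n, tau, dur = 600, seed = 1) {
    set.seed(seed)
    starts <- sort(runif(n, 0, dur - 1))
    dw <- rexp(n, 1 / tau)
    ## enforce non-overlap crudely by spacing
    starts <- cumsum(c(starts[1], pmax(diff(starts), max(dw) + 0.01)))
    df <- data.frame(start_s = starts, dwell_s = dw, I_B_pA = 50,
                     I_EX_pct = 50)
    list(conc_nM = conc, events = EventTable(df),
         protocol = gapFreeProtocol(-75, max(starts + dw) + 10))
  }
  runs <- list(mkRun(10, 200, 0.1, seed = 61), mkRun(20, 400, 0.1, seed = 62))
  kin <- analyzeTitration(runs)
  expect_s4_class(kin$result, "KineticsResult")
  expect_identical(nrow(kin$series), 2L)
  expect_equal(kin$result@kOff, 10, tolerance = 0.15)
  expect_equal(kin$result@kDnM, 1000 * kin$result@kOff / kin$result@kOn,
               tolerance = 1e-9)
  expect_true(all(kin$series$dwell_method == "cumulative-fit"))
})
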