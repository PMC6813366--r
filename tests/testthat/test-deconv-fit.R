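test_that("deconvolution fixes constants and kills its eigen-decay", {
  # constant trace: zero derivative, output equals the input
  expect_equal(deconvolve(rep(2.5, 100), tauMemMs = 20, dtMs = 0.1),
               rep(2.5, 100))
  # exp(-t/tau_mem) is in the null space of (tau d/dt + 1)
  t <- seq(0, 100, by = 0.1)
  out <- deconvolve(exp(-t / 20), tauMemMs = 20, dtMs = 0.1)
  expect_lt(max(abs(out[2:(length(out) - 1)])), 1e-4)
})

test_that("deconvolution inverts the RC filtering on the grid", {
  # synthesize a noiseless sweep, deconvolve, and check the result is the
  # scaled synaptic conductance (round-trip identity of the linear membrane)
  mem <- membraneModel()
  prot <- stimulusProtocol(nPulses = 1L)
  dt <- 0.05
  ev <- methods::new("ReleaseEventSeries", spikeTimesMs = pulseTimes(prot)[1],
                     released = matrix(1L, 1L, 1L), conductanceNs = 1,
                     nRrp = 1L, gMax = 1)
  ss <- synthesizeSweep(mem, ev, prot, noiseParams(0), dtMs = dt)
  v <- drop(sweepVoltages(ss)) - mem@vRestMv
  dec <- deconvolve(v, mem@tauMemMs, dt)
  K <- mem@rInputMOhm * (mem@eRevMv - mem@vRestMv) * 1e-3
  g <- K * exp(-(sweepTimes(ss) - pulseTimes(prot)[1]) / mem@tauSynMs)
  g[sweepTimes(ss) < pulseTimes(prot)[1]] <- 0
  # compare away from the conductance jump (discrete derivative is O(dt)
  # inaccurate at the discontinuity)
  sel <- sweepTimes(ss) > pulseTimes(prot)[1] + 1 &
    sweepTimes(ss) < pulseTimes(prot)[1] + 40
  expect_lt(max(abs(dec[sel] - g[sel])) / max(g), 0.05)
})

test_that("membrane time constant is recovered from the recovery decay", {
  # exact single exponential appended after the recovery peak
  prot <- stimulusProtocol()
  t <- seq(0, sweepDurationMs(prot) - 0.1, by = 0.1)
  tRec <- max(pulseTimes(prot))
  v <- -65 + ifelse(t >= tRec + 2, exp(-(t - tRec - 2) / 20), 0)
  fit <- fitTauMem(sweepSet(t, cbind(v), prot))
  expect_false(fit$flag)
  expect_equal(fit$tauMemMs, 20, tolerance = 1e-6)

  # noiseless synthesized connections round-trip tau_mem within 5%
  for (tau in c(28, 15)) {
    spec <- quick_spec(nConnections = 1L, nSweeps = 6L, sigmaMv = 0)
    spec@membrane@tauMemMs <- tau
    ss <- simulateConnection(spec, seed = 3)
    fit <- fitTauMem(ss)
    expect_equal(fit$tauMemMs, tau, tolerance = 0.05)
  }

  # non-decaying input is flagged, not fitted
  vUp <- -65 + ifelse(t >= tRec, (t - tRec) * 0.01, 0)
  expect_true(fitTauMem(sweepSet(t, cbind(vUp), prot))$flag)
})

test_that("peaks extracted from deconvolved traces track the quantal drive", {
  prot <- stimulusProtocol()
  mem <- membraneModel()
  q <- c(6, 5, 4, 3, 2, 2, 1, 1, 5)
  ev <- methods::new("ReleaseEventSeries", spikeTimesMs = pulseTimes(prot),
                     released = matrix(as.integer(q), 1L), conductanceNs = q,
                     nRrp = 14L, gMax = 14)
  ss <- synthesizeSweep(mem, ev, prot, noiseParams(0))
  base <- sweepSet(sweepTimes(ss),
                   sweepVoltages(ss) - mem@vRestMv, prot)
  peaks <- extractPeaks(deconvolve(base, mem@tauMemMs))
  expect_equal(as.numeric(peaks) / peaks[1], q / q[1], tolerance = 0.01)

  # flat trace: all peaks ~ 0
  flat <- sweepSet(sweepTimes(ss),
                   cbind(rep(0, length(sweepTimes(ss)))), prot)
  expect_equal(as.numeric(extractPeaks(flat)), rep(0, 9))

  # linearity: superposed trains give additive peaks
  ev2 <- methods::new("ReleaseEventSeries", spikeTimesMs = pulseTimes(prot),
                      released = matrix(rep(2L, 9), 1L),
                      conductanceNs = rep(2, 9), nRrp = 14L, gMax = 14)
  ss2 <- synthesizeSweep(mem, ev2, prot, noiseParams(0))
  both <- sweepSet(sweepTimes(ss),
                   (sweepVoltages(ss) - mem@vRestMv) +
                     (sweepVoltages(ss2) - mem@vRestMv), prot)
  p2 <- extractPeaks(deconvolve(sweepSet(
    sweepTimes(ss2), sweepVoltages(ss2) - mem@vRestMv, prot), mem@tauMemMs))
  pBoth <- extractPeaks(deconvolve(both, mem@tauMemMs))
  expect_equal(pBoth, peaks + p2, tolerance = 1e-6)
})

test_that("the GA recovers U from noiseless peaks and respects its ranges", {
  p <- tmParams(U = 0.38, D = 365.6, F = 25.71)
  prot <- stimulusProtocol()
  peaks <- tmDeterministicTrain(p, pulseTimes(prot))
  cfg <- gaConfig(generations = 300L, restarts = 6L)
  fit <- fitTmGA(peaks, cfg, prot, seed = 5)
  expect_lt(fit$mse, 1e-4)
  expect_lt(abs(fit$U - 0.38), 0.05)
  rngs <- cfg@ranges
  expect_true(all(fit$perRestart[, "U"] >= rngs[1, 1] &
                    fit$perRestart[, "U"] <= rngs[2, 1]))
  expect_true(all(fit$perRestart[, "D"] >= rngs[1, 2] &
                    fit$perRestart[, "D"] <= rngs[2, 2]))
  expect_true(all(fit$perRestart[, "F"] >= rngs[1, 3] &
                    fit$perRestart[, "F"] <= rngs[2, 3]))
  # elitism: best-of-generation error never increases
  expect_true(all(diff(fit$bestTrace) <= 1e-15))
})

test_that("a constant peak train is fitted with near-zero error", {
  fit <- fitTmGA(rep(1, 9), gaConfig(generations = 200L, restarts = 4L),
                 seed = 6)
  expect_lt(fit$mse, 1e-3)
  expect_error(fitTmGA(c(rep(1, 8), NA)), "finite")
})

test_that("distribution selection identifies the generating family", {
  set.seed(8)
  u <- rnorm(500, 0.38, 0.1)
  selN <- fitParamDistributions(u, "U")
  expect_identical(selN$family, "norm")
  expect_equal(unname(selN$estimate["mean"]), 0.38, tolerance = 0.06)

  g <- rgamma(500, shape = 2, rate = 1 / 180)
  selG <- fitParamDistributions(g, "D")
  expect_identical(selG$family, "gamma")

  expect_error(fitParamDistributions(rnorm(5), "x"), "10 values")
  expect_error(fitParamDistributions(rep(1, 20), "x"), "degenerate")
})
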