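test_that("leave-one-out averages obey their algebraic identities", {
  ss <- kernel_sweeps(c(1, 2, 3))
  loo <- jkkMeanTraces(ss)
  # N = 3: trace i is the mean of the other two
  expect_equal(sweepVoltages(loo)[, 1],
               rowMeans(sweepVoltages(ss)[, 2:3]))
  # mean of leave-one-out means equals the grand mean exactly
  expect_equal(rowMeans(sweepVoltages(loo)), rowMeans(sweepVoltages(ss)))

  # N = 2: each mean is exactly the other sweep
  ss2 <- kernel_sweeps(c(1, 2))
  loo2 <- jkkMeanTraces(ss2)
  expect_equal(sweepVoltages(loo2)[, 1], sweepVoltages(ss2)[, 2])

  # identical sweeps: all leave-one-out means equal the sweep
  ss3 <- kernel_sweeps(c(2, 2, 2, 2))
  expect_equal(sweepVoltages(jkkMeanTraces(ss3)), sweepVoltages(ss3))

  expect_error(jkkMeanTraces(kernel_sweeps(1)), "2 sweeps")
})

test_that("jackknife CV reproduces the plain sample CV on scaled kernels", {
  # sweeps are the same kernel scaled by 1, 2, 3: leave-one-out amplitudes
  # 2.5, 2.0, 1.5 x kernel amplitude; std = sqrt(2 * 0.5), CV = 0.5
  ss <- kernel_sweeps(c(1, 2, 3))
  prof <- cvProfile(ss, useJackknife = TRUE)
  expect_equal(unname(cvValues(prof)), rep(0.5, 9), tolerance = 1e-10)
  plain <- cvProfile(ss, useJackknife = FALSE)
  expect_equal(cvValues(prof), cvValues(plain), tolerance = 1e-10)

  # property: exact agreement for arbitrary positive scalings
  set.seed(12)
  for (i in 1:5) {
    s <- kernel_sweeps(runif(8, 0.5, 3))
    expect_equal(cvValues(cvProfile(s, TRUE)), cvValues(cvProfile(s, FALSE)),
                 tolerance = 1e-9)
  }
})

test_that("identical sweeps give zero CV and rescaling leaves CV unchanged", {
  ss <- kernel_sweeps(rep(1.5, 5))
  expect_equal(unname(cvValues(cvProfile(ss))), rep(0, 9))

  s1 <- kernel_sweeps(c(0.8, 1.1, 1.7, 2.2))
  s2 <- sweepSet(sweepTimes(s1), 3.7 * sweepVoltages(s1), s1@protocol)
  expect_equal(cvValues(cvProfile(s1)), cvValues(cvProfile(s2)),
               tolerance = 1e-12)
})

test_that("amplitudes are pre-window minimum to post-window maximum", {
  prot <- stimulusProtocol()
  t <- seq(0, sweepDurationMs(prot) - 0.1, by = 0.1)
  v <- rep(0, length(t))
  pt <- pulseTimes(prot)
  v[which.min(abs(t - (pt[1] - 20)))] <- -0.2   # pre-window minimum
  v[which.min(abs(t - (pt[1] + 10)))] <- 1.0    # post-window maximum
  amp <- epspAmplitudes(sweepSet(t, cbind(v), prot))
  expect_equal(amp[1], 1.2)
  expect_equal(unname(epspAmplitudes(
    sweepSet(t, cbind(rep(0, length(t))), prot))), rep(0, 9))
})

test_that("amplitudes of a noiseless train match the per-pulse drive", {
  # deterministic quantal content per pulse -> amplitudes proportional
  prot <- stimulusProtocol()
  k <- epsp_kernel(prot)
  q <- c(5, 4, 3, 2, 2, 1, 1, 1, 4)
  ev <- methods::new("ReleaseEventSeries", spikeTimesMs = pulseTimes(prot),
                     released = matrix(as.integer(q), 1L), conductanceNs = q,
                     nRrp = 14L, gMax = 14)
  ss <- synthesizeSweep(membraneModel(), ev, prot, noiseParams(0))
  amp <- epspAmplitudes(ss)
  # first pulse as reference; later pulses ride on decay tails, so compare
  # the deconvolution-free amplitudes only coarsely at matched quanta
  expect_equal(amp[1] / q[1], amp[9] / q[9], tolerance = 0.02)
  expect_gt(amp[1], amp[6])
})

test_that("profile distance is the mean squared CV difference", {
  mk <- function(cv) methods::new("CVProfile", cv = cv,
                                  meanAmplitudeMv = rep(1, length(cv)),
                                  nSweeps = 5L, jackknife = TRUE)
  p <- mk(rep(0.1, 9))
  expect_identical(profileDistance(p, p), 0)
  expect_equal(profileDistance(p, mk(rep(0.1, 9) + 0.05)), 0.05^2)
  q <- mk(c(0.2, rep(0.1, 8)))
  expect_equal(profileDistance(p, q), 0.01 / 9)
  expect_error(profileDistance(p, mk(rep(0.1, 4))), "length")
})

test_that("power-law fit is exact on exact power-law input", {
  n <- 1:10
  fit <- fitPowerLaw(n, 2 * n^(-0.5))
  expect_equal(fit@amplitude, 2, tolerance = 1e-10)
  expect_equal(fit@index, -0.5, tolerance = 1e-10)
  expect_lt(fit@residual, 1e-20)
  expect_error(fitPowerLaw(1:5, c(1, 1, -1, 1, 1)), "positive")
  expect_error(fitPowerLaw(1:2, c(1, 2)), "levels")
})

test_that("the noiseless binomial closed form has index -1/2", {
  U <- 0.38; M <- 6
  n <- 1:14
  fit <- fitPowerLaw(n, sqrt((1 - U) / (M * n * U)))
  expect_equal(fit@index, -0.5, tolerance = 1e-12)
  expect_equal(fit@amplitude, sqrt((1 - U) / (M * U)), tolerance = 1e-10)
})

test_that("cohort-mean profiles average across connections", {
  cohort <- list(kernel_sweeps(c(1, 2, 3)), kernel_sweeps(c(2, 2, 2)))
  prof <- meanCVProfile(cohort)
  expect_equal(unname(cvValues(prof)), rep(0.25, 9), tolerance = 1e-9)
})
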