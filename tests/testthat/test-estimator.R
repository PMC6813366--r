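test_that("gMax calibration is linear in the target and self-consistent", {
  spec <- quick_spec(nConnections = 15L, nSweeps = 10L, sigmaMv = 0)
  gA <- calibrateGmax(spec, targetMv = 0.75, seed = 3)
  gB <- calibrateGmax(spec, targetMv = 1.5, seed = 3)
  # current-based drive: doubling the target doubles the conductance
  expect_equal(as.numeric(gB) / as.numeric(gA), 2, tolerance = 0.02)
  expect_equal(attr(gB, "achievedMv"), 1.5, tolerance = 0.02)

  # round trip with noise: a fresh cohort at the calibrated gMax hits the
  # target within Monte-Carlo error
  specN <- quick_spec(nConnections = 40L, nSweeps = 10L)
  g <- calibrateGmax(specN, targetMv = 1.46, seed = 4)
  specN@distributions@gMaxNs <- as.numeric(g)
  specN@seed <- 99L
  st <- RRPool:::.cohort_stats(specN)
  expect_equal(mean(st$meanAmp[1, ]), 1.46, tolerance = 0.15)
  expect_error(calibrateGmax(spec, targetMv = -1), "targetMv")
})

test_that("the amplitude exclusion filter retains what it should", {
  cohort <- generateCohort(quick_spec(nConnections = 4L, nSweeps = 4L,
                                      seed = 12L))
  all_in <- exclusionFilter(cohort, range = c(-1e6, 1e6))
  expect_length(all_in, 4L)
  expect_identical(attr(all_in, "nRemoved"), 0L)
  expect_warning(none <- exclusionFilter(cohort, range = c(-1e6, 0)),
                 "all connections removed")
  expect_length(none, 0L)
  expect_error(exclusionFilter(cohort, range = c(1, 1)), "interval")
})

test_that("first-EPSP matching flags references outside the simulated range", {
  spec <- quick_spec(nConnections = 8L, nSweeps = 8L)
  expect_warning(
    res <- estimateNrrpFirstEpsp(5, TRUE, spec, lambdaGrid = c(0, 1, 2),
                                 iterations = 2L, gMax = 3.2, seed = 31),
    "outside the simulated CV range")
  expect_true(res@boundary)
  # the CV decreases with the pool size, so a too-large reference pins the
  # scan at lambda = 0
  expect_identical(res@lambdaGrid[which.min(res@meanError)], 0)
  expect_length(res@meanError, 3L)
  expect_error(estimateNrrpFirstEpsp(-0.1, spec = spec), "positive scalar")
})

test_that("estimates are bit-reproducible under a fixed seed", {
  spec <- quick_spec(nConnections = 6L, nSweeps = 6L)
  a <- estimateNrrpFirstEpsp(0.4, TRUE, spec, lambdaGrid = c(0, 2, 4),
                             iterations = 2L, gMax = 3.2, seed = 55)
  b <- estimateNrrpFirstEpsp(0.4, TRUE, spec, lambdaGrid = c(0, 2, 4),
                             iterations = 2L, gMax = 3.2, seed = 55)
  expect_identical(a@meanError, b@meanError)
  expect_identical(a@recoveredPerIteration, b@recoveredPerIteration)
})

test_that("simulated first-pulse CV decreases with the pool size", {
  spec <- quick_spec(nConnections = 15L, nSweeps = 12L)
  df <- simulateCvByPoolSize(spec, lambdaGrid = c(0, 6), iterations = 2L,
                             gMax = 3.2, seed = 61)
  expect_gt(df$cvJkk[1], df$cvJkk[2])
  expect_gt(df$cvPlain[1], df$cvPlain[2])
  expect_equal(df$meanNrrp[2], 7, tolerance = 0.15)
})

test_that("the CV map machinery is affine and validated", {
  ident <- methods::new("LinearCVMap", slope = 1, intercept = 0, se = 0)
  expect_identical(applyCvMap(ident, 0.31), 0.31)
  m <- methods::new("LinearCVMap", slope = 1.3, intercept = 0.01, se = 0.01)
  expect_equal(applyCvMap(m, c(0.2, 0.4)), c(0.27, 0.53))
  expect_equal(referenceAmplitudeRange(), c(-0.26, 3.18))
  expect_error(buildCvToCvJkkMap(lambdaGrid = c(0, 1)), "3 lambda levels")
})

test_that("profile estimation reports a coherent error curve", {
  spec <- quick_spec(nConnections = 6L, nSweeps = 6L)
  ref <- methods::new("CVProfile", cv = rep(0.4, 9),
                      meanAmplitudeMv = rep(1.4, 9), nSweeps = 20L,
                      jackknife = TRUE)
  res <- estimateNrrpProfile(ref, spec, lambdaGrid = c(0, 2, 4),
                             iterations = 2L, gMax = 3.2, seed = 71)
  expect_length(res@meanError, 3L)
  expect_true(all(res@meanError >= 0))
  expect_identical(res@iterations, 2L)
  expect_length(res@recoveredPerIteration, 2L)
  expect_true(all(res@argminLambda %in% c(0, 2, 4)))
  ec <- errorCurve(res)
  expect_identical(ec$lambda, c(0, 2, 4))
  expect_error(estimateNrrpProfile(ref, spec, lambdaGrid = numeric()),
               "lambdaGrid")
})
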