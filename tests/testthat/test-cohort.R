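test_that("lambda = 0 gives a pool of exactly one vesicle everywhere", {
  conn <- sampleConnection(quick_spec(lambda = 0), seed = 1)
  expect_true(all(conn$nRrp == 1L))
})

test_that("shifted-Poisson pool sizes have mean 1 + lambda", {
  spec <- cohortSpec(lambda = 3, nConnections = 1L,
                     distributions = paramDistributions(contactRange = c(8L, 8L)))
  set.seed(5)
  pools <- unlist(replicate(2000, sampleConnection(spec)$nRrp,
                            simplify = FALSE))
  expect_equal(mean(pools), 4, tolerance = 0.02)
})

test_that("contact counts respect the configured range", {
  set.seed(3)
  counts <- replicate(200, length(sampleConnection(quick_spec())$nRrp))
  expect_true(all(counts >= 4 & counts <= 8))
  expect_gt(length(unique(counts)), 1)
})

test_that("sampled U values follow the truncated normal", {
  set.seed(17)
  spec <- quick_spec()
  u <- replicate(400, sampleConnection(spec)$params@U)
  expect_true(all(u >= 0 & u <= 1))
  ptrunc <- function(q) {
    (pnorm(q, 0.38, 0.1) - pnorm(0, 0.38, 0.1)) /
      (pnorm(1, 0.38, 0.1) - pnorm(0, 0.38, 0.1))
  }
  ks <- suppressWarnings(ks.test(u, ptrunc))
  expect_gt(ks$p.value, 0.01)
})

test_that("gamma draws for D and F have the requested moments", {
  set.seed(23)
  d <- RRPool:::.rgamma_ms(2e4, 365.6, 100.15)
  f <- RRPool:::.rgamma_ms(2e4, 25.71, 45.87)
  expect_equal(mean(d), 365.6, tolerance = 0.01)
  expect_equal(sd(d), 100.15, tolerance = 0.03)
  expect_equal(mean(f), 25.71, tolerance = 0.06)
  expect_true(all(d > 0) && all(f > 0))
})

test_that("cohorts are bit-reproducible under a fixed seed", {
  spec <- quick_spec(nConnections = 2L, nSweeps = 4L, seed = 77L)
  a <- generateCohort(spec)
  b <- generateCohort(spec)
  expect_identical(sweepVoltages(a[[1]]), sweepVoltages(b[[1]]))
  expect_identical(groundTruth(a[[2]])$nRrp, groundTruth(b[[2]])$nRrp)
  spec@seed <- 78L
  c_ <- generateCohort(spec)
  expect_false(identical(sweepVoltages(a[[1]]), sweepVoltages(c_[[1]])))
})

test_that("ground truth is complete and the realized pool mean is tracked", {
  spec <- quick_spec(nConnections = 3L, nSweeps = 4L, seed = 9L)
  cohort <- generateCohort(spec)
  expect_length(cohort, 3L)
  for (s in cohort) {
    gt <- groundTruth(s)
    expect_true(all(c("nRrp", "params", "noise", "membrane", "lambda") %in%
                      names(gt)))
    expect_s4_class(gt$params, "TMParams")
  }
  pools <- unlist(lapply(cohort, function(s) groundTruth(s)$nRrp))
  expect_equal(attr(cohort, "realizedMeanNrrp"), mean(pools))
  expect_length(generateCohort(quick_spec(nConnections = 0L)), 0L)
})

test_that("realized cohort means track 1 + lambda across seeds", {
  set.seed(41)
  means <- vapply(1:6, function(i) {
    attr(generateCohort(cohortSpec(lambda = 3, nConnections = 10L,
                                   nSweeps = 2L)), "realizedMeanNrrp")
  }, numeric(1))
  expect_equal(mean(means), 4, tolerance = 0.1)
})

test_that("cohort specifications are validated", {
  expect_error(cohortSpec(lambda = 20), "lambda")
  expect_error(cohortSpec(dtMs = 2), "tauSyn")
  expect_error(paramDistributions(contactRange = c(0L, 30L)), "contactRange")
})

test_that("per-contact parameter draws are available behind a flag", {
  spec <- quick_spec(nConnections = 1L, nSweeps = 4L)
  spec@perContactParams <- TRUE
  conn <- sampleConnection(spec, seed = 6)
  expect_true(is.list(conn$params))
  expect_length(conn$params, length(conn$nRrp))
  u <- vapply(conn$params, function(p) p@U, numeric(1))
  expect_gt(length(unique(u)), 1L)
  # the simulation path accepts per-contact parameters and round-trips
  ss <- simulateConnection(spec, seed = 6)
  expect_s4_class(ss, "SweepSet")
  expect_true(is.list(groundTruth(ss)$params))
  path <- file.path(withr::local_tempdir(), "pc.csv")
  writeSweepSet(ss, path)
  back <- readSweepSet(path)
  expect_length(groundTruth(back)$params, length(groundTruth(ss)$nRrp))
  expect_equal(groundTruth(back)$params[[2]]@U, groundTruth(ss)$params[[2]]@U)
})
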