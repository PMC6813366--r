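test_that("deterministic recursion reproduces hand-derived amplitudes", {
  # U = 0.5, negligible facilitation, spikes 50 ms apart:
  # A1 = U, A2 = U * (1 - U * exp(-50/D))
  a <- tmDeterministicTrain(tmParams(U = 0.5, D = 100, F = 1e-6), c(0, 50))
  expect_equal(a[1], 0.5)
  expect_equal(a[2], 0.5 * (1 - 0.5 * exp(-0.5)))

  # single spike: A1 = A * U
  expect_equal(tmDeterministicTrain(tmParams(U = 0.3, D = 200, F = 30, A = 2),
                                    5), 0.6)

  # full recovery between spikes: every amplitude equals A * U
  far <- tmDeterministicTrain(tmParams(U = 0.38), seq(0, 4e6, by = 1e6))
  expect_equal(far, rep(0.38, 5), tolerance = 1e-9)

  expect_error(tmDeterministicTrain(tmParams(), c(0, 0)), "increasing")
})

test_that("amplitudes stay within [0, 1] for random parameters and trains", {
  set.seed(11)
  for (i in 1:25) {
    p <- tmParams(U = runif(1), D = runif(1, 1, 1000), F = runif(1, 1, 2000))
    times <- cumsum(runif(9, 0.5, 400))
    a <- tmDeterministicTrain(p, times)
    expect_true(all(a >= 0 & a <= 1))
  }
})

test_that("release probability 0 releases nothing, probability 1 everything", {
  step0 <- advanceContact(synapticContact(5L, tmParams(U = 0)), Inf, seed = 1)
  expect_identical(step0$released, 0L)
  expect_identical(step0$contact@ready, 5L)

  step1 <- advanceContact(synapticContact(5L, tmParams(U = 1)), Inf, seed = 1)
  expect_identical(step1$released, 5L)
  expect_identical(step1$contact@ready, 0L)
})

test_that("vesicles are conserved across stochastic updates", {
  set.seed(42)
  ct <- synapticContact(6L, tmParams(U = 0.4, D = 150, F = 30))
  dt <- Inf
  for (n in 1:30) {
    step <- advanceContact(ct, dt)
    expect_gte(step$released, 0L)
    expect_lte(step$contact@ready + step$released, 6L)
    expect_gte(step$contact@ready, 0L)
    ct <- step$contact
    dt <- 50
  }
})

test_that("first-spike release matches the binomial expectation", {
  set.seed(99)
  rel <- replicate(4000, advanceContact(synapticContact(
    4L, tmParams(U = 0.5)), Inf)$released)
  expect_equal(mean(rel), 2, tolerance = 0.04)
})

test_that("mean release follows the deterministic recursion exactly in expectation", {
  p <- tmParams(U = 0.45, D = 250, F = 40, gMax = 2)
  pt <- pulseTimes(stimulusProtocol())
  set.seed(7)
  cond <- RRPool:::.releaseConductances(3L, p, pt, 3e4)
  # E[conductance_n] = gMax * u_n * R_n, independent of the pool size
  det <- tmDeterministicTrain(p, pt)
  expect_equal(rowMeans(cond) / p@gMax, det, tolerance = 0.05)
})

test_that("empty connections give an all-zero event series", {
  ev <- simulateConnectionEvents(list(), pulseTimes(stimulusProtocol()),
                                 seed = 1)
  expect_equal(ev@conductanceNs, rep(0, 9))
  expect_identical(nrow(ev@released), 0L)
})

test_that("mean first response is pool-size invariant, its variance is not", {
  p <- tmParams(U = 0.4, gMax = 2)
  set.seed(123)
  c1 <- RRPool:::.releaseConductances(rep(1L, 5), p, 0, 3e4)
  c4 <- RRPool:::.releaseConductances(rep(4L, 5), p, 0, 3e4)
  expected <- 5 * p@U * p@gMax
  expect_equal(mean(c1), expected, tolerance = 0.02)
  expect_equal(mean(c4), expected, tolerance = 0.02)
  expect_gt(var(c1[1, ]), var(c4[1, ]))
})

test_that("noiseless first-response CV matches the binomial closed form", {
  M <- 5L; n <- 4L; U <- 0.4
  p <- tmParams(U = U, gMax = 2)
  set.seed(31)
  cond <- RRPool:::.releaseConductances(rep(n, M), p, 0, 5e4)
  cv <- sd(cond[1, ]) / mean(cond[1, ])
  expect_equal(cv, sqrt((1 - U) / (M * n * U)), tolerance = 0.03)
})

test_that("release events survive a JSON round trip", {
  ev <- simulateConnectionEvents(
    list(synapticContact(3L, tmParams(gMax = 1.2)),
         synapticContact(5L, tmParams(gMax = 0.8))),
    pulseTimes(stimulusProtocol()), seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  writeReleaseEvents(ev, path)
  back <- readReleaseEvents(path)
  expect_identical(back@released, ev@released)
  expect_equal(back@conductanceNs, ev@conductanceNs)
  expect_identical(back@nRrp, ev@nRrp)
})

test_that("seeded simulations are bit-reproducible", {
  contacts <- list(synapticContact(4L, tmParams()))
  pt <- pulseTimes(stimulusProtocol())
  a <- simulateConnectionEvents(contacts, pt, seed = 8)
  b <- simulateConnectionEvents(contacts, pt, seed = 8)
  expect_identical(a@released, b@released)
})
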