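## Cohort-level pool-size estimation.
##
## The estimator scans shifted-Poisson rates lambda (per-contact pool size
## 1 + Poisson(lambda)): at each rate it simulates a cohort with calibrated
## g_max, drops connections whose mean first-EPSP amplitude falls outside the
## reference range, and measures how far the cohort's mean jackknife CV
## profile (or first-pulse CV alone) is from the reference.  The scan is
## repeated over iterations and the realized cohort-mean pool size at each
## iteration's error minimum is aggregated into mean +/- SD.

#' Reference first-EPSP amplitude range
#'
#' Default exclusion range `mean +/- 2 SD` built from a reference dataset's
#' first-EPSP amplitude distribution; defaults are the in vitro L5 values
#' (1.46 +/- 0.86 mV).
#'
#' @param meanMv reference mean first-EPSP amplitude (mV).
#' @param sdMv reference SD (mV).
#' @return numeric length-2 range (mV).
#' @export
referenceAmplitudeRange <- function(meanMv = 1.46, sdMv = 0.86) {
  meanMv + c(-2, 2) * sdMv
}

#' Calibrate the maximal conductance to a target mean amplitude
#'
#' Finds the `gMax` at which the simulated cohort-mean first-EPSP amplitude
#' matches the target. Because the synaptic drive is current-based, the
#' response is essentially linear in `gMax`; a secant iteration under common
#' random numbers converges in a few steps.
#'
#' @param spec a [CohortSpec-class] template (its `gMaxNs` is the starting
#'   point).
#' @param targetMv target mean first-EPSP amplitude (mV, > 0); default the
#'   in vitro mean 1.46 mV.
#' @param tol relative tolerance on the match (default 2%).
#' @param maxIter maximum secant steps.
#' @param seed integer seed for the common-random-number evaluations.
#' @return calibrated `gMax` (nS) with attributes `achievedMv` and
#'   `iterations`.
#' @export
calibrateGmax <- function(spec, targetMv = 1.46, tol = 0.02, maxIter = 8L,
                          seed = 1L) {
  stopifnot(is(spec, "CohortSpec"))
  if (targetMv <= 0) stop("targetMv must be > 0")
  evalAmp <- function(g) {
    sp <- spec
    sp@distributions@gMaxNs <- g
    sp@seed <- as.integer(seed)
    st <- .cohort_stats(sp)
    mean(st$meanAmp[1L, ])
  }
  g0 <- spec@distributions@gMaxNs
  a0 <- evalAmp(g0)
  g1 <- g0 * targetMv / a0
  it <- 1L
  repeat {
    a1 <- evalAmp(g1)
    it <- it + 1L
    if (abs(a1 - targetMv) <= tol * targetMv || it >= maxIter) break
    slope <- (a1 - a0) / (g1 - g0)
    g0 <- g1; a0 <- a1
    g1 <- g1 + (targetMv - a1) / slope
    if (g1 <= 0) g1 <- g0 / 2
  }
  structure(g1, achievedMv = a1, iterations = it)
}

#' Exclude connections outside a reference amplitude range
#'
#' Removes connections whose mean first-EPSP amplitude (amplitude of the
#' averaged trace) lies outside `range`.
#'
#' @param cohort list of [SweepSet-class] objects (from [generateCohort()]).
#' @param range numeric length-2 amplitude interval (mV), min < max.
#' @return the retained subset, with attributes `nRemoved` and
#'   `meanAmplitudesMv`.
#' @export
exclusionFilter <- function(cohort, range = referenceAmplitudeRange()) {
  if (length(range) != 2L || range[1L] >= range[2L])
    stop("range must be an increasing length-2 interval")
  amps <- vapply(cohort, function(s) {
    gm <- sweepSet(s@timeMs, cbind(rowMeans(s@voltageMv)), s@protocol)
    epspAmplitudes(gm)[1L]
  }, numeric(1))
  keep <- amps >= range[1L] & amps <= range[2L]
  if (!any(keep) && length(cohort))
    warning("all connections removed by the amplitude filter")
  structure(cohort[keep], nRemoved = sum(!keep), meanAmplitudesMv = amps)
}

# Core lambda scan shared by the estimators and the CV map.
# Returns per-iteration x per-lambda summaries of retained connections.
.scan_lambda <- function(spec, lambdaGrid, iterations, gMax, ampRange,
                         seed = NULL) {
  nL <- length(lambdaGrid)
  nP <- spec@protocol@nPulses + 1L
  .with_seed(seed, function() {
    profJ <- array(NA_real_, c(iterations, nL, nP))
    cvJ1 <- cvP1 <- realized <- retained <- matrix(NA_real_, iterations, nL)
    for (it in seq_len(iterations)) {
      for (l in seq_len(nL)) {
        sp <- spec
        sp@lambda <- lambdaGrid[l]
        sp@distributions@gMaxNs <- gMax
        sp@seed <- NA_integer_
        st <- .cohort_stats(sp)
        keep <- st$meanAmp[1L, ] >= ampRange[1L] &
          st$meanAmp[1L, ] <= ampRange[2L]
        if (!any(keep)) keep <- rep(TRUE, length(keep))  # degenerate filter
        profJ[it, l, ] <- rowMeans(st$cvJkk[, keep, drop = FALSE])
        cvJ1[it, l] <- mean(st$cvJkk[1L, keep])
        cvP1[it, l] <- mean(st$cvPlain[1L, keep])
        realized[it, l] <- mean(st$meanNrrp[keep])
        retained[it, l] <- sum(keep)
      }
    }
    list(profJ = profJ, cvJ1 = cvJ1, cvP1 = cvP1, realized = realized,
         retained = retained)
  })
}

.aggregate_scan <- function(lambdaGrid, err, realized, iterations) {
  argmin <- apply(err, 1L, which.min)
  recovered <- realized[cbind(seq_len(iterations), argmin)]
  meanErr <- colMeans(err)
  bestIdx <- which.min(meanErr)
  boundary <- bestIdx == 1L || bestIdx == length(lambdaGrid)
  new("EstimationResult", lambdaGrid = lambdaGrid, meanError = meanErr,
      argminLambda = lambdaGrid[argmin], recoveredPerIteration = recovered,
      nrrpMean = mean(recovered), nrrpSd = stats::sd(recovered),
      iterations = as.integer(iterations), boundary = boundary)
}

#' Estimate the mean pool size by CV-profile matching
#'
#' For each rate on `lambdaGrid`, simulates a cohort (with `gMax` calibrated
#' to the reference amplitude and the amplitude exclusion filter applied),
#' computes the cohort-mean jackknife CV profile, and measures the mean
#' squared distance to the reference profile. The rate with minimum error is
#' found per iteration; the reported pool size is the mean +/- SD over
#' iterations of the realized cohort-mean pool size at the per-iteration
#' minimum.
#'
#' @param reference a [CVProfile-class] with one value per protocol pulse.
#' @param spec a [CohortSpec-class] template (cohort size, sweeps, protocol,
#'   membrane, noise, distributions).
#' @param lambdaGrid rates to scan (within \[0, 13\]; default integers 0-13).
#' @param iterations scan repetitions (default 50).
#' @param gMax calibrated maximal conductance (nS); when NULL it is
#'   calibrated to `targetMv`.
#' @param targetMv calibration target used when `gMax` is NULL.
#' @param ampRange exclusion range for mean first-EPSP amplitudes (mV).
#' @param seed optional integer seed making the whole scan reproducible.
#' @return An [EstimationResult-class].
#' @export
estimateNrrpProfile <- function(reference, spec = cohortSpec(),
                                lambdaGrid = 0:13, iterations = 50L,
                                gMax = NULL, targetMv = 1.46,
                                ampRange = referenceAmplitudeRange(),
                                seed = NULL) {
  stopifnot(is(reference, "CVProfile"))
  if (!length(lambdaGrid)) stop("lambdaGrid must not be empty")
  if (length(reference@cv) != spec@protocol@nPulses + 1L)
    stop("reference profile length must match the protocol pulse count")
  if (is.null(gMax)) gMax <- as.numeric(calibrateGmax(spec, targetMv,
                                                      seed = seed %||% 1L))
  sc <- .scan_lambda(spec, lambdaGrid, iterations, gMax, ampRange, seed)
  err <- apply(sc$profJ, c(1L, 2L), function(p) mean((p - reference@cv)^2))
  .aggregate_scan(lambdaGrid, err, sc$realized, iterations)
}

#' Estimate the mean pool size from the first-EPSP CV alone
#'
#' Same scan as [estimateNrrpProfile()], but the matching error at each rate
#' is the absolute difference between the simulated cohort-mean first-pulse
#' CV and the scalar reference CV; per iteration the rate with the closest CV
#' is selected.
#'
#' @param referenceCv scalar reference first-EPSP CV (> 0).
#' @param useJackknife compare against the jackknife (TRUE) or plain (FALSE)
#'   simulated CV.
#' @inheritParams estimateNrrpProfile
#' @return An [EstimationResult-class]; `boundary` is TRUE (with a warning)
#'   when the reference lies outside the simulated CV range.
#' @export
estimateNrrpFirstEpsp <- function(referenceCv, useJackknife = TRUE,
                                  spec = cohortSpec(), lambdaGrid = 0:13,
                                  iterations = 50L, gMax = NULL,
                                  targetMv = 1.46,
                                  ampRange = referenceAmplitudeRange(),
                                  seed = NULL) {
  if (!is.numeric(referenceCv) || length(referenceCv) != 1L || referenceCv <= 0)
    stop("referenceCv must be a positive scalar")
  if (!length(lambdaGrid)) stop("lambdaGrid must not be empty")
  if (is.null(gMax)) gMax <- as.numeric(calibrateGmax(spec, targetMv,
                                                      seed = seed %||% 1L))
  sc <- .scan_lambda(spec, lambdaGrid, iterations, gMax, ampRange, seed)
  cv <- if (useJackknife) sc$cvJ1 else sc$cvP1
  err <- abs(cv - referenceCv)
  res <- .aggregate_scan(lambdaGrid, err, sc$realized, iterations)
  meanCv <- colMeans(cv)
  if (referenceCv > max(meanCv) || referenceCv < min(meanCv)) {
    warning("reference CV lies outside the simulated CV range; ",
            "estimate sits on the grid boundary")
    res@boundary <- TRUE
  }
  res
}

#' Simulate cohort CV statistics across pool-size levels
#'
#' For each shifted-Poisson rate on `lambdaGrid`, simulates `iterations`
#' cohorts (with the amplitude exclusion filter applied) and reports the
#' iteration-mean first-pulse CV with and without the jackknife, the realized
#' mean pool size, and the mean number of retained connections. This is the
#' CV-vs-pool-size relationship that follows an approximate power law.
#'
#' @inheritParams estimateNrrpProfile
#' @return data.frame with columns `lambda`, `meanNrrp`, `cvJkk`, `cvPlain`,
#'   `retained`.
#' @export
simulateCvByPoolSize <- function(spec = cohortSpec(), lambdaGrid = 0:13,
                                 iterations = 10L, gMax = NULL,
                                 targetMv = 1.46,
                                 ampRange = referenceAmplitudeRange(),
                                 seed = NULL) {
  if (!length(lambdaGrid)) stop("lambdaGrid must not be empty")
  if (is.null(gMax)) gMax <- as.numeric(calibrateGmax(spec, targetMv,
                                                      seed = seed %||% 1L))
  sc <- .scan_lambda(spec, lambdaGrid, iterations, gMax, ampRange, seed)
  data.frame(lambda = lambdaGrid, meanNrrp = colMeans(sc$realized),
             cvJkk = colMeans(sc$cvJ1), cvPlain = colMeans(sc$cvP1),
             retained = colMeans(sc$retained))
}

#' Build the plain-CV to jackknife-CV transformation
#'
#' Simulates cohorts across `lambdaGrid`, computes the iteration-mean
#' first-pulse CV with and without the jackknife at each rate, and fits
#' `cv_jkk = slope * cv + intercept` by least squares. Literature CV values
#' (usually computed without the jackknife) can then be mapped with
#' [applyCvMap()] before first-EPSP matching.
#'
#' @inheritParams estimateNrrpProfile
#' @return A [LinearCVMap-class] with the underlying per-rate CV means as
#'   attribute `levels`.
#' @export
buildCvToCvJkkMap <- function(spec = cohortSpec(), lambdaGrid = 0:13,
                              iterations = 50L, gMax = NULL, targetMv = 1.46,
                              ampRange = referenceAmplitudeRange(),
                              seed = NULL) {
  if (length(lambdaGrid) < 3L) stop("at least 3 lambda levels are required")
  if (is.null(gMax)) gMax <- as.numeric(calibrateGmax(spec, targetMv,
                                                      seed = seed %||% 1L))
  sc <- .scan_lambda(spec, lambdaGrid, iterations, gMax, ampRange, seed)
  cv <- colMeans(sc$cvP1)
  cvj <- colMeans(sc$cvJ1)
  if (stats::sd(cv) < 1e-12) stop("plain CVs are degenerate across rates")
  fit <- stats::lm(cvj ~ cv)
  structure(new("LinearCVMap", slope = stats::coef(fit)[[2L]],
                intercept = stats::coef(fit)[[1L]],
                se = summary(fit)$sigma),
            levels = data.frame(lambda = lambdaGrid, cv = cv, cvJkk = cvj))
}

#' Apply a plain-CV to jackknife-CV map
#'
#' @param map a [LinearCVMap-class].
#' @param cv numeric plain CV value(s).
#' @return transformed CV value(s).
#' @export
applyCvMap <- function(map, cv) {
  stopifnot(is(map, "LinearCVMap"))
  map@slope * cv + map@intercept
}

`%||%` <- function(a, b) if (is.null(a)) b else a
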