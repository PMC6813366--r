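## Jackknife (leave-one-out) CV profiles of EPSP amplitude trains.
##
## Amplitudes are measured per pulse as max(V) in the post-stimulus window
## minus min(V) in the 50 ms pre-stimulus window.  The post window runs to the
## next stimulus (300 ms for the recovery pulse).  The jackknife CV uses
##   std_n = sqrt((N - 1) * sum_i (A_in - Abar_n)^2),  CV_n = std_n / Abar_n,
## where A_in is the amplitude measured on the i-th leave-one-out average
## trace.  For amplitudes linear in the sweeps this equals the plain sample
## CV exactly, while measuring on averaged traces suppresses noise bias.

# Per-pulse contiguous index windows (1-based inclusive lo/hi) on a uniform
# grid: 50 ms pre-stimulus and post-stimulus up to the next pulse (300 ms for
# the recovery pulse).
.pulse_windows <- function(protocol, timeMs) {
  pt <- pulseTimes(protocol)
  nP <- length(pt)
  isi <- c(diff(pt), 300)
  dt <- timeMs[2L] - timeMs[1L]
  n <- length(timeMs)
  bound <- function(tv) as.integer(round((tv - timeMs[1L]) / dt)) + 1L
  preLo <- bound(pt - 50)
  preHi <- bound(pt) - 1L
  postLo <- bound(pt)
  postHi <- bound(pt + pmin(isi, 300))
  if (any(preLo < 1L) || any(postHi > n) || any(preHi < preLo) ||
      any(postHi <= postLo))
    stop("amplitude windows lie outside the trace")
  list(preLo = preLo, preHi = preHi, postLo = postLo, postHi = postHi)
}

# Amplitude matrix [nPulses x nTraces] from a voltage matrix.
.amplitude_matrix <- function(v, protocol, timeMs) {
  w <- .pulse_windows(protocol, timeMs)
  cpp_window_amplitudes(v, w$preLo, w$preHi, w$postLo, w$postHi)
}

#' Leave-one-out average traces
#'
#' Returns a [SweepSet-class] whose i-th sweep is the average of all sweeps
#' except the i-th. The mean of the leave-one-out averages equals the grand
#' mean exactly.
#'
#' @param sweeps a [SweepSet-class] with at least 2 sweeps.
#' @return A [SweepSet-class] of N leave-one-out averages.
#' @export
jkkMeanTraces <- function(sweeps) {
  stopifnot(is(sweeps, "SweepSet"))
  x <- sweeps@voltageMv
  n <- ncol(x)
  if (n < 2L) stop("at least 2 sweeps are required for leave-one-out averages")
  loo <- (rowSums(x) - x) / (n - 1)
  sweepSet(sweeps@timeMs, loo, sweeps@protocol, sweeps@groundTruth)
}

#' EPSP amplitudes of a trace
#'
#' Per pulse, the maximum voltage in the post-stimulus window minus the
#' minimum voltage in the 50 ms pre-stimulus window. The post window extends
#' to the next stimulus and to 300 ms for the recovery pulse.
#'
#' @param sweeps a [SweepSet-class] (typically a single averaged trace).
#' @return numeric vector of amplitudes (mV) for a single trace, otherwise a
#'   pulses x sweeps matrix.
#' @export
epspAmplitudes <- function(sweeps) {
  stopifnot(is(sweeps, "SweepSet"))
  a <- .amplitude_matrix(sweeps@voltageMv, sweeps@protocol, sweeps@timeMs)
  if (ncol(a) == 1L) drop(a) else a
}

#' Per-pulse CV profile of a sweep set
#'
#' With `useJackknife = TRUE` (default) amplitudes are measured on the N
#' leave-one-out average traces and the SD is reconstructed with the
#' jackknife factor `sqrt((N - 1) * sum((A_i - Abar)^2))`; otherwise the plain
#' sample SD/mean of per-sweep amplitudes is used.
#'
#' @param sweeps a [SweepSet-class] (N >= 2; >= 3 recommended).
#' @param useJackknife logical.
#' @return A [CVProfile-class]; pulses whose mean amplitude is ~0 get `NA`
#'   CV with a warning.
#' @export
cvProfile <- function(sweeps, useJackknife = TRUE) {
  stopifnot(is(sweeps, "SweepSet"))
  n <- nSweeps(sweeps)
  if (n < 2L) stop("at least 2 sweeps are required")
  if (useJackknife) {
    a <- .amplitude_matrix(jkkMeanTraces(sweeps)@voltageMv,
                           sweeps@protocol, sweeps@timeMs)
    abar <- rowMeans(a)
    std <- sqrt((n - 1) * rowSums((a - abar)^2))
  } else {
    a <- .amplitude_matrix(sweeps@voltageMv, sweeps@protocol, sweeps@timeMs)
    abar <- rowMeans(a)
    std <- apply(a, 1L, stats::sd)
  }
  cv <- std / abar
  degenerate <- abs(abar) < 1e-12
  if (any(degenerate)) {
    warning("CV undefined for pulses with ~0 mean amplitude: ",
            paste(which(degenerate), collapse = ", "))
    cv[degenerate] <- NA_real_
  }
  new("CVProfile", cv = cv, meanAmplitudeMv = abar, nSweeps = as.integer(n),
      jackknife = isTRUE(useJackknife))
}

#' Mean squared distance between two CV profiles
#'
#' @param p,q [CVProfile-class] objects of equal length.
#' @return scalar mean squared difference over the per-pulse CVs.
#' @export
profileDistance <- function(p, q) {
  stopifnot(is(p, "CVProfile"), is(q, "CVProfile"))
  if (length(p@cv) != length(q@cv)) stop("CV profiles have different lengths")
  mean((p@cv - q@cv)^2)
}

#' Power-law fit of CV against pool size
#'
#' Least-squares fit of `CV = a * N^b` by linear regression on the log-log
#' scale.
#'
#' @param nrrp numeric, mean pool size per level (>= 3 levels, > 0).
#' @param cv numeric, mean CV per level (> 0).
#' @return A [PowerLawFit-class].
#' @export
fitPowerLaw <- function(nrrp, cv) {
  if (length(nrrp) != length(cv)) stop("nrrp and cv must have equal length")
  if (length(nrrp) < 3L) stop("at least 3 pool-size levels are required")
  if (any(!is.finite(cv)) || any(cv <= 0) || any(nrrp <= 0))
    stop("pool sizes and CVs must be positive and finite")
  fit <- stats::lm(log(cv) ~ log(nrrp))
  cf <- stats::coef(fit)
  new("PowerLawFit", amplitude = exp(cf[[1L]]), index = cf[[2L]],
      residual = sum(stats::residuals(fit)^2))
}

#' Cohort-mean CV profile
#'
#' Averages per-connection CV profiles (and mean amplitudes) across a cohort.
#'
#' @param cohort list of [SweepSet-class] objects.
#' @param useJackknife logical, passed to [cvProfile()].
#' @return A [CVProfile-class] with the across-connection mean per-pulse CV.
#' @export
meanCVProfile <- function(cohort, useJackknife = TRUE) {
  if (!length(cohort)) stop("empty cohort")
  profs <- lapply(cohort, cvProfile, useJackknife = useJackknife)
  cv <- rowMeans(vapply(profs, cvValues, numeric(length(profs[[1]]@cv))))
  amp <- rowMeans(vapply(profs, meanAmplitudes, numeric(length(profs[[1]]@cv))))
  new("CVProfile", cv = cv, meanAmplitudeMv = amp,
      nSweeps = profs[[1]]@nSweeps, jackknife = isTRUE(useJackknife))
}
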