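## Passive-membrane EPSP synthesis and Ornstein-Uhlenbeck membrane noise.
##
## The synaptic drive is current-based: each released quantum adds an
## instantaneous-rise, tau_syn-decay conductance, and the injected current is
## I_syn(t) = g(t) * (E_rev - V_rest), so the membrane equation is exactly
## linear and the deconvolution operator tau_mem dV/dt + V inverts it.
## Discrete updates use exponential (AR(1)) integration:
##   g_k = exp(-dt/tau_syn) g_{k-1} + [quanta landing at sample k]
##   V_k = exp(-dt/tau_mem) V_{k-1} + (1 - exp(-dt/tau_mem)) R I_k
## (R in MOhm, g in nS, driving force in mV; R*g*drive*1e-3 gives mV).

# Recursive AR(1) filter per column: y_k = phi * y_{k-1} + x_k.
.ar1_filter <- function(x, phi) {
  if (is.matrix(x)) {
    y <- stats::filter(x, phi, method = "recursive")
    matrix(as.numeric(y), nrow(x), ncol(x))
  } else {
    as.numeric(stats::filter(x, phi, method = "recursive"))
  }
}

#' Generate an Ornstein-Uhlenbeck noise trace
#'
#' Euler discretization of the OU process:
#' `X(t+dt) = X(t) - X(t)/tau * dt + sigma * sqrt(2/tau) * sqrt(dt) * W`,
#' with `W` standard normal increments and `X(t0) = x0`. With `sigma = 0` the
#' trace relaxes as `x0 * exp(-(t - t0)/tau)` (up to the Euler discretization
#' error); in general it fluctuates with stationary SD close to `sigma` for
#' `dt << tau`.
#'
#' @param noise a [NoiseParams-class].
#' @param dtMs time step (ms), must be < `tauMs`.
#' @param n number of samples (>= 1), including the initial one.
#' @param x0 initial value (mV).
#' @param seed optional integer seed.
#' @return numeric vector of length `n` (mV).
#' @export
ouGenerate <- function(noise, dtMs, n, x0 = 0, seed = NULL) {
  stopifnot(is(noise, "NoiseParams"), n >= 1)
  if (dtMs >= noise@tauMs)
    stop("dtMs must be smaller than the noise correlation time tauMs")
  .with_seed(seed, function() {
    phi <- 1 - dtMs / noise@tauMs
    s <- noise@sigmaMv * sqrt(2 * dtMs / noise@tauMs)
    if (n == 1L) return(x0)
    w <- stats::rnorm(n - 1L, sd = s)
    x <- .ar1_filter(w + c(phi * x0, numeric(n - 2L)), phi)
    c(x0, x)
  })
}

# OU noise matrix [n x nSweeps], each sweep started from its stationary
# distribution.  Uses the same Euler discretization as ouGenerate.
.ou_matrix <- function(noise, dtMs, n, nSweeps) {
  phi <- 1 - dtMs / noise@tauMs
  s <- noise@sigmaMv * sqrt(2 * dtMs / noise@tauMs)
  if (s == 0) return(matrix(0, n, nSweeps))
  sdStat <- s / sqrt(1 - phi^2)
  w <- matrix(stats::rnorm(n * nSweeps, sd = s), n, nSweeps)
  w[1L, ] <- stats::rnorm(nSweeps, sd = sdStat)   # stationary start
  y <- stats::filter(w, phi, method = "recursive")
  matrix(as.numeric(y), n, nSweeps)
}

# Shared synthesis core: conductance amplitudes per spike and sweep ->
# voltage matrix [n x nSweeps] including rest potential and OU noise.
# One fused C++ pass over the samples (hot path of the cohort simulations).
.synth_traces <- function(condAmp, spikeTimesMs, membrane, noise, dtMs,
                          durationMs) {
  n <- as.integer(round(durationMs / dtMs))
  nSweeps <- ncol(condAmp)
  idx <- as.integer(round(spikeTimesMs / dtMs)) + 1L
  if (any(idx < 1L | idx > n)) stop("event times fall outside the sweep")
  aM <- exp(-dtMs / membrane@tauMemMs)
  gain <- (1 - aM) * (membrane@eRevMv - membrane@vRestMv) *
    membrane@rInputMOhm * 1e-3                                  # nS -> mV
  phiOu <- 1 - dtMs / noise@tauMs
  s <- noise@sigmaMv * sqrt(2 * dtMs / noise@tauMs)
  useNoise <- s > 0
  if (useNoise && dtMs >= noise@tauMs)
    stop("dtMs must be smaller than the noise correlation time")
  w <- if (useNoise) {
    w <- matrix(stats::rnorm(n * nSweeps, sd = s), n, nSweeps)
    w[1L, ] <- stats::rnorm(nSweeps, sd = s / sqrt(1 - phiOu^2))
    w
  } else matrix(0, 1L, 1L)
  cpp_synth_voltage(idx, condAmp, n, exp(-dtMs / membrane@tauSynMs), aM,
                    gain, w, phiOu, useNoise, membrane@vRestMv)
}

#' Synthesize one voltage sweep from release events
#'
#' Turns the quantal conductance events of one stochastic trial into a
#' membrane-voltage sweep: conductance quanta with instantaneous rise and
#' `tauSynMs` decay drive the passive membrane as a current with fixed driving
#' force `eRevMv - vRestMv`, and an OU noise realization is added. Because the
#' drive is current-based, superposition of events is exact.
#'
#' @param membrane a [MembraneModel-class].
#' @param events a [ReleaseEventSeries-class] (spike times within the sweep).
#' @param protocol a [StimulusProtocol-class]; sets the sweep duration.
#' @param noise a [NoiseParams-class]; use `sigmaMv = 0` for a noiseless sweep.
#' @param dtMs sampling step (ms); must resolve `tauSynMs`.
#' @param seed optional integer seed.
#' @return A [SweepSet-class] with one sweep.
#' @export
synthesizeSweep <- function(membrane, events, protocol = stimulusProtocol(),
                            noise = noiseParams(0), dtMs = 0.1, seed = NULL) {
  stopifnot(is(membrane, "MembraneModel"), is(events, "ReleaseEventSeries"))
  if (dtMs >= membrane@tauSynMs)
    stop("dtMs must be smaller than tauSynMs to resolve the quantal rise")
  .with_seed(seed, function() {
    dur <- sweepDurationMs(protocol)
    v <- .synth_traces(cbind(events@conductanceNs), events@spikeTimesMs,
                       membrane, noise, dtMs, dur)
    n <- nrow(v)
    sweepSet(timeMs = (seq_len(n) - 1L) * dtMs, voltageMv = v,
             protocol = protocol)
  })
}

#' Noise-calibration segment of a sweep set
#'
#' Returns the baseline-subtracted voltage samples of the quiet stretch
#' between the train and the recovery pulse: from one inter-stimulus interval
#' plus a 50 ms settling guard after the last train pulse, up to the recovery
#' pulse (400 ms under the default protocol). Each sweep is centred on its
#' own segment mean.
#'
#' @param sweeps a [SweepSet-class].
#' @return numeric matrix, segment samples x sweeps (mV, centred).
#' @export
noiseSegment <- function(sweeps) {
  stopifnot(is(sweeps, "SweepSet"))
  pt <- pulseTimes(sweeps@protocol)
  np <- sweeps@protocol@nPulses
  isi <- 1000 / sweeps@protocol@frequencyHz
  from <- pt[np] + isi + 50
  to <- pt[np + 1L]
  sel <- sweeps@timeMs >= from & sweeps@timeMs < to
  if (!any(sel)) stop("calibration window lies outside the sweep")
  seg <- sweeps@voltageMv[sel, , drop = FALSE]
  sweep(seg, 2L, colMeans(seg), "-")
}

#' Estimate OU noise parameters from a quiet segment
#'
#' `sigma` is the per-sweep sample SD of the (centred) segment; `tau` is the
#' time constant of an exponential fit to the per-sweep autocorrelation
#' function. Per-connection values are the means across sweeps.
#'
#' @param segment numeric vector or matrix (samples x sweeps) of
#'   baseline-subtracted voltage, e.g. from [noiseSegment()].
#' @param dtMs sampling step of the segment (ms).
#' @param maxLagMs largest autocorrelation lag used in the fit (ms).
#' @return list with `sigmaMv`, `tauMs` (NA when undefined), per-sweep values
#'   `perSweepSigma`, `perSweepTau`, and a logical `flag` set for degenerate
#'   segments (constant input or non-decaying autocorrelation).
#' @export
estimateOuParams <- function(segment, dtMs, maxLagMs = 150) {
  x <- if (is.matrix(segment)) segment else cbind(as.numeric(segment))
  x <- sweep(x, 2L, colMeans(x), "-")
  sds <- apply(x, 2L, stats::sd)
  maxLag <- max(2L, min(nrow(x) - 2L, as.integer(round(maxLagMs / dtMs))))
  fitTau <- function(col, colSd) {
    if (!is.finite(colSd) || colSd == 0) return(NA_real_)
    rho <- as.numeric(stats::acf(col, lag.max = maxLag, plot = FALSE,
                                 demean = FALSE)$acf)[-1L]
    # correlation already gone at lag 1: white-noise-like, tau at resolution
    if (rho[1L] <= 0.05) return(dtMs)
    lagMs <- seq_along(rho) * dtMs
    keep <- seq_len(max(2L, suppressWarnings(min(which(rho <= 0.05)) - 1L)))
    keep <- keep[keep <= length(rho)]
    if (length(keep) < 2L || any(rho[keep] <= 0)) return(NA_real_)
    tau0 <- -1 / stats::coef(stats::lm(log(rho[keep]) ~ 0 + lagMs[keep]))[[1L]]
    if (!is.finite(tau0) || tau0 <= 0) return(NA_real_)
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ exp(-l / tau),
                        data = list(r = rho[keep], l = lagMs[keep]),
                        start = list(tau = tau0),
                        lower = dtMs / 100, upper = 1e6),
      error = function(e) NULL)
    if (is.null(fit)) tau0 else stats::coef(fit)[[1L]]
  }
  taus <- vapply(seq_len(ncol(x)), function(j) fitTau(x[, j], sds[j]),
                 numeric(1))
  sigma <- mean(sds)
  tau <- if (all(is.na(taus))) NA_real_ else mean(taus, na.rm = TRUE)
  flag <- sigma == 0 || is.na(tau)
  if (!is.na(tau) && tau <= 2 * dtMs)
    warning("fitted noise correlation time is at the sampling resolution; ",
            "segment is white-noise-like")
  list(sigmaMv = sigma, tauMs = tau, perSweepSigma = sds, perSweepTau = taus,
       flag = flag)
}
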