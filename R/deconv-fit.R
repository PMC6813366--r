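## Recovery of TM parameters from sweep sets: membrane time constant from the
## recovery-EPSP decay, voltage deconvolution (tau_mem dV/dt + V), peak
## extraction, and a genetic-algorithm fit of U, D, F to the normalized peak
## train.

# central differences, one-sided at the boundaries
.ddt <- function(v, dt) {
  n <- length(v)
  if (n < 3L) stop("trace too short to differentiate")
  d <- numeric(n)
  d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
  d[1L] <- (v[2L] - v[1L]) / dt
  d[n] <- (v[n] - v[n - 1L]) / dt
  d
}

#' Voltage deconvolution
#'
#' Applies the inverse membrane operator `tau_mem * dV/dt + V` to expose the
#' unfiltered synaptic drive, using central differences (forward/backward at
#' the boundaries). A trace that is a pure `exp(-t/tau_mem)` decay maps to 0,
#' and re-filtering the output through the RC membrane recovers the input up
#' to discretization error.
#'
#' @param x a [SweepSet-class] or numeric vector (baseline-subtracted).
#' @param tauMemMs membrane time constant (ms).
#' @param dtMs sampling step; taken from `x` when it is a [SweepSet-class].
#' @return same shape as the input (SweepSet or numeric vector).
#' @export
deconvolve <- function(x, tauMemMs, dtMs = NULL) {
  stopifnot(tauMemMs > 0)
  if (is(x, "SweepSet")) {
    dt <- diff(x@timeMs[1:2])
    out <- apply(x@voltageMv, 2L, function(v) tauMemMs * .ddt(v, dt) + v)
    return(sweepSet(x@timeMs, out, x@protocol, x@groundTruth))
  }
  if (is.null(dtMs)) stop("dtMs is required for a bare numeric trace")
  tauMemMs * .ddt(as.numeric(x), dtMs) + as.numeric(x)
}

#' Fit the membrane time constant from the recovery-EPSP decay
#'
#' Averages the sweeps, locates the recovery (last) EPSP peak, and fits a
#' single exponential to the decay that follows it.
#'
#' @param sweeps a [SweepSet-class]; multiple sweeps are averaged first.
#' @param fitStartMs delay after the recovery peak before the fit window
#'   starts (ms), skipping the fast synaptic-decay phase.
#' @param fitLengthMs length of the fitted decay window (ms, >= 100).
#' @return list with `tauMemMs` (NA on failure), `amplitudeMv`, `rss`, and
#'   logical `flag` set when the segment does not decay.
#' @export
fitTauMem <- function(sweeps, fitStartMs = 10, fitLengthMs = 250) {
  stopifnot(is(sweeps, "SweepSet"), fitLengthMs >= 100)
  v <- rowMeans(sweeps@voltageMv)
  t <- sweeps@timeMs
  prot <- sweeps@protocol
  base <- stats::median(v[t < max(prot@onsetMs - 5, t[2L])])
  v <- v - base
  tRec <- max(pulseTimes(prot))
  win <- which(t >= tRec & t <= tRec + 300)
  if (!length(win)) stop("recovery EPSP window lies outside the trace")
  pk <- win[which.max(v[win])]
  sel <- which(t >= t[pk] + fitStartMs & t <= t[pk] + fitStartMs + fitLengthMs)
  if (length(sel) < 10L) stop("fewer than 10 samples available for the decay fit")
  y <- v[sel]
  ts <- t[sel] - t[sel[1L]]
  fail <- list(tauMemMs = NA_real_, amplitudeMv = NA_real_, rss = NA_real_,
               flag = TRUE)
  if (y[1L] <= 0 || mean(diff(y)) >= 0) return(fail)
  pos <- y > max(y) * 1e-3
  if (sum(pos) < 5L) return(fail)
  tau0 <- -1 / stats::coef(stats::lm(log(y[pos]) ~ 0 + ts[pos],
                                     weights = y[pos]))[[1L]]
  if (!is.finite(tau0) || tau0 <= 0) return(fail)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-ts / tau),
                      start = list(a = y[1L], tau = tau0),
                      lower = c(1e-9, 1e-3)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  cf <- stats::coef(fit)
  list(tauMemMs = cf[["tau"]], amplitudeMv = cf[["a"]],
       rss = sum(stats::residuals(fit)^2), flag = FALSE)
}

#' Extract EPSP peaks from a deconvolved trace
#'
#' Per pulse, the maximum of the deconvolved trace in the pulse's search
#' window (up to the next stimulus; 300 ms for the recovery pulse), measured
#' from the common pre-train baseline level.
#'
#' @param deconvolved a [SweepSet-class] holding one deconvolved averaged
#'   trace (extra sweeps are averaged).
#' @return numeric vector of peak values, one per pulse, with the pulse times
#'   as the `times` attribute.
#' @export
extractPeaks <- function(deconvolved) {
  stopifnot(is(deconvolved, "SweepSet"))
  v <- rowMeans(deconvolved@voltageMv)
  t <- deconvolved@timeMs
  prot <- deconvolved@protocol
  base <- stats::median(v[t < max(prot@onsetMs - 5, t[2L])])
  pt <- pulseTimes(prot)
  isi <- c(diff(pt), 300)
  peaks <- vapply(seq_along(pt), function(p) {
    win <- which(t >= pt[p] & t <= pt[p] + min(isi[p], 300))
    if (!length(win)) stop(sprintf("search window of pulse %d is empty", p))
    max(v[win]) - base
  }, numeric(1))
  structure(peaks, times = pt)
}

# Vectorized normalized TM peak prediction for GA populations.
# U, D, F: vectors of candidate parameters; dts: inter-spike intervals.
.tm_mse <- function(U, D, F, dts, peaksNorm) {
  m <- length(U)
  n <- length(dts) + 1L
  u <- U
  R <- rep(1, m)
  pred <- matrix(0, n, m)
  pred[1L, ] <- u
  for (k in seq_len(n - 1L)) {
    Rn <- 1 + (R - R * u - 1) * exp(-dts[k] / D)
    u <- U + u * (1 - U) * exp(-dts[k] / F)
    R <- Rn
    pred[k + 1L, ] <- u * R
  }
  mx <- apply(pred, 2L, max)
  pred <- sweep(pred, 2L, mx, "/")
  colMeans((pred - peaksNorm)^2)
}

# One GA run; returns the best solution and the best-of-generation error
# trajectory.  Elitism makes the trajectory non-increasing.
.ga_run <- function(dts, peaksNorm, cfg) {
  lo <- cfg@ranges[1L, ]
  hi <- cfg@ranges[2L, ]
  span <- hi - lo
  m <- cfg@popSize
  pop <- sapply(1:3, function(j) stats::runif(m, lo[j], hi[j]))
  fit <- .tm_mse(pop[, 1L], pop[, 2L], pop[, 3L], dts, peaksNorm)
  trace <- numeric(cfg@generations)
  for (g in seq_len(cfg@generations)) {
    ord <- order(fit)
    elite <- pop[ord[seq_len(cfg@elitism)], , drop = FALSE]
    eliteFit <- fit[ord[seq_len(cfg@elitism)]]
    # tournament selection
    pick <- matrix(sample.int(m, m * cfg@tournamentSize, replace = TRUE),
                   nrow = cfg@tournamentSize)
    fm <- matrix(fit[pick], nrow = cfg@tournamentSize)
    winners <- pick[cbind(max.col(t(-fm), ties.method = "first"), seq_len(m))]
    parents <- pop[winners, , drop = FALSE]
    # uniform crossover on consecutive pairs
    half <- seq_len(m %/% 2L) * 2L
    doCx <- stats::runif(length(half)) < cfg@crossoverRate
    for (i in half[doCx]) {
      mask <- stats::runif(3L) < 0.5
      tmp <- parents[i - 1L, mask]
      parents[i - 1L, mask] <- parents[i, mask]
      parents[i, mask] <- tmp
    }
    # Gaussian mutation, clipped to the ranges
    mut <- matrix(stats::runif(m * 3L) < cfg@mutationRate, m, 3L)
    if (any(mut)) {
      noise <- matrix(stats::rnorm(m * 3L), m, 3L) *
        rep(span * cfg@mutationSdFrac, each = m)
      parents[mut] <- parents[mut] + noise[mut]
      parents <- pmin(pmax(parents, rep(lo, each = m)), rep(hi, each = m))
    }
    parents[seq_len(cfg@elitism), ] <- elite
    pop <- parents
    fit <- .tm_mse(pop[, 1L], pop[, 2L], pop[, 3L], dts, peaksNorm)
    fit[seq_len(cfg@elitism)] <- pmin(fit[seq_len(cfg@elitism)], eliteFit)
    trace[g] <- min(fit)
  }
  best <- which.min(fit)
  list(par = pop[best, ], mse = fit[best], trace = trace)
}

#' Fit TM parameters to a peak train with a genetic algorithm
#'
#' Minimizes the mean squared distance between the (max-normalized) input
#' peaks and the deterministic TM prediction `u_n * R_n` (also
#' max-normalized, `A = 1`) over `restarts` independent GA runs; the restart
#' with the smallest distance wins. Search ranges default to U in \[0, 1\],
#' D in \[0, 1000\] ms, F in \[0, 2000\] ms.
#'
#' @param peaks numeric peak vector (one per pulse), e.g. from
#'   [extractPeaks()].
#' @param config a [GAConfig-class].
#' @param protocol a [StimulusProtocol-class] providing the pulse timing.
#' @param seed optional integer seed.
#' @return list with `U`, `D`, `F`, `mse`, `params` (a [TMParams-class] with
#'   `A = 1`; `gMax` is not estimated by this fit and is left at its default),
#'   `perRestart` (restarts x 4 matrix of solutions and errors), and
#'   `bestTrace` (best-of-generation error of the winning restart;
#'   non-increasing by elitism).
#' @export
fitTmGA <- function(peaks, config = gaConfig(), protocol = stimulusProtocol(),
                    seed = NULL) {
  peaks <- as.numeric(peaks)
  if (any(!is.finite(peaks))) stop("peaks must be finite")
  pt <- pulseTimes(protocol)
  if (length(peaks) != length(pt))
    stop("peaks must have one value per protocol pulse")
  pk <- peaks / max(peaks)
  dts <- diff(pt)
  .with_seed(seed, function() {
    rr <- lapply(seq_len(config@restarts),
                 function(r) .ga_run(dts, pk, config))
    runs <- cbind(t(vapply(rr, `[[`, numeric(3), "par")),
                  vapply(rr, `[[`, numeric(1), "mse"))
    colnames(runs) <- c("U", "D", "F", "mse")
    best <- which.min(runs[, "mse"])
    list(U = runs[best, "U"], D = runs[best, "D"], F = runs[best, "F"],
         mse = runs[best, "mse"],
         params = tmParams(U = runs[best, "U"],
                           D = max(runs[best, "D"], 1e-9),
                           F = max(runs[best, "F"], 1e-9), A = 1),
         perRestart = runs, bestTrace = rr[[best]]$trace)
  })
}

#' Select a population distribution for a fitted parameter
#'
#' Fits beta, gamma and normal families by maximum likelihood
#' (`fitdistrplus::fitdist`) and selects by highest Kolmogorov-Smirnov
#' p-value, breaking ties with the smallest KS distance. The beta family is
#' only attempted when all values lie strictly inside (0, 1).
#'
#' @param values numeric vector of per-connection parameter values (>= 10,
#'   at least 2 distinct).
#' @param name parameter label for messages.
#' @return list with `family`, `estimate` (named parameter vector), `p`, `D`,
#'   and `candidates` (per-family p and D).
#' @export
fitParamDistributions <- function(values, name = "parameter") {
  values <- as.numeric(values)
  if (length(values) < 10L) stop(name, ": at least 10 values are required")
  if (length(unique(values)) < 2L) stop(name, ": values are degenerate")
  fams <- c("norm", "gamma")
  if (all(values > 0 & values < 1)) fams <- c("beta", fams)
  res <- lapply(fams, function(f) {
    fit <- tryCatch(fitdistrplus::fitdist(values, f), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    est <- as.list(fit$estimate)
    ks <- suppressWarnings(do.call(stats::ks.test,
                                   c(list(values, paste0("p", f)), est)))
    list(family = f, estimate = fit$estimate,
         p = unname(ks$p.value), D = unname(ks$statistic))
  })
  res <- Filter(Negate(is.null), res)
  if (!length(res)) stop(name, ": no candidate family could be fitted")
  p <- vapply(res, `[[`, numeric(1), "p")
  D <- vapply(res, `[[`, numeric(1), "D")
  best <- order(-p, D)[1L]
  out <- res[[best]]
  out$candidates <- data.frame(
    family = vapply(res, `[[`, character(1), "family"), p = p, D = D)
  out
}
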