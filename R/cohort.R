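## Synthetic-cohort generator.
##
## A cohort is a set of connections; each connection gets a contact count
## drawn uniformly from the configured range, one TM parameter draw shared by
## its contacts (the fitting pipeline recovers one U/D/F per connection), and
## a per-contact pool size nRrp = 1 + Poisson(lambda).  Sweeps are synthesized
## from stochastic release events through the passive membrane with OU noise.

# mean/sd -> shape/rate gamma draws
.rgamma_ms <- function(n, mean, sd) {
  shape <- (mean / sd)^2
  stats::rgamma(n, shape = shape, rate = shape / mean)
}

# normal(mean, sd) truncated to [0, 1] by rejection
.rtruncnorm01 <- function(n, mean, sd) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= 0 & x <= 1])
  }
  out[seq_len(n)]
}

#' Sample one connection from a cohort specification
#'
#' Draws the contact count, the per-contact pool sizes
#' `nRrp = 1 + Poisson(lambda)`, and one set of TM parameters shared by all
#' contacts of the connection (U truncated-normal, D and F gamma).
#'
#' @param spec a [CohortSpec-class].
#' @param seed optional integer seed.
#' @return list with elements `nRrp` (integer vector, one per contact),
#'   `params` (a [TMParams-class], or a list of one per contact when
#'   `spec@perContactParams` is TRUE), `membrane`, `noise`.
#' @export
sampleConnection <- function(spec, seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  .with_seed(seed, function() .sample_connection(spec))
}

.sample_connection <- function(spec) {
  d <- spec@distributions
  nContacts <- sample(d@contactRange[1L]:d@contactRange[2L], 1L)
  nRrp <- 1L + stats::rpois(nContacts, spec@lambda)
  draw <- function() tmParams(U = .rtruncnorm01(1L, d@uMean, d@uSd),
                              D = .rgamma_ms(1L, d@dMeanMs, d@dSdMs),
                              F = .rgamma_ms(1L, d@fMeanMs, d@fSdMs),
                              A = 1, gMax = d@gMaxNs)
  params <- if (isTRUE(spec@perContactParams))
    replicate(nContacts, draw(), simplify = FALSE) else draw()
  list(nRrp = nRrp, params = params, membrane = spec@membrane,
       noise = spec@noise)
}

# Simulate all sweeps of one sampled connection; returns the voltage matrix.
# With per-contact parameters each contact is simulated with its own release
# dynamics and the conductances superpose (current-based linearity).
.connection_voltages <- function(conn, spec) {
  pt <- pulseTimes(spec@protocol)
  cond <- if (is.list(conn$params)) {
    Reduce(`+`, lapply(seq_along(conn$nRrp), function(j)
      .releaseConductances(conn$nRrp[j], conn$params[[j]], pt, spec@nSweeps)))
  } else {
    .releaseConductances(conn$nRrp, conn$params, pt, spec@nSweeps)
  }
  .synth_traces(cond, pt, conn$membrane, conn$noise, spec@dtMs,
                sweepDurationMs(spec@protocol))
}

# Per-connection summary statistics without retaining the traces:
# jackknife and plain CV profiles, amplitudes of the grand-mean trace, and
# the realized mean pool size.
.connection_stats <- function(conn, spec) {
  v <- .connection_voltages(conn, spec)
  timeMs <- (seq_len(nrow(v)) - 1L) * spec@dtMs
  n <- ncol(v)
  loo <- (rowSums(v) - v) / (n - 1)
  aJ <- .amplitude_matrix(loo, spec@protocol, timeMs)
  abarJ <- rowMeans(aJ)
  cvJ <- sqrt((n - 1) * rowSums((aJ - abarJ)^2)) / abarJ
  aP <- .amplitude_matrix(v, spec@protocol, timeMs)
  cvP <- apply(aP, 1L, stats::sd) / rowMeans(aP)
  gm <- .amplitude_matrix(cbind(rowMeans(v)), spec@protocol, timeMs)[, 1L]
  list(cvJkk = cvJ, cvPlain = cvP, meanAmp = gm, meanNrrp = mean(conn$nRrp))
}

# Cohort-level statistics: one row/element per connection.
.cohort_stats <- function(spec) {
  run <- function() {
    nP <- spec@protocol@nPulses + 1L
    if (spec@nConnections == 0L)
      return(list(cvJkk = matrix(numeric(), nP, 0L),
                  cvPlain = matrix(numeric(), nP, 0L),
                  meanAmp = matrix(numeric(), nP, 0L), meanNrrp = numeric()))
    out <- vector("list", spec@nConnections)
    for (i in seq_len(spec@nConnections))
      out[[i]] <- .connection_stats(.sample_connection(spec), spec)
    list(
      cvJkk = matrix(vapply(out, `[[`, numeric(nP), "cvJkk"), nrow = nP),
      cvPlain = matrix(vapply(out, `[[`, numeric(nP), "cvPlain"), nrow = nP),
      meanAmp = matrix(vapply(out, `[[`, numeric(nP), "meanAmp"), nrow = nP),
      meanNrrp = vapply(out, `[[`, numeric(1), "meanNrrp"))
  }
  .with_seed(if (is.na(spec@seed)) NULL else spec@seed, run)
}

#' Simulate one connection as a sweep set
#'
#' Samples a connection from the specification and synthesizes its sweeps,
#' retaining the complete generating ground truth.
#'
#' @param spec a [CohortSpec-class].
#' @param seed optional integer seed.
#' @return A [SweepSet-class] with `groundTruth` fields `nRrp`, `params`,
#'   `noise`, `membrane`, `lambda`.
#' @export
simulateConnection <- function(spec, seed = NULL) {
  stopifnot(is(spec, "CohortSpec"))
  .with_seed(seed, function() {
    conn <- .sample_connection(spec)
    v <- .connection_voltages(conn, spec)
    sweepSet((seq_len(nrow(v)) - 1L) * spec@dtMs, v, spec@protocol,
             groundTruth = list(nRrp = conn$nRrp, params = conn$params,
                                noise = conn$noise, membrane = conn$membrane,
                                lambda = spec@lambda))
  })
}

#' Generate a synthetic cohort with ground truth
#'
#' Generates `spec@nConnections` sweep sets. The realized cohort-mean pool
#' size (mean over all contacts of all connections of `nRrp`) is attached as
#' attribute `realizedMeanNrrp`; it is an unbiased estimate of
#' `1 + spec@lambda`.
#'
#' @param spec a [CohortSpec-class]; `spec@seed` (when not NA) makes the
#'   cohort bit-reproducible.
#' @return list of [SweepSet-class] objects with attribute
#'   `realizedMeanNrrp`.
#' @export
generateCohort <- function(spec) {
  stopifnot(is(spec, "CohortSpec"))
  run <- function() {
    cohort <- lapply(seq_len(spec@nConnections), function(i)
      simulateConnection(spec))
    pools <- unlist(lapply(cohort, function(s) groundTruth(s)$nRrp))
    attr(cohort, "realizedMeanNrrp") <-
      if (length(pools)) mean(pools) else NA_real_
    cohort
  }
  .with_seed(if (is.na(spec@seed)) NULL else spec@seed, run)
}
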