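## Stochastic multi-vesicular generalization of the Tsodyks-Markram synapse.
##
## Deterministic recursion (per spike n, inter-spike interval dt_n):
##   u_1 = U,  R_1 = 1
##   u_{n+1} = U + u_n (1 - U) exp(-dt_n / F)
##   R_{n+1} = 1 + (R_n - R_n u_n - 1) exp(-dt_n / D)
##   A_n = A u_n R_n
## Stochastic counterpart: each of the `ready` vesicles releases independently
## with probability u_n; each empty slot refills independently with
## probability 1 - exp(-dt/D) before release accounting.  By linearity of
## expectation E[ready_n / nRrp] follows the deterministic R_n exactly.

# Run fun() under a temporary seed, restoring the caller's RNG stream.
.with_seed <- function(seed, fun) {
  if (!is.null(seed) && !is.na(seed)) {
    old <- .GlobalEnv$.Random.seed
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = .GlobalEnv))
          rm(".Random.seed", envir = .GlobalEnv)
      } else assign(".Random.seed", old, envir = .GlobalEnv)
    })
    set.seed(as.integer(seed))
  }
  fun()
}

# Inter-spike intervals with Inf prepended for the first spike (full recovery,
# facilitation starts from zero so u jumps to U).
.spike_dts <- function(timesMs) {
  if (length(timesMs) > 1L && any(diff(timesMs) <= 0))
    stop("spike times must be strictly increasing")
  c(Inf, diff(timesMs))
}

# Facilitation sequence u_n for a train; shared by the deterministic and
# stochastic paths.
.u_sequence <- function(U, F, dts) {
  u <- numeric(length(dts))
  prev <- 0
  for (n in seq_along(dts)) {
    prev <- U + prev * (1 - U) * exp(-dts[n] / F)
    u[n] <- prev
  }
  u
}

#' Deterministic Tsodyks-Markram amplitude train
#'
#' Evaluates the deterministic short-term plasticity recursion for a spike
#' train and returns the predicted relative amplitude `A_n = A * u_n * R_n`
#' at each spike, where `u_n` tracks facilitation (recovery time constant `F`)
#' and `R_n` the fraction of available synaptic resources (depression recovery
#' time constant `D`).
#'
#' @param params a [TMParams-class].
#' @param train a [SpikeTrain-class] or numeric vector of strictly increasing
#'   spike times (ms).
#' @return numeric vector of amplitudes `A_n`, one per spike.
#' @examples
#' tmDeterministicTrain(tmParams(U = 0.5, D = 100, F = 1e-6), c(0, 50))
#' @export
tmDeterministicTrain <- function(params, train) {
  stopifnot(is(params, "TMParams"))
  times <- if (is(train, "SpikeTrain")) train@timesMs else as.numeric(train)
  if (length(times) < 1L) stop("at least one spike required")
  dts <- .spike_dts(times)
  u <- .u_sequence(params@U, params@F, dts)
  R <- numeric(length(dts))
  Rprev <- 1
  for (n in seq_along(dts)) {
    if (n > 1L)
      Rprev <- 1 + (Rprev - Rprev * u[n - 1L] - 1) * exp(-dts[n] / params@D)
    R[n] <- Rprev
  }
  params@A * u * R
}

#' Advance one stochastic contact by one spike
#'
#' Performs one event-driven step of the stochastic synapse: the facilitation
#' variable is updated by the deterministic recursion, each empty vesicle slot
#' refills independently with probability `1 - exp(-dtMs/D)`, and each ready
#' vesicle then releases independently with probability `u`. Use `dtMs = Inf`
#' for the first spike of a train (full pool, `u` jumps to `U`).
#'
#' @param contact a [SynapticContact-class].
#' @param dtMs time since the previous spike (ms), >= 0 or Inf.
#' @param seed optional integer seed (the caller's RNG stream is restored).
#' @return list with elements `contact` (updated state after release) and
#'   `released` (integer vesicle count).
#' @export
advanceContact <- function(contact, dtMs, seed = NULL) {
  stopifnot(is(contact, "SynapticContact"), dtMs >= 0)
  .with_seed(seed, function() {
    p <- contact@params
    u <- p@U + contact@u * (1 - p@U) * exp(-dtMs / p@F)
    empty <- contact@nRrp - contact@ready
    refill <- stats::rbinom(1L, empty, 1 - exp(-dtMs / p@D))
    ready <- contact@ready + refill
    released <- stats::rbinom(1L, ready, u)
    contact@ready <- as.integer(ready - released)
    contact@u <- u
    validObject(contact)
    list(contact = contact, released = as.integer(released))
  })
}

#' Simulate one stochastic trial of a multi-contact connection
#'
#' Runs every contact independently through the spike train and collects the
#' per-spike released vesicle counts and total quantal conductance. Each
#' released vesicle at contact `j` contributes `gMax_j / nRrp_j` nS, so the
#' mean first-response conductance is independent of the pool size at fixed
#' `gMax`, while its variance decreases with the pool size.
#'
#' @param contacts list of [SynapticContact-class] objects in their resting
#'   state (all vesicles ready, `u = 0`).
#' @param train a [SpikeTrain-class] or numeric spike times (ms).
#' @param seed optional integer seed.
#' @return A [ReleaseEventSeries-class].
#' @export
simulateConnectionEvents <- function(contacts, train, seed = NULL) {
  times <- if (is(train, "SpikeTrain")) train@timesMs else as.numeric(train)
  dts <- .spike_dts(times)
  nC <- length(contacts)
  .with_seed(seed, function() {
    released <- matrix(0L, nrow = nC, ncol = length(times))
    for (j in seq_len(nC)) {
      ct <- contacts[[j]]
      for (n in seq_along(dts)) {
        step <- advanceContact(ct, dts[n])
        ct <- step$contact
        released[j, n] <- step$released
      }
    }
    nRrp <- vapply(contacts, function(ct) ct@nRrp, integer(1))
    gMax <- vapply(contacts, function(ct) ct@params@gMax, numeric(1))
    cond <- if (nC) colSums(released * (gMax / nRrp)) else numeric(length(times))
    new("ReleaseEventSeries", spikeTimesMs = times, released = released,
        conductanceNs = cond, nRrp = nRrp, gMax = gMax)
  })
}

# Vectorized stochastic release for one connection: all sweeps at once.
# nRrp: integer vector (one per contact); params shared across contacts.
# Returns the per-spike total conductance matrix [nSpikes x nSweeps] (nS).
.releaseConductances <- function(nRrp, params, spikeTimesMs, nSweeps) {
  dts <- .spike_dts(spikeTimesMs)
  u <- .u_sequence(params@U, params@F, dts)
  nC <- length(nRrp)
  nS <- length(dts)
  cond <- matrix(0, nS, nSweeps)
  if (nC == 0L) return(cond)
  quantal <- params@gMax / nRrp                     # per-vesicle conductance
  pool <- matrix(rep(nRrp, nSweeps), nC, nSweeps)   # full pool per sweep
  ready <- pool                                     # resting state
  nCell <- nC * nSweeps
  for (n in seq_len(nS)) {
    pRefill <- 1 - exp(-dts[n] / params@D)
    if (pRefill > 0) {
      ready <- ready + stats::rbinom(nCell, pool - ready, pRefill)
      dim(ready) <- dim(pool)
    }
    rel <- stats::rbinom(nCell, ready, u[n])
    dim(rel) <- dim(pool)
    ready <- ready - rel
    cond[n, ] <- colSums(rel * quantal)
  }
  cond
}

#' Write / read release events as JSON
#'
#' Lossless JSON serialization of a [ReleaseEventSeries-class] for debugging
#' and fixtures.
#'
#' @param events a [ReleaseEventSeries-class].
#' @param path file path.
#' @return `readReleaseEvents` returns a [ReleaseEventSeries-class];
#'   `writeReleaseEvents` returns `path` invisibly.
#' @export
writeReleaseEvents <- function(events, path) {
  stopifnot(is(events, "ReleaseEventSeries"))
  jsonlite::write_json(list(
    spike_times_ms = events@spikeTimesMs,
    released = events@released,
    conductance_ns = events@conductanceNs,
    n_rrp = events@nRrp,
    g_max_ns = events@gMax), path, digits = NA)
  invisible(path)
}

#' @rdname writeReleaseEvents
#' @export
readReleaseEvents <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rel <- matrix(as.integer(x$released), nrow = length(x$n_rrp))
  new("ReleaseEventSeries", spikeTimesMs = as.numeric(x$spike_times_ms),
      released = rel, conductanceNs = as.numeric(x$conductance_ns),
      nRrp = as.integer(x$n_rrp), gMax = as.numeric(x$g_max_ns))
}
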