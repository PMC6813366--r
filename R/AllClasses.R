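#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core parameter containers
## ---------------------------------------------------------------------------

#' Tsodyks-Markram synapse parameters
#'
#' Container for the four short-term plasticity parameters plus the maximal
#' conductance of one synaptic contact. `U` is the fraction of synaptic
#' resources used by a single spike, `D` the depression recovery time constant
#' (ms), `F` the facilitation recovery time constant (ms), `A` the absolute
#' synaptic efficacy (fixed to 1 for normalized fits) and `gMax` the maximal
#' conductance per contact (nS). With a pool of `nRrp` vesicles each released
#' vesicle contributes a quantal conductance `gMax / nRrp`.
#'
#' @slot U numeric, release fraction in \[0, 1\].
#' @slot D numeric, depression recovery time constant (ms), > 0.
#' @slot F numeric, facilitation recovery time constant (ms), > 0.
#' @slot A numeric, absolute efficacy (unitless).
#' @slot gMax numeric, maximal conductance per contact (nS), >= 0.
#' @export
setClass("TMParams",
  slots = c(U = "numeric", D = "numeric", F = "numeric",
            A = "numeric", gMax = "numeric"),
  prototype = prototype(U = 0.38, D = 365.6, F = 25.71, A = 1, gMax = 1.5))

setValidity("TMParams", function(object) {
  msg <- character()
  for (s in c("U", "D", "F", "A", "gMax")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, sprintf("%s must be a finite scalar", s))
  }
  if (length(msg) == 0L) {
    if (object@U < 0 || object@U > 1) msg <- c(msg, "U must lie in [0, 1]")
    if (object@D <= 0) msg <- c(msg, "D must be > 0")
    if (object@F <= 0) msg <- c(msg, "F must be > 0")
    if (object@gMax < 0) msg <- c(msg, "gMax must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct TMParams
#'
#' @param U release fraction in \[0, 1\].
#' @param D depression recovery time constant (ms).
#' @param F facilitation recovery time constant (ms).
#' @param A absolute synaptic efficacy; 1 for normalized fitting.
#' @param gMax maximal conductance per contact (nS).
#' @return A [TMParams-class] object.
#' @examples
#' tmParams(U = 0.5, D = 100, F = 10)
#' @export
tmParams <- function(U = 0.38, D = 365.6, F = 25.71, A = 1, gMax = 1.5) {
  new("TMParams", U = as.numeric(U), D = as.numeric(D), F = as.numeric(F),
      A = as.numeric(A), gMax = as.numeric(gMax))
}

setMethod("show", "TMParams", function(object) {
  cat(sprintf("TMParams: U = %.3f, D = %.1f ms, F = %.2f ms, A = %.2f, gMax = %.3f nS\n",
              object@U, object@D, object@F, object@A, object@gMax))
})

## ---------------------------------------------------------------------------
## Stimulation protocol and spike trains
## ---------------------------------------------------------------------------

#' Stimulation protocol
#'
#' The paired-recording stimulation protocol: a train of `nPulses` presynaptic
#' pulses at `frequencyHz`, followed by one recovery pulse `recoveryDelayMs`
#' after the last train pulse. `onsetMs` is the pre-stimulus baseline length at
#' the start of each sweep.
#'
#' @slot nPulses integer, pulses in the train (default 8).
#' @slot frequencyHz numeric, train frequency (default 20 Hz).
#' @slot recoveryDelayMs numeric, delay of the recovery pulse after the last
#'   train pulse (default 500 ms).
#' @slot onsetMs numeric, baseline before the first pulse (ms).
#' @export
setClass("StimulusProtocol",
  slots = c(nPulses = "integer", frequencyHz = "numeric",
            recoveryDelayMs = "numeric", onsetMs = "numeric"),
  prototype = prototype(nPulses = 8L, frequencyHz = 20,
                        recoveryDelayMs = 500, onsetMs = 100))

setValidity("StimulusProtocol", function(object) {
  msg <- character()
  if (object@nPulses < 1L) msg <- c(msg, "nPulses must be >= 1")
  if (object@frequencyHz <= 0) msg <- c(msg, "frequencyHz must be > 0")
  if (object@recoveryDelayMs <= 0) msg <- c(msg, "recoveryDelayMs must be > 0")
  if (object@onsetMs < 0) msg <- c(msg, "onsetMs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a stimulation protocol
#'
#' Defaults describe the standard depression protocol: 8 pulses at 20 Hz plus
#' a recovery pulse 500 ms later.
#'
#' @param nPulses pulses in the train.
#' @param frequencyHz train frequency in Hz.
#' @param recoveryDelayMs recovery-pulse delay after the last train pulse (ms).
#' @param onsetMs pre-stimulus baseline (ms).
#' @return A [StimulusProtocol-class] object.
#' @export
stimulusProtocol <- function(nPulses = 8L, frequencyHz = 20,
                             recoveryDelayMs = 500, onsetMs = 100) {
  new("StimulusProtocol", nPulses = as.integer(nPulses),
      frequencyHz = as.numeric(frequencyHz),
      recoveryDelayMs = as.numeric(recoveryDelayMs), onsetMs = as.numeric(onsetMs))
}

setMethod("show", "StimulusProtocol", function(object) {
  cat(sprintf("StimulusProtocol: %d pulses @ %g Hz + recovery after %g ms (onset %g ms)\n",
              object@nPulses, object@frequencyHz, object@recoveryDelayMs, object@onsetMs))
})

#' Presynaptic spike train
#'
#' Strictly increasing spike times in ms.
#'
#' @slot timesMs numeric vector of spike times (ms), strictly increasing.
#' @export
setClass("SpikeTrain", slots = c(timesMs = "numeric"))

setValidity("SpikeTrain", function(object) {
  t <- object@timesMs
  if (length(t) < 1L) return("at least one spike time required")
  if (any(!is.finite(t))) return("spike times must be finite")
  if (length(t) > 1L && any(diff(t) <= 0)) return("spike times must be strictly increasing")
  TRUE
})

#' Construct a spike train
#' @param timesMs strictly increasing spike times (ms).
#' @return A [SpikeTrain-class] object.
#' @export
spikeTrain <- function(timesMs) new("SpikeTrain", timesMs = as.numeric(timesMs))

## ---------------------------------------------------------------------------
## Stochastic synapse state and release events
## ---------------------------------------------------------------------------

#' One synaptic contact of the stochastic synapse model
#'
#' Holds the vesicle pool size `nRrp`, the number of vesicles currently in the
#' ready state, the running facilitation variable `u`, and the TM parameters.
#'
#' @slot nRrp integer >= 1, readily releasable pool size.
#' @slot ready integer in \[0, nRrp\], vesicles currently releasable.
#' @slot u numeric in \[0, 1\], running facilitation variable.
#' @slot params [TMParams-class].
#' @export
setClass("SynapticContact",
  slots = c(nRrp = "integer", ready = "integer", u = "numeric", params = "TMParams"))

setValidity("SynapticContact", function(object) {
  msg <- character()
  if (object@nRrp < 1L) msg <- c(msg, "nRrp must be >= 1")
  if (object@ready < 0L || object@ready > object@nRrp)
    msg <- c(msg, "ready must lie in [0, nRrp]")
  if (object@u < 0 || object@u > 1) msg <- c(msg, "u must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a synaptic contact in its resting state
#'
#' A fresh contact has all vesicles ready and facilitation at zero (the
#' facilitation variable jumps to `U` at the first spike).
#'
#' @param nRrp pool size (integer >= 1).
#' @param params [TMParams-class] for this contact.
#' @return A [SynapticContact-class] object.
#' @export
synapticContact <- function(nRrp, params = tmParams()) {
  new("SynapticContact", nRrp = as.integer(nRrp), ready = as.integer(nRrp),
      u = 0, params = params)
}

#' Release events of one stochastic trial
#'
#' Per spike and per contact, the number of vesicles released, plus the summed
#' quantal conductance per spike. Each released vesicle contributes
#' `gMax / nRrp` nS of conductance.
#'
#' @slot spikeTimesMs numeric, spike times (ms).
#' @slot released integer matrix, contacts x spikes.
#' @slot conductanceNs numeric, per-spike total conductance (nS).
#' @slot nRrp integer vector, pool size per contact.
#' @slot gMax numeric vector, maximal conductance per contact (nS).
#' @export
setClass("ReleaseEventSeries",
  slots = c(spikeTimesMs = "numeric", released = "matrix",
            conductanceNs = "numeric", nRrp = "integer", gMax = "numeric"))

setValidity("ReleaseEventSeries", function(object) {
  msg <- character()
  if (nrow(object@released) != length(object@nRrp))
    msg <- c(msg, "released must have one row per contact")
  if (ncol(object@released) != length(object@spikeTimesMs))
    msg <- c(msg, "released must have one column per spike")
  if (length(object@conductanceNs) != length(object@spikeTimesMs))
    msg <- c(msg, "conductanceNs must have one value per spike")
  if (length(object@nRrp) && any(object@released > object@nRrp))
    msg <- c(msg, "released cannot exceed nRrp")
  if (length(msg) == 0L && length(object@nRrp)) {
    expect <- colSums(object@released * (object@gMax / object@nRrp))
    if (max(abs(expect - object@conductanceNs)) > 1e-9)
      msg <- c(msg, "conductanceNs inconsistent with released counts")
  }
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Membrane, noise, sweeps
## ---------------------------------------------------------------------------

#' Passive membrane model
#'
#' Linear RC membrane used to turn synaptic conductance events into voltage.
#' The synaptic drive is current-based with fixed driving force
#' `eRevMv - vRestMv`, so superposition holds exactly and the voltage
#' deconvolution operator is its exact inverse.
#'
#' @slot tauMemMs membrane time constant (ms).
#' @slot rInputMOhm input resistance (MOhm).
#' @slot vRestMv resting potential (mV).
#' @slot tauSynMs synaptic conductance decay time constant (ms).
#' @slot eRevMv synaptic reversal potential (mV).
#' @export
setClass("MembraneModel",
  slots = c(tauMemMs = "numeric", rInputMOhm = "numeric", vRestMv = "numeric",
            tauSynMs = "numeric", eRevMv = "numeric"),
  prototype = prototype(tauMemMs = 28.2, rInputMOhm = 59.7, vRestMv = -65.3,
                        tauSynMs = 1.7, eRevMv = 0))

setValidity("MembraneModel", function(object) {
  msg <- character()
  if (object@tauSynMs <= 0) msg <- c(msg, "tauSynMs must be > 0")
  if (object@tauMemMs <= object@tauSynMs) msg <- c(msg, "tauMemMs must exceed tauSynMs")
  if (object@rInputMOhm <= 0) msg <- c(msg, "rInputMOhm must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a passive membrane model
#'
#' Defaults follow somatic whole-cell measurements from juvenile rat L5
#' thick-tufted pyramidal cells: resting potential -65.3 mV, input resistance
#' 59.7 MOhm, membrane time constant 28.2 ms, and an AMPA-like rapid synaptic
#' decay of 1.7 ms.
#'
#' @param tauMemMs membrane time constant (ms).
#' @param rInputMOhm input resistance (MOhm).
#' @param vRestMv resting potential (mV).
#' @param tauSynMs synaptic decay time constant (ms).
#' @param eRevMv synaptic reversal potential (mV).
#' @return A [MembraneModel-class] object.
#' @export
membraneModel <- function(tauMemMs = 28.2, rInputMOhm = 59.7, vRestMv = -65.3,
                          tauSynMs = 1.7, eRevMv = 0) {
  new("MembraneModel", tauMemMs = as.numeric(tauMemMs),
      rInputMOhm = as.numeric(rInputMOhm), vRestMv = as.numeric(vRestMv),
      tauSynMs = as.numeric(tauSynMs), eRevMv = as.numeric(eRevMv))
}

#' Ornstein-Uhlenbeck noise parameters
#'
#' Stationary standard deviation `sigmaMv` (mV) and correlation time `tauMs`
#' (ms) of the Gaussian, exponentially correlated membrane-voltage noise.
#'
#' @slot sigmaMv numeric >= 0 (mV).
#' @slot tauMs numeric > 0 (ms).
#' @export
setClass("NoiseParams",
  slots = c(sigmaMv = "numeric", tauMs = "numeric"),
  prototype = prototype(sigmaMv = 0.22, tauMs = 28.2))

setValidity("NoiseParams", function(object) {
  msg <- character()
  if (object@sigmaMv < 0) msg <- c(msg, "sigmaMv must be >= 0")
  if (object@tauMs <= 0) msg <- c(msg, "tauMs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct OU noise parameters
#' @param sigmaMv stationary noise SD (mV); default the calibrated 0.22 mV.
#' @param tauMs correlation time (ms); default the calibrated 28.2 ms.
#' @return A [NoiseParams-class] object.
#' @export
noiseParams <- function(sigmaMv = 0.22, tauMs = 28.2) {
  new("NoiseParams", sigmaMv = as.numeric(sigmaMv), tauMs = as.numeric(tauMs))
}

#' A set of voltage sweeps from one connection
#'
#' Voltage sweeps (repetitions of the stimulation protocol) on one uniform
#' time grid, with the protocol and, for synthetic data, the generating ground
#' truth (per-contact pool sizes, TM parameters, membrane and noise models).
#'
#' @slot timeMs numeric, uniform time grid (ms).
#' @slot voltageMv numeric matrix, samples x sweeps (mV).
#' @slot protocol [StimulusProtocol-class].
#' @slot groundTruth list, empty for real recordings.
#' @export
setClass("SweepSet",
  slots = c(timeMs = "numeric", voltageMv = "matrix",
            protocol = "StimulusProtocol", groundTruth = "list"))

setValidity("SweepSet", function(object) {
  msg <- character()
  if (length(object@timeMs) != nrow(object@voltageMv))
    msg <- c(msg, "timeMs length must equal nrow(voltageMv)")
  if (length(object@timeMs) > 1L) {
    dt <- diff(object@timeMs)
    if (any(dt <= 0) || (max(dt) - min(dt)) > 1e-6 * max(dt))
      msg <- c(msg, "time grid must be uniform and increasing")
  }
  if (any(!is.finite(object@voltageMv))) msg <- c(msg, "voltage samples must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a SweepSet
#' @param timeMs uniform time grid (ms).
#' @param voltageMv samples x sweeps voltage matrix (mV).
#' @param protocol the [StimulusProtocol-class] used.
#' @param groundTruth optional list of generating parameters.
#' @return A [SweepSet-class] object.
#' @export
sweepSet <- function(timeMs, voltageMv, protocol = stimulusProtocol(),
                     groundTruth = list()) {
  new("SweepSet", timeMs = as.numeric(timeMs),
      voltageMv = as.matrix(voltageMv), protocol = protocol,
      groundTruth = groundTruth)
}

setMethod("show", "SweepSet", function(object) {
  cat(sprintf("SweepSet: %d sweeps x %d samples (dt = %.4g ms, %.1f ms)\n",
              ncol(object@voltageMv), nrow(object@voltageMv),
              if (length(object@timeMs) > 1) diff(object@timeMs[1:2]) else NA_real_,
              max(object@timeMs)))
  show(object@protocol)
  if (length(object@groundTruth))
    cat("  with ground truth:", paste(names(object@groundTruth), collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## CV statistics and estimation results
## ---------------------------------------------------------------------------

#' Per-pulse coefficient-of-variation profile
#'
#' CV of the EPSP amplitude at each pulse of the protocol, with the mean
#' amplitudes it was computed from. With `jackknife = TRUE` the amplitudes are
#' measured on leave-one-out average traces and the SD is rescaled by
#' `sqrt((N - 1) * sum((A_i - Abar)^2))`, which reproduces the plain sample CV
#' exactly for amplitudes that are linear in the sweeps.
#'
#' @slot cv numeric, per-pulse CV (NA where the mean amplitude is ~0).
#' @slot meanAmplitudeMv numeric, per-pulse mean amplitude (mV).
#' @slot nSweeps integer, sweeps used.
#' @slot jackknife logical.
#' @export
setClass("CVProfile",
  slots = c(cv = "numeric", meanAmplitudeMv = "numeric",
            nSweeps = "integer", jackknife = "logical"))

setValidity("CVProfile", function(object) {
  msg <- character()
  if (length(object@cv) != length(object@meanAmplitudeMv))
    msg <- c(msg, "cv and meanAmplitudeMv must have equal length")
  if (any(object@cv < 0, na.rm = TRUE)) msg <- c(msg, "cv must be >= 0")
  if (object@nSweeps < 2L) msg <- c(msg, "nSweeps must be >= 2")
  if (length(msg)) msg else TRUE
})

setMethod("show", "CVProfile", function(object) {
  cat(sprintf("CVProfile (%s, N = %d sweeps):\n",
              if (object@jackknife) "jackknife" else "plain", object@nSweeps))
  print(round(stats::setNames(object@cv, paste0("p", seq_along(object@cv))), 3))
})

#' Power-law fit CV = a * N^b
#'
#' @slot amplitude numeric, coefficient a (> 0).
#' @slot index numeric, exponent b.
#' @slot residual numeric, residual sum of squares on the log scale.
#' @export
setClass("PowerLawFit",
  slots = c(amplitude = "numeric", index = "numeric", residual = "numeric"))

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf("PowerLawFit: CV = %.3f * N^(%.3f)  [log-scale RSS %.3g]\n",
              object@amplitude, object@index, object@residual))
})

#' Result of a pool-size estimation scan
#'
#' The error curve over the shifted-Poisson rate grid, the per-iteration
#' recovered pool sizes, and their mean and SD. `recoveredPerIteration` holds
#' the realized cohort-mean pool size of the best-matching cohort at each
#' iteration; `argminLambda` the corresponding rate.
#'
#' @slot lambdaGrid numeric, scanned shifted-Poisson rates.
#' @slot meanError numeric, mean matching error per rate.
#' @slot argminLambda numeric, per-iteration best rate.
#' @slot recoveredPerIteration numeric, per-iteration realized mean pool size.
#' @slot nrrpMean numeric.
#' @slot nrrpSd numeric.
#' @slot iterations integer.
#' @slot boundary logical, TRUE when the best match sat on the grid edge.
#' @export
setClass("EstimationResult",
  slots = c(lambdaGrid = "numeric", meanError = "numeric",
            argminLambda = "numeric", recoveredPerIteration = "numeric",
            nrrpMean = "numeric", nrrpSd = "numeric",
            iterations = "integer", boundary = "logical"))

setValidity("EstimationResult", function(object) {
  msg <- character()
  if (length(object@meanError) != length(object@lambdaGrid))
    msg <- c(msg, "meanError must match lambdaGrid length")
  if (any(object@meanError < 0, na.rm = TRUE)) msg <- c(msg, "errors must be >= 0")
  if (any(object@lambdaGrid < 0 | object@lambdaGrid > 13))
    msg <- c(msg, "lambdaGrid must lie within [0, 13]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EstimationResult", function(object) {
  cat(sprintf("EstimationResult: N_RRP = %.2f +/- %.2f (%d iterations)%s\n",
              object@nrrpMean, object@nrrpSd, object@iterations,
              if (isTRUE(object@boundary)) " [boundary]" else ""))
  cat("  error minimum at lambda =",
      object@lambdaGrid[which.min(object@meanError)], "\n")
})

#' Affine map from plain CV to jackknife CV
#'
#' Linear fit of the jackknife first-pulse CV on the plain first-pulse CV
#' across simulated pool-size levels, used to transform literature CV values
#' before pool-size matching.
#'
#' @slot slope numeric.
#' @slot intercept numeric.
#' @slot se numeric, residual standard error of the fit.
#' @export
setClass("LinearCVMap",
  slots = c(slope = "numeric", intercept = "numeric", se = "numeric"))

setMethod("show", "LinearCVMap", function(object) {
  cat(sprintf("LinearCVMap: cv_jkk = %.3f * cv + %.3f (SE %.3g)\n",
              object@slope, object@intercept, object@se))
})

## ---------------------------------------------------------------------------
## Cohort specification
## ---------------------------------------------------------------------------

#' Population distributions of synaptic parameters
#'
#' Cohort-level sampling distributions: U truncated-normal on \[0, 1\],
#' D and F gamma (parameterized by mean and SD; internally shape =
#' (mean/sd)^2, scale = sd^2/mean), contact counts uniform on an integer
#' range, and a common maximal conductance scale.
#'
#' @slot uMean,uSd numeric, truncated normal for U.
#' @slot dMeanMs,dSdMs numeric, gamma for D (ms).
#' @slot fMeanMs,fSdMs numeric, gamma for F (ms).
#' @slot contactRange integer length-2, inclusive range of contacts per
#'   connection, within \[1, 20\].
#' @slot gMaxNs numeric, maximal conductance per contact (nS).
#' @export
setClass("ParamDistributions",
  slots = c(uMean = "numeric", uSd = "numeric", dMeanMs = "numeric",
            dSdMs = "numeric", fMeanMs = "numeric", fSdMs = "numeric",
            contactRange = "integer", gMaxNs = "numeric"),
  prototype = prototype(uMean = 0.38, uSd = 0.1, dMeanMs = 365.6, dSdMs = 100.15,
                        fMeanMs = 25.71, fSdMs = 45.87,
                        contactRange = c(4L, 8L), gMaxNs = 1.5))

setValidity("ParamDistributions", function(object) {
  msg <- character()
  pos <- c(uSd = object@uSd, dMean = object@dMeanMs, dSd = object@dSdMs,
           fMean = object@fMeanMs, fSd = object@fSdMs)
  if (any(pos <= 0)) msg <- c(msg, "distribution means/SDs must be positive")
  cr <- object@contactRange
  if (length(cr) != 2L || cr[1] > cr[2] || cr[1] < 1L || cr[2] > 20L)
    msg <- c(msg, "contactRange must be an increasing integer pair within [1, 20]")
  if (object@gMaxNs < 0) msg <- c(msg, "gMaxNs must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct population parameter distributions
#'
#' Defaults are the fitted L5 thick-tufted pyramidal population values:
#' U ~ normal(0.38, 0.1) truncated to \[0, 1\], D ~ gamma(365.6, 100.15) ms,
#' F ~ gamma(25.71, 45.87) ms, 4-8 contacts per connection.
#'
#' @param uMean,uSd truncated-normal parameters for U.
#' @param dMeanMs,dSdMs gamma mean and SD for D (ms).
#' @param fMeanMs,fSdMs gamma mean and SD for F (ms).
#' @param contactRange inclusive integer range of contacts per connection.
#' @param gMaxNs maximal conductance per contact (nS).
#' @return A [ParamDistributions-class] object.
#' @export
paramDistributions <- function(uMean = 0.38, uSd = 0.1,
                               dMeanMs = 365.6, dSdMs = 100.15,
                               fMeanMs = 25.71, fSdMs = 45.87,
                               contactRange = c(4L, 8L), gMaxNs = 1.5) {
  new("ParamDistributions", uMean = as.numeric(uMean), uSd = as.numeric(uSd),
      dMeanMs = as.numeric(dMeanMs), dSdMs = as.numeric(dSdMs),
      fMeanMs = as.numeric(fMeanMs), fSdMs = as.numeric(fSdMs),
      contactRange = as.integer(contactRange), gMaxNs = as.numeric(gMaxNs))
}

#' Specification of a synthetic cohort
#'
#' Everything needed to generate a cohort of connections with known ground
#' truth: the shifted-Poisson rate `lambda` (per-contact pool size is
#' 1 + Poisson(lambda)), the cohort size, sweeps per connection, protocol,
#' membrane model, noise model, parameter distributions, sampling step and
#' seed.
#'
#' @slot lambda numeric in \[0, 13\].
#' @slot nConnections integer >= 0.
#' @slot nSweeps integer >= 2.
#' @slot protocol [StimulusProtocol-class].
#' @slot membrane [MembraneModel-class].
#' @slot noise [NoiseParams-class].
#' @slot distributions [ParamDistributions-class].
#' @slot dtMs numeric, sampling step (ms).
#' @slot seed integer, RNG seed (NA for "leave RNG stream alone").
#' @slot perContactParams logical; when TRUE each contact draws its own
#'   U/D/F instead of sharing one draw per connection (default FALSE — the
#'   fitting pipeline recovers one triplet per connection).
#' @export
setClass("CohortSpec",
  slots = c(lambda = "numeric", nConnections = "integer", nSweeps = "integer",
            protocol = "StimulusProtocol", membrane = "MembraneModel",
            noise = "NoiseParams", distributions = "ParamDistributions",
            dtMs = "numeric", seed = "integer",
            perContactParams = "logical"),
  prototype = prototype(perContactParams = FALSE))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@lambda < 0 || object@lambda > 13)
    msg <- c(msg, "lambda must lie in [0, 13]")
  if (object@nConnections < 0L) msg <- c(msg, "nConnections must be >= 0")
  if (object@nSweeps < 2L) msg <- c(msg, "nSweeps must be >= 2")
  if (object@dtMs <= 0) msg <- c(msg, "dtMs must be > 0")
  if (object@dtMs >= object@membrane@tauSynMs)
    msg <- c(msg, "dtMs must resolve the synaptic decay (dtMs < tauSynMs)")
  if (length(msg)) msg else TRUE
})

#' Construct a cohort specification
#'
#' @param lambda shifted-Poisson rate; per-contact pool size is
#'   `1 + Poisson(lambda)`.
#' @param nConnections connections in the cohort.
#' @param nSweeps protocol repetitions per connection (default 20).
#' @param protocol,membrane,noise,distributions component models.
#' @param dtMs sampling step (ms); default 0.1 ms (10 kHz).
#' @param seed integer RNG seed or NA to use the current RNG stream.
#' @param perContactParams draw U/D/F per contact instead of per connection.
#' @return A [CohortSpec-class] object.
#' @export
cohortSpec <- function(lambda = 2.78, nConnections = 100L, nSweeps = 20L,
                       protocol = stimulusProtocol(), membrane = membraneModel(),
                       noise = noiseParams(), distributions = paramDistributions(),
                       dtMs = 0.1, seed = NA_integer_,
                       perContactParams = FALSE) {
  new("CohortSpec", lambda = as.numeric(lambda),
      nConnections = as.integer(nConnections), nSweeps = as.integer(nSweeps),
      protocol = protocol, membrane = membrane, noise = noise,
      distributions = distributions, dtMs = as.numeric(dtMs),
      seed = as.integer(seed),
      perContactParams = isTRUE(perContactParams))
}

setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d connections x %d sweeps, lambda = %.2f (mean pool %.2f)\n",
              object@nConnections, object@nSweeps, object@lambda, 1 + object@lambda))
})

#' Genetic-algorithm configuration for TM parameter fitting
#'
#' Search ranges follow the standard fitting convention: U in \[0, 1\],
#' D in \[0, 1000\] ms, F in \[0, 2000\] ms.
#'
#' @slot generations integer, generations per run (default 500).
#' @slot restarts integer, independent runs; the best is kept (default 50).
#' @slot popSize integer, population size.
#' @slot tournamentSize integer, tournament selection size.
#' @slot crossoverRate numeric, per-pair uniform crossover probability.
#' @slot mutationRate numeric, per-gene mutation probability.
#' @slot mutationSdFrac numeric, Gaussian mutation SD as a fraction of range.
#' @slot elitism integer, elites copied unchanged each generation.
#' @slot ranges numeric matrix 2 x 3 (rows lo/hi; columns U, D, F).
#' @export
setClass("GAConfig",
  slots = c(generations = "integer", restarts = "integer", popSize = "integer",
            tournamentSize = "integer", crossoverRate = "numeric",
            mutationRate = "numeric", mutationSdFrac = "numeric",
            elitism = "integer", ranges = "matrix"))

setValidity("GAConfig", function(object) {
  msg <- character()
  if (object@generations < 1L) msg <- c(msg, "generations must be >= 1")
  if (object@restarts < 1L) msg <- c(msg, "restarts must be >= 1")
  if (object@popSize < 4L) msg <- c(msg, "popSize must be >= 4")
  if (!all(dim(object@ranges) == c(2L, 3L))) msg <- c(msg, "ranges must be 2 x 3")
  else if (any(object@ranges[1, ] >= object@ranges[2, ]))
    msg <- c(msg, "range lower bounds must be below upper bounds")
  if (length(msg)) msg else TRUE
})

#' Construct a GA configuration
#'
#' @param generations generations per GA run.
#' @param restarts independent GA runs (best-of-restarts is returned).
#' @param popSize population size.
#' @param tournamentSize tournament selection size.
#' @param crossoverRate uniform crossover probability.
#' @param mutationRate per-gene Gaussian mutation probability.
#' @param mutationSdFrac mutation SD as a fraction of each parameter range.
#' @param elitism number of elites kept unchanged.
#' @param uRange,dRange,fRange search ranges for U, D (ms), F (ms).
#' @return A [GAConfig-class] object.
#' @export
gaConfig <- function(generations = 500L, restarts = 50L, popSize = 100L,
                     tournamentSize = 3L, crossoverRate = 0.7,
                     mutationRate = 0.2, mutationSdFrac = 0.05, elitism = 1L,
                     uRange = c(0, 1), dRange = c(0, 1000), fRange = c(0, 2000)) {
  ranges <- cbind(U = uRange, D = dRange, F = fRange)
  rownames(ranges) <- c("lo", "hi")
  new("GAConfig", generations = as.integer(generations),
      restarts = as.integer(restarts), popSize = as.integer(popSize),
      tournamentSize = as.integer(tournamentSize),
      crossoverRate = as.numeric(crossoverRate),
      mutationRate = as.numeric(mutationRate),
      mutationSdFrac = as.numeric(mutationSdFrac),
      elitism = as.integer(elitism), ranges = ranges)
}
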