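#' Pulse times of a protocol
#'
#' Times (ms) of all presynaptic pulses, train pulses first, recovery pulse
#' last.
#'
#' @param x a [StimulusProtocol-class].
#' @return numeric vector of pulse times (ms).
#' @export
setGeneric("pulseTimes", function(x) standardGeneric("pulseTimes"))

#' @rdname pulseTimes
setMethod("pulseTimes", "StimulusProtocol", function(x) {
  isi <- 1000 / x@frequencyHz
  train <- x@onsetMs + (seq_len(x@nPulses) - 1L) * isi
  c(train, train[x@nPulses] + x@recoveryDelayMs)
})

#' Default sweep duration for a protocol
#'
#' Recovery pulse time plus the 300 ms recovery-response window plus a 50 ms
#' tail.
#'
#' @param x a [StimulusProtocol-class].
#' @return duration in ms.
#' @export
setGeneric("sweepDurationMs", function(x) standardGeneric("sweepDurationMs"))

#' @rdname sweepDurationMs
setMethod("sweepDurationMs", "StimulusProtocol", function(x) {
  max(pulseTimes(x)) + 300 + 50
})

#' Number of sweeps
#' @param x a [SweepSet-class].
#' @return integer.
#' @export
setGeneric("nSweeps", function(x) standardGeneric("nSweeps"))

#' @rdname nSweeps
setMethod("nSweeps", "SweepSet", function(x) ncol(x@voltageMv))

#' Voltage matrix of a sweep set
#' @param x a [SweepSet-class].
#' @return numeric matrix, samples x sweeps (mV).
#' @export
setGeneric("sweepVoltages", function(x) standardGeneric("sweepVoltages"))

#' @rdname sweepVoltages
setMethod("sweepVoltages", "SweepSet", function(x) x@voltageMv)

#' Time grid of a sweep set
#' @param x a [SweepSet-class].
#' @return numeric vector (ms).
#' @export
setGeneric("sweepTimes", function(x) standardGeneric("sweepTimes"))

#' @rdname sweepTimes
setMethod("sweepTimes", "SweepSet", function(x) x@timeMs)

#' Ground truth of a synthetic sweep set
#' @param x a [SweepSet-class].
#' @return list (empty for real recordings).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))

#' @rdname groundTruth
setMethod("groundTruth", "SweepSet", function(x) x@groundTruth)

#' Per-pulse CV values
#' @param x a [CVProfile-class].
#' @return numeric vector of CVs.
#' @export
setGeneric("cvValues", function(x) standardGeneric("cvValues"))

#' @rdname cvValues
setMethod("cvValues", "CVProfile", function(x) x@cv)

#' Per-pulse mean amplitudes
#' @param x a [CVProfile-class].
#' @return numeric vector (mV).
#' @export
setGeneric("meanAmplitudes", function(x) standardGeneric("meanAmplitudes"))

#' @rdname meanAmplitudes
setMethod("meanAmplitudes", "CVProfile", function(x) x@meanAmplitudeMv)

#' Recovered pool size of an estimation
#' @param x an [EstimationResult-class].
#' @return named numeric: mean and sd.
#' @export
setGeneric("nrrpEstimate", function(x) standardGeneric("nrrpEstimate"))

#' @rdname nrrpEstimate
setMethod("nrrpEstimate", "EstimationResult", function(x) {
  c(mean = x@nrrpMean, sd = x@nrrpSd)
})

#' Error curve of an estimation scan
#' @param x an [EstimationResult-class].
#' @return data.frame with columns `lambda`, `meanNrrp`, `error`.
#' @export
setGeneric("errorCurve", function(x) standardGeneric("errorCurve"))

#' @rdname errorCurve
setMethod("errorCurve", "EstimationResult", function(x) {
  data.frame(lambda = x@lambdaGrid, meanNrrp = 1 + x@lambdaGrid,
             error = x@meanError)
})
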