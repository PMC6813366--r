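# Shared fixtures, all generated in code.

# Small cohort specification for fast unit tests.
quick_spec <- function(lambda = 3, nConnections = 5L, nSweeps = 10L,
                       sigmaMv = 0.22, seed = NA_integer_, gMaxNs = 1.5) {
  cohortSpec(lambda = lambda, nConnections = nConnections, nSweeps = nSweeps,
             noise = noiseParams(sigmaMv), seed = seed,
             distributions = paramDistributions(gMaxNs = gMaxNs))
}

# Noiseless single-contact kernel: one vesicle released at every pulse,
# unit quantal conductance.  Returned baseline-subtracted (rest at 0 mV).
epsp_kernel <- function(protocol = stimulusProtocol(), dtMs = 0.1,
                        membrane = membraneModel()) {
  ev <- methods::new("ReleaseEventSeries",
                     spikeTimesMs = pulseTimes(protocol),
                     released = matrix(1L, 1L, protocol@nPulses + 1L),
                     conductanceNs = rep(1, protocol@nPulses + 1L),
                     nRrp = 1L, gMax = 1)
  ss <- synthesizeSweep(membrane, ev, protocol, noiseParams(0), dtMs)
  list(timeMs = sweepTimes(ss),
       v = drop(sweepVoltages(ss)) - membrane@vRestMv,
       protocol = protocol)
}

# Sweeps that are positive scalings of one kernel (amplitudes exactly linear
# in the sweeps, so jackknife and plain CV must agree exactly).
kernel_sweeps <- function(scales, kernel = epsp_kernel()) {
  sweepSet(kernel$timeMs, outer(kernel$v, scales), kernel$protocol)
}
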