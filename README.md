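# RRPool

Estimation of the readily releasable vesicle pool size (N_RRP) per synaptic
contact from the trial-to-trial variability of evoked postsynaptic potential
(EPSP) trains.

## The problem

In a paired whole-cell recording, a presynaptic pulse train (8 pulses at
20 Hz plus a recovery pulse 500 ms later, repeated 20–60 times) evokes a
train of EPSPs whose amplitudes fluctuate from sweep to sweep. Whether each
synaptic contact releases at most one vesicle per spike (univesicular
release) or draws on a pool of several docked vesicles (multivesicular
release) cannot be read off a single trace — but it sets the coefficient of
variation (CV) of the response. For `M` contacts, each with a pool of `N`
vesicles released independently with probability `U` and quantal conductance
`g_max / N`, the noiseless first-response CV is

    CV = sqrt((1 - U) / (M * N * U))

decreasing in the pool size while the mean response `M * U * g_max` is
independent of it. `RRPool` estimates the cohort-mean pool size by scanning
shifted-Poisson pool distributions (`N = 1 + Poisson(lambda)`,
`lambda = 0..13`), simulating each candidate cohort with a stochastic
multi-vesicular Tsodyks–Markram synapse model, and matching the simulated
jackknife CV profiles against a reference cohort.

The package implements the full pipeline:

* **Synapse model** — deterministic TM recursion
  (`tmDeterministicTrain()`) and its stochastic per-vesicle generalization
  (binomial release, exponential slot refill; `advanceContact()`,
  `simulateConnectionEvents()`).
* **Trace engine** — current-based passive-membrane sweep synthesis with
  Ornstein–Uhlenbeck membrane noise (`synthesizeSweep()`, `ouGenerate()`,
  `estimateOuParams()`).
* **Synthetic cohorts** — ground-truth cohorts with population
  distributions U ~ N(0.38, 0.1) truncated, D ~ Gamma(365.6, 100.15) ms,
  F ~ Gamma(25.71, 45.87) ms, 4–8 contacts per connection
  (`generateCohort()`).
* **Parameter recovery** — membrane time constant from the recovery-EPSP
  decay, voltage deconvolution `tau_mem * dV/dt + V`, peak extraction, and
  a 50-restart genetic algorithm for (U, D, F) (`fitTauMem()`,
  `deconvolve()`, `extractPeaks()`, `fitTmGA()`,
  `fitParamDistributions()`).
* **CV statistics** — leave-one-out (jackknife) CV profiles, profile
  distances, and the CV-vs-pool-size power law (`cvProfile()`,
  `profileDistance()`, `fitPowerLaw()`).
* **Estimators** — `estimateNrrpProfile()` (full 9-pulse profile
  matching), `estimateNrrpFirstEpsp()` (first-response CV matching),
  `buildCvToCvJkkMap()` / `applyCvMap()` (transforming literature CV
  values to the jackknife convention), with `calibrateGmax()` and
  `exclusionFilter()` reproducing the amplitude-matching and screening
  steps.

Sweep sets travel as CSV (`time_ms` + one column per sweep) with a JSON
sidecar (`readSweepSet()` / `writeSweepSet()`), and a thin command-line
front-end `exec/rrpool` wires the stages
(`generate | cv | fit-noise | fit-tm | estimate | transform-cv | validate`).

## Worked example

Build a synthetic 30-connection cohort whose contacts carry on average four
vesicles (`lambda = 3`), then recover that pool size from its CV profile
alone:

```r
library(RRPool)

spec <- cohortSpec(lambda = 3, nConnections = 30L, nSweeps = 20L, seed = 42L)
g <- calibrateGmax(spec, targetMv = 1.46, seed = 1L)   # match 1.46 mV mean EPSP
spec@distributions@gMaxNs <- as.numeric(g)

cohort <- generateCohort(spec)
attr(cohort, "realizedMeanNrrp")
#> [1] 3.937853

prof <- meanCVProfile(cohort)
prof
#> CVProfile (jackknife, N = 20 sweeps):
#>    p1    p2    p3    p4    p5    p6    p7    p8    p9
#> 0.380 0.456 0.576 0.640 0.721 0.800 0.736 0.864 0.450

est <- estimateNrrpProfile(prof, cohortSpec(nConnections = 30L),
                           iterations = 5L, gMax = as.numeric(g), seed = 7L)
est
#> EstimationResult: N_RRP = 3.69 +/- 0.55 (5 iterations)
#>   error minimum at lambda = 3
```

The CV profile rises along the depressing train (pulse 1 → 8) and drops back
at the recovery pulse, and the scan's error curve has its minimum at the
generating rate: the cohort that was built with a realized mean pool of 3.94
vesicles per contact is recovered as 3.69 ± 0.55.

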