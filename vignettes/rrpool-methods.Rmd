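---
title: "Estimating the readily releasable pool size from EPSP train variability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the readily releasable pool size from EPSP train variability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

At a cortical synaptic connection, each anatomical contact holds a readily
releasable pool (RRP) of docked vesicles. Whether a single action potential
releases at most one vesicle per contact (univesicular release, UVR) or
several (multivesicular release, MVR) is not directly observable in a paired
whole-cell recording: only the compound postsynaptic potential (PSP) is.
The pool size does, however, leave a statistical fingerprint. If a connection
has $M$ contacts each holding $N_{RRP}$ vesicles released independently with
probability $U$, and every vesicle contributes a quantal conductance
$g_{max}/N_{RRP}$, the first-response coefficient of variation in the
noiseless limit is

$$ CV = \sqrt{\frac{1-U}{M\,N_{RRP}\,U}}, $$

strictly decreasing in the pool size while the *mean* response
($M\,U\,g_{max}$) does not depend on it. `RRPool` exploits this: it simulates
cohorts of connections over a grid of candidate pool-size distributions and
finds the one whose simulated CV statistics match a reference (recorded or
synthetic) cohort.

## The synapse model

Short-term dynamics follow the Tsodyks–Markram (TM) recursion. For spikes
separated by intervals $\Delta t_n$,

$$ u_1 = U,\qquad R_1 = 1, $$
$$ u_{n+1} = U + u_n (1-U)\, e^{-\Delta t_n / F}, $$
$$ R_{n+1} = 1 + (R_n - R_n u_n - 1)\, e^{-\Delta t_n / D}, $$

and the deterministic relative amplitude at spike $n$ is $A_n = A\,u_n R_n$
(`tmDeterministicTrain()`, with $A = 1$ for normalized fits). $U$ is the
fraction of resources used per spike, $D$ (ms) the depression recovery time
constant, $F$ (ms) the facilitation recovery time constant.

The stochastic multi-vesicular generalization (`advanceContact()`,
`simulateConnectionEvents()`) replaces the continuous resource $R$ by a pool
of $N_{RRP}$ vesicle slots per contact: at each spike, every empty slot first
refills independently with probability $1 - e^{-\Delta t / D}$, then every
ready vesicle releases independently with probability $u_n$. Released
vesicles contribute $g_{max}/N_{RRP}$ each. Three modelling choices the
source literature leaves open were resolved as follows:

* the facilitation variable $u$ is deterministic and shared within a
  contact — only release and recovery are stochastic;
* recovery is applied per empty slot once per inter-spike interval
  (event-driven), which reproduces the deterministic $R_n$ recursion exactly
  in expectation (this is asserted by a Monte-Carlo test);
* at the first spike the pool is full and $u$ jumps to $U$.

## From release events to voltage sweeps

Sweeps are synthesized by a passive point membrane (`synthesizeSweep()`).
Each released quantum adds an instantaneous-rise conductance decaying with
$\tau_{syn}$ (default 1.7 ms, AMPA-like). The drive is *current-based* with
fixed driving force $E_{rev} - V_{rest}$, so the membrane equation

$$ \tau_{mem}\frac{dV}{dt} = -(V - V_{rest}) + R_{input} I_{syn}(t) $$

is exactly linear: superposition holds, calibrating $g_{max}$ is a linear
problem, and the deconvolution operator below is the exact inverse of the
membrane filter. Membrane defaults come from the L5 thick-tufted pyramidal
recordings the method was developed on: $V_{rest} = -65.3$ mV,
$R_{input} = 59.7\ \mathrm{M\Omega}$, $\tau_{mem} = 28.2$ ms. Discrete
updates use exponential (AR(1)) integration at $dt = 0.1$ ms (10 kHz, the
upper end of the experimental sampling range), fused into a single compiled
pass per sweep.

Membrane noise is an Ornstein–Uhlenbeck process in the Euler form

$$ X(t+dt) = X(t) - \frac{X(t)}{\tau}dt + \sigma\sqrt{2/\tau}\sqrt{dt}\,W_t $$

with defaults $\sigma = 0.22$ mV, $\tau = 28.2$ ms (the values calibrated
from the quiet 400 ms stretch between the train and the recovery pulse).
`estimateOuParams()` inverts this: $\sigma$ is the per-sweep SD of the
centred segment and $\tau$ the time constant of an exponential fit to its
autocorrelation, averaged across sweeps (the per-sweep-then-average order is
our choice; the alternative — concatenating sweeps — differs only at second
order). `noiseSegment()` starts the window one inter-stimulus interval plus
a 50 ms settling guard after the eighth pulse, giving the canonical 400 ms;
the guard length is a package choice, only the 400 ms total is prescribed.

## Recovering U, D, F from recordings

`fitTauMem()` fits a single exponential to the decay after the recovery
(9th) EPSP of the averaged trace. `deconvolve()` then applies
$\tau_{mem}\,dV/dt + V$ (central differences; one-sided at the boundaries)
to undo the membrane low-pass, and `extractPeaks()` reads one peak per pulse
from the common pre-train baseline, searching up to the next stimulus
(300 ms for the recovery pulse). `fitTmGA()` fits $(U, D, F)$ to the
max-normalized peak train by minimizing the mean squared distance to the
max-normalized deterministic prediction, with a genetic algorithm over
$U \in [0,1]$, $D \in [0,1000]$ ms, $F \in [0,2000]$ ms: 500 generations per
run, 50 independent restarts, best restart wins. GA internals (population
100, tournament size 3, uniform crossover 0.7, Gaussian mutation rate 0.2
with SD 5% of each range, elitism 1) are not prescribed by the method —
any configuration passing the elitism-monotonicity and U-recovery tests is
equivalent. With 9 peaks, $U$ is well identified (recovered within
$\pm 0.05$ from noiseless peaks); $D$ and to a larger degree $F$ carry the
wide identifiability bands that the population spread of $F$
(25.71 ± 45.87 ms) itself implies.

`fitParamDistributions()` selects a population distribution per parameter
among beta, gamma and normal by maximum-likelihood fit plus
Kolmogorov–Smirnov ranking (highest p, then smallest distance). Beta is
attempted only when all values lie strictly inside $(0,1)$.

## Jackknife CV profiles

With $N$ sweeps per connection, amplitudes measured on single sweeps are
noise-inflated. The jackknife route (`cvProfile(useJackknife = TRUE)`)
instead measures each pulse's amplitude — post-window maximum minus the
minimum in the 50 ms pre-window — on the $N$ leave-one-out average traces
$A_{in}$ and reconstructs the per-observation spread with

$$ std_n = \sqrt{(N-1)\sum_i (A_{in} - \bar A_n)^2},\qquad
   CV_n = std_n / \bar A_n. $$

For amplitudes that are linear functionals of the sweeps this equals the
plain sample CV *exactly* (the leave-one-out deviations are
$-(a_i - \bar a)/(N-1)$), which the test suite asserts on scaled-kernel
fixtures; on noisy data the averaging suppresses the noise bias of the
max/min windows. The post window is capped at the next stimulus: a 300 ms
window would overlap later pulses of the 20 Hz train and is kept only for
the recovery pulse, where it is the printed convention.

## The pool-size estimator

`estimateNrrpProfile()` scans shifted-Poisson rates $\lambda \in [0, 13]$
(per-contact pool $1 + \mathrm{Poisson}(\lambda)$, so mean pools 1–14). At
each rate it simulates a cohort (default 100 connections × 20 sweeps) with:

* $U \sim \mathcal N(0.38, 0.1)$ truncated to $[0,1]$,
  $D \sim \Gamma(365.6, 100.15)$ ms, $F \sim \Gamma(25.71, 45.87)$ ms, one
  draw per connection shared by its contacts (the fitting pipeline recovers
  one triplet per connection; per-contact draws are available via the
  `perContactParams` flag of `cohortSpec()` but off by default);
* 4–8 contacts per connection, uniform;
* $g_{max}$ calibrated once (`calibrateGmax()`, secant iteration under
  common random numbers) so the simulated cohort-mean first-EPSP amplitude
  matches the reference (1.46 mV for the reference dataset);
* connections with mean first-EPSP amplitude outside the reference range
  removed (`exclusionFilter()`; default mean ± 2 SD of the reference
  amplitudes, i.e. $[-0.26, 3.18]$ mV — the original used the raw
  experimental min–max, which is not published).

The matching error at each rate is the mean squared distance between the
cohort-mean jackknife CV profile and the reference profile. The scan is
repeated (50 iterations by default; the acceptance runs use 10), each
iteration's arg-min rate is mapped to the *realized* cohort-mean pool size
(not $1+\lambda$ itself — the realized means are what validation cohorts
report), and the estimate is their mean ± SD. `estimateNrrpFirstEpsp()`
is the same scan with the scalar error
$|\overline{CV}_1^{sim} - CV^{ref}|$, for references where only a
first-response CV is available; `buildCvToCvJkkMap()` fits the affine map
from plain to jackknife CV across the rate grid so that literature CV values
(usually computed without the jackknife) can be transformed before matching.

Two aggregation ambiguities were resolved as follows: the reported SD is
across scan iterations, and $g_{max}$ is calibrated once per reference
rather than per rate (the mean first response is pool-size invariant, so a
per-rate calibration would only add Monte-Carlo jitter).

## What the synthetic cohorts do and do not emulate

`generateCohort()` emulates: stochastic vesicle release with TM short-term
depression/facilitation, quantal scaling $g_{max}/N_{RRP}$, population
heterogeneity of $U/D/F$ and contact counts, passive somatic filtering, and
correlated membrane noise at the calibrated level. It does **not** emulate
dendritic filtering and electrotonic attenuation, receptor saturation or
desensitization, vesicle-recycling pools beyond the RRP, calcium dynamics,
or electrode artifacts. Passing tests therefore demonstrate correct
recovery of ground truth *within this generative family*; on real
recordings the same pipeline additionally inherits whatever variability
those omitted mechanisms contribute. Concretely, the univesicular
first-pulse CV under this reduced membrane (~0.55, matching the binomial
closed form above and the package's own power-law amplitude) is larger than
the value a morphologically detailed tissue model produces (~0.45), while
multivesicular cohorts (mean pool ≈ 3.8) agree at ~0.35 either way.

## Numerical choices

* $dt = 0.1$ ms everywhere; the OU Euler step and the AR(1) membrane
  updates are stable and accurate for $dt \ll \min(\tau_{syn}, \tau)$, and
  constructors refuse $dt \ge \tau_{syn}$.
* Degenerate inputs: zero-amplitude pulses yield `NA` CV with a warning;
  constant noise segments are flagged rather than fitted; a white-noise
  segment reports $\tau$ at the sampling resolution with a warning;
  a non-decaying recovery tail makes `fitTauMem()` return a failure flag.
* Ties in the GA tournament resolve to the first index; elitism guarantees
  the best-of-generation error is non-increasing.
* Gamma distributions are parameterized by (mean, sd), converted internally
  with shape $= (m/s)^2$, rate $= m/s^2$.
* All randomness flows through R's RNG; every simulating function accepts a
  seed and restores the caller's RNG state, and a seeded cohort, fit or
  estimate is bit-reproducible.

## Problem sizes

The defaults follow the experimental protocol (8 pulses at 20 Hz, recovery
pulse 500 ms later, 20 sweeps, 100-connection cohorts, rate grid 0–13, 50
scan iterations). The test suite and the acceptance script run the same
pipeline at the scale a desk validation warrants: 10 scan iterations,
cohorts of 30–100 connections, and 1–3 repetitions per reported mean; the
validation experiment (recovery of cohorts built at mean pools ≈ 1, 4, 10)
uses 30-connection references, mirroring the size of a realistic recorded
dataset.

## Known limitations

* The estimator is cohort-level: it recovers the *mean* pool size of a
  population of connections, not per-connection values.
* $g_{max}$ and $N_{RRP}$ are not jointly identified; $g_{max}$ is fixed by
  amplitude calibration first, and a miscalibrated $g_{max}$ biases the
  recovered pool size (larger conductance, larger inferred pool at equal
  CV).
* The reduced membrane makes the univesicular CV prediction an upper
  bound relative to morphologically detailed simulations (see above).
* $F$ is weakly identified in strongly depressing connections; its fitted
  population spread should be read as an identifiability band.
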