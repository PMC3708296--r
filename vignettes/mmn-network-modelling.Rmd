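---
title: "Modelling auditory mismatch networks with mmnet"
author: "mmnet authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling auditory mismatch networks with mmnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmnet)
```

## The scientific problem

Automatic auditory change detection produces the mismatch response (MMN, or
MMNm in magnetoencephalography): a deflection of the evoked field between
roughly 100 and 200 ms after a rare "deviant" tone interrupts a stream of
repeated "standard" tones. The response is generated by a distributed
cortical network — bilateral auditory (temporal) cortex, prefrontal cortex
and parietal cortex — and the *effective connectivity* of that network, and
how the deviant context modulates it, is of direct interest in
neurodegenerative disease, where frontal damage is hypothesised to
reorganise the network from a sparse, efficient architecture into a more
distributed and less efficient one.

`mmnet` implements the full computational chain of such a study on
synthetic data: stimulus generation, a biophysical forward model of the
six-node cortical network, trial-level data simulation, epoch
preprocessing, waveform metrics, Bayesian model inversion, and group-level
random-effects model selection over a space of fifteen competing network
architectures. Because no recordings are distributed with studies of this
kind, the package's synthetic-data module plays the role of the
participants: every downstream stage can be exercised, and scored against
ground truth, without any external data.

## The stimulus: a multi-feature oddball sequence

`generateSequence()` produces the multi-feature "Optimum-1" design: tones
every 500 ms, three blocks, each block starting with fifteen standard tones
after which standards strictly alternate with deviants. Five deviant types
(frequency, intensity, duration, side, gap) are arranged so that every
aligned 10-tone window contains each type exactly once and the same type
never repeats immediately; the within-window order is a seeded uniform
permutation with rejection at window boundaries. With 600 alternating
tones per block the session delivers exactly 900 analysed standards and
900 deviants; the lead-in standards are flagged and excluded from all
counts. `toneCatalog()` records the acoustic attributes of the six tone
types as metadata — the analysis operates on evoked responses, so no audio
is synthesised.

```{r}
seq <- generateSequence(sequenceConfig(seed = 1))
seq
```

## The forward model

Each of the six sources (bilateral temporal, frontal, parietal; fixed MNI
coordinates) is a three-subpopulation neural mass: spiny stellate cells,
pyramidal cells and inhibitory interneurons, each with second-order
synaptic kinetics (excitatory gain `He` = 3.25 mV, time constant `taue` =
10 ms; inhibitory `Hi` = 29.3 mV, `taui` = 16 ms) and intrinsic coupling
gains `gamma = 135 * (1, 0.8, 0.25, 0.25)`. Firing is the threshold
sigmoid `2*e0 / (1 + exp(r*(v0 - v)))` with `e0` = 2.5/s, `r` = 0.56/mV
and threshold `v0` = 6 mV, with the resting rate subtracted so that the
origin is an exact fixed point. Placing rest on the low-slope part of the
sigmoid is what makes the default operating point a damped focus — the
impulse response is an evoked-like transient peaking near 100–130 ms —
rather than the self-sustained alpha-band limit cycle the same equations
produce when rest sits at the point of maximum gain.

Sources are coupled by directed extrinsic connections with fixed
conduction delays (2 ms within, 16 ms between sources): *forward*
connections (base gain 32) target the stellate population, *backward*
connections (gain 16) target pyramidal cells and interneurons, *lateral*
interhemispheric connections (gain 4) target all three. These equations
and constants are the canonical evoked-response neural-mass
parameterisation of the dynamic-causal-modelling literature; adopting them
wholesale is the package's single largest modelling commitment, made
because the study design this package reproduces specifies the network
*architecture* but not the microcircuit equations.

The driving input — a gamma-shaped bump (shape 2, onset 60 ms, dispersion
16 ms, amplitude 0.3/ms) — enters at left and right auditory cortex in
every model. The observed response per source is an observation gain times
the pyramidal depolarisation; sensor-level lead fields are deliberately
not modelled, since the analysis and its acceptance experiments live
entirely in source space.

In the deviant condition each modulated extrinsic connection is multiplied
by `exp(B)` and the intrinsic stellate-loop gain of the two temporal nodes
by the exponential of an intrinsic log-gain — the multiplicative
modulation convention, with the standard condition as baseline.

Integration uses a fixed-step Heun scheme in compiled code at
`oversample` substeps per output sample (4 by default), with the delayed
state history linearly interpolated so the effective delay does not depend
on the step. Halving the default step changes the response by well under
0.5% relative RMS; a single isolated node agrees with an adaptive
high-order reference solution to better than 1%.

```{r}
space <- buildModelSpace()
m <- findModel(space, "sparse", "anterior")
p <- defaultNMMParams(m)
r <- integrateModel(m, p, "standard", times = seq(0, 280, by = 3))
r
```

## The model space

`buildModelSpace()` enumerates the fifteen candidate architectures: three
connectivity families (full / partial / sparse) crossed with five
modulation schemes (all / anterior / posterior / forward / backward).
Sparse models have only intrahemispheric temporal–frontal and
temporal–parietal edges; partial models add interhemispheric homologous
edges; full models additionally include intrahemispheric frontal–parietal
edges. Ascending intrahemispheric edges are typed forward, their
reciprocals backward, interhemispheric edges lateral. Two conventions were
genuinely open and are fixed as follows: parietal→frontal is treated as
the forward direction of the frontal–parietal pair (parietal sits below
frontal in the auditory hierarchy), and the "all" scheme modulates lateral
edges too, while the forward/backward schemes exclude them. Intrinsic
modulation at the temporal nodes is present in all fifteen models.

## Synthetic subjects and cohorts

`simulateSubject()` turns a stimulus sequence into trial epochs
(−100..400 ms at 333 Hz): the condition-appropriate noiseless response
plus white Gaussian source noise, and an EOG channel with background noise
and raised-cosine blink transients (400 ms, 200 µV, 10% of epochs) that
leak weakly into the sources. Choices that deliberately simplify real MEG:
noise is white (no 1/f, no sensor covariance), blinks are stereotyped, and
no head movement or sensor-level artifacts exist. Passing tests therefore
demonstrates the *pipeline's* correctness and the method's behaviour under
controlled conditions, not robustness to every pathology of real
recordings.

The per-trial noise sd defaults to 0.7 times the noiseless
standard-response RMS — single-trial SNR below one, as in evoked
recordings — so that averages over the 50–900 trials used here retain a
few-percent residual. Inter-subject heterogeneity multiplies dynamic
constants (one log-normal draw per subject, sd 0.1 — a subject-level
synaptic operating point, matching the granularity at which these
constants are estimated), individual connection gains and observation
gains (per-edge/per-source draws, sd 0.1), and perturbs modulatory
log-gains (sd 0.25 around means of ln 1.5 extrinsic, ln 1.2 intrinsic —
moderate, identifiable effect sizes).

The generative model treats all five deviant types as one deviant
condition, exactly as the network analysis does. The per-type amplitude
and latency differences that the waveform metrics display are applied
afterwards to per-type *averages* by `applyTypeEffects()` — an explicitly
synthetic convenience, since the study's generative claims make no
distinction between deviant types.

## Preprocessing

The "dcm" profile reproduces the network-analysis pipeline: 1 Hz
high-pass (6 dB/oct) and 40 Hz low-pass (24 dB/oct) zero-phase Butterworth
filters, −100..0 ms baseline correction, rejection of epochs whose EOG
exceeds 150 µV, and robust averaging of all standards and all (pooled)
deviants. Filter edges are handled by steady-state initial conditions
(equivalently, constant extension of the edge values): no data-derived
padding shapes the interior, and a DC epoch passes the lowpass exactly —
the behaviour the filters' passband specification implies. On 500 ms
epochs a 1 Hz high-pass with cold (zero) initial state would otherwise
produce edge transients larger than the averaging noise. Robust averaging is a Huber-type iteratively reweighted mean per
time point (tuning constant 1.345 on a frozen MAD scale, at most 20
iterations, weight tolerance 1e-6); with weights forced to one it reduces
exactly to the plain mean. The "waveform" profile keeps the five deviant
types separate, uses a source-amplitude artifact threshold instead of the
EOG rule, and averages plainly.

Two subtleties matter for model comparison. First, high-pass filtering
500 ms epochs and subtracting a baseline distort the evoked waveform by
more than the residual noise level; model inversion therefore applies the
identical deterministic operations — they are linear, so they form a
single time-axis operator `P` — to the model predictions whenever the
evoked object carries a preprocessing manifest. Second, filtering makes
the residual noise *smooth*, while the likelihood assumes independent
samples; smooth noise then masquerades as structure that richer
connectivity families absorb, biasing the family comparison towards
extra edges. Since white trial noise acquires covariance proportional to
`P Pᵀ`, both data and predictions are projected onto the passband
eigenspace of that covariance (eigenvalues above 1e-4 of the maximum —
the filter's spectral gap makes the threshold uncritical) and whitened
there. The stopband carries neither signal nor noise, so weighting it is
meaningless; after reduce-and-whiten the independent-noise likelihood is
calibrated, nested families are separated only by genuine structure plus
the Occam complexity term, and in practice the free-energy ascent also
becomes markedly more reliable. This mirrors the data-reduction and
error-whitening steps that sensor-space implementations of this analysis
perform.

## Waveform metrics

`differenceWave()`, `mmnMetrics()` and `m100Peak()` compute the study's
measures on the temporal sources: the deviant-minus-standard difference,
its mean amplitude over 100–200 ms (signed, with a magnitude variant also
reported since displayed group means could be either), its peak latency
(time of the largest absolute deflection, earliest sample on ties — the
extremum definition is a documented package choice), and the signed M100
peak of the standard response in 50–150 ms. `groupSummary()` produces the
per-group mean/SE tables; inferential ANOVAs are deliberately out of
scope.

## Inversion: variational Laplace

`invertModel()` fits a model's parameters to the standard and deviant
evoked responses jointly over 0–250 ms. Free parameters (all priors are
the package's own choices, as none are dictated by the study design):
log-gains on `He`, `Hi`, `taue`, `taui` shared across sources and on the
input amplitude (Normal(0, 1/16)); per-edge log-scalings of extrinsic
gains (Normal(0, 1/16)); modulatory log-gains `B` and the two intrinsic
log-gains (Normal(0, 1/4)); per-source observation log-gains
(Normal(0, 1/16)). Input onset and dispersion and the conduction delays
are fixed — freeing them adds little at this problem scale and degrades
conditioning. Observation noise is i.i.d. Gaussian with a single precision
updated by EM.

The ascent is Gauss–Newton with Levenberg–Marquardt damping: candidate
steps are accepted on the exact log joint (which does not depend on the
local Jacobian), damping is multiplied by 8 on rejection and relaxed on
acceptance, and the free energy
`F = accuracy − KL(posterior ‖ prior)` (including the Gauss–Newton trace
term) is monitored for convergence (ΔF < 0.01 nat, 64 iterations cap).
With a linear forward model and fixed precision this F is the exact log
evidence, which the test suite verifies against the closed form.

The free-energy surface of a delayed nonlinear network model is
multimodal, and two devices keep the ascent reliable. `n_starts` adds
seeded extra starting points around the prior mean, with an optional
`patience` that stops exploring once several consecutive starts fail to
improve the best free energy. More importantly,
`computeEvidenceMatrix()` chains warm starts through the nested structure
of the model space: family anchors (the all-modulated model of each
family) are fitted sparse→partial→full with upward seeding, re-seeded
downward from the richer family's optimum, and the remaining schemes start
from their family anchor. Every anchor retains an independent prior-mean
start and the best optimum wins; the chaining only improves each model's
own optimum — nothing is shared between models except starting points.
Finally, any family whose best member lags the global best by more than
`retry_gap` nats (30 by default) has its anchor re-optimised from extra
seeded starts — a stuck ascent is the usual cause of such a lag between
nested models, and the retry applies to whichever family lags, so no
architecture is favoured. Without these devices, local optima produce
spurious evidence differences of hundreds of nats between nested models,
which is impossible at the true optima and drowns the family comparison.

## Group-level Bayesian model selection

`rfxBMS()` implements random-effects model selection: the model identity
is a subject-level random variable with Dirichlet-distributed frequencies.
Variational updates alternate subject-wise posterior assignments
(softmax of evidence plus digamma terms) with the Dirichlet concentration
update until the concentration changes by less than 1e-4. Exceedance
probabilities come from seeded Dirichlet Monte Carlo (1e6 draws by
default; the seed and sample count are recorded in the result).
`familyBMS()` compares families with the prior re-balanced so each family
carries equal prior mass (concentration `1/size` per member), summing
sampled frequencies over members within each draw; `withinFamilyBMS()`
restricts to the winning family for the second stage. Expected posterior
probabilities `r` and exceedance probabilities `xp` are both reported,
since published "posterior probability" figures can refer to either.
A fixed-effects column-sum comparator (`ffxLogGroupEvidence()`) is
available as a diagnostic only.

## The pipeline and what it reproduces

`runPipeline()` wires the stages together for two synthetic cohorts: a
"control-like" cohort generated from the sparse-family anterior-modulated
model and a "patient-like" cohort from the partial-family all-modulated
model — the qualitative group dissociation under study. The labels are
simulation metadata, not clinical claims. The report carries per-stage
timings, counts, a config digest, and the metrics/evidence/BMS tables;
`makeFigures()` renders the group bar charts from byte-stable data tables.

Problem sizes: the recovery experiments shipped in the tests and the
acceptance script use single-block sequences of 100 alternating tones,
cohorts of six subjects with three replicates per generating family, a
32-iteration inversion cap for cohort-scale evidence matrices, and 20
subjects for modulation-gain recovery. These sizes were chosen so the full
suite completes comfortably on one core; the same functions scale to the
full session design (three blocks, 900/900 events) and larger cohorts
unchanged.

## Numerical choices and degenerate inputs

* Integration: fixed-step Heun, oversample 4 (simulation) / 2 (inversion);
  delays interpolated on the history; non-finite states abort with the
  offending parameter regime named.
* Robust averaging freezes its scale at the initial MAD; zero-MAD time
  points fall back to the plain mean.
* `mmnMetrics()` breaks latency ties toward the earliest sample;
  a constant difference therefore reports the first window sample.
* `rejectEpochs()` with threshold 0 rejects every epoch with any nonzero
  EOG; rejection reports are per condition.
* BMS refuses evidence matrices with missing entries — failed inversions
  must be handled explicitly by the caller; silent imputation is
  forbidden.
* All stochastic steps (sequence permutations, noise, blinks, jitter,
  Dirichlet sampling, extra starts) derive from explicit seeds, and
  derived seeds stay within the 32-bit integer range.

## Known limitations

* The microcircuit equations and priors come from the evoked-response
  modelling literature, not from the study being emulated; conclusions
  about the method transfer only insofar as those conventions are shared.
* Source waveforms are observed directly; lead fields, sensor noise
  covariance and source reconstruction error are outside the model.
* White noise and stereotyped blinks understate real artifact structure.
* Backward modulatory gains are estimated with more shrinkage than
  forward ones (their sensitivity per prior sd is lower), so single-subject
  backward estimates are conservative.
* The family comparison detects extra structure more confidently than its
  absence: nested extra edges cost little evidence when unused, so
  sparse-generated cohorts win by smaller margins than partial-generated
  ones — visible in the acceptance experiment's exceedance probabilities.
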