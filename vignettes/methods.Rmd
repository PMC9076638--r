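---
title: "Phase coupling, circular phase-behavior statistics, and Bayesian moderated mediation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase coupling, circular phase-behavior statistics, and Bayesian moderated mediation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the tunable parameters and defaults, what
the synthetic-data generator emulates (and does not), the numerical
choices, and known limitations. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## The experimental setting being modelled

A bimanual tapping paradigm alternates a stable mirror-symmetric *in-phase*
mode (homologous fingers synchronous) and a less stable *anti-phase* mode
(index and middle of opposite hands synchronous). Trials consist of a start
cue, a transition cue — *continue* or *switch*, at roughly 1:5
continuation:switching so that switches stay non-automatic — and a fixed
3000 ms pause; other inter-stimulus intervals jitter uniformly in
5000–8000 ms. A thumb reaction-time (tRT) probe replaces any scheduled
event with 5% probability and is always followed by a pause at 1000 ms.
Behavior is scored in a 2000 ms window after each switch cue: the error
fraction over tap pairs, the transition latency to the first pair in the
cued mode, and a hurdle code (*failed* = all pairs wrong, latency
undefined; *fully correct*; *partial* with error fraction inside (0,1),
ready for beta-family modelling). Thumb RTs are trimmed below 100 ms and
above the within-group mean + 3 SD (moments computed after the lower cut —
the conservative order).

EEG enters at source level: three sources (left and right sensorimotor,
occipital control), 250 Hz, epochs of ±2.5 s around cues.

## Spectral decomposition

Complex Morlet wavelets — a complex sine tapered by
`exp(-4 ln 2 · t² / FWHM²)` — at 50 log-spaced frequencies from 2 to
40 Hz. The time-domain FWHM interpolates **log-linearly in frequency**
from 400 ms at 2 Hz to 104 ms at 40 Hz; only the endpoints are given by
the source methodology, and log-linear interpolation matches the
log-spaced frequency grid. Kernels are normalized to unit spectral peak
gain so narrowband power is comparable across frequencies (white-noise
flatness is a test invariant). Convolution is FFT-based, "same"-length and
centered; samples within half a kernel of an epoch edge are flagged in an
edge mask — the ±2.5 s epoch padding exists to absorb them. Power can be
converted to dB change against the per-frequency mean of a
−500..−200 ms baseline window.

## Inter-site phase clustering

`ISPC_f = |n⁻¹ Σ exp(i(φ_x − φ_y))|`. As printed, the sum runs over time
points; time-frequency-resolved maps, however, require clustering **over
trials** at each cell, and that is the default here (`ispc()`), with
`ispc_over_time()` as the windowed literal reading. ISPC is computed on a
50 Hz grid (every 5th sample at 250 Hz) for 5–40 Hz, baseline-corrected by
subtracting the per-frequency −500..−200 ms mean. Response-locked analysis
re-windows every trial to ±260 ms around the subject-and-condition median
latency (median of an even count = midpoint of the central pair,
everywhere). Single-trial phase lags are pooled over a band's bins by the
**circular** mean — arithmetic averaging of wrapped angles would be wrong
at the ±π boundary (the `{+170°, −170°} → 180°` case is a frozen test).
The baseline control condition extracts the lag at start-cue −300 ms, as
specified, not re-randomized.

## Cluster-corrected permutation inference

Three steps, applied identically to ISPC and dB power maps:

1. **Within-subject z.** The observed TOI-minus-baseline change is
   standardized against a permutation null in which a random subset of
   trials swaps its TOI and baseline segment roles (the permutable unit is
   genuinely open; trial-subset exchange is used and recorded). Cells with
   a degenerate null SD are masked and counted.
2. **Group-level cluster tests.** Per-cell t statistics (one-sample
   sign-flip, or pooled two-sample with full label permutation), two-tailed
   cluster-forming threshold at p < 0.05, 4-connected same-signed
   clusters, max-cluster statistic null, `(b+1)/(m+1)` p-values. The
   cluster statistic defaults to **mass** (sum of t) for sensitivity, with
   extent as a config alternative; the choice is recorded in the result
   metadata because the procedure is often described in terms of extent.
3. **Contrasts.** Per-subject in-phase − anti-phase differences feed the
   between-group test of the interaction (difference of differences); the
   same differences give the one-sample mode main effect, and mode-pooled
   maps the group main effect for the follow-up tests run when the
   interaction is null.

The type-I error of the full procedure is verified by simulation in the
test suite (20 subjects, 35×60 grid, 200 replicates, 500 permutations;
family-wise rate within 3 binomial SEs of 0.05). The permutation core is
compiled (Rcpp) so this simulation runs in about a minute.

## Circular statistics

Rayleigh `z = n·R̄²` with the standard small-sample-corrected exponential
p-value; circular mean with the Fisher/Zar confidence arc (the
high-concentration branch above R̄ = 0.9; below the validity region the
arc is flagged undefined rather than fabricated); Mardia circular-linear
correlation with the χ²(2) approximation; and the Harrison–Kanji two-way
circular ANOVA with automatic branch choice by estimated concentration
(recorded in the output). In the low-concentration branch each term is
referred to a chi-square with **2 × (levels − 1)** degrees of freedom: the
cosine and sine components of the between-level resultants each contribute
one chi-square(levels − 1), which is also why a two-level factor is
reported on 2 df. Calibration of both branches is a test invariant.
BH-FDR is applied across the family of all subgroup × band × condition
tests of one analysis run. GABA+ dichotomization uses the within-group
median with ties going to "low" (deterministic).

## GABA+ preparation

Tissue correction follows the standard compartment assumptions — GABA+
negligible in CSF and twice as high in GM as in WM (α = 0.5):

```
corrected = raw × (fGM·w_GM + fWM·w_WM + fCSF·w_CSF) / (fGM + α·fWM)
```

The water visibility/relaxation terms ship as an editable constants table
with literature-style defaults (`gaba_constants()`); the exact constants
are cited, not printed, in the source methodology, so results reproduce
the formula's structure, not any particular institutional-unit scale.
Group normalization re-evaluates the correction factor at the
outlier-trimmed (±3 SD, configurable) group-mean composition and rescales
each subject by the ratio of factors. This multiplicative reading
satisfies all the defining properties at once: identity under homogeneous
composition, a fixed point for a subject at the group-mean composition,
and removal of the spurious composition dependence the subject-specific
factor introduces when the raw value is composition-independent.

## Bayesian moderated mediation

Outcome and mediator models (all inputs centered; transition mode enters
the outcome model as a centered covariate when provided):

```
Y = i1 + c1·X + c2·W + c3·X·W + b1·M + b2·M·W + e1
M = i2 + a1·X + a2·W + a3·X·W + e2
```

Residuals are exGaussian (Normal(0, σ) + Exponential(mean β)) with
identity links on all three parameters; priors are uniform — bounds are
not stated by the source methodology, so the defaults are ±50 on
coefficients and (0, 50] on scales, configurable and recorded in the
result. The sampler contract is deliberately about the *posterior*, not a
specific algorithm: 4 chains × 10,000 iterations with 1,000 warmup by
default, gated on split R-hat < 1.01 and ESS > 400 per coefficient, with
non-converged fits flagged, never silent. The shipped sampler is an
adaptive random-walk Metropolis with three ingredients: a jointly adapted
(Haario-style, diminishing) proposal covariance; an independence proposal
from the adapted Gaussian approximation; and a dedicated "ridge move"
exchanging mass between the intercept and the exponential mean along
`i + β = const`, the known exGaussian identifiability ridge. Bayesian R²
is reported per model.

Derived quantities are computed on draws, never point estimates:
α(W) = a1 + a3·W, β(W) = b1 + b2·W, τ′(W) = c1 + c3·W, indirect
α(W)·β(W), and total effect τ(W) from the mediator-free refit. Conditional
effects are evaluated at the 20th/80th percentile of the moderator (for a
binary ±0.5 moderator these are exactly the group codes) and summarized by
posterior medians, 89% HDIs (shortest interval on sorted draws), and the
probability of direction, `pd = 100·max(P(>0), P(<0))`, converted to a
two-sided p as `2·(1 − pd/100)`.

A degenerate case worth knowing: the "zero-noise" limit can only be taken
one model at a time. If both residuals vanish, M is an exact linear
function of X, W and XW, and (c1, b1) lose identifiability in the outcome
model; the deterministic-limit tests therefore zero one model's residuals
while keeping the other's at their defaults.

## The synthetic data-generating process

The generator is first-class, tested code and defines the study
conditions:

- **Schedule**: per-trial Bernoulli switch with p = 5/6 (the 1:5 design),
  per-event Bernoulli tRT substitution at 5%. Substituted tRT events keep
  their slot; the mandatory pause inserted 1000 ms after a tRT slightly
  dilutes the raw tRT fraction (to ≈4.8% of all events at the default
  rate), which stays within the 3-SE acceptance band at 10,000 events.
- **Taps**: pairs paced at 2 Hz (configurable) with 5 ms within-pair
  asynchrony; mode changes after a switch cue at a gamma(9, 60 ms) latency
  by default; error models `none`, `random(p)` and `always` (the last
  yields failed transitions).
- **Sources**: three labelled sources on 1/f-plus-white background noise
  (the standard EEG surrogate; the source methodology states no noise
  model), with a shared band-limited oscillation between LSM1 and RSM1
  whose per-trial lag is von Mises(mean_lag, κ) and can follow a step
  time course around the transition; OCC is uncoupled unless specified;
  SNR is the oscillation-to-noise power ratio.
- **Cohort**: X standard normal, W the centered ±0.5 group code, M and Y
  generated *exactly* by the mediator/outcome equations with exGaussian
  residuals (defaults σ = 0.5, β = 0.3 — moderate noise a cohort of ~400
  would plausibly show); per-voxel raw GABA+ with a 0.6 i.u. young-older
  offset in sensorimotor voxels only, plus tissue fractions and quality
  metrics. Ground truth serializes losslessly to JSON.

What the generator does **not** emulate: volume conduction and source
leakage, non-stationary 1/f slopes, artifacts (EMG, eye movements),
learning effects beyond trial-number bookkeeping, or realistic MRS
spectra. Passing tests therefore demonstrate the correctness and
calibration of the estimators under a clean, known data-generating
process — not robustness to real-data pathologies.

## Numerical choices and problem sizes

All RNG streams are keyed by (master seed, stage, subject, …) through a
hash, so every stage is independently reproducible and a pipeline run is
byte-identical under the same config and seed (a test asserts this on the
demo cohort). Angles are wrapped to (−π, π]; phase unwrap and circular
means go through resultant vectors, never raw averages. Cluster p-values
are `(b+1)/(m+1)`-corrected, so never zero. The test suite runs its
simulations at desk scale chosen as the smallest sizes with adequate
power: type-I simulation at 200 replicates × 500 permutations, mediation
recovery at 40 replicates of 4 chains × 2,000 iterations (the default
10,000-iteration layout is used in the convergence-gate tests), circular
oracles at n ≤ 12 with 1,000–4,000 permutation/Monte-Carlo draws. The
demo pipeline configuration (`demo_config()`: 12 + 12 subjects, 24
trials, a 12-frequency bank, 100 permutations, 4 × 1,500 iterations) is
sized to finish an end-to-end run in about ten seconds while exercising
every stage.

## Known limitations

- ISPC is non-directional and leakage-uncorrected by design; no Granger,
  phase-slope index, or amplitude coupling.
- The literal over-time ISPC reading is provided but the default clusters
  over trials; single-trial time courses from the windowed variant have
  lower effective resolution.
- The circular ANOVA uses asymptotic approximations; with very small cells
  (< 5 observations) it warns and its calibration degrades.
- Mediation is associational: no causal identification machinery is
  included, and the conditional quintile analysis inherits the centering
  convention (effects are relative to group means).
- The GABA+ correction reproduces the formula's structure with documented
  default constants, not any site's institutional-unit scale.
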