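# ispcmed

Multimodal analysis of interhemispheric sensorimotor coupling during
bimanual motor-state transitions: wavelet-based inter-site phase clustering
(ISPC) on source-level EEG, nonparametric cluster-corrected inference on
time-frequency maps, single-trial circular phase-behavior statistics, MRS
GABA+ preparation, and a Bayesian moderated mediation model linking
connectivity, GABA+ and behavior. A synthetic-data module generates every
input with known ground truth, so the full pipeline is testable without
human recordings.

## Who this is for

Researchers studying phase-based cortico-cortical connectivity and its
behavioral and neurochemical correlates — e.g., how left/right sensorimotor
(S/M1) beta-band coupling around a cued switch between in-phase and
anti-phase bimanual tapping relates to transition latency and error rate,
and whether edited-MRS GABA+ mediates that relation, moderated by age
group.

## The statistics at the core

**Inter-site phase clustering.** For phase angles φ_x, φ_y of two sources
at frequency f,

    ISPC_f = | n^-1 Σ exp(i (φ_x − φ_y)) |

clustered over trials at each time-frequency cell (a windowed over-time
variant is also provided). 1 means a perfectly consistent lag of any
value; 0 means uniformly scattered lags. Phases come from convolution with
complex Morlet wavelets, 2–40 Hz in 50 logarithmic steps, time-domain FWHM
interpolating log-linearly from 400 ms to 104 ms; ISPC is evaluated on a
50 Hz grid and baseline-corrected against −500..−200 ms.

**Cluster-corrected permutation inference.** Within-subject change from
baseline is z-transformed against a trial-subset exchange null; group-level
maps are tested with per-cell t statistics, 4-connected supra-threshold
clustering, and a max-cluster-mass permutation null (sign flips for
one-sample designs, group-label permutation for between-group), including
the difference-of-differences scheme for the group × transition-mode
interaction.

**Circular statistics.** Rayleigh test (z = n·R̄²), circular mean with
confidence arc, Mardia circular-linear correlation, Harrison–Kanji two-way
circular ANOVA (a two-level factor is tested on 2 df in the
low-concentration branch), BH-FDR, and within-group median dichotomization
of GABA+.

**Bayesian moderated mediation.** Outcome and mediator models

    Y = i1 + c1 X + c2 W + c3 XW + b1 M + b2 MW + e1
    M = i2 + a1 X + a2 W + a3 XW + e2

with exGaussian residuals, identity links, and uniform priors, sampled by
an adaptive random-walk Metropolis scheme (4 chains × 10,000 iterations,
1,000 warmup by default; gates: split R-hat < 1.01, ESS > 400). Derived
paths α(W) = a1 + a3·W, β(W) = b1 + b2·W, τ′(W) = c1 + c3·W, the indirect
effect α(W)·β(W), and the total effect τ(W) from the mediator-free model
are summarized with posterior medians, 89% highest-density intervals, and
the probability of direction pd, with p = 2·(1 − pd/100).

## Worked example

```r
library(ispcmed)

# paradigm with ~1:5 continuation:switching and 5% thumb-RT probes
sched <- generate_schedule(n_trials = 200, seed = 42)
table(sched$event)
#> continue    pause    start   switch      tRT
#>       29      209      192      159       35

# coupled sources, wavelet phases, ISPC
cp   <- coupling_spec(band = c(15, 22), mean_lag = 0.6, kappa = 8, snr = 2)
src  <- generate_sources(60, cp, seed = 42)
bank <- design_bank(fs = 250)
ph_l <- tf_phase(decompose(src, bank, source = "LSM1"))
ph_r <- tf_phase(decompose(src, bank, source = "RSM1"))
m    <- ispc(ph_l, ph_r, bank$freqs, src$time_s)
mean(m$values[bank$freqs >= 15 & bank$freqs <= 22, ])
#> 0.921        # strong locking planted in the beta band

# single-trial phase lags are non-uniform (Rayleigh)
lag <- extract_phase_lag(ph_l, ph_r, bank$freqs, src$time_s, c(15, 22), 0)
rayleigh_test(lag$lag_rad)
#>  n  r_bar     z        p
#> 60  0.920  50.8  9.4e-32

# moderated mediation on a synthetic cohort (true a1 = 0.5, b1 = -0.4)
co  <- generate_cohort(21, 21, mediation_truth(a1 = 0.5, b1 = -0.4), seed = 42)
fit <- fit_mediation(co, chains = 4, iter = 4000, warmup = 1000, seed = 42)
glance(fit)
#> converged  max_rhat  min_ess  r2_outcome  r2_mediator   n
#> TRUE       1.01      756      0.232       0.399         42
ce  <- conditional_effects(fit)
ind <- ce$indirect[ce$w_level == min(ce$w_level)]
c(mean = mean(ind), hdi(ind), pd = pd(ind))
#> mean -0.304, 89% HDI [-0.582, -0.020], pd 96.8%
```

The Rayleigh z of ~51 at n = 60 reflects the planted von Mises lag
concentration; the indirect-effect posterior recovers the planted
a1·b1 = −0.20 within its (wide, n = 42) credible interval, with pd 96.8%
(equivalent two-sided p = 0.064).

An end-to-end run (simulate → behavior → connectivity → clusters →
circular stats → GABA+ → mediation) with archived config, logs and a
manifest:

```r
run_pipeline(demo_config(), "out/demo")
```

## Vignette

`vignettes/methods.Rmd` documents the models, the synthetic data-generating
process and what it does and does not emulate, numerical choices,
tolerances, and known limitations.
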