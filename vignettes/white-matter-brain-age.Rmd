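---
title: "White matter brain age: model, synthetic cohort and analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{White matter brain age: model, synthetic cohort and analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

White matter microstructure degrades with age, and cerebrovascular risk
factors (hypertension, diabetes, hypercholesterolemia, obesity, smoking)
accelerate that degradation. A compact way to quantify it is a *white
matter brain age*: a convolutional regressor is trained to predict
chronological age from diffusion-tensor maps, and the *white matter brain
age gap* (WMBAG) — corrected predicted age minus chronological age — then
serves as a per-person index of accelerated white matter ageing. This
package implements that pipeline end to end for five co-registered
DWI-derived maps (FA, MD, AxD, RD, MO), together with the downstream
epidemiology: vascular risk scoring, cognition composites, association
models, bootstrap mediation and two-timepoint change analysis.

Because the imaging cohorts such models are normally trained on are
restricted, the package ships a fully synthetic generator whose ground
truth is known. Every stage — network, bias correction, regression
machinery, mediation — is validated on data where the right answer is
planted by construction.

## The age-regression network

Each map is modelled by an eight-block 3D CNN in the SFCN family:

* blocks 1–5: 3×3×3 convolution (zero padding 1), 3D batch
  normalisation, 2×2×2 max pooling (stride 2, floor division), ReLU;
* block 6: 1×1×1 convolution, batch normalisation, ReLU;
* block 7: flatten, dropout (rate 0.5, training only), fully connected
  layer to a 100-entry feature vector;
* block 8: linear regression over the features concatenated with the
  covariates (sex and scanner for a single-map network), yielding the
  scalar predicted age.

With the default channels `[32, 64, 128, 256, 256, 64]` and a
91×109×91 input, the spatial extent after block 6 is 2×3×2, so block 7
maps 64·(2·3·2) = 768 entries to 100 features:

```{r}
library(wmbrainage)
shape_trace(network_spec())
```

The five single-map networks are trained independently; fusion reuses
their frozen block-7 features and fits only block 8 by ordinary least
squares on the concatenated `100·5 + 3` vector (five feature sets plus
sex, scanner and intracranial volume). If the design is rank deficient
the head falls back to ridge regression and records the penalty.

Implementation notes (the numerical choices that were genuinely open):

* **Loss.** Default L1, which directly optimises the mean-absolute-error
  metric brain-age models are judged by; squared error is available as a
  configuration option.
* **Optimiser.** Adam with learning rate 0.01, batch size 16, and the
  block-8 intercept initialised at the training-mean age so optimisation
  starts from the no-information predictor. All training randomness
  (shuffling, dropout masks, initialisation) derives from one seed, and
  runs are bit-reproducible under a fixed seed and single-threaded BLAS.
* **Pooling arithmetic.** Kernel 2, stride 2, floor division is the only
  scheme that reproduces 91×109×91 → 2×3×2. Axes already reduced to one
  voxel pass through later pools unchanged; this keeps quarter-scale
  grids such as 24×28×24 usable without changing the full-size trace.
* **Covariates.** Scanner enters as a single numeric site code (0/1/2)
  so the fused input length is exactly 100·5 + 3; ICV is used only at
  the fusion stage.
* **Input normalisation.** Per-volume z-scoring (configurable off)
  stabilises small-batch batch-norm statistics.

The convolution itself is im2col + GEMM with hand-written
Rcpp/RcppArmadillo gather/scatter and pooling kernels; the backward pass
is checked against numerical differentiation in the test suite.

## Bias correction and performance

Raw brain-age predictions suffer regression dilution: the old are
predicted too young, the young too old. On the held-out validation set
the package fits `yhat = alpha*y + beta` and corrects test predictions by
`yhat_co = (yhat - beta)/alpha`; the gap is `wmbag = yhat_co - y`.
Two algebraic identities follow and are enforced to machine precision in
the tests: re-regressing corrected predictions on age over the fit set
gives slope 1 and intercept 0, and the corrected gap is uncorrelated with
age on the fit set. Correction is fitted on validation only and applied
unchanged everywhere else (including follow-up scans); it may raise MAE —
performance is therefore always reported alongside, never hidden.

## The synthetic cohort

`synth_config()` fixes the study conditions; `simulate_cohort()`,
`render_maps()`, `simulate_cognition()`, `make_splits()` and
`make_longitudinal_subset()` realise them. Defaults emulate the
published cohort: risk prevalences 0.504/0.055/0.245/0.190/0.381,
45.8% male, ages truncated-normal(64, 7.5²) on [45, 83], APOE ε4
distribution 72.2/25.5/2.3%, a 2.25 ± 0.12-year follow-up interval for a
12.6% longitudinal subset, and planted gap offsets of 1.390 y (diabetes),
0.871 y (hypertension), 0.689 y (smoking), 0.311 y
(hypercholesterolemia) and 0 (obesity) plus a male-only obesity
interaction of 1.023 y. Individual gap noise is N(0, 1²); participants
labelled unhealthy (9.1%) carry an extra 0.51 y and are quarantined into
the test split.

Two deliberate design choices:

* **Risk factors are independent Bernoulli draws.** Real factors are
  correlated; independence makes every planted coefficient identifiable
  and the recovery tests sharp. A consequence worth knowing: because the
  only sex-specific mechanism is the male-obesity term, the male excess
  in the top vascular-risk tier (three or more factors) *emerges* as
  `1.023 × P(obesity | count ≥ 3) ≈ 0.57` rather than being planted
  separately — consistent with the interpretation that obese men drive
  that tier. An explicit `vrs3plus_male_offset` field exists for
  experiments that want the tier effect without the obesity mechanism.
* **Maps are smooth phantoms, not anatomy.** Each map is a fixed
  spatial template plus an age-dependent amplitude driven by *effective
  age* (chronological age + true gap): the FA analogue declines by
  0.0030/y, MD/AxD/RD rise (0.0050/0.0045/0.0055 per year), and MO
  follows a concave quadratic, all modulated by a unit-mean spatial
  weight so the voxel-mean slope equals the configured slope. A shared
  participant-level field correlates the five maps, and i.i.d. Gaussian
  voxel noise (sd 0.02) is added. Nothing about tracts, lesions, scanner
  physics or registration artefacts is simulated — so passing tests show
  the *pipeline machinery* is correct, not that the network would reach
  any particular accuracy on real scans.

Cognition is generated with an explicit mediation structure: each latent
domain is `-(b_domain)·gap - Σ c'_k·factor_k + age/sex/education terms +
noise`, with defaults b = 0.025/0.008/0.018 per year of gap for
processing speed / memory / executive, a direct obesity path of 0.103
and a direct smoking path of 0.03; the seven raw test scores are affine
transforms of their domain latent, reversed where lower raw scores mean
better performance (reaction time, both trail-making tests,
pairs-matching errors). Note that z-scoring against the sample
attenuates path coefficients by the latent's total standard deviation,
so recovery tests on the z scale assert signs and calibration, not the
raw path values.

## Risk score, cognition composites and the association models

The vascular risk score counts the five binary factors, collapses ≥3,
and is dummy-coded against the zero-factor reference; any missing factor
makes the score missing (complete case). APOE is coded by ε4 allele
count. Cognition domains are available-case means of their constituent
z-scores (the reference sample is the baseline analysis sample) and the
global composite is the equal-weight mean of the three domains (rather
than a pooled mean over all seven tests) — equal-domain weighting is
this package's documented choice where either convention is defensible.

All inferential models are ordinary least squares with classical t-based
95% intervals and complete-case handling, the standard reporting
convention in this literature: an ANCOVA healthy/unhealthy contrast;
model 1a
(VRS dummies), 1b (plus sex×VRS, with delta-method within-level sex
contrasts), 2a (all five factors simultaneously), 2b–f (one factor plus
its sex interaction at a time); and the four WMBAG–cognition regressions
with Bonferroni control at 0.05/4 = 0.0125. Scanner and APOE enter as
single numeric codes by default (their table analogues have single
coefficient rows); every model is cross-checked against an independent
normal-equations solver at 1e-8 in the tests.

## Mediation

`mediate()` is a native product-of-coefficients implementation: `a` from
`M ~ X + C`, `b` and `c'` from `Y ~ X + M + C`; ACME = a·b, ADE = c',
total = ACME + ADE exactly. Confidence intervals are percentile
intervals from nonparametric case resampling (default 5000 draws,
seed-reproducible); bootstrap p-values are twice the smaller tail
proportion crossing zero. No exposure–mediator interaction is modelled —
the emulated analysis is plainly linear. Bootstrap resamples that lose
all exposure variance are redrawn and counted. Calibration is checked by
simulation: over 200 replicate datasets the 95% interval covers the
true a·b at close to nominal rate.

## Longitudinal analysis

Change scores are follow-up minus baseline for the gap, the corrected
predicted age and the cognition composites; the dependent t-test on gap
change is algebraically the one-sample t-test on differences (asserted
as an identity). Change regressions and change mediation reuse the
cross-sectional machinery with baseline covariates; the follow-up
interval is *not* a covariate by default (flag available), and baseline
gap adjustment is likewise off by default. The generator's follow-up
drift is +0.1 y beyond ageing, deliberately near-null so the
longitudinal battery exercises its null path; a planted-drift variant is
used as the positive control in the tests.

## Pipeline and problem sizes

`run_pipeline()` chains simulate → split → train → predict → correct →
analyse with one YAML-serialisable configuration and a single global
seed from which every stage derives its stream; each stage is also
runnable alone from its persisted intermediates (NIfTI maps, CSV
manifests and tables, JSON summary), and re-running with an unchanged
configuration reproduces identical summaries. The shipped problem sizes
are deliberate: the smoke preset (n = 120, 16³ grid, 2 epochs) completes
in seconds; the validation-scale runs used by the test-suite train five
networks on n = 400 at 24×28×24 with channels (8,16,32,32,32,16) and a
16-entry feature vector — enough for the fused validation MAE to beat
every single map and for test-set r ≈ 0.97 — and the effect-recovery and
mediation studies use n = 5000 and 200×499 bootstrap replicates on the
latent gap directly, bypassing the CNN where only the statistical
machinery is under test.

## Known limitations

* The phantom maps carry a strong, smooth age signal; real DWI maps are
  far noisier and anatomically structured, so desk-scale accuracy says
  nothing about attainable MAE on real cohorts.
* Risk-factor independence is a test harness choice, not epidemiology.
* Batch-norm statistics are running averages from small batches; very
  small training sets can leave them noisy (the evaluation path is
  nevertheless fully deterministic).
* The mediation model is linear with no exposure–mediator interaction
  and offers no sensitivity analysis for unmeasured confounding.
* Only two timepoints are supported; there is no trajectory modelling.
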