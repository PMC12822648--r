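---
title: "Models and methods behind mvpainfo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mvpainfo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mvpainfo` implements a complete multivariate fMRI analysis for
cross-decoding the *proximal shape* of objects — whether an object projects
a wide or a narrow silhouette on the retina — together with a synthetic
BOLD generator that emulates the two event-related designs the analysis is
built for. Because every stage can be run against simulated subjects with
known ground truth, every stage is testable: estimator identities are
checked against closed forms, and the group-level inferences are checked by
Monte-Carlo calibration (type-I error) and recovery (power) studies.

This vignette documents the generative model, the analysis model, the
tunable parameters and their defaults, the numerical choices, and what the
simulation-based validation does and does not establish about real data.

## The two experimental designs

The generator reproduces the trial structure of two experiments in which
participants watch indoor scenes rotate around the vertical axis while a
central object is temporarily occluded.

**Experiment 1** (7 main-task runs x 48 trials): after the rotation, the
object reappears either *congruently* with the new scene viewpoint (75% of
trials) or *incongruently* (25%). The four orientation-by-rotation
combinations (A30, A90, B30, B90) are balanced within each congruency
cell. The reappearance is a brief flash, modelled as an impulse. Because
the congruent cell has three times the trials of the incongruent cell, the
congruent trials of each run are split into three subsets the size of the
incongruent cell; each subset is modelled as a separate regressor, decoded
separately, and averaged. Splits are balanced within condition (9
congruent trials per condition split 3/3/3), which guarantees that every
condition-by-split decoding cell is populated.

**Experiment 2** (8 main-task runs x 40 trials): the object never
reappears except on 12.5% catch trials (2 to 10 per run), and the analysis
target is the *occluded* final period, modelled as a boxcar. Catch trials
receive their own regressors and are excluded from all decoding. At the
end of each run, the simulated participant reports how many times the
object reappeared; the run-wise correlation between true and reported
counts feeds the attention-based exclusion rule.

Both experiments include three classifier-training runs (mini-blocks of
the four combinations in Experiment 1; background-free wide/narrow
mini-blocks in Experiment 2) and two functional localizer runs. Timing
constants (TR 1 s; run lengths 404/315/333/318 volumes; mini-block and
trial durations) follow the acquisition protocol of the study designs; the
critical event carries a uniformly jittered onset. Trials sit on a fixed
within-run grid, and the design validator rejects configurations whose
events (plus a 15 s tail) do not fit the run.

## The generative model

Each simulated voxel $v$ carries:

* a nonnegative *responsiveness* gain $g_v \sim \Gamma(k, k)$ (mean 1,
  `responsiveness_shape` $k = 6$);
* shape patterns $w_v, n_v \sim g_v a_v \mathcal N(0,1)$ for wide and
  narrow projections, where $a_v$ is the per-ROI pattern amplitude
  (`roi_amp`, defaults EVC 1, LVC 0.7);
* background-confound patterns for the 30 and 90 degree scene
  orientations, scaled by `conf_amp` (default 0.5) — these let the
  background-matched decoding scheme be meaningful, since a classifier
  trained across backgrounds could otherwise exploit scene orientation;
* a synthetic localizer statistic `localizer_t` $= 5 g_v + \mathcal
  N(0,1)$.

Coupling signal amplitude to responsiveness makes top-N localizer
selection informative, which is the implicit premise of localizer-ranked
sub-ROIs. The correlation between responsiveness and absolute pattern
size is about 0.5 at the defaults and is property-tested.

A trial's true amplitude vector is the pattern of the *shown* (Experiment
1) or *expected* (Experiment 2) shape plus the background pattern of the
final scene orientation. Congruency acts multiplicatively through per-ROI
gains (`gain_congruent`, `gain_incongruent`; defaults 1.09/0.92 in the EVC
analog and 1/1 in the LVC analog, confining the effect to one region, as a
congruency-by-ROI interaction requires). Incongruent reappearances
additionally add a spatially uniform `surprise_amplitude` (default 0.5),
producing the higher univariate response to incongruent objects without
any multivariate claim. In Experiment 2 the occluded period carries the
expected-shape pattern scaled by a per-ROI `occluded_signal_gain`
(defaults EVC 0.095, LVC 0.155 — the top-down trace is relatively
stronger in the higher-order region) on top of the visible background
pattern;
backgrounds are balanced across shapes, so this is nuisance variance, not
a label confound.

Signals are convolved with the canonical double-gamma HRF (delays 6/16 s,
unit dispersions, undershoot ratio 1/6, unit peak) on a grid oversampled
4x relative to the TR (0.25 s resolution, finer than any design jitter
needs); impulses contribute the kernel itself, boxcars its running
integral. Noise is AR(1) Gaussian per voxel with marginal SD
`noise_sigma` (default 100) and lag-1 autocorrelation `ar1_rho` (default
0.3); white noise is the `ar1_rho = 0` case. Nothing is claimed about the
spatial or temporal noise structure of any real dataset — AR(1) is simply
the minimal temporally autocorrelated model, and spatial correlation is
deliberately absent.

The default noise and gain values were calibrated once so that the default
configuration lands in the empirically plausible regime for this kind of
study: mean classifier information around 0.30 (congruent) and 0.22
(incongruent) in the EVC analog, around 0.16 in the LVC analog, an EVC
congruency difference near 0.06, Experiment 2 occluded-period information
near 0.06 (higher-order region) with a between-subject SD near 0.1.

All randomness flows from a single integer seed through
`derive_seed(seed, ...)` (cohort -> subject -> run -> stage), so cohorts
are exactly reproducible and subjects are independent. Bulk noise uses a
dedicated xoshiro256++ generator in C++; design randomization uses R's
RNG under a locally scoped seed.

## The analysis model

**GLM.** One regressor per condition (per split, per mini-block) convolved
with the canonical HRF; a run intercept is always included, and motion or
button-press regressors can be appended as given columns. Estimation is
ordinary least squares via the SVD pseudoinverse (with a Cholesky fast
path for well-conditioned designs), so rank-deficient designs return the
minimum-norm solution and all-zero columns are flagged with zero
estimates. No prewhitening and no HRF derivatives: decoding consumes
relative pattern geometry, not single-voxel p-values. The FIR basis uses
ten non-overlapping 1-volume sticks per condition, bin 0 at the onset
volume (0-based).

**Sub-ROIs.** Voxels are ranked within each ROI-by-hemisphere mask by the
localizer statistic (descending, ties broken by ascending voxel index for
reproducibility) and the top-N sets are taken for N on a grid — 100 to
6000 in steps of 100 at full scale, yielding 60 nested sub-ROIs per mask.
Nesting and invariance to monotone transforms of the statistic are
property-tested.

**Decoding.** Linear hinge-loss SVMs (cost fixed at 1, recorded in the
configuration) are trained on standardized benchmark patterns; training
and test sets are z-scored separately per voxel with the population SD,
zero-variance voxels mapping to flagged zero columns. The decoding score
is *classifier information*:
$$\mathrm{CI} = \frac{1}{n}\sum_{i=1}^n d_i\, l_i,$$
with $d_i$ the z-scored signed distances from the decision boundary
across test samples and $l_i \in \{-1, +1\}$ the true labels. Chance is 0
by construction, the statistic is invariant to positive rescaling of raw
distances, and degenerate distances score 0. Distances are raw decision
values $w \cdot x + b$; the weight-norm scaling drops out in the
z-scoring. A classification-accuracy mode (chance 0.5) is available for
parity checks.

In Experiment 1, classifiers discriminate the two object orientations
against a matched background (A30 vs B30; A90 vs B90), so shape, not
scene orientation, drives the decision; information is averaged over
backgrounds, congruent splits, and both train/test directions. The
reverse direction trains one classifier per congruency-by-background-by-
split cell on the main-task betas and tests it on the matching-background
training betas. Incongruent test labels are the orientation actually
shown. In Experiment 2 a single wide-versus-narrow classifier is trained
on the background-free benchmark and tested on the occluded-period betas
(and vice versa). Test distances are pooled across runs within a cell
before z-scoring; a `within_run` mode exists, but with two samples per
run it degenerates to plus/minus 1 and is therefore not the default —
the ambiguity is documented rather than resolved.

The SVM solver is a deterministic cyclic coordinate-descent dual solver
with an L2-regularized intercept (augmented-feature formulation),
warm-started across nested sub-ROI sizes. It is validated in the test
suite against a brute-force margin search and against an independent
reference implementation (`e1071`); the regularized intercept makes
decision values agree with the reference closely but not identically,
which the scale-invariant information statistic is insensitive to.

**Group inference.** Per subject, classifier information is averaged over
sub-ROI sizes and hemispheres; conditions are compared with paired t
tests (Cohen's d and 95% CI reported), regions against zero with
one-sample t tests, and the congruency-by-ROI interaction with the
repeated-measures F that equals the squared paired t of each subject's
difference-of-differences — an identity the tests verify to 1e-10.
Robustness across the voxel-inclusion sweep uses one-dimensional TFCE,
$\mathrm{TFCE}(s) = \sum_{h} e(h,s)^{E} h^{H}\, \Delta h$, with the
field-standard exponents E = 0.5, H = 2 and step
$\Delta h = \max|t|/100$; negative statistics are enhanced on the
mirrored curve with the sign restored. The null distribution flips each
subject's whole curve with probability 1/2 (10,000 permutations by
default); with the default `max` null mode each permutation contributes
its maximum enhanced value, so the per-point p values are family-wise
corrected (a `pointwise` mode is available — which of the two a given
report used is often ambiguous, so both are explicit here). Permutation
p values use the add-one convention $(1 + \#\{\text{null} \ge
\text{obs}\})/(1 + n_\text{perm})$, which is valid and slightly
conservative.

**Univariate and whole-brain.** Within-ROI univariate summaries average
betas over voxels, then sub-ROI sizes. The whole-brain contrast runs a
per-voxel one-sample t across subjects, thresholds at an uncorrected
alpha (default 0.001), groups surviving voxels into face-adjacent
(6-connected) clusters, and removes clusters below 10 voxels; positive
and negative voxels cluster separately under the two-sided test.

**Information-activation coupling.** FIR time courses (10 bins of 1 s)
are estimated per shape-by-congruency condition; the seed region's
time-resolved classifier information (classifier trained on wide versus
narrow mini-blocks, applied to each bin's patterns) is correlated,
across bins, with every voxel's condition-wise activation curve. The
analysis repeats for seed sizes 500-1000 voxels (pooled across
hemispheres, per the seed-selection rule) and averages the maps before
the one-sided congruent-greater-than-incongruent cluster contrast.
Zero-variance voxels contribute r = 0 rather than being dropped, keeping
map geometry identical across subjects; correlations are used raw, with
a Fisher-z option behind a flag.

**Exclusion rule.** A subject is excluded when the mean true-versus-
reported correlation falls strictly below Q1 minus twice the
interquartile range. Quartiles use linear interpolation (R type 7) —
IQR rules depend on the quantile convention, so it is fixed and
documented.

## Validation design and problem sizes

The acceptance suite validates the pipeline at reduced problem sizes,
chosen so the whole suite runs in well under half an hour on one CPU;
the statistical properties under test are size-invariant, which is why
scaling is legitimate:

* **Type-I calibration.** 200 replicate null cohorts (equal congruency
  gains, no surprise), 6 subjects each, EVC analog with 600 voxels per
  hemisphere, sub-ROIs 100-600, 500 sign-flip permutations. The
  exchangeability of the sign-flip null does not depend on cohort size,
  so the family-wise false-positive rate of the TFCE test is expected in
  the [0.02, 0.09] acceptance band around the nominal 0.05 at any n; a
  200-cohort binomial estimate resolves that band, and the test suite
  computes the realized rate.
* **Effect recovery (Experiment 1).** The EVC-analog gains of
  1.185/0.815 were calibrated once, from the configuration's measured
  dose-response, to put the expected per-subject congruent-minus-
  incongruent difference near 0.057 (the test asserts the realized
  value); cohorts use 30 subjects, at which a one-sided paired t has
  roughly 90% power against the between-subject SD the generator
  produces (about 0.1 at this configuration). The no-effect LVC analog
  bounds the false-declare rate.
* **Effect recovery (Experiment 2).** A strong occluded-signal
  configuration (gain 0.9: mean information 0.14, SD 0.08 per subject)
  against a zero-gain null, 8-subject cohorts, LVC analog with 200
  voxels: detection is near-certain with the effect and near-alpha
  without it.
* **Coupling recovery.** Constructed FIR/seed curves (a 15-voxel block
  tracking the congruent-condition information curve) exercise the
  coupling correlation and cluster contrast directly, with a matched
  null establishing the reference false-positive rate.

What passing these tests shows: the estimators match their closed forms,
the decoding statistic is unbiased at chance, the permutation machinery
controls family-wise error under exchangeable nulls, and the pipeline
recovers effects of the size and reliability the generator injects. What
they do not show: anything about preprocessing, spatially structured
noise, HRF misspecification, or any particular real dataset — the
generator's noise is temporally AR(1), spatially white, and its HRF is
exactly the analysis HRF, so the validation isolates the statistical
pipeline rather than stress-testing physiological assumptions.

## Known limitations

* The simulated noise is spatially independent; cluster-extent
  inferences on simulated whole-brain maps are calibrated for that case
  only, and real smoothed data would need a spatially correlated
  extension (off by default, not implemented).
* The forward model and the analysis share one HRF, so HRF mismatch is
  untested by construction.
* With two test samples per run, within-run distance z-scoring is
  degenerate; the pooled default is a documented choice, not a resolved
  question.
* Anatomical ROI construction is out of scope: region identity comes
  from voxel metadata (synthetic mode) or caller-provided masks.
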