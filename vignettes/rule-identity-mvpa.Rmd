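---
title: "Stage-resolved MVPA of newly instructed rule identities: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-resolved MVPA of newly instructed rule identities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rulemvpa)
```

## The question and the statistic

When people learn arbitrary stimulus-response (S-R) rules from one-shot
instruction ("for BUTTER, press the middle finger"), the first few
implementation trials are the only window in which the brand-new rule
representation can be observed. `rulemvpa` implements a time-resolved
multivoxel pattern analysis for exactly this window, together with a
ground-truthed simulator so that every stage of the pipeline can be validated
without any scanner data.

The core statistic is *identity-specific pattern similarity*. Within one
learning block, four stimuli are each implemented twice per *stage* (stage
$s$ spans repetitions $2s-1$ and $2s$). For the 8 single-trial activation
patterns $\mathbf{b}_1,\dots,\mathbf{b}_8$ of a block-stage, all
$\binom{8}{2}=28$ pairwise Pearson correlations over voxels are computed and

$$\Delta \;=\; \overline{r}_{\text{same stimulus}} \;-\;
              \overline{r}_{\text{different stimulus}}$$

with 4 same-stimulus and 24 different-stimulus pairs. $\Delta > 0$ indicates
that the region carries information about *which* rule is being implemented,
over and above any condition-general activation. Per subject, $\Delta$ is
averaged over blocks separately per condition and stage
(`subject_similarity()`), and group inference uses within-subject ANOVA and
one-sample tests (`rm_anova()`, `one_sample_t()`).

Correlations are computed on raw single-trial betas without voxel-wise
normalization, and same/different cells are averaged as plain correlations; a
Fisher-z flag exists (`fisher_z`) but defaults off, since the statistic is
defined as a difference of mean correlations.

## Why trial order must be built from atomic sequences

Single-trial estimates of temporally close trials are correlated through the
estimator whenever BOLD responses overlap (SOAs of 2–4 s at TR = 2 s).
For any *fixed* trial sequence, $\Delta$ therefore has a nonzero expectation
even for pure noise patterns — a design-induced bias. The package's design
generator composes each block's implementation order from independently
randomized *atomic sequences*, one per stage, each containing exactly two
occurrences of each of the four stimuli (`generate_atomic_sequence()`).
Under uniformly random atomic sequences every trial-position pair is equally
likely to host a same-stimulus pair, so the expected bias is exactly zero;
individual blocks still carry nonzero bias, distributed around zero.

`estimate_sequence_bias()` measures this by Monte Carlo: every trial gets an
independent random pattern, the noise-free data are pushed through the LSS
estimator, and the stage-wise $\Delta$ is averaged. Because the estimator is
linear, the noise-free betas are an exact linear mixing of the true patterns
(`lss_trial_mixing()`), which serves as a fast, algebraically equivalent
route; both routes agree draw-by-draw to numerical precision and the full
route is kept as a cross-check. `scheme_bias_profile()` contrasts the atomic
scheme with the naive alternative — fully randomizing all 16 (or 32) trials
and splitting stages retrospectively by occurrence order — which is both
systematically biased away from zero and spreads per-block bias more widely.

Because the realized bias of a block's sequences is shared by every region,
subjects' block-wise deltas in a white-matter control region (where no
stimulus information is expected) measure it directly.
`wm_bias_adjust()` regresses ROI block deltas on white-matter block deltas
and uses the regression *intercept* — the ROI delta expected at zero measured
bias — as the adjusted estimate. The residual-mean alternative would equal
the raw mean and remove nothing. Adjustment is applied per condition-by-stage
cell; adjusting before condition averaging is the plausible alternative and
differs only in weighting.

## The single-trial GLM

`fit_lss()` implements least-squares-separate estimation: one GLM per
implementation trial with (i) the target-trial regressor, (ii) one regressor
for all other implementation trials of the run (including other blocks),
(iii) an instruction-phase model, (iv) one feedback regressor pooling all
feedback displays of the run, (v) the run constant, and (vi) a
discrete-cosine high-pass set with $K = \lfloor 2\,T\,\mathrm{TR}/
\mathrm{cutoff}\rfloor$ columns (128 s cutoff for the 4-repetition
experiment, 256 s for the 8-repetition experiment, matching the block
lengths). Announcement displays are deliberately unmodeled (absorbed by the
baseline). All trial-wise designs share their nuisance block, so the package
residualizes once per run and solves each trial's 2×2 normal equations in
closed form — algebraically identical to, and verified against, fitting every
design separately.

Event regressors are stick functions at stimulus onset convolved with the
canonical double-gamma HRF (peak 6 s, undershoot 16 s, unit dispersions,
undershoot ratio 1/6, 32 s support), built at a microtime resolution of
TR/16 and sampled at the middle microtime bin.

The instruction phase (announcement, 4 or 10 noun-response pairings,
implementation announcement; 12–14 s) produces a sustained response of
unknown shape. It is modeled with an order-10 Fourier set — 20 sine and
cosine regressors spanning a 44 s window (the instruction span plus the HRF
support), time-locked to each instruction onset. Two points matter here:

* The 20 regressors are *pure harmonics without a DC term*; window-mean
  activity is left to the baseline, so instruction responses contribute at
  most a voxel-constant offset to nearby trial betas, which pattern
  correlations cancel exactly (Pearson centers each trial over voxels).
* One set of coefficients is shared by *all* instruction phases of a run:
  the basis functions superpose the per-block windows, as when a basis set
  is convolved with the pooled onset stick. This is essential. Giving every
  block its own 20 columns would place ~20 free parameters on the ~22
  volumes of its window, nearly saturating it; early implementation trials
  (which overlap the window) would then be estimable only from their
  response tails, inflating stage-1 beta variance by an order of magnitude
  and effectively erasing stage-1 effects. With the shared set, only the
  across-block common response shape is removed and all stages are estimated
  with comparable precision — which is also the only reading consistent with
  stage-1 effects being observable at all.

Temporal autocorrelation is handled by AR(1) prewhitening with one pooled
coefficient per run (`ar1 = "estimate"`), estimated as the lag-1
autocorrelation of the residuals of the reduced model (all-trials regressor
plus nuisance). The near-saturated all-trials-separate design is *not* used
for this estimate: with only ~50 residual degrees of freedom per run it
produces strongly negative artifactual autocorrelations. The estimated
coefficient absorbs unmodeled smooth trial-amplitude variation as well as
the noise process and therefore tends to exceed the innovation value used in
simulation; this is the standard behavior of residual-based AR estimation
and is harmless for the (unbiased) GLS fit. `ar1 = "off"` and
`ar1 = "fixed"` are available, and fixed-zero is bit-identical to off.

## What the simulator emulates — and what it does not

`simulate_subject()` generates runs in which every implementation trial
contributes, in each responsive region, a mean amplitude plus a multivoxel
pattern, convolved with the canonical HRF:

* a **rule-identity code** (`sigma_identity`, default SD 1.0) in the signal
  prefrontal region, drawn once per block per stimulus — *block-local*, so
  no information transfers across blocks — and absent in the control
  condition, where the response cue removes the need to memorize rules;
* a **stimulus-identity code** in the visual region and a
  **response-identity code** (keyed to the *executed* response) in the motor
  region (`sigma_stim`, `sigma_resp`, default 1.0), in all conditions;
* **no identity code** in the contrast prefrontal region, white matter, or
  striatum;
* i.i.d. per-trial pattern noise (`trial_noise_sd`, default 1.0) in every
  responsive region, so same-stimulus correlations stay well below 1;
* declining mean amplitude over repetitions (`amp_by_repetition`, default
  3.0 → 1.2 over 8 repetitions), emulating the rapid practice-related
  decrease of mean activity that coexists with stable identity coding;
* per-trial amplitude jitter (`amp_noise_sd`, default 0.5) whose
  prefrontal-striatal correlation is the connectivity ground truth
  (`coupling`: learning 0.1 early → 0.6 late, control flat 0.1;
  intermediate repetitions use the early value);
* sustained instruction activity (boxcar × HRF, amplitude 2.0, gray-matter
  regions), event-related feedback activity (1.5), and stationary AR(1)
  voxel noise (`noise_sd` 1.0, `ar1_rho` 0.3).

The behavioral generator draws errors per condition and repetition
(declining; higher under difficult instructions, near-floor with response
cues), response times (declining, slower for difficult), and implements
perseveration: after an erroneous execution the subject adopts the executed
response as their rule with probability 0.5, so later repetitions of the
error are consistent. This is what makes the *subjective* accuracy rule
(score against the previously executed response; against the instruction at
repetition 1) exceed objective accuracy, as `score_accuracy()` measures.
Omissions (default probability 0) are errors under both rules and the
subjective reference skips them.

True effect magnitudes of prefrontal identity codes are unknown — published
results report statistics, not pattern amplitudes — so the defaults are
explicitly arbitrary, chosen once to give comfortable recovery at a cohort
size of 20 and documented as such. Passing recovery tests therefore
demonstrates that the *pipeline* is correct and selective (signal appears
where and only where it was implanted), not that real effects of this size
exist. The simulator also deliberately omits physiological noise structure,
motion, spatial autocorrelation, susceptibility dropout and slice timing;
the phantom atlas packs compact synthetic regions rather than anatomical
ROIs.

## Group inference

`rm_anova()` builds fully within-subject factorial ANOVAs from orthonormal
(polynomial) contrast variables. For each effect, per-subject scores
$Z = Y\,C$ give $F = \frac{n\,\|\bar z\|^2 / q}{\mathrm{tr}(S_Z)\,(n-1)/
(q(n-1))}$, the Greenhouse-Geisser $\varepsilon =
\mathrm{tr}(S)^2 / (q\,\mathrm{tr}(S^2))$ comes from the contrast
covariance (clamped to $[1/q, 1]$; identically 1 for 2-level factors), and
partial $\eta^2 = F\,df_1/(F\,df_1 + df_2)$. The constant term tests the
grand mean against zero and equals the squared one-sample $t$. Implementing
the decomposition directly (rather than delegating) makes $\varepsilon$ and
partial $\eta^2$ first-class outputs; the suite verifies the F statistics
against the classical `aov()` error-strata decomposition. Linear trends over
repetition are polynomial-contrast tests (`rm_contrast()`, `poly_weights()`).
Missing cells are refused with instructions to aggregate upstream; post-hoc
tests are reported uncorrected and labeled as such.

For voxel maps, family-wise error is controlled by max-statistic sign-flip
permutation (`maxstat_fwe()`): corrected $p(v) = (1 + \#\{\max_b t \ge
t(v)\})/(B+1)$. This replaces random-field theory deliberately: it is
self-contained, assumption-light, exact under sign symmetry, and dominates
the per-voxel permutation p by construction.

## Connectivity

`connectivity_change()` correlates seed and target single-trial beta series
(unweighted region means) within the early (repetitions 1–2) and late
(repetitions 7–8) windows, Fisher-z transforms, and contrasts
$(z_{\text{late}}-z_{\text{early}})_{\text{learning}} -
(z_{\text{late}}-z_{\text{early}})_{\text{control}}$. Error trials are
excluded. Trials are pooled across a condition's blocks before correlating —
per-block windows hold only 8 trials, too few for stable correlations — with
per-block correlation and averaging available as an option
(`per_block = TRUE`); whether the original analyses pooled or averaged is
not documented, so the default is the variant that is statistically stable
at these window sizes. Note that shared trial-amplitude structure (the
repetition-wise amplitude decline, instruction spillover) inflates the
*baseline* beta-series correlation in all windows alike; the double
difference removes it, which is exactly why the contrast rather than raw
correlations is the unit of inference.

## Numerical and degenerate-input policy

* Correlation of a constant pattern is undefined: `stage_similarity()`
  errors, and block-stage cells hitting such errors (or losing the
  two-occurrences-per-stimulus structure under correct-only filtering)
  become `NA` and are dropped from block averages; group cells average the
  remaining blocks and `n_blocks` records how many.
* Searchlight spheres use Euclidean distance in voxel units, include the
  center (123 voxels at radius 3), are clipped at mask borders, and yield
  `NA` below 2 usable voxels.
* LSS designs are checked for rank; exact collinearity (e.g. coincident
  trial onsets) errors with the offending column names.
* Beta-series correlations of |r| = 1 or zero-variance series error rather
  than returning infinite z.
* All randomness flows through explicit integer seeds; per-subject seeds are
  derived deterministically from a master seed, and identical seeds
  reproduce BOLD arrays bit-for-bit.

## Validation problem sizes

The shipped test-suite exercises the pipeline at sizes chosen to give tight
Monte-Carlo error at interactive runtimes: 200 fresh blocks per sequencing
scheme (100 pattern draws each) for the bias profile; a default-parameter
cohort of 20 subjects of the full 8-repetition paradigm for recovery,
selectivity and connectivity; 100 null cohorts of 15 subjects on a reduced
grid (two 40-voxel regions, four blocks, one run) for false-positive
calibration; and 100 random 8×50 inputs for oracle equivalence of the
similarity statistic at 1e-12.

## Known limitations

* The generative model is linear in the HRF (as is the GLM); saturation and
  nonlinear interactions of 2 s SOA stimuli are not emulated.
* No spatial structure: noise and patterns are voxel-independent, so
  searchlight maps on synthetic data are optimistic about spatial precision.
* The subjective-accuracy fallback chain for omissions (previous non-omitted
  execution, else the instruction) is one of several defensible readings.
* The AR(1) coefficient is pooled per run rather than spatially varying.
* With only two blocks per condition-stage cell, white-matter adjustment is
  skipped (mean returned); the adjustment needs several blocks to be useful.
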