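---
title: "Synthetic T1-weighted cord MRI: models, phantoms and trial statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthetic T1-weighted cord MRI: models, phantoms and trial statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`cordsynth` implements a complete desk-scale workflow around synthetic
T1-weighted (MPRAGE-contrast) MRI of the cervical spinal cord: voxelwise
contrast synthesis from quantitative maps, cross-sectional-area (CSA)
morphometry, calibration of the reconstruction parameters against a
reference contrast, and the agreement, longitudinal-trajectory and
trial-planning statistics built on top of CSA tables. This vignette is the
package's account of the underlying models, the choices that were open, and
what the synthetic-data experiments do and do not demonstrate.

## 1. The signal model

A magnetization-prepared spoiled gradient-echo acquisition repeats the
cycle *inversion → wait `TA = TI − τ/2` → readout train of `n` excitations
of flip angle α spaced `ES` → wait `TD`*, with `τ = n·ES` and
`TD = TR − (TI − τ/2) − τ`. Under linear (centric-ordered in partition
direction) k-space sampling the image contrast is set at the central
excitation, giving the closed-form voxel signal

\[
S \;=\; PD\,\sin\alpha\; e^{-TE\cdot R_2^*} \; Q(R_1;\alpha,TI,TR,ES,n),
\]

where `Q` is the steady-state longitudinal magnetization just before the
central excitation, normalized to equilibrium:

\[
Q=\frac{E_4\,(1-2E_1+E_1E_2)+T_1^{*}R_1\,(1+E_1E_2E_3-E_1E_2E_4-E_4)}
       {1+E_1E_2E_3},
\]

with `E1 = exp(−(TI − τ/2)R1)`, `E2 = exp(−TD·R1)`, `E3 = exp(−τ/T1*)`,
`E4 = exp(−τ/(2T1*))` and the apparent relaxation time
`T1* = (R1 − ln cos α / ES)^{−1}`. All times are seconds internally;
constructors accept milliseconds (`seq_params_ms()`) because protocols are
printed that way — this removes an entire class of ms/s unit bugs at the
boundary.

**Reconstruction vs acquisition.** Nothing in the closed form requires the
timing to be playable on a scanner. `derive_timing()` flags parameter sets
with `TD < 0` or `TI < τ/2` as infeasible; synthesis proceeds with a
warning (then `E2 > 1`, an "anti-decay" over a negative interval), because
a reconstruction is free of pulse-timing constraints. The pulse-by-pulse
simulator refuses such settings — it simulates physical sequences only. We
deliberately do not clamp `E2`.

**Verification, and a known approximation.** `bloch_oracle()` simulates the
cycle pulse by pulse (perfect inversion and spoiling, relaxation between
pulses) to its fixed point, sampling `sin α · Mz` at the excitation played
at `τ/2` (index `⌊n/2⌋ + 1`, 1-based — the pulse at exactly `τ/2` for even
`n`). Two facts emerged from building this oracle, both covered by tests:

* The closed form above uses the *continuous-train* equilibrium
  `m = T1*·R1`. Substituting the exact pulsed-train equilibrium
  `m = (1 − e^{−ES·R1})/(1 − cos α · e^{−ES·R1})` — available as
  `compute_Q(..., train_equilibrium = "discrete")` — reproduces the
  pulse-by-pulse fixed point to machine precision (the per-step decay
  `cos α · e^{−ES·R1} = e^{−ES/T1*}` is exact, so the only approximation in
  the closed form is the equilibrium value).
* Consequently the published form deviates from the discrete steady state
  by a relative `≈ −ln(cos α)/2`: 0.2% at α = 6° up to ~2% at α = 14° in
  the regimes exercised here. For image synthesis this is immaterial (it is
  a smooth, nearly multiplicative perturbation of contrast), but any claim
  of sub-0.1% agreement between the closed form and a genuine pulse
  simulation at these flip angles is not attainable, and our acceptance
  suite records that honestly rather than weakening the oracle.

## 2. Phantoms and the synthetic cohort

No imaging or cohort data are redistributable, so the package generates
both.

**Geometry phantoms** (`phantom_spec()`, `make_cord_phantom()`) rasterize a
tilted cylinder ("cord") inside an annulus ("CSF") inside background onto
PD/R1/R2\* maps. Partial-volume fractions at class boundaries come from
regular `k³` sub-voxel sampling (`k = 5` default; error bounded by the
sampling resolution and tested against the analytic areas). Tissue values
are *plausible defaults, not measured values*: cord PD 0.7 / R1 1.0 s⁻¹ /
R2\* 30 s⁻¹ and CSF PD 1.0 / R1 0.25 s⁻¹ / R2\* 1.5 s⁻¹. The default
background is an air-like low-signal class, like a cord phantom in a water
bath, so that threshold segmentation is well posed; a muscle-like
background is one `tissue_params` entry away but then the cord is no longer
separable by a single global threshold, which is precisely why clinical
pipelines use learned segmenters. Ground truth per slice: the in-plane cut
of a cylinder of radius `r` tilted by θ is an ellipse of area `πr²/cos θ`;
after centerline angle correction the true CSA is `πr²`. The phantom also
returns its exact cord-fraction field and the majority-voxel mask.

One real physical effect falls out of this construction: at boundary
voxels the *parameter maps* mix, and the signal equation is concave in the
mixing fraction, so the intensity of a 50/50 voxel is not midway between
the class intensities. Threshold segmentation of the synthesized contrast
therefore carries a contrast-dependent partial-volume bias of several
percent in area — the same kind of synthetic-vs-reference CSA bias that
motivates calibrating the reconstruction parameters in the first place. The
phantom tests separate this effect (full-pipeline checks use the
digitization bound) from the geometry of angle correction (checked on the
ground-truth mask, which recovers `πr²` to 0.2% at a 30° tilt).

**Cohort simulator** (`cohort_spec()`, `simulate_cohort()`) draws
long-format CSA records — one row per subject × timepoint × vertebral level
× modality — from the same generative structure the trajectory model fits:
group-specific intercept, linear and quadratic time, an age×time term,
per-subject random intercept/slope/quadratic and per-level offsets, a
shared residual, and per-modality additive bias plus measurement noise.
Defaults are the study conditions: 21 controls + 23 patients at months
{0, 2, 6, 12, 24} over C1–C3; fixed effects mirroring the synthetic-contrast
trajectory (baselines 66.15/63.64 mm², rates 0.041/−0.489 mm²/month — rate
difference −0.530 — and quadratics −0.00136/+0.00442 mm²/month², which
place the 24-month group means at 66.35/54.45 mm²); a synthetic-modality
bias of −0.31 mm². Values with no published anchor were chosen once as
field-plausible and are documented here: random-effect SDs 6 mm²
(intercept), 0.08 mm²/month (slope), 0.002 (quadratic), 1 mm² (level),
residual SD 1.4 mm², modality noise 0.7 mm², ages uniform around group
means of ~34/~47 years, and a scanner indicator switching mid-study.

What passing these simulations shows — and what it does not: the
statistics recover exactly the structure they assume, so these experiments
validate *implementation* (estimators, contrasts, intervals), not
robustness to real-world violations (artifact-driven exclusions, outcome
truncation, non-Gaussian noise, segmentation failures in pathology), which
the generator deliberately does not model.

## 3. Morphometry

`segment_cord()` is a documented, reproducible stand-in for learned cord
segmentation: global threshold, then per-slice largest connected component.
The default `"midpoint"` threshold is estimated in two stages — a
deterministic 2-means split (centers initialized at the intensity extremes)
gives an initial mask; the threshold is then recomputed as the midpoint
between the median intensity inside the mask and the median in a 2-voxel
shell around it. The refinement matters: with three intensity classes the
single global split lumps CSF with background and dilates the cord by ~20%
in area; the shell-based midpoint removes this. Otsu and fixed thresholds
are available. Both relative methods make the mask invariant to global
intensity scaling (tested). An optional partial-volume refinement
(`pv_refine`) estimates sub-voxel areas from a bilinearly upsampled slice;
it is off by default so that the default pipeline is exact integer voxel
counting.

`measure_csa()` computes per-slice areas, estimates the centerline as the
Gaussian-smoothed centroid path (σ = 2 slices; the path is padded by linear
extrapolation before smoothing so a straight centerline keeps its slope at
the volume edges — plain truncated kernels flatten the tangent there and
underestimate the angle), takes the tangent by central differences in
physical coordinates, and corrects each slice by `cos θ`. Correction is per
slice (`raw × cos θ`), the simplest defensible reading of
"angle-corrected"; path-length rescaling would differ only for curved
cords. Vertebral levels are user-supplied disjoint slice ranges — vertebral
labeling is out of scope.

## 4. Calibrating reconstruction parameters

`grid_search()` exhaustively evaluates a full factorial grid; per subject
the synthesized volume is segmented, level CSAs are computed, the median
across levels is compared with the subject's reference CSA, and the
default objective is the absolute value of the mean signed difference
across subjects (`"abs_mean"`; the mean of absolute differences is one
flag away — the mean-based objective deliberately allows cancellation,
matching an accuracy-across-cohort reading, and the tests document this
property). Default ranges are α 6–14°, TI 400–1000 ms, TR 1000–2500 ms,
TE 0–10 ms, ES 5–16 ms; default steps (2°, 100 ms, 250 ms, 2 ms, 1 ms;
17,640 cells) are round values spanning those ranges chosen so the full
grid runs in minutes on one CPU (~10 min at the packaged calibration-set
size). `Q` does not depend on TE, so each (α, TI, TR, ES) synthesis is
reused across the TE axis.

Because the objective is built from binary masks of noiseless phantoms, it
is a step function of the parameters: distinct cells can give bit-identical
masks and hence *exact* ties — including wide ties at objective 0 when the
reference was generated by the pipeline itself. Ties are first-class
output: the argmin is the lexicographically first tied cell (α, TI, TR,
TE, ES ascending) and all tied cells are recorded. Recovery experiments
therefore assert that the generating cell attains objective exactly 0 and
sits in the recorded minimizer set. The calibration phantoms ship with
sub-voxel center offsets, small tilts and per-slice radius ramps precisely
to break grid symmetry and shrink these plateaus.

## 5. Agreement and precision statistics

`bland_altman()` uses the textbook estimator: differences `b − a`, bias =
mean, limits of agreement = bias ± 1.96·SD (sample SD; the multiplier is a
parameter), percentages relative to the mean of the two method means. One
analysis point is one subject at one timepoint, averaged across levels
(`csa_pairs()`), keeping points independent for the group comparison.

The group-bias comparison uses a default-prior Bayesian two-sample test:
the JZS Bayes factor with a Cauchy prior (scale `√2/2`) on the
standardized effect, computed by adaptive quadrature over the g-prior
integral. No packaged implementation is available in this environment, so
the integrand is written out and its test oracle is an independent
fixed-grid trapezoid quadrature at 10× density (agreement to 1e−6). Labels
follow the Jeffreys reading: BF₁₀ > 3 evidence for a group difference,
< 1/3 evidence for equivalence, otherwise inconclusive; degenerate
zero-variance inputs return the t = 0 limit with a warning.

`repeatability_sd()` quantifies precision as the per-subject SD of CSA
across timepoints — per level then averaged (default), or on the
across-level mean series — summarized as cohort mean ± SD, intended for
stable (control) measurements.

## 6. Longitudinal trajectory model

`fit_trajectory_model()` fits, per modality,

```
csa ~ level + time*group + I(time^2)*group + age_c:time + scanner + (RE)
```

by REML (flag for ML), with time in months since enrollment (uncentered)
and age mean-centered before its interaction. The requested random
structure starts at per-subject intercept + slope + quadratic + level and,
when singular or non-convergent, is reduced stepwise (drop time², then
level, then all random effects → `lm`), with messages; the realized
structure is recorded. p-values and intervals use the normal approximation
by default (`df_method = "satterthwaite"` is the documented alternative) —
the original cohort's exact inference is not reproducible anyway, so the
contract favors simplicity. `group_contrast()` reports per-group linear
rates (the instantaneous slope at baseline), quadratic terms, or marginal
CSA at a timepoint (averaged over levels, age at the cohort mean,
reference scanner), always with the patients − controls difference; when a
call requests several contrasts they form the multiplicity family,
adjusted by the multivariate-normal method. Replicate simulations at the
study size recover the generative rate difference of −0.530 mm²/month with
|bias| < 0.03 over 200 cohorts.

## 7. Trial sample size

`ancova_n()` implements the baseline-adjusted two-arm comparison:
`n = ⌈2 (z_{1−α/2} + z_{power})² σ² (1 − ρ²) / Δ²⌉` per group (floor 2),
with Δ a fraction of the reference patients-minus-controls difference at
follow-up. σ is a *required* input: the value behind any published pair of
sample sizes is not recoverable without it, so only ratio arithmetic
(`relative_reduction()`) of published sizes is reproducible. At ρ = 0 the
formula reduces exactly to the two-sample normal approximation. The normal
quantiles are slightly anticonservative at small n (Monte-Carlo power 0.75
at n = 8, ρ = 0.94); `method = "t"` iterates t-quantiles at the ANCOVA
residual df `2n − 3` and restores the target within sampling error.
`simulate_ancova_power()` is the cross-check: bivariate-normal
baseline/follow-up pairs, `lm(followup ~ baseline + arm)`, two-sided test
of the arm coefficient.

## 8. Numerical and reproducibility choices

* Every stochastic operation takes an explicit integer seed; generators are
  pure functions of (spec, seed), and derived sub-seeds stay below 2³¹.
* Oracle convergence: cycle-to-cycle change of the sampled signal < 1e−10
  (configurable), error with residual on non-convergence.
* Exact-tie bookkeeping in the grid search uses exact floating equality on
  the objective deliberately: ties of interest are bit-identical, not
  approximately equal.
* Degenerate inputs: all-constant volumes error ("no cord found"); empty
  slices are excluded with a message; subjects failing morphometry are
  excluded from the calibration objective with a message (all-fail is an
  error); CSA draws ≤ 0 are resampled and counted.
* Problem sizes used by the packaged experiments — 20×20×9 calibration
  phantoms, a 48×28×40 tilt phantom, 200-subject agreement cohorts, 200
  replicate trajectory fits, 2000 Monte-Carlo trials — were chosen as the
  smallest sizes at which the checked quantities are statistically stable.

## 9. Known limitations

* The closed form inherits the continuous-train equilibrium approximation
  (section 1); reconstruction contrast is faithful to the published model,
  not to a discrete Bloch simulation, and the two differ by up to ~2% at
  α = 14°.
* Threshold segmentation presumes a cord separable from its immediate
  surround by one global threshold; it is a stand-in for learned
  segmentation, not a competitor.
* The cohort simulator models none of the artifact/exclusion processes of
  real data, and its Gaussian random effects make the mixed model exactly
  well-specified.
* Marginal estimates fix covariates at reference values (cohort-mean age,
  first scanner level, equal level weights); other conventions shift
  intercept-like quantities but not contrasts of interest.
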