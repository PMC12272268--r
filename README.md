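# cordsynth

Synthetic T1-weighted MRI of the cervical spinal cord, end to end: contrast
synthesis from quantitative maps, cord cross-sectional-area (CSA)
morphometry, calibration of the reconstruction parameters against a
reference contrast, and the agreement / longitudinal-atrophy / trial-design
statistics that CSA studies run on top.

## Who this is for

Quantitative multi-parameter mapping (MPM) protocols yield voxelwise maps
of proton density (PD), the longitudinal relaxation rate R1 = 1/T1 and the
effective transverse rate R2\* = 1/T2\*. From a single such acquisition a
T1-weighted (MPRAGE-like) contrast can be *reconstructed* instead of
acquired, saving scanner time — but CSA measured on synthetic contrast can
be biased relative to the acquired reference, which matters when CSA is the
outcome of a neurodegeneration study. `cordsynth` is for imaging
methodologists and trial statisticians who want to reproduce, test, and
plan around this workflow at desk scale: every input it needs can be
simulated with known ground truth.

## The models at the core

**Signal equation.** For sequence parameters (α, TI, TR, TE, ES, n) with
readout duration τ = n·ES and delay TD = TR − (TI − τ/2) − τ, the voxel
signal is

    S = PD · sin(α) · exp(−TE · R2*) · Q,

    Q = [E4·(1 − 2E1 + E1E2) + T1*R1·(1 + E1E2E3 − E1E2E4 − E4)]
        / (1 + E1E2E3),

with E1 = exp(−(TI − τ/2)·R1), E2 = exp(−TD·R1), E3 = exp(−τ/T1\*),
E4 = exp(−τ/(2T1\*)) and T1\* = (R1 − ln cos α / ES)⁻¹. An independent
pulse-by-pulse Bloch simulation (`bloch_oracle()`) verifies the steady
state; reconstruction-only settings with TD < 0 are allowed (flagged), as
the contrast need not be acquirable.

**Downstream statistics.** Bland-Altman bias and 95% limits of agreement
with a JZS (default-prior Cauchy) two-sample Bayes factor for group-bias
equivalence; per-subject repeatability SDs; a linear mixed-effects
trajectory model `csa ~ level + (time + time²)×group + age·time + scanner`
with per-subject random effects and marginal group contrasts; and
baseline-adjusted (ANCOVA) sample sizes
n = ⌈2(z₁₋α/₂+z₁₋β)²σ²(1−ρ²)/Δ²⌉ per arm.

## Worked example

```r
library(cordsynth)

# 1. a cord phantom with known ground truth (r = 4 mm -> CSA = 50.27 mm^2)
ph <- make_cord_phantom(phantom_spec(grid_shape = c(20, 20, 9),
                                     cord_radius = 4, seed = 1))

# 2. synthesize the T1-weighted contrast at the optimized settings
p <- seq_params_ms(flip_angle_deg = 14, TI = 900, TR = 1400, TE = 0,
                   ES = 14, n_partitions = 176)
derive_timing(p)
#> # A tibble: 1 × 4
#>     tau     TD     TA feasible
#>   <dbl>  <dbl>  <dbl> <lgl>
#> 1  2.46 -0.732 -0.332 FALSE
vol <- synthesize_volume(ph$maps, p)   # warns: reconstruction-only timing

# 3. segment and measure CSA with centerline angle correction
meas <- measure_csa(segment_cord(vol))
meas$overall_mm2
#> [1] 52

# 4. simulate a two-group longitudinal cohort and quantify agreement
rec <- simulate_cohort(cohort_spec(seed = 1))   # 21 controls + 23 patients
ba  <- bland_altman(csa_pairs(rec), reference, synthetic, group = group)
ba
#> <bland_altman> n=220  bias -0.261 mm^2 (-0.4%)  LoA [-1.37, 0.85] mm^2
#>   group-bias comparison: BF10 = 0.429 (inconclusive)

# 5. fit the atrophy trajectory and contrast the groups
fit <- fit_trajectory_model(rec, trajectory_spec("intercept_slope"),
                            modality = "reference")
group_contrast(fit, "linear_rate")
#> # A tibble: 3 × 7
#>   quantity    term              estimate     se conf.low conf.high  p.value
#> 1 linear_rate control             0.0862 0.0518  -0.0153    0.188  NA
#> 2 linear_rate patient            -0.483  0.0488  -0.579    -0.388  NA
#> 3 linear_rate patient - control  -0.570  0.0701  -0.707    -0.432  4.37e-16

# 6. plan a treatment trial on the 2-year CSA difference
design <- trial_design(sigma = 10, rho = 0.94, reference_difference = -11.89)
treatment_effect_table(design)[1:3, ]
#> # A tibble: 3 × 5
#>   effect_fraction   rho delta_mm2 n_per_group n_total
#> 1             0.2  0.94      2.38          33      66
#> 2             0.3  0.94      3.57          15      30
#> 3             0.4  0.94      4.76           9      18
```

Reading the numbers: the phantom's measured 52 mm² vs true 50.27 mm² is
voxel-count digitization plus a documented partial-volume bias of threshold
segmentation on synthesized contrast; the simulated cohort injects a
−0.31 mm² synthetic-modality bias, which the Bland-Altman bias estimate
recovers within its standard error (a single 44-subject cohort leaves the
group-equivalence Bayes factor inconclusive; at the acceptance script's
200-subject cohort it drops to ≈ 0.11, substantial evidence for equal
bias); the recovered linear-rate difference matches the generative
−0.53 mm²/month within sampling error; and the sample-size table shows how
the required trial size falls with the treatment-effect fraction and the
baseline–follow-up correlation ρ.

Plot methods exist for the main results: `autoplot(ba)`,
`autoplot(meas)`, `autoplot(fit)`, `autoplot(treatment_effect_table(...))`.

A thin command-line wrapper over the same functions ships at
`inst/cli/cordsynth-cli.R` with subcommands `phantom`, `synthesize`,
`csa`, `agree`, `power` and `demo`; `run_pipeline(demo_config())` runs the
whole chain and writes a provenance manifest.

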