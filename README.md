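# tspoquant

Absolute quantification of dynamic TSPO PET with an arterial input function,
implemented as a tested, fully synthetic-data-capable R package.

TSPO (the 18-kDa translocator protein) is upregulated in activated microglia
and is imaged with second-generation radioligands such as [¹⁸F]-FEPPA. These
tracers have no reference region, so quantification runs through the full
arterial chain: the continuously sampled blood curve is corrected for line
dispersion (monoexponential kernel, τ = 16 s, iterative deconvolution),
merged with timed manual samples, converted to plasma by a bi-exponential
blood-to-plasma ratio model and to *parent* plasma by a Hill model of the
unmetabolised fraction. Tissue curves are then fitted with the reversible
two-tissue compartment model (2-TCM) with a 5% vascular contribution,

  dC₁/dt = K₁·c_p − (k₂+k₃)·C₁ + k₄·C₂,  dC₂/dt = k₃·C₁ − k₄·C₂,
  C_model = (1−v_b)(C₁+C₂) + v_b·C_blood,

whose primary outcome is the total distribution volume

  V_T = K₁/k₂ · (1 + k₃/k₄)  [mL/cm³],

with a standard error from the fit covariance (delta method) and the quality
filter %COV = 100·SE/V_T ≤ 20. Logan graphical analysis provides ROI and
voxel-wise parametric V_T; Müller-Gärtner partial-volume correction uses
tissue-probability maps and the scanner PSF (FWHM 4.4/4.4/4.5 mm). The
cohort layer reproduces a genotype-stratified group analysis: factorial
Type III ANCOVA of V_T by disease (HC/PD) × TSPO genotype (HAB/MAB) with
injected amount as nuisance covariate, Levene variance checks (with a
stricter α = 0.01 where violated), stratified pooled t tests, Pearson
clinical correlations and genotype percentage differences.

Because raw scanner data cannot ship with code, a first-class synthetic-data
module generates ground-truth input functions, TACs, two-tissue digital
phantoms and calibrated 52-subject cohorts (HAB regional V_T ≈ 30–45% above
MAB, null disease effect), so every stage is testable end to end against
known truth.

## Worked example

```r
library(tspoquant)

# 1. ground-truth input function + blood observations for one subject
sim <- simulate_input_function(seed = 42, auto_noise = 0, manual_noise = 0)
input_fn <- estimate_input_function(sim$observations$auto, sim$observations$manual)

# 2. simulate a frontal-cortex TAC with known kinetics (true VT = 13.9) and fit it
pars <- params_for_target_vt(13.9, seed = 42)
tc <- simulate_2tcm(pars, sim$truth, feppa_frame_schedule(), label = "frontal")
fit <- fit_2tcm(tc, input_fn, vb = 0.05)
print(fit)
#> <kinetic_fit> VT=14.026 (SE 0.00647, %COV 0.05) RSS=0.101 converged

# 3. Logan graphical estimate of the same curve
print(logan_vt(tc, input_fn, t_star = 30))
#> <logan_fit> VT=13.100 intercept=-47.8 t*=30.0 min (19 points, max rel dev 0.0496)

# 4. a calibrated 52-subject cohort, %COV QC filter and the group statistics
cohort <- simulate_cohort(cohort_design(seed = 42))
summ <- region_summary(cohort$table)
summ[summ$roi == "frontal", c("roi", "mean_hc_mab", "mean_hc_hab",
                              "pct_diff_hc", "genotype_F", "genotype_p", "disease_p")]
#>       roi mean_hc_mab mean_hc_hab pct_diff_hc genotype_F genotype_p disease_p
#> 1 frontal        12.7        19.7        43.1       86.9    1.4e-11     0.228
attr(summ, "overall_pct_diff")
#>       HC       PD
#> 37.84897 41.47455
```

The fitted V_T of 14.03 sits 0.9% from the generating truth (the residual
error comes from re-estimating the input function from the sampled blood
data, not from the fit); Logan at t* = 30 min lands a few percent lower, its
expected direction for kinetics this slow. In the simulated cohort the
genotype effect is overwhelming (F ≈ 87) while the disease effect is null
(p = 0.23), matching the design.

A one-command demonstration, `run_demo(seed = 1)`, chains input-function
estimation, a kinetic fit, cohort simulation, QC filtering and the regional
summary, and writes `cohort.csv`, `summary.csv` and `report.json` (with the
full resolved configuration) to a directory. The same pipeline is scriptable
from a shell via `inst/cli/tspoquant` (subcommands: simulate, input-fn,
fit-tac, logan-image, pvc, cohort-stats, demo).

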