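---
title: "Methods: TSPO PET quantification with an arterial input function"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TSPO PET quantification with an arterial input function}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tspoquant)
```

This vignette is the package's account of its science: the models it
implements, the numerical choices behind them, what the synthetic-data
generator does and does not emulate, and the limitations that follow.

## The quantification problem

TSPO radioligands such as [¹⁸F]-FEPPA have no brain region devoid of
specific binding, so reference-tissue shortcuts are unavailable and the
outcome measure is the total distribution volume
\(V_T = K_1/k_2\,(1 + k_3/k_4)\), the equilibrium ratio of tissue to parent
plasma concentration under the reversible two-tissue compartment model. That
requires an arterial input function — the parent radioligand concentration in
plasma — assembled from continuous sampler data and timed manual samples.
Everything downstream (Logan analysis, partial-volume correction, the
genotype-stratified cohort statistics) hangs off these two objects.

All activities are assumed decay-corrected (standard for reconstructed PET);
time is minutes internally, and file headers declaring seconds are converted
on read. The packaged acquisition schedule is 34 frames over 125 min: an
initial variable-length frame (default 30 s; the true length depends on when
activity reaches the field of view and is configurable), then
5×30 s, 45 s, 2×60 s, 90 s, 120 s, 210 s and 22×300 s — the fixed portion
sums to 7335 s.

## Input function construction

**Dispersion.** The sampling line smears the blood curve by convolution with
\((1/\tau)e^{-t/\tau}\), \(\tau = 16\) s by default. Deconvolution is
iterative: projected Van Cittert updates
\(g \leftarrow \max(g + (m - K g), 0)\), default 200 iterations. For this
kernel the iteration contracts at every frequency (worst-case factor
\(2\alpha/(1+\alpha) < 1\) at Nyquist, \(\alpha = e^{-\Delta t/\tau}\)), so
200 iterations reach numerical convergence on a 1-s grid; we chose it over
multiplicative (Richardson–Lucy-type) updates, whose edge convergence is too
slow to meet the package's own step-recovery contract. The analytic inverse
\(g = m + \tau\,m'\) is kept as an independent cross-check (`method =
"direct"`); the two agree to a fraction of a percent away from slope
discontinuities. Deconvolution amplifies high-frequency noise by up to
\(2\tau/\Delta t\), so `estimate_input_function()` applies a 5-s-FWHM
Gaussian to the deconvolved curve by default; `dispersion_model()` itself
defaults to no smoothing so that the exact numerical contracts hold for
noise-free data. One caveat is intrinsic: the continuous convolution of a
discontinuity is zero *at* the jump time, so no discrete deconvolution can
recover the jump sample itself — accuracy statements for steps exclude that
single sample.

**Blood-to-plasma ratio and parent fraction.** Ratios are fitted with
\(r(t) = A_1 e^{-\lambda_1 t} + A_2 e^{-\lambda_2 t}\) (bounded
least squares; constant data land in the \(\lambda \to 0\) degenerate
direction, where the *predicted curve*, not the parameter vector, is the
contract). The unmetabolised parent fraction uses the standard Hill form
\(f_p(t) = 1 - a\,t^b/(c + t^b)\) with \(a \in [0,1]\), \(b, c > 0\), which
satisfies \(f_p(0) = 1\) and is monotone non-increasing by construction.
Plasma parent concentration is then
\(c_p(t) = [\text{blood}(t)/r(t)]\cdot f_p(t)\), clipped at zero; the
convention that \(r\) is *blood over plasma* is a configuration-level choice.

**Merging.** The dispersion-corrected sampler curve covers the first
22.5 min; manual samples (2.5, 7, 12, 15, 30, 45, 60, 90, 120 min) carry the
curve beyond. When a manual sample falls inside the sampler window, the auto
curve is rescaled to pass through the first such sample — a pragmatic
cross-calibration of sampler versus well counter, since the true calibration
procedure is site-specific. Between late manual samples the curve is
interpolated log-linearly (exponential bridges); past the last sample a
single exponential fitted to the last three manual samples extrapolates the
tail. The dense evaluation grid is 1 s over 0–125 min, fine enough to
resolve the bolus peak.

## Compartment modelling

`simulate_2tcm()` solves the two-state linear system in closed form: the
rate matrix is eigen-decomposed analytically and each mode is an exponential
convolution computed as a recursive trapezoidal recurrence
(`stats::filter`), exact to \(O(\Delta t^2)\) on the 1-s grid; tests verify
agreement with an adaptive ODE integrator to a few parts in \(10^4\).
Coincident eigenvalues (possible only on a measure-zero parameter set) are
perturbed by \(10^{-8}\). Frame values are duration averages of the
continuous solution via a cumulative trapezoid — mid-frame evaluation would
be visibly biased in the early 30-s frames. The vascular term multiplies
whole blood (not plasma) and tissue is scaled by \(1 - v_b\), the standard
convention; \(v_b = 0.05\) by default.

`fit_2tcm()` is bounded Levenberg–Marquardt over \((K_1, k_2, k_3, k_4)\)
with \(K_1 \in (0, 2]\), \(k_{2,3,4} \in (0, 1]\) (per-minute units),
\(v_b\) fixed at 0.05 unless `fit_vb = TRUE`. Because 2-TCM objectives are
multimodal, three deterministic starts are tried and the lowest residual sum
of squares wins, ties broken by the smaller \(K_1\). Weights are uniform by
default (frame-duration weights optional). The covariance comes from a
numeric Jacobian at the solution; \(V_T\)'s standard error follows by the
delta method with gradient
\([\,(1+k_3/k_4)/k_2,\; -V_T/k_2,\; K_1/(k_2 k_4),\; -K_1 k_3/(k_2 k_4^2)\,]\),
and %COV \(= 100\,\mathrm{SE}/V_T\). The QC rule retains fits with
%COV ≤ 20 (boundary inclusive), applied to \(V_T\) only — whether the filter
should also gate the micro-parameters is genuinely open, so a configuration
switch exists but the default follows the \(V_T\)-only reading. A singular
covariance yields %COV = ∞ with a warning rather than an error, so cohort
runs degrade gracefully.

## Logan analysis

The Logan plot regresses \(\int_0^t C/C\) on \(\int_0^t c_p/C\) over frames
with mid-time ≥ t\*; its slope estimates \(V_T\) for reversible tracers. The
plasma integral is accumulated on the dense input grid (a mid-time trapezoid
across the bolus peak would bias the abscissa by several percent), while the
tissue integral uses trapezoids on frame mid-times anchored at (0, 0), since
tissue data exist only as frame averages. Default t\* = 30 min;
`choose_t_star()` picks the earliest mid-time from which all later points
stay within a relative deviation (default 10%) of the terminal-segment
line. Logan is asymptotically unbiased but approaches \(V_T\) from below
when equilibration is incomplete: with \(k_4\) around 0.01/min the 125-min
scan is simply too short for a 30-min t\*, and the cross-validation suite
therefore uses equilibrating kinetics (\(k_4 \ge 0.03\)/min) and \(v_b = 0\)
(the Logan formulation here does not model a vascular term; with
\(v_b = 0.05\) in the data its slope absorbs the blood compartment, a ~2–4%
effect). Voxel-wise `parametric_logan()` is exactly the ROI computation per
voxel — no cross-voxel coupling — with optional Gaussian spatial
pre-smoothing standing in for more elaborate noise-management schemes, and
is off by default so the voxel/ROI equivalence is exact.

## Partial-volume correction

Müller-Gärtner with CSF activity fixed at zero:
\[\hat C_{GM} = \frac{C_{obs} - C_{WM}\,G(p_{WM}) - 0\cdot G(p_{CSF})}{G(p_{GM})},\]
valid where the PSF-smoothed GM probability exceeds 0.3 (conventional range
0.25–0.5, configurable), NaN elsewhere. \(G\) is separable Gaussian
convolution with the scanner PSF — zero boundary, i.e. genuine spill-out,
not renormalised edges — at the reconstructed resolution FWHM
(4.4, 4.4, 4.5) mm. The white-matter estimate is the frame mean over deep
white matter (probability > 0.95, eroded by one voxel to limit GM spill-in),
re-estimated per frame in dynamic use because white matter has its own
kinetics. The correction is homogeneous of degree one in the frame by
construction. Whether PVC should act on voxel images before ROI extraction
or on ROI values directly is ambiguous in routine practice; both paths exist
(`pvc_dynamic()` then `roi_tac()`, or `mueller_gartner()` per frame).

## Cohort statistics

The group layer mirrors an SPSS-style analysis: per ROI a factorial ANCOVA
of \(V_T\) by disease (HC/PD) and genotype (HAB/MAB) with injected amount as
nuisance covariate, Type III sums of squares under effects (sum-to-zero)
coding — the combination that reproduces SPSS output — computed via
`car::Anova` on a `stats::lm` fit and verified in the tests against a
hand-coded model-comparison regression oracle to 10⁻⁸. Levene's test
(centre = mean, the classic W) flags heteroscedastic ROIs, whose
significance threshold then tightens from 0.05 to 0.01; pooled-variance
(Student) t tests compare genotypes within each disease stratum (Welch by
flag); Pearson correlations probe clinical measures within genotype strata
of the patient group. Genotype contrast sizes are reported as
\(100\,(\bar V_{HAB} - \bar V_{MAB}) / \frac{1}{2}(\bar V_{HAB} + \bar V_{MAB})\)
— the difference as a percentage of the mean of the two group means, the
unique simple form consistent with the reference values the generator is
calibrated to. Nonparametric demographic screens (Kolmogorov–Smirnov,
Mann–Whitney, Kruskal–Wallis, chi-square) are deliberately thin wrappers
over the standard `stats` routines. LAB (low-affinity binder) genotypes are
rejected at validation: FEPPA-class tracers are not quantifiable in LABs and
such subjects are excluded from these designs.

## What the synthetic-data generator emulates

`simulate_input_function()` builds a FEPPA-like parent plasma curve (linear
rise to a bolus peak at 0.75 min, tri-exponential washout with fractions
0.55/0.35/0.10 and rates 4/0.5/0.02 per min), derives total plasma through
the Hill parent-fraction model (a = 0.9, b = 2, c = 400 minᵇ: parent
fraction ≈ 12% by 120 min) and whole blood through the bi-exponential ratio
model (≈1.1 falling towards 0.8), then emulates measurement: the sampler
sees the dispersion-convolved blood at 1 Hz for 22.5 min, manual samples
follow the 9-point schedule, both with seeded multiplicative noise (defaults
1% auto, 2% manual — plausible well-counter precision).

`params_for_target_vt()` realises any target \(V_T\) exactly by sampling
micro-parameters from plausibility priors (\(k_2 \in [0.05, 0.3]\)/min,
\(k_3/k_4 \in [0.5, 4]\), \(k_4 \in [0.01, 0.06]\)/min, rejection-sampled to
keep \(K_1 \le 2\)) and solving for \(K_1\). `simulate_phantom()` renders a
white-matter sphere inside a gray-matter shell with per-tissue kinetics,
blurs each frame with the PSF and ships exact binary probability maps, so
partial-volume recovery can be asserted against literal truth.

`simulate_cohort()` is calibrated to a published 52-subject design
(cells 11/11/14/16, ten ROIs, injected amount 4.79 ± 0.22 mCi in controls
vs 5.04 ± 0.27 in patients) via `feppa_reference_cells()`. Two deliberate
design choices matter here:

* **The disease null is imposed in distribution.** The calibration cells are
  one noisy realisation of a study whose inference was "no disease effect".
  Using those cell means verbatim as generating truth would bake in a false
  disease signal (and their very unequal cell SDs — one is printed as 0.0 —
  would miscalibrate the null rejection rate). By default the generator
  therefore pools means (sample-size-weighted) and variances (df-weighted)
  across disease within each (ROI, genotype), adds `disease_effect`
  (default 0) to the patient cells, and keeps the genotype structure intact.
  `disease_null = FALSE` restores the verbatim cells, which is what the
  calibration-convergence tests use.
* **Two modes.** `mode = "fit"` realises every subject × ROI through the full
  chain — micro-parameters, simulated TAC with proportional Gaussian noise
  (SD 5% of activity, scaled by 1/√duration, the usual count-statistics
  proxy), an actual NLS fit — and is exercised in the tests at reduced size
  (a four-subject, two-ROI cohort: ~10⁰ s per fit makes full-size replicated
  studies infeasible, ~10⁵ fits). `mode = "fast"` (default) draws fitted
  \(V_T\) from the calibrated cell distributions directly and %COV from a
  lognormal model whose median hits the targeted pass fraction (default
  0.75) with a dominant subject-level component (SDs 0.45 subject, 0.15
  residual on the log scale, plus a mild offset making low-\(V_T\) regions
  noisier) — scan quality is a property of the subject, so QC retention is
  correlated across ROIs within subject, as in real cohorts. The fast mode
  preserves exactly the statistical structure the cohort-level claims are
  about.

What the generator does **not** emulate: reconstruction artefacts and
spatially correlated HRRT noise, head motion, anatomical atlases,
scanner/well-counter cross-calibration drift, plasma free-fraction
measurement, or genotype effects on kinetics beyond \(V_T\). Passing tests
therefore demonstrate correctness of the estimation machinery under the
stated generative assumptions, not robustness to everything real data can
do.

## Numerical choices and degenerate inputs

* Optimiser tolerances: `nls.lm` with ftol = ptol = 10⁻¹², 300 iterations,
  per start; fits that exhaust iterations are flagged `converged = FALSE`
  rather than discarded.
* \(K_1 = 0\) is allowed in the forward simulator (pure vascular signal);
  the irreversible corner \(k_3 > 0, k_4 = 0\) is rejected because \(V_T\)
  is undefined there; \(k_3 = 0\) collapses to \(K_1/k_2\) regardless of
  \(k_4\).
* Logan points with non-positive tissue activity are excluded; fewer than
  three usable points is an error at the ROI level and NaN at the voxel
  level.
* Table readers auto-detect comma/tab, require strictly increasing
  non-overlapping frames, and round-trip numeric values at ≥ 6 significant
  digits (`%.10g`).
* All stochastic functions take explicit seeds; identical (design, seed)
  pairs are bit-reproducible.

## Problem sizes used in validation

The shipped checks run: 50 noise-free fit-recovery draws spanning
\(V_T \in [5, 25]\); 8 Logan cross-validation draws; a 32³-voxel phantom at
2-mm voxels for partial-volume recovery; 200 simulated cohorts for genotype
power and disease-null calibration (the per-ROI QC envelope is summarised as
the median over 5 cohorts — a single realisation has binomial spread of
±3 subjects and is the wrong object to assert a range on); and 1000-draw
identity grids for the \(V_T\) algebra. These sizes were chosen so the whole
suite completes in about a minute and a half while keeping every Monte-Carlo
margin comfortable.

## Known limitations

* The dispersion inverse assumes the nominal \(\tau\); no joint estimation
  of \(\tau\) from calibration data.
* Logan \(V_T\) carries the usual noise-dependent negative bias; no
  likelihood-based or multilinear reformulation is provided.
* The ANCOVA is the fixed-effects, homoscedastic form (as in the reference
  protocol); heteroscedasticity is only *flagged* (Levene → stricter α),
  not modelled.
* Voxel-level fitting is Logan-only; voxel-wise 2-TCM NLS is intentionally
  out of scope.
* No decay correction, dead-time, or free-fraction handling: inputs are
  assumed fully pre-corrected reconstructions.
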