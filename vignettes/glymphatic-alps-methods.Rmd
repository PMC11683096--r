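---
title: "Methods: the DTI-ALPS index, its phantom, and the cohort readout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the DTI-ALPS index, its phantom, and the cohort readout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glymphr)
```

## The model

The glymphatic system exchanges cerebrospinal and interstitial fluid
through perivascular channels. At the level of the lateral-ventricle body
the local geometry is unusually convenient: projection fibres run
superior–inferior (z), association fibres anterior–posterior (y), and the
medullary veins — and with them the perivascular spaces — run left–right
(x), perpendicular to both fibre systems. Diffusivity measured along x
inside those fibre bundles therefore cannot be attributed to axonal
structure and is read as a proxy for perivascular fluid movement.

With `D_k(ROI)` the mean of the diffusion-tensor diagonal element along
axis *k* over a small ROI,

$$\mathrm{ALPS} = \frac{\mathrm{mean}(D_{x,\mathrm{assoc}},\; D_{x,\mathrm{proj}})}
                      {\mathrm{mean}(D_{z,\mathrm{assoc}},\; D_{y,\mathrm{proj}})}.$$

The denominator is the cross-axonal diffusivity of the two fibre systems;
the ratio is dimensionless, scale-invariant (multiplying every tensor by
a constant leaves it unchanged), and equals 1 when x-diffusivity carries
no perivascular excess. "Dx/Dy/Dz" are taken as the tensor **diagonal
elements** in subject axes — the standard ALPS reading — and diffusivities
are averaged over ROI voxels *before* forming the ratio, matching the
ROI-level notation of the defining formula. The index is a single-slice,
direction-dependent measure; we implement it exactly as defined and make
no claim that it separates perivascular flow from other x-oriented
compartments.

For controls the left/right mean is reported; for patients the lesion-side
index (`lesion_side` argument of `compute_alps()`).

## The synthetic phantom

`make_phantom()` builds the geometry that the index presumes, with known
answers. On a 40×40×20 grid of 2 mm voxels (mirroring a 2 mm isotropic
clinical DTI acquisition), one mid-axial slice carries two bilateral
"projection" slabs with diagonal tensor
$(d_{pv}\,f,\; d_\perp,\; d_\parallel)$ and, lateral to them, two
"association" slabs with $(d_{pv}\,f,\; d_\parallel,\; d_\perp)$; the
background is isotropic (0.7×10⁻³ mm²/s). Defaults
$d_\parallel = 1.4\times10^{-3}$, $d_\perp = 0.5\times10^{-3}$,
$d_{pv} = 1.1\times10^{-3}$ mm²/s are typical white-matter axial/radial
values with a perivascular x-excess; all stay below the free-water bound
3.5×10⁻³ mm²/s. The glymphatic factor $f \in (0,1]$ scales only the
x-diffusivity inside the slabs, so the closed-form ground truth is

$$\mathrm{ALPS}_{\mathrm{true}} = \frac{f\, d_{pv}}{d_\perp},$$

strictly increasing in $f$ — at the defaults, 2.2 for a healthy phantom
and 1.1 at $f = 0.5$.

Signals are synthesised voxelwise as $S = S_0 e^{-b\,g^\top D g}$ over a
b = 0 volume plus one b = 1000 s/mm² shell with 32 directions (the
acquisition the method is normally run on). Directions come from a
deterministic Fibonacci-sphere scheme, which is near-uniform and
reproducible; vendor tables vary and none is canonical. Noise, when
requested, is Rician — magnitude MRI's noise floor — calibrated as
SNR = S₀/σ on the b = 0 signal. The phantom deliberately omits head
motion, eddy currents, susceptibility distortion, partial-volume mixtures
and spatially varying noise; passing tests on it validate the estimator
chain (fit → peak search → ratio), not robustness to real-world artefacts,
which the source method handles with external preprocessing.

## Tensor estimation

`fit_tensor()` solves the log-linearised model
$\ln(S/S_0) = -b\,g^\top D g$ per voxel for the six unique tensor
elements. The default is the standard two-pass weighted least squares
(weights = squared first-pass predicted signals, which undoes the
log-transform's heteroscedasticity); plain OLS is kept because it is the
cleaner oracle on noiseless data, where both are exact to machine
precision. S₀ is the mean of all b = 0 volumes. Negative eigenvalues —
possible at low SNR — are clamped to zero with a warning and a count,
rather than refitted, for determinism. FA uses the usual
$\sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert/\lVert\lambda\rVert$ form,
defined as 0 for an all-zero tensor. Colour-FA channels are
FA·|v₁| componentwise (red = x, green = y, blue = z), so the squared
channels sum to FA² identically.

## ROI placement

The source method seeds ROIs from an MNI-space FA template and refines
them on the colour-FA map. Template registration is out of scope here;
seeds are explicit voxel coordinates (the phantom's ground-truth slab
centres, or user-supplied coordinates for real data). The refinement is
reconstructed as: projection centres move to the blue-channel maximum,
association centres to the green-channel maximum, within an in-plane disc
of radius 10 mm around the seed; ties break to the nearest candidate,
then lexicographic voxel order, so placement is deterministic. An empty
or all-zero search disc falls back to the seed with a warning. ROI
membership is every voxel on the slice whose centre lies within 3 mm of
the adjusted centre (with 2 mm voxels this is the 3×3 in-plane
neighbourhood, as the diagonal-neighbour distance 2.83 mm is inside the
radius). The exact peak-adjustment neighbourhood of the original in-house
algorithm is unpublished; both radii are arguments, so the reconstruction
is isolated behind configuration.

## The synthetic cohort

`make_cohort()` draws a two-arm cohort in which the ALPS index is the
exogenous driver: per subject, ALPS ~ N(group mean, sd); grey-matter
proportion GM% = intercept + a·ALPS + ε; MoCA = intercept + b·GM% +
c′·ALPS + ε, clipped to [0, 30] and rounded (clipping after noise, so the
generator emits realistic integer scores; the clipping makes large-n path
recovery conservative rather than exact); poor 90-day outcome
(mRS 3–6) ~ Bernoulli(expit(γ₀ + γ₁·ALPS)); and haematoma volume,
generated for acute-subacute patients only, = intercept + β·ALPS + ε
floored at 0. Age, sex, TIV, hypertension, diabetes and GCS are drawn
independently of ALPS, so they are genuine null covariates.

Defaults are chosen once to sit on the scale of a mild-to-moderate sICH
cohort: ALPS means 1.5 (controls) vs 1.25 (patients) with sd 0.2; GM%
centred at 44, MoCA at 26, haematoma at 13 mL; γ = (9, −8) gives roughly
a quarter poor outcomes; 40% of patients acute-subacute; lesion side
uniform. No study deposits the generating effect sizes of its clinical
data, so these defaults reproduce the *sign pattern* of the clinical
findings (lower ALPS in patients, ALPS–haematoma negative, ALPS–MoCA
positive with GM% mediation, ALPS protective for outcome), not any
particular magnitudes. Intercepts are derived from the target means
rather than exposed directly, which keeps every column clinically
plausible under arbitrary path settings. MoCA (and GCS, haematoma, mRS)
are generated only for patients, as controls receive no such assessments.

## Statistical readout

* **Group contrast** — OLS of ALPS on group plus age, sex, hypertension,
  diabetes and TIV, with listwise deletion and an explicit rank check.
  With no informative covariates it reduces exactly to the pooled
  two-sample t-test. A greedy 1:1 propensity match (caliper 0.2 SD of the
  logit) is provided as a sensitivity utility, since matching and
  covariate adjustment are sometimes combined in this literature.
* **Partial correlation** — residualise-then-correlate, with t-based
  p-values on n − k − 2 degrees of freedom. "Partial Spearman" is
  rank-transform x and y first, covariates untransformed — the common
  convention when only the method family is named. Families of tests
  reported together are corrected by Benjamini–Hochberg FDR
  (`fdr_adjust()`, delegating to `p.adjust`).
* **Mediation** — product of coefficients from three least-squares fits,
  covariates {age, sex, TIV} by default for consistency with the
  correlation analyses. The percentile bootstrap (5,000 replicates in
  conventional reporting) is the default interval, matching the usual
  PROCESS output; BCa is behind a flag. In the linear system
  total = direct + indirect holds at machine precision on every fitted
  sample — an identity the tests assert. Resampling is simple,
  subject-level, seed-deterministic; degenerate resamples are redrawn and
  counted.
* **Prognosis** — `glm` (IRLS) logistic fit with backward elimination on
  the Wald p at p_out = 0.10, the SPSS-style convention when a paper
  names only "backwards elimination"; a likelihood-ratio criterion is a
  flag away. Both the full and reduced coefficient tables are kept, since
  reports rarely say which one a quoted coefficient comes from.
  Divergence (‖β‖ > 50) is reported as probable complete separation.
* **ROC** — the empirical curve over midpoint thresholds; AUC via
  midranks (identical to the tie-corrected Mann–Whitney probability and
  to the trapezoidal area); DeLong placement-value CI; Youden cutoff with
  ties broken toward higher sensitivity. Because the ALPS index is lower
  in poor-outcome patients, its natural orientation is `"<"`: the
  reported cutoff flags scores *below* it as high risk, and AUC stays
  above 0.5 by construction.

## Numerical and design choices

* Voxel coordinates are 1-based array indices in R (the documentation of
  any exchange format states this); world coordinates follow the NIfTI
  affine.
* b-values ≤ 50 s/mm² are treated as b = 0; b-vectors must be unit to
  1e-3 (scanner rounding) and are renormalised exactly.
* Gradient identifiability requires ≥ 6 directions unique up to sign and
  a full-rank design; both are checked before fitting.
* The bootstrap CI uses quantile type 6, whose percentiles of a
  point-mass replicate distribution collapse to that point.
* Seeds: every stochastic function takes an explicit seed; the pipeline
  derives per-phantom seeds from the master seed, and the JSON report
  embeds a config hash so resumed runs cannot silently mix
  configurations.

## Problem sizes in the test-suite and acceptance runs

Phantom checks run on the default 40×40×20 grid (32,000 voxels, 33
volumes) or a 24×24×10 variant for unit tests. Cohort recovery uses
n = 200/arm for the readout, n = 5,000/arm for large-sample recovery of
the indirect effect, 500 null cohorts at n = 200 patients for bootstrap
coverage, and 1,000 (tests) / 500 (acceptance script) null cohorts for
type-I error calibration. These sizes give Monte-Carlo error comfortably
inside the asserted tolerances (e.g. a ±10% band on the indirect effect,
a [0.03, 0.07] band on a 5% error rate).

## Known limitations

* The phantom's fibre slabs are axis-aligned and piecewise constant;
  oblique fibres, crossing fibres and partial-volume gradients are not
  simulated, so ROI peak search is easier here than on real colour-FA.
* GM% is consumed as a column, not computed: segmentation is outside the
  package's scope.
* The cohort generator's linear-Gaussian structure makes least-squares
  mediation correctly specified by construction; it cannot reveal
  misspecification biases that real cohorts may carry.
* No DICOM ingestion, no template registration, no denoising or eddy
  correction — inputs are assumed preprocessed NIfTI + bvals/bvecs.
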