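---
title: "Tracking maximum-point motion during AAA growth: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tracking maximum-point motion during AAA growth: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaamotion)
```

## The problem

Abdominal aortic aneurysms (AAA) under surveillance are imaged
repeatedly with CT angiography. Two scans of the same patient, months
apart, live in different scanner coordinate frames, and the aneurysm
itself has grown between them. Three clinically interesting points —
where the intraluminal thrombus (ILT) is thickest, where the wall
stress peaks (PWS), and where the wall-stress-to-strength ratio peaks
(peak wall rupture index, PWRI) — may migrate over the wall as the sac
remodels. Measuring that migration requires mapping the earlier scan's
points into the later scan's frame, which `aaamotion` does with a
landmark-based least-squares linear transformation.

## The registration model

Per patient, up to nine paired anatomical fit landmarks (renal
arteries, superior mesenteric artery, aortic bifurcation, common iliac
origins, up to three lumbar arteries) define correspondences
$x_i \mapsto y_i$ between the two frames. The transform $y = A x + t$
is fitted by minimising $\sum_i \lVert A x_i + t - y_i \rVert^2$ in
one of three nested families:

* **rigid** — $A$ a proper rotation (orthogonal Procrustes via SVD
  with a reflection guard);
* **similarity** — $A = sR$ with $s > 0$ (scaled Procrustes);
* **affine** — unconstrained $A$ (normal equations on centered
  coordinates), the default, because aneurysm growth implies genuinely
  non-rigid landmark motion.

The nesting guarantees `fit_rms(affine) <= fit_rms(similarity) <=
fit_rms(rigid)` on the same correspondences, which the test suite
verifies as an invariant. An additional validation landmark (for
example the inferior mesenteric artery origin or a calcified plaque) is
held out of the fit *structurally* — the correspondence container
refuses a validation label that also appears among the fit labels. The
transform is accepted only when the predicted-to-actual distance of the
validation point is **strictly below 15 mm** (configurable); exactly
15.0 mm is a rejection. Accepted transforms project each maximum point
into the later frame, and its spatial motion is the Euclidean distance
to where that maximum actually appeared, measured in the later
(prediction) frame.

Numerical safeguards: the condition number of the centered source
design matrix must stay below 1e6 — coplanar fit points (for affine)
or collinear ones (for rigid/similarity) raise an explicit error
naming the landmarks rather than silently corrupting motion distances.
Landmarks are never weighted; coordinates are world millimetres, and
any fixed axis convention works as long as both timepoints share it.

## Morphometry

Geometry is computed from a parametric vessel model: a centerline
polyline with anatomical stations plus per-station lumen and outer
radii.

* **Tortuosity** is arclength over straight-line ("raceline") distance
  between stations — lowest renal artery to aortic bifurcation
  (aortic), bifurcation to inguinal ligament (iliac). The model keeps
  one continuous polyline running through the left common iliac, so
  both indices are station pairs on the same centerline; a separate
  iliac branch object is unnecessary, and when stations are missing
  the index is reported `NA`, never imputed.
* **Neck angulation** ($\alpha$: suprarenal vs infrarenal neck;
  $\beta$: neck vs proximal aneurysm) uses mean unit tangents averaged
  over fixed 15 mm arclength windows rather than two-point chords. The
  window is a declared parameter: clinical software does not document
  its own convention, so this is a design choice, robust to sampling
  density, not a reproduction of any vendor's definition.
* **Volumes** integrate conical frusta of the radius profiles along
  the centerline. "Vessel volume" is everything inside the outer
  contour; the wall is not modelled separately, so ILT volume is
  defined as vessel minus lumen and additivity is exact by
  construction. ILT *thickness* is radial (outer minus lumen radius
  per station) — a simplification of 3-D normal-distance thickness
  that is adequate here because the synthetic generator uses the same
  definition.
* Ties in any maximum (diameter, ILT thickness, stress) break toward
  the proximal station, with a message.

## The biomechanical surrogate

Patient-specific finite-element wall-stress analysis is commercial,
closed, and out of scope. In its place sits a deliberately simple
analytic surrogate whose role is to produce plausible, controllable
stress and rupture-index maxima for the motion pipeline:

$$\sigma(s) = \frac{P\, r_\text{outer}(s)}{2\,t_\text{wall}}
  \, e^{-\kappa\, d_\text{ILT}(s)},
\qquad
S(s) = \max\left(S_\text{floor},\; S_0 - \lambda\, d_\text{ILT}(s)\right)$$

a thin-wall Laplace estimate with exponential ILT stress buffering and
a linear ILT-dependent strength loss. PWRI is the per-station ratio
$\sigma/S$ maximised over stations. Defaults: wall thickness 2 mm,
$\kappa$ = 0.03/mm, $S_0$ = 800 kPa, $\lambda$ = 15 kPa/mm, floor
300 kPa — all configurable. The spherical factor $P r/2t$ (not the
cylindrical $P r/t$) was chosen because a fusiform sac is closer to a
spherical cap at the bulge; it affects only the overall scale. The
analysis pressure defaults to the mean arterial pressure of the
standardized 140/80 mm Hg cuff pressure (100 mm Hg = 13.33 kPa),
switchable to systolic. Stress is linear in pressure, so PWS scales
with pressure while the PWS and PWRI *locations* are
pressure-invariant — a property the acceptance suite checks on random
models. The surrogate's absolute kPa values are not comparable to
nonlinear FEM output and are never presented as such; "mean ILT
stress" is exported as a clearly-labelled proxy (mean stress over
stations with positive ILT).

## The synthetic cohort generator

No imaging data accompany this method, so every downstream stage is
exercised on synthetic paired-timepoint patients. The generator's
defaults are the study conditions, chosen once:

* **Cohort**: 32 patients, surveillance interval uniform 6–24 months.
* **Growth**: annual diameter growth is log-normal with median
  3.7 mm/year and IQR 2.25–5.44 (positive and right-skewed; the
  log-normal is parameterised exactly from the median and quartile
  ratio). CT2 diameter = CT1 + rate x elapsed years.
* **Baselines and changes**: CT1 values and multiplicative changes of
  volumes, ILT measures, PWS and PWRI are log-normal with medians and
  IQRs matching a surveillance cohort at open-repair workup (median
  first-scan diameter about 50 mm); angles and neck measures change
  additively.
* **Correlation structure**: the absolute vessel-volume change is
  correlated with the PWS change (target Pearson r = 0.68) and the
  PWRI change (0.60) through a Gaussian copula on log-changes. Because
  log-normal baselines and the exponential map attenuate Pearson
  correlations of the *absolute* deltas, the constructor calibrates
  the latent copula correlation once by a deterministic internal
  Monte-Carlo root-solve so that the induced delta correlation meets
  the requested target (for the defaults the latent value is about
  0.86 for a realised 0.68). With the calibration, the induced
  population correlation measured on 100,000 generated patients is
  0.682.
* **Maximum-point motion**: true motions are log-normal (median 10 mm)
  and drawn *independently* of every geometric and biomechanical
  change — mirroring the null structure the cohort analysis is meant
  to detect. Each CT2 maximum point is the planted transform applied
  to the CT1 point plus a vector of exactly the drawn magnitude,
  tangent to the local surface (spanned by the centerline tangent and
  the circumferential direction), so motion never aliases into radial
  growth.
* **Landmark noise**: isotropic Gaussian, sd 1.5 mm — the scale of
  digitisation error on sub-2.5 mm slice spacing.
* **Transforms**: planted per patient (default affine: a rotation up
  to 10 degrees composed with shear/scale perturbations up to +/-3%,
  translation up to +/-30 mm per axis).
* **Reproducibility**: one global seed; per-patient seeds are derived
  splitmix-style, so any patient can be regenerated alone and
  record-only draws are bit-identical to full materialisations
  (records are drawn before geometry in a fixed RNG order).

The generated vessel is a fusiform bulge (Gaussian radius profile,
ILT peak offset 8 mm from the diameter peak so the three maxima do not
coincide) on a centerline with planted neck angulation and sinusoidal
tangent tilt producing aortic tortuosity near 1.05–1.1 and iliac near
1.13.

**What the generator does not emulate**: real CT intensities and
segmentation error, bifurcated 3-D iliac anatomy, saccular or
thrombus-free morphologies, inter-observer landmark placement bias
(noise is isotropic and independent), and any coupling between motion
and growth. Passing tests therefore demonstrate the *pipeline's*
correctness and calibration under these conditions — not clinical
accuracy on patient imaging.

## Statistical analysis

`build_cohort_tables()` reproduces the cohort analysis surface:

* per-variable change table: median [IQR] per timepoint, per-patient
  absolute and percent change (CT1 denominator; CT1 = 0 excluded with
  a count), paired Wilcoxon signed-rank p, and the per-12-months
  normalised change. Normalisation and percent change are computed
  **per patient before** any cohort summary; a fixture in the test
  suite guards against the median-of-ratios vs ratio-of-medians error.
* Pearson r/p of every change against the PWS and PWRI changes, and of
  the three motion distances against every change.
* median-split comparison of high- versus low-motion patients by
  rank-sum test; ties at the median go to the low group (logged
  convention — the split rule is otherwise arbitrary).

Conventions, fixed and documented in the emitted `conventions.json`:
type-7 (linear interpolation) quantiles; zero differences dropped from
the signed-rank test; exact signed-rank p-values when the non-zero
absolute differences are untied, exact by direct sign-pattern
enumeration when tied with n <= 15 (this keeps the
all-differences-equal case at its exact 2/2^n), normal approximation
with continuity and tie correction otherwise; Mann-Whitney exact for
small untied groups. No multiple-testing correction is applied in the
primary columns — matching how such exploratory cohort tables are
conventionally reported — with optional, clearly-labelled
Benjamini-Hochberg columns as an extension. The paired signed-rank
test is used for CT1-vs-CT2 comparisons and the two-sample rank-sum
test only for group splits.

## Pipeline and gating policy

`run_pipeline()` chains simulate/load -> geometry -> surrogate
biomechanics -> transform + gate -> motion -> cohort tables. Patients
failing the 15 mm gate are excluded **from the motion analyses only**:
the gate validates the transformation, not the per-timepoint
measurements, so their geometric and biomechanical changes stay in the
change tables and the exclusion is listed in the manifest. Per-patient
stage errors are logged and the pipeline continues. Outputs carry a
manifest with the config hash (MD5 of the serialised configuration)
and tool version; tables contain no timestamps, so a fixed seed and
config give byte-identical tables across runs.

## Problem sizes and calibration results

The test suite runs entirely on generated data at these sizes, chosen
to keep each property statistically sharp at interactive runtimes:
200 planted-transform recoveries (all three families, error below
1e-8); 100 instances each against the independent Procrustes
(`vegan`) and normal-equations (`lm`) oracles; 500 simulated patients
for the gate calibration (pass rate 96–97% at 2 mm noise, strictly
decreasing with noise) and for motion recovery (median absolute
recovery error about 1.5 mm at the default 1.5 mm landmark noise,
monotone in noise); 2000 record-only cohorts of n = 32 for the
correlation calibration (mean sample r within 0.02 of the 0.68
target) and 1000 for the type-I calibration of motion-change
correlations (5.0% significant at alpha = 0.05); exhaustive
enumeration cross-checks of both rank tests for all n <= 10.

## Known limitations

* The linear transform family cannot represent local, non-linear sac
  deformation; motion estimates inherit whatever residual the affine
  fit leaves (reported per patient as `fit_rms_mm`).
* The stress surrogate is a scale model, not FEM; only properties that
  are invariant to its scale (locations, linearity, orderings) carry
  meaning.
* Radial ILT thickness underestimates true normal-distance thickness
  on strongly curved or eccentric sacs.
* The motion measurement is directional (earlier scan projected into
  the later frame); reversing the roles reproduces distances exactly
  only for noise-free affine correspondences.
* Single-centerline iliac representation; no bifurcated 3-D iliac
  geometry.
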