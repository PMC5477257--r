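---
title: "CT texture features and survival: methods and design notes"
author: "GLCMSurv"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT texture features and survival: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GLCMSurv)
```

## The measurement model

GLCMSurv quantifies the spatial texture of a radiologist-drawn region of
interest (ROI) on a contrast-enhanced CT volume and asks whether that
texture carries prognostic information about overall survival. The
measurement chain for one ROI is:

1. **HU admissibility filtering.** In-mask voxels with Hounsfield values
   below −10 or above 500 are removed (bounds inclusive: −10 and 500
   themselves survive). The lower bound excludes fat, which surrounds and
   interdigitates pancreatic tissue and would otherwise create texture
   driven by fatty infiltration rather than tumor biology; the upper bound
   excludes stents and other metal-dense artefacts.
2. **Largest cross-section.** Features are measured on the single axial
   slice with the most in-mask pixels after filtering (ties go to the
   lowest slice index). Cross-sectional size is that pixel count times the
   in-plane pixel area, reported in mm².
3. **Grey-level quantization.** HU values on the slice are binned into
   `G` equal-width levels over the filter range `[-10, 500]`, so level
   `k = floor(G · (HU + 10)/510)`, with HU = 500 clamped into the top bin.
4. **Masked co-occurrence matrix.** For interpixel distance δ = 1 and each
   of the four in-plane orientations (0°, 45°, 90°, 135°), every pixel
   pair with *both* ends inside the ROI contributes a count
   `P[i, j]`. Pixels of the bounding box outside the ROI never
   contribute. Counts are pooled over orientations, symmetrized
   (`P + t(P)`) and normalized: `C = P / sum(P)`.
5. **Texture statistics.** With all sums over level pairs `(i, j)`:

   * uniformity `= Σ C_ij²`
   * entropy `= Σ C_ij log C_ij` (natural log, `0·log 0 = 0`)
   * dissimilarity `= Σ C_ij |i − j|`
   * correlation `= Σ (i − μx)(j − μy) C_ij / (σx σy)`
   * inverse difference normalized (IDN) `= Σ C_ij / (1 + |i − j|²/G²)`

   Two conventions deserve a note. Entropy is implemented *exactly as
   defined above*, i.e. without the customary minus sign, and is therefore
   non-positive; users expecting the Shannon convention should negate it.
   The IDN denominator `1 + |i − j|²/G²` is the formula most references
   call inverse difference *moment* normalized; the package keeps the
   short label `idn` for the statistic as defined here.

Alongside the five statistics the feature vector carries the mean HU of
the filtered in-mask pixels on the measured slice and the cross-sectional
area.

## The statistical layer

* **Tumor vs normal comparison** (`mannWhitney`): two-sided Mann–Whitney
  rank test per feature, exact when the combined sample size is ≤ 12 with
  no ties, otherwise the normal approximation with tie-corrected variance
  and continuity correction.
* **Survival association** (`coxUnivariate`): univariate Cox proportional
  hazards per feature, Breslow tie handling by default (Efron available),
  with the Wald statistic `(B/SE)²` referred to χ²(1). Monotone
  likelihoods (a covariate that perfectly orders the risk sets) are
  detected and reported as a divergence error rather than returning a
  runaway coefficient.
* **Prognostic value** (`rocAnalysis`): rank-based AUC with ties counted
  1/2, oriented so the reported AUC ≥ 0.5; Youden-optimal threshold (ties
  resolved toward the lower threshold); Hanley–McNeil 95% interval; the
  AUC ≠ 0.5 p-value comes from the equivalent Mann–Whitney test. The AUC
  satisfies `AUC = U/(n₁·n₀)` identically, which the test suite asserts on
  tied data.
* **Kaplan–Meier** (`kmCurve`, `medianSplitKM`): product-limit curves,
  median split of a feature (high group: feature ≥ median), log-rank
  χ²(1).

**Outcome dichotomization for ROC.** Published analyses of this design
rarely state how survival was binarized for ROC. The package defaults to
the cohort-median rule — positive class = survival time ≥ the cohort
median — because with a 30-patient cohort it produces a 15/15 split whose
sensitivities and specificities are multiples of 1/15, matching the
granularity seen in published tables of this kind. The rule is a
reconstruction, is flagged as such here, and a fixed-horizon alternative
(`rocRule = "horizon"`) is available. The median rule ignores censoring
when labelling; with substantial early censoring a fixed horizon is the
sounder choice.

**Early-death exclusion.** `filterCohort` removes subjects who *died*
within 3 months (default) of surgery, because very early deaths reflect
post-operative complications rather than tumor biology; subjects censored
before 3 months are retained.

**Multiplicity.** No multiple-testing adjustment is applied across the
seven covariates; the reports print raw p-values and the run log notes
this explicitly.

## Tunable parameters

| parameter | default | units | rationale |
|---|---|---|---|
| HU window `lo`, `hi` | −10, 500 | HU | fat / stent exclusion; bounds inclusive |
| grey levels `G` | 64 | – | common radiomics practice; dense enough GLCM at ROI sizes of 10²–10³ pixels over a 510-HU range (~8 HU per bin) |
| offset δ | 1 | pixels | adjacent-pixel texture |
| orientations θ | 0°, 45°, 90°, 135° | – | pooled into one symmetric GLCM before normalizing, giving one rotation-robust value per feature; any subset may be requested |
| Cox ties | Breslow | – | the default of the legacy statistical packages this workflow descends from; Efron available |
| ROC rule | median | – | see above |
| exclusion horizon | 3 | months | early post-operative deaths |

Pooling counts across orientations (rather than averaging one GLCM per
orientation) is a deliberate choice: it weights each orientation by its
number of admissible pairs, behaves gracefully for masks so thin that
some orientation has few or no pairs, and is consistent with reporting a
single value per feature. For large, roughly isotropic ROIs the two
conventions differ negligibly.

The analysis is deliberately 2D (per-slice): features are defined on the
largest cross-section, so 3D offsets are out of scope.

## The synthetic cohort generator

No patient imaging ships with the package; `generatePhantom` and
`generateCohort` provide a fully reproducible stand-in that emulates the
*statistical structure* the pipeline assumes:

* a darker tumor ellipse (mean 57 HU) and a brighter normal-pancreas
  ellipse (mean 71 HU) on a fat-like −100 HU background, with in-plane
  radii shrinking away from the central slice like an ellipsoid;
* spatially correlated Gaussian texture: white noise smoothed by a
  separable moving average of half-width ℓ (circular edges keep the field
  stationary) and rescaled by the theoretical variance reduction
  `(2ℓ+1)²`, so the target SD is honoured at every ℓ. A moving-average
  field was chosen over spectral Gaussian-random-field synthesis because
  it is dependency-light and its GLCM feature response is empirically
  monotone in ℓ (the suite checks dissimilarity decreases when ℓ grows);
* in-ROI values clipped into the HU window (clip counts are reported), so
  quantization always sees admissible values;
* per-subject texture heterogeneity: tumor noise SD drawn uniformly from
  6–18 HU, which makes dissimilarity vary across the cohort; tumor
  in-plane radii additionally jittered by ±30% per subject so the size
  covariate is not degenerate;
* survival linked to texture through a proportional-hazards model:
  `T ~ Exponential(λ₀ · exp(β · z))` with `z` the cohort-standardized
  driven feature (dissimilarity by default), administrative censoring
  uniform on (0, `censorMax`). The hazard is linear in the *standardized*
  feature so that β is comparable across features whose raw scales differ
  by orders of magnitude. Defaults emulate a resected-pancreatic-cancer
  cohort: n = 30, λ₀ = 1/31 per month (mean survival ≈ 31 months),
  72-month follow-up, β = 0.8.

One master seed reproduces the entire cohort bit-for-bit: subject seeds
are drawn once from the master stream, and every phantom is deterministic
given its seed.

**What the phantoms do not emulate** — and therefore what passing tests
do *not* establish about real data: anatomical shape and neighbouring
organs, scanner physics (beam hardening, reconstruction kernels, dose
noise), contrast-phase timing, inter-observer contour variability, and
any real association between texture and outcome. The generator validates
the *software*: that the measurement chain computes what it claims and
that the statistical layer recovers effects it is fed.

## Numerical choices and degenerate inputs

* GLCMs with no admissible pair (mask too thin for the offset) raise a
  degenerate-GLCM error; nothing silently emits NaN.
* Correlation is undefined when a marginal SD is zero (constant texture);
  it is recorded as `NA` with a warning, and downstream fits drop such
  subjects pairwise with a logged count — it is neither coerced to 0 nor
  an error.
* Quantization refuses in-mask values outside `[lo, hi]` (a contract
  violation: the HU filter must run first), and clamps only the exact
  `HU = hi` boundary.
* The Cox fit requires ≥ 2 events and a non-constant covariate, and turns
  monotone-likelihood warnings into errors.
* Medians and quartiles use the mid-point convention for even sample
  sizes (R's default type-7 quantiles for the IQR columns).
* Byte-identical reruns: the report CSVs contain no timestamps and every
  random quantity flows from the configured seed.

## Problem sizes used by the test suite

The suite validates the GLCM core against a brute-force pair enumerator
on hundreds of random instances up to 8×8 pixels and 8 grey levels (where
exhaustive enumeration is exact and fast), checks Cox parameter recovery
on 100 synthetic cohorts of n = 300 subjects rendered as small 3-slice
phantoms (24×24 pixels — the phantom grid only has to be large enough to
give the texture statistics room to vary), calibrates the rank and
log-rank tests with 2000 null replicates at 15/15 split sizes, and runs
the full pipeline end-to-end on a written 100-subject cohort at the
default 48×48×5 geometry. These sizes were chosen so each property is
measured with comfortable statistical resolution while the whole suite
stays desk-scale.

## Known limitations

* Single-feature (univariate) survival modelling only; a 30-patient
  design cannot support multivariate adjustment, and the package does not
  offer it.
* No proportional-hazards diagnostics or time-dependent ROC.
* The texture family is GLCM-only (no run-length, size-zone or wavelet
  features) and is not IBSI-certified.
* The NIfTI reader trusts the header's voxel spacing; DICOM series
  assembly, registration and RTSTRUCT contours are out of scope.
* Published tables of this workflow sometimes report entropy at a scale
  (×10⁻³) that no GLCM entropy reaches at plausible G under the printed
  formula; the package implements the formula as defined above and makes
  no attempt to reproduce such scalings.
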