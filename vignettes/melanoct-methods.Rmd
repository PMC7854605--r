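---
title: "Quantifying RPE changes in serous PED from multi-contrast OCT: methods and design"
author: "melanoct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RPE changes in serous PED from multi-contrast OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In age-related macular degeneration, the retinal pigment epithelium (RPE)
over a serous pigment epithelial detachment (PED) responds with sloughing,
hypertrophy, stacking and intraretinal migration. These responses are
melanin-associated and are believed to indicate RPE activity, so mapping
*where* on a PED the RPE-melanin has thickened is clinically informative.
Multi-contrast OCT (MC-OCT) acquires three co-registered volumes in one
scan — standard intensity OCT, OCT angiography (flow) and
polarization-sensitive OCT — and this package implements the quantitative
pipeline that turns such a dataset into per-eye measurements:

1. **DOPU** (degree of polarization uniformity) from the Stokes volume;
2. a **depth-resolved attenuation coefficient** from the intensity volume;
3. the **RPE-melanin-specific index**
   \( F_{RPE} = \mu_{norm} \times (1 - DOPU) \times (1 - OCTA_b) \);
4. en-face **melanin thickness maps** by per-A-line voxel counting;
5. **PED morphometry** (maximum height, area, Cavalieri volume, peak/slope
   partition) from segmentation surfaces;
6. **RPE\(_{70}\)** active-lesion areas and area ratios per region;
7. the **cohort statistics** (Wilcoxon signed-rank, simple and stepwise
   multiple linear regression with standardized coefficients).

Because clinical MC-OCT volumes of this kind are not publicly deposited, the
package ships a synthetic phantom generator that reproduces the instrument
geometry and the contrast structure the method relies on, with exact ground
truth for every downstream quantity. All validation is phantom-based.

## Polarimetry

**DOPU.** Melanin scrambles the polarization state of backscattered light.
DOPU at a voxel is the degree of polarization of the kernel-averaged Stokes
vector, \( \sqrt{\bar S_1^2 + \bar S_2^2 + \bar S_3^2} / \bar S_0 \),
computed within each B-scan over an (axial x lateral) window, 3 x 3 by
default. Uniformly polarized tissue gives DOPU = 1; melanin voxels carry
mutually incoherent states whose component means cancel, driving DOPU down.
Two details matter:

* *Kernel averaging is constitutive, not cosmetic.* A single fully polarized
  voxel has DOPU 1 regardless of its state; only disagreement between
  neighbouring states within the window reveals depolarization. The flip
  side is a resolution cost: every melanin/tissue interface is blurred by
  about half a kernel, which biases depolarization-based thickness counts
  upward by roughly one voxel per interface. The \(F_{RPE}\)-based
  RPE-melanin map does not inherit this bias because its attenuation factor
  is computed per A-line and stays low in the bled-into voxels.
* *Noise correction.* An additive-noise correction subtracts a configured
  noise variance from the squared component means and from \(\bar S_0\)
  before the ratio (default 0: the phantoms control their own noise).
  Windows with no signal at all have no polarization evidence; they are
  emitted as DOPU = 1 and flagged, so they can never masquerade as melanin.
  Values within one part in \(10^{12}\) of 1 are snapped to exactly 1 so
  that uniform polarization tests as the limit it is.

**Attenuation.** The depth-resolved single-scattering estimator attributes
the signal at depth \(z\) to local backscatter relative to the energy still
arriving below:
\( \hat\mu(z) = I(z) \,/\, \{2\Delta [\sum_{z'>z} I(z') + I(z)/2]\} \).
Numerical choices: the below-voxel sum is accumulated bottom-up (a top-down
cumulative sum subtracted from the total cancels catastrophically where the
tail is \(10^{-13}\) of the total), and the \(I(z)/2\) term makes the
denominator the trapezoidal estimate of the tail integral, reducing the
discretization bias from first to second order in \(\mu\Delta\) (for a pure
exponential the estimate is \(\tanh(\mu\Delta)/\Delta\)). Depths whose tail
carries no signal are emitted as \(\mu = 0\) and flagged. The estimate is
valid "away from the tail": within \(2.3/\mu\) mm of the volume bottom the
truncated tail inflates \(\hat\mu\) by more than 1%. For the \(F_{RPE}\)
product the coefficient is normalized, \( \mu_{norm} = \mathrm{clip}(\mu /
\mu_{ref}, 0, 1) \) with \(\mu_{ref} = 10\) mm\(^{-1}\) by default, so the
index is bounded and its fixed threshold meaningful. Whether the original
index used a physical-unit or normalized coefficient is not documented; the
normalization reference is an exposed configuration key, not a claim.

**Flow.** OCT angiography is consumed as a normalized decorrelation-like
scalar in [0, 1] and binarized at 0.5 by default (\(\ge\) threshold = flow).
The instrument's own binarization threshold is not documented; 0.5 on a
normalized scale separates the phantom's choroid (~0.9) from avascular
tissue (~0.05) with large margin.

## Melanin contrast and thickness maps

Melanin in both the RPE and the choroid depolarizes, but only the choroid
carries flow. \(F_{RPE}\) therefore multiplies three per-voxel factors:
normalized attenuation (melanin attenuates strongly), \(1 - DOPU\)
(depolarization), and \(1 - OCTA_b\) (no flow). Choroidal melanin is
suppressed by the last factor; weakly scattering depolarization artifacts by
the first.

Thickness maps count voxels per A-line over the full depth range and
multiply by the axial pitch:

* chorioretinal melanin: DOPU **< 0.8**, strict;
* RPE melanin: \(F_{RPE}\) **\(\ge\) 0.15**, inclusive.

Tie handling at each threshold follows the printed definitions exactly, and
is boundary-tested. Counting over the full depth range matches the method's
description; an optional depth mask argument can restrict counting (e.g. to
exclude artifacts below Bruch's membrane) and is off by default.

## PED morphometry

All morphometry runs on two en-face depth-index surfaces — Bruch's membrane
and the outer boundary of the RPE band — plus a manually determined PED
margin mask. Segmentation itself is out of scope (it was manual in the
source workflow); the phantom supplies exact surfaces.

* **Height** = (Bruch index − outer-RPE index) x axial pitch, zero outside
  the margin; inverted surfaces are rejected listing the offending A-lines.
* **Maximum PED height** = max over the margin; ties resolve to the first
  maximum in raster order (fast axis first) and the location is reported.
* **PED area** = margin pixel count x true pixel area. The grid is
  anisotropic (6/512 x 6/256 mm by default); no square-pixel assumption is
  ever made.
* **Volume** follows the Cavalieri principle: per-B-scan cross-sectional
  area (sum of height x pixel width within the margin) times B-scan
  spacing.
* **Peak/slope partition**: the peak region is the super-level set of the
  height map at 70% of the maximum height; the slope region is the residual
  PED. For the unimodal domes of serous PEDs this coincides with the area
  inside the manually traced 70%-height contour. In multimodal height maps
  every super-level pixel belongs to the peak (no largest-component
  selection). A degenerate flat PED (max height 0) goes entirely to the
  slope region with a warning. Note that raising the peak fraction *grows*
  the slope area ratio (the peak super-level set shrinks), from 0 at
  fraction 0 towards 1 at fraction 1.

Indices are 1-based (R convention); every reported quantity is an index
difference or a count, so no off-by-one can leak into measurements.

## RPE\(_{70}\) lesions

An active RPE lesion is operationally a region of thickened RPE-melanin:
RPE-melanin thickness \(\ge\) 70 um (inclusive), i.e. \(\ge\) 20 axial
pixels at the default 3.5 um pitch. No minimum-size or connectivity filter
is applied — the definition is a pure thickness threshold — and the cutoff
is a configuration key (the 70 um value is provisional in the source
workflow). Lesion areas and area ratios (lesion area / region area) are
reported for the whole PED, the peak and the slope regions, along with the
distribution pattern (both regions / peak only / slope only / none).
Evaluation is restricted to the PED margin; thickened pixels outside it are
excluded from all ratios and reported separately. A ratio over an empty
region is undefined and reported as NA, never as 0.

## Cohort statistics

* **Wilcoxon signed-rank** (slope- vs peak-region lesion areas): two-sided;
  zero differences dropped; mid-ranks for ties; exact null distribution for
  n \(\le\) 25 without ties, else normal approximation with continuity
  correction. All-zero differences are undefined and flagged.
* **Simple linear regression**: Pearson r with its two-sided t-test.
* **Multiple linear regression** is computed on z-scored predictors and
  response, so coefficients are standardized \(\beta\)s with t-based 95%
  CIs (df = n − p − 1). Standardization is a design choice: reported
  \(\beta\) magnitudes of 0.1–1 across variables whose raw units differ by
  orders of magnitude (mm vs mm\(^3\)) only make sense on a standardized
  scale. For a single predictor the standardized \(\beta\) equals Pearson r
  exactly, which the tests assert to 1e-10.
* **Stepwise selection** is bidirectional with p-value entry/stay thresholds
  0.05/0.10 by default (an AIC criterion via `stats::step` is available).
  The selection criterion of the original analysis is not documented, and
  it is ambiguous whether its reported coefficient tables come from full or
  selected models — so every report carries both: the refit selected model
  and the full four-predictor table, with the selection path.
* Two-sided tests throughout; no multiplicity correction (none was applied
  in the source analysis); eyes are treated as independent even when two
  eyes share a patient — both choices are flagged in the analysis output.

## The phantom generator

The phantom reproduces the features the pipeline *measures*, with exact
ground truth:

* **Geometry**: 512 A-lines x 256 B-scans over 6.0 x 6.0 mm by default.
  The axial sampling pitch of the instrument is not documented (only its
  6 um depth resolution), so the pitch is a free parameter, default 3.5
  um/pixel — chosen so the 70 um cutoff is exactly 20 pixels — and recorded
  in all output metadata.
* **Anatomy**: a dome-shaped PED (spherical cap with analytic volume
  \(\pi h (3a^2 + h^2)/6\), or truncated Gaussian with analytic volume
  \(2\pi\sigma^2 H (1 - e^{-a^2/2\sigma^2})\)); an RPE melanin band of
  configurable thickness riding on the outer-RPE surface; optional planted
  lesions (extra band thickness in the peak or slope region, or
  intraretinal melanin foci); serous fluid under the dome; a vascular
  melanin-bearing choroid below Bruch's membrane.
* **Contrasts**: melanin voxels draw per-voxel polarization states
  uniformly on the Poincaré sphere (kernel-averaged DOPU concentrates near
  1/3 for a 3x3 kernel); all other tissue shares one state plus Gaussian
  noise (DOPU ~ 1). The choroid carries flow ~0.9, everything else ~0.05.
  Intensity follows a piecewise-exponential single-scattering model
  \(I(z) = \mu(z) e^{-2\int\mu}\) with high attenuation (8 mm\(^{-1}\))
  inside melanin, so the attenuation estimator sees a self-consistent
  scene. Generation is bit-identical for a fixed seed.

What the phantom does **not** emulate — and what passing tests therefore do
not establish about clinical data: speckle statistics, eye-motion artifacts,
Jones-matrix physics (true diattenuation/retardance), the empirical
DOPU–melanin-density relationship (real maps are proportional to, not equal
to, melanin thickness), vessel shadowing, hard exudates (which depolarize
without flow and are a documented confounder), and segmentation error
(surfaces are exact by construction). The pipeline's *estimators* are
validated; the biological calibration of the 0.8 / 0.15 / 70 um thresholds
is inherited, not re-derived.

**The parametric cohort generator** emits per-eye tables for statistical
validation: lognormal maximum height (0.288 ± 0.202 mm) and PED area
(7.345 ± 7.378 mm²), volume = 0.66 x area x height x lognormal noise
(0.66 ~ a dome shape factor), truncated-normal slope area ratio
(0.713 ± 0.097), and a planted linear volume→lesion-area effect with
correlation 0.873. The whole-PED lesion-area baseline is 0.055 mm²,
calibrated by simulation so that the cohort mean slope-region area ratio
lands on its 0.011 target after zero-truncation; the resulting mean
whole-PED lesion area (~0.066 mm²) sits about 9% below the corresponding
cohort mean — a four-parameter model cannot match every moment of the
empirical joint distribution at once, and the ratio target takes priority.

## Problem sizes and tolerances

The test-suite and the acceptance script choose grid sizes per task:
surface-only morphometry runs at the full 512 x 256 grid (it is cheap);
volumetric pipeline checks run on reduced grids (typically 96 x 48 to
128 x 64 en-face, 200–240 depth samples), which preserve every contrast
mechanism at ~2% of the full voxel count. Statistical recovery properties
use 26-eye cohorts (the study size) with 100–200 replicates, and population
-level generator checks use 200–2000 eyes. Key numeric tolerances: F_RPE
vectorized-vs-oracle 1e-12 relative; attenuation recovery 2% away from the
tail; morphometry 2% against analytic references; partition level-set 3%;
lesion-area recovery ±10%; float TIFF round trips 1e-6 relative.

## Known limitations

* DOPU-based thickness inherits a +1 voxel/interface kernel bias (above);
  chorioretinal maps are accordingly biased high by 2–4 axial pixels while
  \(F_{RPE}\)-based maps are not.
* The stepwise p-entry criterion tests each candidate marginally, so with
  k pure-noise predictors an empty selection happens with probability about
  \(0.95^k\) (~81% for k = 4), not more.
* Cavalieri volumes quantize heights to the axial pitch; at 3.5 um the
  resulting error floor (~1e-3 relative) dominates en-face refinement below
  ~128 B-scans.
* The statistics module treats eyes as independent; a mixed-effects
  extension for two-eyes-per-patient designs is deliberately out of scope.
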