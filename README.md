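# melanoct

Quantitative mapping of retinal pigment epithelium (RPE) changes in serous
pigment epithelial detachments (PED) from multi-contrast OCT (MC-OCT).

## The problem

MC-OCT collects three co-registered volumes in one scan: standard intensity
OCT, OCT angiography (flow) and polarization-sensitive OCT. Melanin — in
both the RPE and the choroid — scrambles the polarization of backscattered
light, which shows up as low **DOPU** (degree of polarization uniformity).
To isolate *RPE* melanin from choroidal melanin, a per-voxel index exploits
the avascularity of the RPE:

```
F_RPE = attenuation coefficient x (1 - DOPU) x (1 - OCTA_b)
```

where `OCTA_b` is the binarized angiography signal. High `F_RPE` marks
depolarizing tissue without blood flow, i.e. RPE melanin. Counting voxels
with `F_RPE >= 0.15` on each A-line yields an en-face **RPE-melanin
thickness map**; regions of thickened RPE-melanin (**RPE_70**: >= 70 um)
are the operational "active RPE lesions". Each PED is partitioned into a
**peak region** (height >= 70% of the maximum PED height) and a **slope
region** (the rest), and lesion areas/area ratios are compared against
morphometric PED parameters (maximum height, area, Cavalieri volume, slope
area ratio) with Wilcoxon signed-rank tests and (stepwise) standardized
linear regression.

The package implements the entire pipeline plus a synthetic MC-OCT phantom
generator (dome-shaped serous PED, depolarizing RPE band and choroid,
planted melanin lesions, exact ground truth), which is how everything is
validated — no clinical data ship with the package. It is aimed at
researchers in quantitative ophthalmic imaging who want a reference
implementation of DOPU / F_RPE / RPE_70 analysis or a ground-truthed
phantom to benchmark their own.

## Worked example

Simulate a PED phantom with a planted lesion in each region and run the
full pipeline:

```r
library(melanoct)

cfg <- pipelineConfig(phantom = phantomConfig(
  nAlines = 128L, nBscans = 64L, nDepth = 240L,
  pedRadiusMm = 1.4, pedMaxHeightMm = 0.26,
  lesions = list(list(region = "peak",  radiusMm = 0.30, addedUm = 70),
                 list(region = "slope", radiusMm = 0.25, addedUm = 70)),
  seed = 7L))
bundle <- runPipeline(cfg)

bundle$morphometry
#> Morphometric PED parameters:
#>   maximum PED height : 0.259 mm
#>   PED area           : 6.170 mm^2
#>   PED volume         : 0.810 mm^3 (Cavalieri)
#>   slope area ratio   : 0.689

bundle$rpe70
#> RPE_70 (cutoff 70 um): pattern 'both regions'
#>   area  whole/peak/slope: 0.4834 / 0.2812 / 0.2021 mm^2
#>   ratio whole/peak/slope: 0.0783 / 0.1468 / 0.0475
```

The recovered maximum height is the 0.26 mm design apex quantized to the
3.5 um axial pitch; the PED area is the pixelated footprint of the 1.4 mm
radius dome (pi r^2 = 6.16 mm^2); and both planted lesions are recovered,
hence pattern "both regions". `runPipeline(cfg, outDir = "out")`
additionally writes every intermediate (TIFF volumes and maps with JSON
sidecars, masks, rendered PNGs, a results CSV) reproducibly — reruns are
byte-identical for a fixed seed.

Cohort-level statistics on a generated 26-eye cohort:

```r
co  <- generateCohortTable(nEyes = 26L, seed = 1L)
res <- analyzeCohort(co)
res$wilcoxonSlopeVsPeak$p       # slope-region lesion areas exceed peak-region
#> [1] 3.814697e-06
res$stepwise$rpe70AreaWholeMm2  # stepwise regression on 4 PED parameters
#> RegressionReport for 'rpe70AreaWholeMm2' (criterion: p)
#>   selected: pedVolumeMm3
#>   selected-model standardized coefficients:
#>          term  beta ciLow ciHigh       p
#>  pedVolumeMm3 0.936 0.787   1.08 2.4e-12
```

The generator plants a volume -> lesion-area effect, and the stepwise
selection recovers PED volume (and nothing else) as the predictor of the
whole-PED RPE_70 area.

A thin CLI over the same functions lives at
`inst/scripts/melanoct-cli.R` (`simulate` and `run-all` subcommands with
`--config/--out/--seed`).

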