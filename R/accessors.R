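# Accessors and show methods.

#' @describeIn DopuVolume-class DOPU array.
#' @param x object.
#' @export
setMethod("dopu", "DopuVolume", function(x) x@dopu)

#' @describeIn DopuVolume-class kernel extent (axial, lateral).
#' @export
setMethod("dopuKernel", "DopuVolume", function(x) x@kernel)

#' @describeIn AttenuationVolume-class attenuation coefficient (mm^-1).
#' @param x object.
#' @export
setMethod("mu", "AttenuationVolume", function(x) x@mu)

#' @describeIn AttenuationVolume-class normalized attenuation in [0, 1].
#' @export
setMethod("muNorm", "AttenuationVolume", function(x) x@muNorm)

#' @describeIn AttenuationVolume-class flagged voxels (no tail signal).
#' @export
setMethod("undefinedMask", "AttenuationVolume", function(x) x@undefined)

#' @describeIn DopuVolume-class flagged voxels (empty kernel).
#' @export
setMethod("undefinedMask", "DopuVolume", function(x) x@undefined)

#' @describeIn FlowMask-class binary flow array.
#' @param x object.
#' @export
setMethod("flowMask", "FlowMask", function(x) x@mask)

#' @describeIn FrpeVolume-class F_RPE array.
#' @param x object.
#' @export
setMethod("frpe", "FrpeVolume", function(x) x@frpe)

#' @describeIn EnFaceMap-class value matrix.
#' @param x object.
#' @export
setMethod("mapValues", "EnFaceMap", function(x) x@values)

#' @describeIn ThicknessMap-class map kind.
#' @export
setMethod("mapKind", "ThicknessMap", function(x) x@kind)

#' @describeIn ThicknessMap-class axial pitch (um).
#' @export
setMethod("axialPitch", "ThicknessMap", function(x) x@axialPitchUm)

#' @describeIn MCOCTVolume-class axial pitch (um).
#' @export
setMethod("axialPitch", "MCOCTVolume", function(x) x@axialPitchUm)

#' @describeIn MCOCTVolume-class en-face pitch c(fast, slow), mm.
#' @export
setMethod("pixelSize", "MCOCTVolume", function(x) x@pixelSizeMm)

#' @describeIn EnFaceMap-class en-face pitch c(fast, slow), mm.
#' @export
setMethod("pixelSize", "EnFaceMap", function(x) x@pixelSizeMm)

#' @describeIn MCOCTVolume-class en-face pixel area, mm^2.
#' @export
setMethod("pixelArea", "MCOCTVolume", function(x) prod(x@pixelSizeMm))

#' @describeIn EnFaceMap-class en-face pixel area, mm^2.
#' @export
setMethod("pixelArea", "EnFaceMap", function(x) prod(x@pixelSizeMm))

#' @describeIn RegionPartition-class en-face pixel area, mm^2.
#' @export
setMethod("pixelArea", "RegionPartition", function(x) x@pixelAreaMm2)

#' @describeIn MCOCTVolume-class intensity array.
#' @export
setMethod("intensityVolume", "MCOCTVolume", function(x) x@intensity)

#' @describeIn MCOCTVolume-class the \linkS4class{StokesVolume}.
#' @export
setMethod("stokesVolume", "MCOCTVolume", function(x) x@stokes)

#' @describeIn MCOCTVolume-class flow array.
#' @export
setMethod("flowVolume", "MCOCTVolume", function(x) x@flow)

#' @describeIn SegmentationSet-class Bruch's membrane depth-index map.
#' @param x object.
#' @export
setMethod("bruchSurface", "SegmentationSet", function(x) x@bruch)

#' @describeIn SegmentationSet-class outer RPE boundary depth-index map.
#' @export
setMethod("rpeOuterSurface", "SegmentationSet", function(x) x@rpeOuter)

#' @describeIn SegmentationSet-class PED margin mask.
#' @export
setMethod("marginMask", "SegmentationSet", function(x) x@margin)

#' @describeIn RegionPartition-class peak-region mask.
#' @param x object.
#' @export
setMethod("peakMask", "RegionPartition", function(x) x@peak)

#' @describeIn RegionPartition-class slope-region mask.
#' @export
setMethod("slopeMask", "RegionPartition", function(x) x@slope)

#' @describeIn RegionPartition-class whole-PED mask.
#' @export
setMethod("wholeMask", "RegionPartition", function(x) x@whole)

setMethod("show", "MCOCTVolume", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("MCOCTVolume: %d depth x %d A-lines x %d B-scans\n", d[1], d[2], d[3]))
  cat(sprintf("  axial pitch %.2f um, en-face pitch %.4f x %.4f mm\n",
              object@axialPitchUm, object@pixelSizeMm[1], object@pixelSizeMm[2]))
  cat("  contrasts: intensity, Stokes (s0..s3), flow\n")
})

setMethod("show", "DopuVolume", function(object) {
  cat(sprintf("DopuVolume: %s, kernel %dx%d (axial x lateral), noise var %.3g\n",
              paste(dim(object@dopu), collapse = " x "),
              object@kernel[1], object@kernel[2], object@noiseVariance))
  cat(sprintf("  range [%.3f, %.3f], %d flagged voxels\n",
              min(object@dopu), max(object@dopu), sum(object@undefined)))
})

setMethod("show", "ThicknessMap", function(object) {
  cat(sprintf("ThicknessMap (%s): %d x %d px, max %.1f um\n", object@kind,
              nrow(object@values), ncol(object@values), max(object@values)))
})

setMethod("show", "MorphometryResult", function(object) {
  cat("Morphometric PED parameters:\n")
  cat(sprintf("  maximum PED height : %.3f mm\n", object@maxHeightMm))
  cat(sprintf("  PED area           : %.3f mm^2\n", object@pedAreaMm2))
  cat(sprintf("  PED volume         : %.3f mm^3 (Cavalieri)\n", object@pedVolumeMm3))
  cat(sprintf("  slope area ratio   : %.3f\n", object@slopeAreaRatio))
})

setMethod("show", "Rpe70Result", function(object) {
  cat(sprintf("RPE_70 (cutoff %.0f um): pattern '%s'\n",
              object@cutoffUm, object@pattern))
  cat(sprintf("  area  whole/peak/slope: %.4f / %.4f / %.4f mm^2\n",
              object@areaWholeMm2, object@areaPeakMm2, object@areaSlopeMm2))
  cat(sprintf("  ratio whole/peak/slope: %s / %s / %s\n",
              formatC(object@ratioWhole, 4, format = "f"),
              formatC(object@ratioPeak, 4, format = "f"),
              formatC(object@ratioSlope, 4, format = "f")))
})

setMethod("show", "RegressionReport", function(object) {
  cat(sprintf("RegressionReport for '%s' (criterion: %s)\n",
              object@response, object@criterion))
  cat(sprintf("  selected: %s\n",
              if (length(object@selected)) paste(object@selected, collapse = ", ")
              else "(intercept only)"))
  if (nrow(object@coefficients)) {
    cat("  selected-model standardized coefficients:\n")
    print(object@coefficients, row.names = FALSE, digits = 3)
  }
})
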