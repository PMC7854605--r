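# Central S4 data containers.
#
# Conventions used throughout the package:
#   * Volumes are numeric arrays with dim = c(n_depth, n_alines, n_bscans),
#     i.e. depth (axial, z) x fast axis (x) x slow axis (y). Depth index
#     increases away from the vitreous (1 = innermost sample).
#   * En-face images are matrices with dim = c(n_alines, n_bscans).
#   * Segmentation surfaces store 1-based depth indices.
#   * pixelSizeMm = c(fast, slow) pitch; the en-face grid is anisotropic
#     (e.g. 6/512 x 6/256 mm) and all areas use the true pixel area.

.isVolume <- function(x) is.array(x) && length(dim(x)) == 3L && is.numeric(x)
.isEnFace <- function(x) is.matrix(x)

#' Stokes-parameter volume
#'
#' Per-voxel polarization state of a polarization-sensitive OCT volume as the
#' four Stokes components. \code{s0} is (proportional to) intensity; the
#' polarized part \code{(s1, s2, s3)} satisfies
#' \eqn{s_1^2+s_2^2+s_3^2 \le s_0^2} up to noise.
#'
#' @slot s0,s1,s2,s3 numeric arrays, depth x fast x slow.
#' @export
setClass("StokesVolume",
  representation(s0 = "array", s1 = "array", s2 = "array", s3 = "array"),
  validity = function(object) {
    if (!all(vapply(list(object@s0, object@s1, object@s2, object@s3),
                    .isVolume, logical(1))))
      return("s0..s3 must be numeric 3-D arrays")
    d <- dim(object@s0)
    for (s in list(object@s1, object@s2, object@s3))
      if (!identical(dim(s), d)) return("Stokes components differ in dimension")
    if (any(!is.finite(object@s0))) return("s0 contains non-finite values")
    if (any(object@s0 < 0)) return("s0 must be non-negative")
    TRUE
  })

#' @rdname StokesVolume-class
#' @param s0,s1,s2,s3 numeric arrays of identical dimension.
#' @export
StokesVolume <- function(s0, s1, s2, s3)
  new("StokesVolume", s0 = s0, s1 = s1, s2 = s2, s3 = s3)

#' Co-registered multi-contrast OCT volume
#'
#' Bundles the three simultaneously acquired contrasts: a standard (intensity)
#' OCT volume, the per-voxel polarization state, and a normalized flow
#' (OCT angiography) volume, plus the voxel pitch metadata needed for any
#' quantitative measurement.
#'
#' @slot intensity numeric array, linear-scale backscatter intensity.
#' @slot stokes a \linkS4class{StokesVolume}.
#' @slot flow numeric array in [0, 1], decorrelation-like angiography signal.
#' @slot axialPitchUm axial sampling pitch, micrometres per pixel.
#' @slot pixelSizeMm en-face pitch c(fast, slow) in mm.
#' @slot metadata free-form list (seed, configuration hash, ...).
#' @export
setClass("MCOCTVolume",
  representation(intensity = "array", stokes = "StokesVolume", flow = "array",
                 axialPitchUm = "numeric", pixelSizeMm = "numeric",
                 metadata = "list"),
  validity = function(object) {
    if (!.isVolume(object@intensity) || !.isVolume(object@flow))
      return("intensity and flow must be numeric 3-D arrays")
    d <- dim(object@intensity)
    if (!identical(dim(object@flow), d) || !identical(dim(object@stokes@s0), d))
      return("intensity, stokes and flow volumes are not co-registered")
    if (length(object@axialPitchUm) != 1L || object@axialPitchUm <= 0)
      return("axialPitchUm must be a single positive number")
    if (length(object@pixelSizeMm) != 2L || any(object@pixelSizeMm <= 0))
      return("pixelSizeMm must be two positive numbers (fast, slow)")
    TRUE
  })

#' @rdname MCOCTVolume-class
#' @param intensity,flow numeric 3-D arrays.
#' @param stokes a \linkS4class{StokesVolume}.
#' @param axialPitchUm,pixelSizeMm voxel pitch metadata.
#' @param metadata list of provenance metadata.
#' @export
MCOCTVolume <- function(intensity, stokes, flow, axialPitchUm, pixelSizeMm,
                        metadata = list())
  new("MCOCTVolume", intensity = intensity, stokes = stokes, flow = flow,
      axialPitchUm = axialPitchUm, pixelSizeMm = pixelSizeMm,
      metadata = metadata)

#' Degree-of-polarization-uniformity volume
#'
#' @slot dopu numeric array in [0, 1].
#' @slot kernel integer pair, kernel extent (axial x lateral-fast).
#' @slot noiseVariance subtractive noise-correction variance used.
#' @slot undefined logical array flagging voxels whose kernel contained no
#'   signal (emitted as DOPU = 1: no evidence of depolarization).
#' @export
setClass("DopuVolume",
  representation(dopu = "array", kernel = "integer", noiseVariance = "numeric",
                 undefined = "array"),
  validity = function(object) {
    if (!.isVolume(object@dopu)) return("dopu must be a numeric 3-D array")
    if (any(object@dopu < 0 | object@dopu > 1, na.rm = TRUE))
      return("dopu values must lie in [0, 1]")
    if (length(object@kernel) != 2L || any(object@kernel < 1L) ||
        any(object@kernel %% 2L == 0L))
      return("kernel must be two odd positive integers (axial, lateral)")
    TRUE
  })

#' @rdname DopuVolume-class
#' @param dopu numeric array in [0,1].
#' @param kernel integer pair (axial, lateral).
#' @param noiseVariance scalar.
#' @param undefined logical array (defaults to all-FALSE).
#' @export
DopuVolume <- function(dopu, kernel = c(3L, 3L), noiseVariance = 0,
                       undefined = array(FALSE, dim(dopu)))
  new("DopuVolume", dopu = dopu, kernel = as.integer(kernel),
      noiseVariance = noiseVariance, undefined = undefined)

#' Depth-resolved attenuation-coefficient volume
#'
#' @slot mu attenuation coefficient, mm^-1.
#' @slot muNorm \code{mu / muRef} clipped to [0, 1].
#' @slot muRefMmInv normalization reference, mm^-1.
#' @slot axialPitchUm axial pitch the estimate was computed at.
#' @slot undefined logical array; TRUE where the below-voxel tail carried no
#'   signal, in which case mu is reported as 0.
#' @export
setClass("AttenuationVolume",
  representation(mu = "array", muNorm = "array", muRefMmInv = "numeric",
                 axialPitchUm = "numeric", undefined = "array"),
  validity = function(object) {
    if (!.isVolume(object@mu)) return("mu must be a numeric 3-D array")
    if (any(object@mu < 0)) return("mu must be non-negative")
    if (any(object@muNorm < 0 | object@muNorm > 1))
      return("muNorm must lie in [0, 1]")
    if (object@muRefMmInv <= 0) return("muRefMmInv must be positive")
    TRUE
  })

#' Binarized OCT-angiography volume
#'
#' @slot mask integer array in {0, 1}: 1 marks flow.
#' @slot threshold binarization threshold on the normalized flow scale.
#' @export
setClass("FlowMask",
  representation(mask = "array", threshold = "numeric"),
  validity = function(object) {
    if (!.isVolume(object@mask)) return("mask must be a numeric 3-D array")
    if (!all(object@mask %in% c(0, 1))) return("mask must be binary (0/1)")
    if (object@threshold <= 0 || object@threshold >= 1)
      return("threshold must lie in (0, 1)")
    TRUE
  })

#' RPE-melanin-specific contrast (F_RPE) volume
#'
#' Per voxel, \eqn{F_{RPE} = \mu_{norm} \times (1 - DOPU) \times (1 - OCTA_b)}:
#' high values mark depolarizing tissue without flow, i.e. RPE melanin.
#'
#' @slot frpe numeric array in [0, 1] (given normalized attenuation).
#' @slot thresholds list recording the ingredients' settings
#'   (flowCut, muRefMmInv, dopu kernel, noiseVariance).
#' @export
setClass("FrpeVolume",
  representation(frpe = "array", thresholds = "list"),
  validity = function(object) {
    if (!.isVolume(object@frpe)) return("frpe must be a numeric 3-D array")
    if (any(object@frpe < 0)) return("frpe must be non-negative")
    TRUE
  })

#' Scalar en-face map
#'
#' A scalar image on the A-line grid (fast x slow), e.g. a height map in mm.
#'
#' @slot values numeric matrix, n_alines x n_bscans.
#' @slot unit unit string ("um", "mm", ...).
#' @slot pixelSizeMm en-face pitch c(fast, slow), mm.
#' @export
setClass("EnFaceMap",
  representation(values = "matrix", unit = "character",
                 pixelSizeMm = "numeric"),
  validity = function(object) {
    if (!is.numeric(object@values)) return("values must be numeric")
    if (length(object@pixelSizeMm) != 2L || any(object@pixelSizeMm <= 0))
      return("pixelSizeMm must be two positive numbers")
    TRUE
  })

#' @rdname EnFaceMap-class
#' @param values numeric matrix.
#' @param unit unit string.
#' @param pixelSizeMm c(fast, slow) pitch in mm.
#' @export
EnFaceMap <- function(values, unit = "mm", pixelSizeMm)
  new("EnFaceMap", values = values, unit = unit, pixelSizeMm = pixelSizeMm)

#' En-face melanin thickness map
#'
#' Thickness in micrometres obtained by per-A-line voxel counting: either all
#' depolarizing voxels (chorioretinal melanin, DOPU below cut) or voxels with
#' high F_RPE (RPE melanin only).
#'
#' @slot kind "chorioretinal_melanin" or "rpe_melanin".
#' @slot axialPitchUm axial pitch used for the count-to-thickness conversion.
#' @slot cutoff the threshold that defined the counted class.
#' @export
setClass("ThicknessMap", contains = "EnFaceMap",
  representation(kind = "character", axialPitchUm = "numeric",
                 cutoff = "numeric"),
  validity = function(object) {
    if (!object@kind %in% c("chorioretinal_melanin", "rpe_melanin"))
      return("kind must be 'chorioretinal_melanin' or 'rpe_melanin'")
    if (any(object@values < 0)) return("thickness values must be >= 0")
    TRUE
  })

#' @rdname ThicknessMap-class
#' @param values numeric matrix of thicknesses (um).
#' @param kind map kind.
#' @param axialPitchUm axial pitch (um / pixel).
#' @param pixelSizeMm en-face pitch.
#' @param cutoff classification threshold used.
#' @export
ThicknessMap <- function(values, kind, axialPitchUm, pixelSizeMm, cutoff = NA_real_)
  new("ThicknessMap", values = values, unit = "um", pixelSizeMm = pixelSizeMm,
      kind = kind, axialPitchUm = axialPitchUm, cutoff = cutoff)

#' Segmentation surfaces of a PED
#'
#' Bruch's membrane and the outer RPE boundary as en-face depth-index maps
#' (1-based; depth increases away from the vitreous, so the detached RPE
#' boundary has a smaller index than Bruch's membrane), plus the manually
#' determined PED margin as a binary en-face mask.
#'
#' @slot bruch,rpeOuter numeric matrices of depth indices.
#' @slot margin logical matrix, TRUE inside the PED margin.
#' @export
setClass("SegmentationSet",
  representation(bruch = "matrix", rpeOuter = "matrix", margin = "matrix"),
  validity = function(object) {
    d <- dim(object@bruch)
    if (!identical(dim(object@rpeOuter), d) || !identical(dim(object@margin), d))
      return("surfaces and margin mask differ in dimension")
    if (!is.logical(object@margin)) return("margin must be a logical matrix")
    inm <- object@margin
    if (any(!is.finite(object@bruch[inm])) || any(!is.finite(object@rpeOuter[inm])))
      return("surfaces must be finite inside the margin")
    TRUE
  })

#' @rdname SegmentationSet-class
#' @param bruch,rpeOuter depth-index matrices.
#' @param margin logical matrix.
#' @export
SegmentationSet <- function(bruch, rpeOuter, margin)
  new("SegmentationSet", bruch = bruch, rpeOuter = rpeOuter,
      margin = if (is.logical(margin)) margin else margin > 0)

#' Peak/slope partition of a PED
#'
#' The peak region is the super-level set of the height map at a fraction
#' (default 70%) of the maximum PED height; the slope region is the residual
#' PED area. The two are disjoint and tile the whole PED.
#'
#' @slot peak,slope,whole logical en-face masks.
#' @slot pixelAreaMm2 area of one en-face pixel, mm^2.
#' @slot fraction height fraction defining the peak.
#' @export
setClass("RegionPartition",
  representation(peak = "matrix", slope = "matrix", whole = "matrix",
                 pixelAreaMm2 = "numeric", fraction = "numeric"),
  validity = function(object) {
    d <- dim(object@whole)
    if (!identical(dim(object@peak), d) || !identical(dim(object@slope), d))
      return("masks differ in dimension")
    if (any(object@peak & object@slope)) return("peak and slope overlap")
    if (!identical(object@peak | object@slope, object@whole))
      return("peak and slope do not tile the whole mask")
    if (object@pixelAreaMm2 <= 0) return("pixelAreaMm2 must be positive")
    TRUE
  })

#' Morphometric PED parameters
#'
#' @slot maxHeightMm greatest Bruch-to-outer-RPE distance, mm.
#' @slot pedAreaMm2 transverse area within the PED margin, mm^2.
#' @slot pedVolumeMm3 Cavalieri volume, mm^3.
#' @slot slopeAreaRatio slope area / whole PED area.
#' @slot heightMap the underlying \linkS4class{EnFaceMap} (mm).
#' @slot partition the peak/slope \linkS4class{RegionPartition}.
#' @export
setClass("MorphometryResult",
  representation(maxHeightMm = "numeric", pedAreaMm2 = "numeric",
                 pedVolumeMm3 = "numeric", slopeAreaRatio = "numeric",
                 heightMap = "EnFaceMap", partition = "RegionPartition"),
  validity = function(object) {
    if (object@maxHeightMm < 0) return("maxHeightMm must be >= 0")
    if (object@slopeAreaRatio < 0 || object@slopeAreaRatio > 1)
      return("slopeAreaRatio must lie in [0, 1]")
    tol <- 1e-9 + 1e-9 * abs(object@pedVolumeMm3)
    if (object@pedVolumeMm3 > object@pedAreaMm2 * object@maxHeightMm + tol)
      return("pedVolume exceeds pedArea x maxHeight")
    TRUE
  })

#' RPE_70 lesion quantification
#'
#' Areas and area ratios of thickened RPE-melanin (the operational "active RPE
#' lesion": RPE-melanin thickness at or above the cutoff, default 70 um)
#' within the whole PED and its peak and slope regions.
#'
#' @slot mask logical en-face RPE_70 mask (restricted to the PED margin).
#' @slot areaWholeMm2,areaPeakMm2,areaSlopeMm2 lesion areas, mm^2.
#' @slot ratioWhole,ratioPeak,ratioSlope lesion area / region area
#'   (NA when the region is empty: undefined, not 0).
#' @slot pattern distribution pattern: "both regions", "peak only",
#'   "slope only" or "none".
#' @slot cutoffUm thickness cutoff used.
#' @export
setClass("Rpe70Result",
  representation(mask = "matrix", areaWholeMm2 = "numeric",
                 areaPeakMm2 = "numeric", areaSlopeMm2 = "numeric",
                 ratioWhole = "numeric", ratioPeak = "numeric",
                 ratioSlope = "numeric", pattern = "character",
                 cutoffUm = "numeric"),
  validity = function(object) {
    tol <- 1e-9
    if (abs(object@areaWholeMm2 -
            (object@areaPeakMm2 + object@areaSlopeMm2)) > tol)
      return("whole-PED lesion area must equal peak + slope lesion areas")
    for (r in c(object@ratioWhole, object@ratioPeak, object@ratioSlope))
      if (!is.na(r) && (r < 0 || r > 1 + tol)) return("ratios must lie in [0, 1]")
    if (!object@pattern %in% c("both regions", "peak only", "slope only", "none"))
      return("unknown pattern label")
    TRUE
  })

#' Regression report (standardized coefficients)
#'
#' Result of a (stepwise) multiple linear regression on z-scored predictors
#' and response: per-predictor standardized coefficient beta, 95% CI and
#' two-sided p-value, for the selected model and for the full model.
#'
#' @slot response response variable name.
#' @slot coefficients data.frame (term, beta, ciLow, ciHigh, p) of the
#'   selected model (empty if no predictor entered).
#' @slot fullCoefficients same table for the all-predictor model.
#' @slot selected names of selected predictors.
#' @slot path selection path, e.g. c("+pedVolumeMm3").
#' @slot criterion "p" or "AIC".
#' @export
setClass("RegressionReport",
  representation(response = "character", coefficients = "data.frame",
                 fullCoefficients = "data.frame", selected = "character",
                 path = "character", criterion = "character"),
  validity = function(object) {
    cf <- object@coefficients
    if (nrow(cf) && !all(cf$ciLow <= cf$beta + 1e-12 & cf$beta <= cf$ciHigh + 1e-12))
      return("CI bounds must bracket beta")
    if (nrow(cf) && any(cf$p < 0 | cf$p > 1)) return("p-values must lie in [0, 1]")
    TRUE
  })
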