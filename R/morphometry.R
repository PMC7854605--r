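# Morphometric PED parameters from segmentation surfaces: height map,
# maximum height, transverse area, Cavalieri volume, and the peak/slope
# partition at a fraction of the maximum height.

#' PED height map from segmentation surfaces
#'
#' Height at each A-line is the distance between Bruch's membrane and the
#' outer boundary of the RPE band:
#' \code{(bruch_index - rpe_outer_index) * axial_pitch}, converted to mm,
#' and 0 outside the PED margin.
#'
#' @param seg a \linkS4class{SegmentationSet}.
#' @param axialPitchUm axial pitch, um per pixel.
#' @param pixelSizeMm en-face pitch c(fast, slow), mm.
#' @return an \linkS4class{EnFaceMap} in mm.
#' @export
heightMap <- function(seg, axialPitchUm, pixelSizeMm) {
  stopifnot(is(seg, "SegmentationSet"))
  dz <- seg@bruch - seg@rpeOuter
  bad <- seg@margin & dz < 0
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    shown <- utils::head(apply(idx, 1, paste, collapse = ","), 10)
    stopf("inverted surfaces (outer RPE below Bruch's membrane) at %d A-line(s), e.g. (fast,slow) = %s",
          nrow(idx), paste(shown, collapse = "; "))
  }
  h <- dz * (axialPitchUm / 1000)
  h[!seg@margin] <- 0
  EnFaceMap(h, unit = "mm", pixelSizeMm = pixelSizeMm)
}

#' Maximum PED height
#'
#' The greatest Bruch-to-outer-RPE distance over the PED. Ties are resolved
#' to the first maximum in raster order (fast axis first); its en-face
#' position is attached as attribute \code{"location"} (fast, slow indices).
#'
#' @param hm height map (\linkS4class{EnFaceMap}, mm) or numeric matrix.
#' @param margin optional logical mask restricting the search; default: the
#'   whole map (the height map is already 0 outside the margin).
#' @return maximum height in mm, with attribute \code{"location"}.
#' @export
maxPedHeight <- function(hm, margin = NULL) {
  v <- if (is(hm, "EnFaceMap")) hm@values else hm
  if (!is.null(margin)) {
    if (!any(margin)) stopf("empty PED margin: maximum height undefined")
    w <- v
    w[!margin] <- -Inf
    v <- w
  } else if (length(v) == 0L) stopf("empty height map")
  i <- which.max(v)                     # first maximum in column-major = raster(fast-first) order
  out <- v[i]
  attr(out, "location") <- as.integer(arrayInd(i, dim(v)))
  out
}

#' Transverse PED area
#'
#' Pixel count of the margin mask times the true (anisotropic) pixel area.
#'
#' @param margin logical en-face mask.
#' @param pixelAreaMm2 area of one en-face pixel, mm^2
#'   (default (6/512) x (6/256), the instrument grid).
#' @return area in mm^2.
#' @export
pedArea <- function(margin, pixelAreaMm2 = (6 / 512) * (6 / 256)) {
  if (!is.logical(margin)) margin <- margin > 0
  sum(margin) * pixelAreaMm2
}

#' Cavalieri PED volume
#'
#' Sums per-B-scan cross-sectional areas times the B-scan spacing
#' (Cavalieri principle): the cross-sectional area of one B-scan is the sum
#' over its A-lines of height x pixel width, within the PED margin.
#'
#' @param seg a \linkS4class{SegmentationSet}.
#' @param bscanSpacingMm slow-axis spacing between B-scans, mm.
#' @param pixelWidthMm fast-axis A-line spacing, mm.
#' @param axialPitchUm axial pitch, um per pixel.
#' @return volume in mm^3.
#' @export
pedVolumeCavalieri <- function(seg, bscanSpacingMm, pixelWidthMm, axialPitchUm) {
  hm <- heightMap(seg, axialPitchUm, pixelSizeMm = c(pixelWidthMm, bscanSpacingMm))
  crossAreas <- colSums(hm@values) * pixelWidthMm   # one value per B-scan
  sum(crossAreas) * bscanSpacingMm
}

#' Peak/slope partition of the PED
#'
#' The peak region is the set of PED pixels whose height reaches
#' \code{fraction} (default 0.7) of the maximum PED height; the slope region
#' is the residual PED area. For a unimodal dome this super-level set
#' coincides with the area inside the manually traced fractional-height
#' contour. A degenerate flat PED (maximum height 0) is assigned entirely to
#' the slope region, with a warning.
#'
#' @param hm height map (\linkS4class{EnFaceMap} or matrix, mm).
#' @param margin logical en-face PED mask.
#' @param fraction height fraction in [0, 1] defining the peak (default 0.7).
#' @param pixelAreaMm2 pixel area; taken from the map when omitted.
#' @return a \linkS4class{RegionPartition}.
#' @export
partitionRegions <- function(hm, margin, fraction = 0.7, pixelAreaMm2 = NULL) {
  v <- if (is(hm, "EnFaceMap")) hm@values else hm
  if (is.null(pixelAreaMm2)) {
    if (!is(hm, "EnFaceMap")) stopf("pixelAreaMm2 required when hm is a bare matrix")
    pixelAreaMm2 <- prod(hm@pixelSizeMm)
  }
  if (!is.logical(margin)) margin <- margin > 0
  if (!any(margin)) stopf("empty PED margin")
  if (fraction < 0 || fraction > 1) stopf("fraction must lie in [0, 1]")
  hmax <- max(v[margin])
  if (hmax <= 0) {
    warning("degenerate flat PED (maximum height 0): whole PED assigned to slope region")
    peak <- margin & FALSE
  } else {
    peak <- margin & (v >= fraction * hmax)
  }
  new("RegionPartition", peak = peak, slope = margin & !peak, whole = margin,
      pixelAreaMm2 = pixelAreaMm2, fraction = fraction)
}

#' Slope area ratio
#'
#' Area of the slope region divided by the area of the whole PED (pixel
#' counts; the pixel area cancels). A small ratio marks a steep slope.
#'
#' @param partition a \linkS4class{RegionPartition}.
#' @return scalar in [0, 1].
#' @export
slopeAreaRatio <- function(partition) {
  stopifnot(is(partition, "RegionPartition"))
  nWhole <- sum(partition@whole)
  if (nWhole == 0L) stopf("empty PED: slope area ratio undefined")
  sum(partition@slope) / nWhole
}

#' All morphometric PED parameters at once
#'
#' Convenience wrapper computing the height map, maximum PED height, PED
#' area, Cavalieri PED volume, the peak/slope partition and the slope area
#' ratio from one segmentation set.
#'
#' @param seg a \linkS4class{SegmentationSet}.
#' @param axialPitchUm axial pitch, um per pixel.
#' @param pixelSizeMm en-face pitch c(fast, slow), mm.
#' @param peakFraction height fraction defining the peak region (default 0.7).
#' @return a \linkS4class{MorphometryResult}.
#' @export
pedMorphometry <- function(seg, axialPitchUm, pixelSizeMm, peakFraction = 0.7) {
  hm <- heightMap(seg, axialPitchUm, pixelSizeMm)
  part <- partitionRegions(hm, seg@margin, fraction = peakFraction)
  new("MorphometryResult",
      maxHeightMm = as.numeric(maxPedHeight(hm, seg@margin)),
      pedAreaMm2 = pedArea(seg@margin, prod(pixelSizeMm)),
      pedVolumeMm3 = pedVolumeCavalieri(seg, bscanSpacingMm = pixelSizeMm[2],
                                        pixelWidthMm = pixelSizeMm[1],
                                        axialPitchUm = axialPitchUm),
      slopeAreaRatio = slopeAreaRatio(part),
      heightMap = hm, partition = part)
}
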