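# RPE_70 active-lesion quantification: thickness-thresholded mask, per-region
# areas and area ratios, and the distribution-pattern classification.

#' RPE_70 lesion mask
#'
#' An active RPE lesion is operationally defined as an area of thickened
#' RPE-melanin: RPE-melanin thickness at or above \code{cutoffUm}
#' (default 70 um, inclusive). When a margin mask is supplied the lesion mask
#' is restricted to the PED; thickened pixels outside the margin are excluded
#' (they are reported separately by \code{\link{rpe70RegionStats}}).
#'
#' @param map a \linkS4class{ThicknessMap} of kind "rpe_melanin".
#' @param cutoffUm inclusive thickness cutoff, um (default 70).
#' @param margin optional logical en-face PED mask.
#' @return logical en-face mask.
#' @export
rpe70Mask <- function(map, cutoffUm = 70, margin = NULL) {
  stopifnot(is(map, "ThicknessMap"))
  if (map@kind != "rpe_melanin")
    stopf("RPE_70 requires an RPE-melanin thickness map, got kind '%s'", map@kind)
  m <- map@values >= cutoffUm
  if (!is.null(margin)) {
    if (!is.logical(margin)) margin <- margin > 0
    m <- m & margin
  }
  m
}

#' RPE_70 areas and area ratios per region
#'
#' Computes the lesion area inside the whole PED, the peak region and the
#' slope region (pixel counting times the true pixel area), the corresponding
#' area ratios (lesion area / region area), and the distribution pattern:
#' "both regions", "peak only", "slope only" or "none". A ratio over an empty
#' region is undefined and reported as NA, never 0. Lesion pixels outside
#' the PED margin are excluded from all areas and ratios and reported in the
#' attribute \code{"areaOutsideMm2"}.
#'
#' @param mask logical en-face RPE_70 mask (as from \code{\link{rpe70Mask}}).
#' @param partition a \linkS4class{RegionPartition} on the same grid.
#' @param cutoffUm cutoff recorded in the result (default 70).
#' @return an \linkS4class{Rpe70Result}.
#' @export
rpe70RegionStats <- function(mask, partition, cutoffUm = 70) {
  stopifnot(is(partition, "RegionPartition"))
  if (!is.logical(mask)) mask <- mask > 0
  if (!identical(dim(mask), dim(partition@whole)))
    stopf("mask and partition grids differ: %s vs %s",
          paste(dim(mask), collapse = "x"),
          paste(dim(partition@whole), collapse = "x"))
  pa <- partition@pixelAreaMm2
  inWhole <- mask & partition@whole
  nPeak <- sum(mask & partition@peak)
  nSlope <- sum(mask & partition@slope)
  regionRatio <- function(nLesion, regionMask) {
    nRegion <- sum(regionMask)
    if (nRegion == 0L) NA_real_ else nLesion / nRegion
  }
  pattern <- if (nPeak > 0 && nSlope > 0) "both regions"
    else if (nPeak > 0) "peak only"
    else if (nSlope > 0) "slope only"
    else "none"
  out <- new("Rpe70Result", mask = inWhole,
             areaWholeMm2 = sum(inWhole) * pa,
             areaPeakMm2 = nPeak * pa, areaSlopeMm2 = nSlope * pa,
             ratioWhole = regionRatio(sum(inWhole), partition@whole),
             ratioPeak = regionRatio(nPeak, partition@peak),
             ratioSlope = regionRatio(nSlope, partition@slope),
             pattern = pattern, cutoffUm = cutoffUm)
  attr(out, "areaOutsideMm2") <- sum(mask & !partition@whole) * pa
  out
}
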