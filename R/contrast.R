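# RPE-melanin-specific contrast: the F_RPE index and en-face melanin
# thickness maps by per-A-line voxel counting.

#' Compute the RPE-melanin-specific contrast index F_RPE
#'
#' Per voxel,
#' \deqn{F_{RPE} = \mu_{norm} \times (1 - DOPU) \times (1 - OCTA_b).}
#' Melanin in both the RPE and the choroid depolarizes (low DOPU), but only
#' the choroid carries flow; the \eqn{(1 - OCTA_b)} factor therefore
#' suppresses choroidal melanin, and the attenuation factor suppresses
#' weakly scattering depolarization artifacts, leaving RPE melanin.
#'
#' @param att an \linkS4class{AttenuationVolume}.
#' @param dopuVol a \linkS4class{DopuVolume}.
#' @param flow a \linkS4class{FlowMask}.
#' @return an \linkS4class{FrpeVolume}. By construction \code{frpe} is 0
#'   wherever \code{OCTA_b = 1} or \code{DOPU = 1}.
#' @export
computeFrpe <- function(att, dopuVol, flow) {
  stopifnot(is(att, "AttenuationVolume"), is(dopuVol, "DopuVolume"),
            is(flow, "FlowMask"))
  checkSameDim(att@muNorm, dopuVol@dopu, flow@mask)
  f <- att@muNorm * (1 - dopuVol@dopu) * (1 - flow@mask)
  new("FrpeVolume", frpe = f,
      thresholds = list(flowCut = flow@threshold, muRefMmInv = att@muRefMmInv,
                        dopuKernel = dopuVol@kernel,
                        noiseVariance = dopuVol@noiseVariance))
}

.countMap <- function(classified, axialPitchUm) {
  # per-A-line voxel count over the full depth range, converted to um
  apply(classified, c(2, 3), sum) * axialPitchUm
}

#' Chorioretinal melanin thickness map
#'
#' Counts, on each A-line, the voxels with low DOPU (strictly below
#' \code{dopuCut}, default 0.8) and converts the count to micrometres using
#' the axial pitch. The resulting map reflects the total melanin along each
#' A-line, RPE and choroid combined.
#'
#' @param dopuVol a \linkS4class{DopuVolume}.
#' @param dopuCut strict upper DOPU threshold (default 0.8).
#' @param axialPitchUm axial pitch, um per pixel.
#' @param pixelSizeMm en-face pitch c(fast, slow), mm.
#' @param depthMask optional logical array restricting the counted depth
#'   range (e.g. retina only); NULL (default) counts the full depth range.
#' @return a \linkS4class{ThicknessMap} of kind "chorioretinal_melanin".
#' @export
chorioretinalMelaninMap <- function(dopuVol, dopuCut = 0.8, axialPitchUm,
                                    pixelSizeMm, depthMask = NULL) {
  stopifnot(is(dopuVol, "DopuVolume"))
  cls <- dopuVol@dopu < dopuCut
  if (!is.null(depthMask)) {
    checkSameDim(cls, depthMask)
    cls <- cls & depthMask
  }
  ThicknessMap(.countMap(cls, axialPitchUm), kind = "chorioretinal_melanin",
               axialPitchUm = axialPitchUm, pixelSizeMm = pixelSizeMm,
               cutoff = dopuCut)
}

#' RPE-melanin thickness map
#'
#' Counts, on each A-line, the voxels with high F_RPE (at or above
#' \code{frpeCut}, default 0.15) and converts the count to micrometres.
#' Choroidal melanin is excluded by construction through the flow factor of
#' F_RPE, so the map isolates RPE-associated melanin.
#'
#' @param frpeVol an \linkS4class{FrpeVolume}.
#' @param frpeCut inclusive F_RPE threshold (default 0.15).
#' @param axialPitchUm axial pitch, um per pixel.
#' @param pixelSizeMm en-face pitch c(fast, slow), mm.
#' @param depthMask optional logical array restricting the counted depth range.
#' @return a \linkS4class{ThicknessMap} of kind "rpe_melanin".
#' @export
rpeMelaninMap <- function(frpeVol, frpeCut = 0.15, axialPitchUm,
                          pixelSizeMm, depthMask = NULL) {
  stopifnot(is(frpeVol, "FrpeVolume"))
  cls <- frpeVol@frpe >= frpeCut
  if (!is.null(depthMask)) {
    checkSameDim(cls, depthMask)
    cls <- cls & depthMask
  }
  ThicknessMap(.countMap(cls, axialPitchUm), kind = "rpe_melanin",
               axialPitchUm = axialPitchUm, pixelSizeMm = pixelSizeMm,
               cutoff = frpeCut)
}

#' Render an en-face map to a PNG file
#'
#' Deterministic mapping of map values to a greyscale or color-coded image.
#' Values are scaled linearly from 0 (black / colormap start) to
#' \code{scaleMax} (white / colormap end); the scale and units are recorded
#' in the PNG text metadata so rendered maps stay self-describing.
#'
#' @param map an \linkS4class{EnFaceMap}.
#' @param file output PNG path.
#' @param mode "greyscale" or "color_coded".
#' @param scaleMax full-scale value; default the map maximum (or 1 for an
#'   all-zero map).
#' @return the file path, invisibly.
#' @export
renderMap <- function(map, file, mode = c("greyscale", "color_coded"),
                      scaleMax = NULL) {
  stopifnot(is(map, "EnFaceMap"))
  mode <- match.arg(mode)
  v <- map@values
  if (is.null(scaleMax)) scaleMax <- if (max(v) > 0) max(v) else 1
  scaled <- clip01(v / scaleMax)
  # image rows = slow axis, columns = fast axis
  img <- t(scaled)[rev(seq_len(ncol(scaled))), , drop = FALSE]
  if (mode == "color_coded") {
    ramp <- grDevices::colorRamp(c("black", "blue", "cyan", "green",
                                   "yellow", "red"))
    rgb <- ramp(as.vector(img)) / 255
    img <- array(rgb, c(dim(img), 3L))
  }
  png::writePNG(img, target = file,
                text = c(unit = map@unit, scale_max = format(scaleMax),
                         pixel_mm = paste(map@pixelSizeMm, collapse = "x")))
  invisible(file)
}
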