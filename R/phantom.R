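# Synthetic multi-contrast OCT phantom: a dome-shaped serous PED with a
# depolarizing RPE band, planted melanin lesions, a depolarizing vascular
# choroid, and exact ground truth for every downstream quantity.
#
# Contrast model (by construction, not full Jones-matrix physics):
#   * melanin voxels (RPE band, planted lesions, choroid) carry a per-voxel
#     random polarization state drawn uniformly on the Poincare sphere, so
#     kernel-averaged DOPU is low;
#   * all other tissue shares one fixed state plus Gaussian noise (DOPU ~ 1);
#   * the choroid carries a high normalized flow signal, everything else a
#     low one;
#   * intensity follows a piecewise-exponential single-scattering model
#     I(z) = mu(z) * exp(-2 * integral of mu above z), with high attenuation
#     inside melanin.

#' Phantom configuration
#'
#' Defaults reproduce the instrument geometry: 512 A-lines x 256 B-scans
#' over 6.0 x 6.0 mm. The axial pitch is a free parameter of the phantom
#' (the instrument's depth *resolution* in tissue is 6 um; its sampling
#' pitch is not part of the geometry above), default 3.5 um per pixel so
#' that the 70 um thickness cutoff corresponds to 20 axial pixels.
#'
#' @slot nAlines,nBscans,nDepth grid size (fast, slow, axial).
#' @slot scanExtentMm en-face extent c(fast, slow), mm.
#' @slot axialPitchUm axial pitch, um per pixel.
#' @slot pedCenterMm dome centre (fast, slow), mm; default scan centre.
#' @slot pedRadiusMm dome footprint radius, mm.
#' @slot pedMaxHeightMm dome apex height, mm.
#' @slot domeProfile "spherical_cap" (analytic volume) or "gaussian".
#' @slot domeSigmaMm Gaussian dome width sigma; default pedRadiusMm / 3.
#' @slot rpeBandThicknessUm baseline RPE melanin band thickness, um.
#' @slot lesions list of planted lesions; each a list with fields
#'   \code{region} ("peak", "slope", "intraretinal" or "custom"),
#'   \code{radiusMm}, \code{addedUm}, and optionally \code{centerMm} or
#'   \code{angleDeg} (direction from the dome centre for slope/intraretinal
#'   placement).
#' @slot noiseSd relative Gaussian noise level on Stokes components and
#'   intensity.
#' @slot seed RNG seed; the phantom is bit-identical for a fixed seed.
#' @slot tissue list of tissue parameters (layer positions in pixels,
#'   attenuation coefficients in mm^-1, flow levels); see
#'   \code{\link{phantomConfig}}.
#' @export
setClass("PhantomConfig",
  representation(nAlines = "integer", nBscans = "integer", nDepth = "integer",
                 scanExtentMm = "numeric", axialPitchUm = "numeric",
                 pedCenterMm = "numeric", pedRadiusMm = "numeric",
                 pedMaxHeightMm = "numeric", domeProfile = "character",
                 domeSigmaMm = "numeric", rpeBandThicknessUm = "numeric",
                 lesions = "list", noiseSd = "numeric", seed = "integer",
                 tissue = "list"),
  validity = function(object) {
    if (any(c(object@nAlines, object@nBscans, object@nDepth) < 8L))
      return("grid dimensions must be >= 8")
    if (any(object@scanExtentMm <= 0) || object@axialPitchUm <= 0)
      return("scan extent and axial pitch must be strictly positive")
    if (object@pedRadiusMm <= 0 || object@pedMaxHeightMm < 0)
      return("PED radius must be positive and height non-negative")
    if (object@pedMaxHeightMm > object@nDepth * object@axialPitchUm / 1000)
      return("dome taller than the axial extent of the volume")
    if (!object@domeProfile %in% c("gaussian", "spherical_cap"))
      return("domeProfile must be 'gaussian' or 'spherical_cap'")
    if (object@rpeBandThicknessUm < 0) return("band thickness must be >= 0")
    if (object@noiseSd < 0) return("noiseSd must be >= 0")
    TRUE
  })

#' Ground truth of a phantom
#'
#' Exact per-pixel and scalar truth for all downstream quantities: surfaces,
#' margin, quantized height map, PED area (pixel-count) and closed-form dome
#' volume, the RPE-melanin thickness map, the RPE_70 mask, the peak/slope
#' partition, and (when volumes were generated) the voxel-level melanin
#' class masks.
#'
#' @slot bruch,rpeOuter depth-index surfaces (1-based).
#' @slot margin logical PED mask.
#' @slot heightMapMm quantized height map, mm.
#' @slot pedAreaMm2 margin pixel count x pixel area.
#' @slot pedVolumeMm3 closed-form dome volume (cap: pi*h*(3a^2+h^2)/6;
#'   truncated Gaussian: 2*pi*sigma^2*H*(1-exp(-a^2/(2 sigma^2)))).
#' @slot melaninThicknessUm per-A-line RPE-melanin thickness truth, um.
#' @slot rpe70Mask melaninThicknessUm >= 70, logical.
#' @slot partition true peak/slope \linkS4class{RegionPartition}.
#' @slot choroidThicknessUm choroidal melanin band thickness, um.
#' @slot rpeMelaninVoxels,choroidMelaninVoxels logical voxel masks
#'   (NULL when only surfaces were generated).
#' @export
setClass("PhantomTruth",
  representation(bruch = "matrix", rpeOuter = "matrix", margin = "matrix",
                 heightMapMm = "matrix", pedAreaMm2 = "numeric",
                 pedVolumeMm3 = "numeric", melaninThicknessUm = "matrix",
                 rpe70Mask = "matrix", partition = "RegionPartition",
                 choroidThicknessUm = "numeric",
                 rpeMelaninVoxels = "ANY", choroidMelaninVoxels = "ANY"))

#' Build a phantom configuration
#'
#' See \linkS4class{PhantomConfig} for the meaning of each argument. The
#' \code{tissue} list may override any of: \code{retinaTopPx} (first retinal
#' depth row), \code{choroidThicknessPx}, \code{subBruchGapPx} (rows kept
#' free below the choroid), \code{intraretinalGapPx} (retina rows between an
#' intraretinal lesion and the RPE band), attenuation coefficients
#' \code{muBackgroundMmInv}, \code{muFluidMmInv}, \code{muRetinaMmInv},
#' \code{muMelaninMmInv}, \code{muChoroidMmInv}, and flow levels
#' \code{flowChoroid}, \code{flowBackground}, \code{flowNoiseSd}.
#'
#' @param nAlines,nBscans,nDepth grid size; defaults 512, 256, 400.
#' @param scanExtentMm en-face extent, default c(6, 6) mm.
#' @param axialPitchUm axial pitch, default 3.5 um.
#' @param pedCenterMm dome centre; default scan centre.
#' @param pedRadiusMm footprint radius, default 1.5 mm.
#' @param pedMaxHeightMm apex height, default 0.288 mm (a typical serous PED).
#' @param domeProfile "spherical_cap" (default) or "gaussian".
#' @param domeSigmaMm Gaussian sigma; default pedRadiusMm / 3.
#' @param rpeBandThicknessUm baseline band thickness, default 35 um.
#' @param lesions list of lesion specifications (see
#'   \linkS4class{PhantomConfig}); default none.
#' @param noiseSd relative noise level, default 0.1.
#' @param seed RNG seed, default 1.
#' @param tissue named list of tissue-parameter overrides.
#' @return a validated \linkS4class{PhantomConfig}.
#' @export
phantomConfig <- function(nAlines = 512L, nBscans = 256L, nDepth = 400L,
                          scanExtentMm = c(6, 6), axialPitchUm = 3.5,
                          pedCenterMm = scanExtentMm / 2,
                          pedRadiusMm = 1.5, pedMaxHeightMm = 0.288,
                          domeProfile = c("spherical_cap", "gaussian"),
                          domeSigmaMm = pedRadiusMm / 3,
                          rpeBandThicknessUm = 35,
                          lesions = list(), noiseSd = 0.1, seed = 1L,
                          tissue = list()) {
  domeProfile <- match.arg(domeProfile)
  tis <- list(retinaTopPx = 40L, choroidThicknessPx = 60L, subBruchGapPx = 20L,
              intraretinalGapPx = 15L,
              muBackgroundMmInv = 0.05, muFluidMmInv = 0.2,
              muRetinaMmInv = 1.0, muMelaninMmInv = 8.0, muChoroidMmInv = 6.0,
              flowChoroid = 0.9, flowBackground = 0.05, flowNoiseSd = 0.05)
  unknown <- setdiff(names(tissue), names(tis))
  if (length(unknown))
    stopf("unknown tissue parameter(s): %s", paste(unknown, collapse = ", "))
  tis[names(tissue)] <- tissue
  new("PhantomConfig", nAlines = as.integer(nAlines),
      nBscans = as.integer(nBscans), nDepth = as.integer(nDepth),
      scanExtentMm = scanExtentMm, axialPitchUm = axialPitchUm,
      pedCenterMm = pedCenterMm, pedRadiusMm = pedRadiusMm,
      pedMaxHeightMm = pedMaxHeightMm, domeProfile = domeProfile,
      domeSigmaMm = domeSigmaMm, rpeBandThicknessUm = rpeBandThicknessUm,
      lesions = lesions, noiseSd = noiseSd, seed = as.integer(seed),
      tissue = tis)
}

# Analytic dome height (mm) at radial distance r (mm) from the centre.
.domeHeight <- function(config, r) {
  a <- config@pedRadiusMm
  H <- config@pedMaxHeightMm
  h <- numeric(length(r))
  inside <- r <= a
  if (config@domeProfile == "spherical_cap") {
    if (H > 0) {
      R <- (a^2 + H^2) / (2 * H)        # sphere radius of the cap
      h[inside] <- sqrt(pmax(R^2 - r[inside]^2, 0)) - (R - H)
    }
  } else {
    s <- config@domeSigmaMm
    h[inside] <- H * exp(-r[inside]^2 / (2 * s^2))
  }
  pmax(h, 0)
}

# Radius of the analytic peak region (height >= fraction * H).
.peakRadius <- function(config, fraction = 0.7) {
  a <- config@pedRadiusMm; H <- config@pedMaxHeightMm
  if (H <= 0) return(0)
  if (config@domeProfile == "spherical_cap") {
    R <- (a^2 + H^2) / (2 * H)
    hf <- fraction * H
    sqrt(max(2 * R * (H - hf) - (H - hf)^2, 0))
  } else {
    min(config@domeSigmaMm * sqrt(-2 * log(fraction)), a)
  }
}

# Resolve lesion placements to explicit en-face centres; validate geometry.
.resolveLesions <- function(config) {
  if (!length(config@lesions)) return(list())
  cx <- config@pedCenterMm[1]; cy <- config@pedCenterMm[2]
  a <- config@pedRadiusMm
  rPeak <- .peakRadius(config)
  lapply(seq_along(config@lesions), function(k) {
    L <- config@lesions[[k]]
    if (is.null(L$region)) L$region <- "custom"
    if (is.null(L$radiusMm) || is.null(L$addedUm))
      stopf("lesion %d: radiusMm and addedUm are required", k)
    ang <- if (is.null(L$angleDeg)) 0 else L$angleDeg * pi / 180
    if (is.null(L$centerMm)) {
      L$centerMm <- switch(L$region,
        peak = c(cx, cy),
        slope = ,
        intraretinal = {
          rMid <- (rPeak + a) / 2
          c(cx + rMid * cos(ang), cy + rMid * sin(ang))
        },
        custom = stopf("lesion %d: custom placement requires centerMm", k))
    }
    dx <- L$centerMm[1]; dy <- L$centerMm[2]
    if (dx - L$radiusMm < 0 || dx + L$radiusMm > config@scanExtentMm[1] ||
        dy - L$radiusMm < 0 || dy + L$radiusMm > config@scanExtentMm[2])
      stopf("lesion %d ('%s') extends outside the %g x %g mm scan extent",
            k, L$region, config@scanExtentMm[1], config@scanExtentMm[2])
    if (sqrt((dx - cx)^2 + (dy - cy)^2) + L$radiusMm > a + 1e-12)
      stopf("lesion %d ('%s') footprint lies outside the PED margin (radius %g mm)",
            k, L$region, a)
    L
  })
}

# En-face geometry shared by the surface-only and full-volume paths.
.phantomGeometry <- function(config) {
  nx <- config@nAlines; ny <- config@nBscans
  dx <- config@scanExtentMm[1] / nx; dy <- config@scanExtentMm[2] / ny
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dy
  X <- matrix(xs, nx, ny)
  Y <- matrix(ys, nx, ny, byrow = TRUE)
  r <- sqrt((X - config@pedCenterMm[1])^2 + (Y - config@pedCenterMm[2])^2)
  margin <- r <= config@pedRadiusMm
  pitch <- config@axialPitchUm
  tis <- config@tissue
  bruchPx <- config@nDepth - tis$choroidThicknessPx - tis$subBruchGapPx
  if (bruchPx < 1L) stopf("nDepth too small for the choroid configuration")
  hPx <- matrix(round(.domeHeight(config, as.vector(r)) * 1000 / pitch), nx, ny)
  rpeOuter <- bruchPx - hPx
  bandPx <- round(config@rpeBandThicknessUm / pitch)
  lesions <- .resolveLesions(config)
  addedSurfacePx <- matrix(0L, nx, ny)    # extra band thickness (peak/slope lesions)
  intrPxMap <- matrix(0L, nx, ny)         # intraretinal melanin thickness
  footprints <- lapply(lesions, function(L) {
    fp <- (X - L$centerMm[1])^2 + (Y - L$centerMm[2])^2 <= L$radiusMm^2
    px <- as.integer(round(L$addedUm / pitch))
    if (L$region == "intraretinal") intrPxMap[fp] <<- intrPxMap[fp] + px
    else addedSurfacePx[fp] <<- addedSurfacePx[fp] + px
    list(footprint = fp, px = px, region = L$region)
  })
  bandTop <- rpeOuter - bandPx - addedSurfacePx + 1L
  intrBottom <- bandTop - tis$intraretinalGapPx - 1L
  minTop <- min(bandTop - ifelse(intrPxMap > 0, tis$intraretinalGapPx + intrPxMap, 0L))
  if (minTop <= tis$retinaTopPx)
    stopf("dome plus melanin band/lesions do not fit above the retina: reduce pedMaxHeightMm or increase nDepth")
  melaninPxMap <- bandPx + addedSurfacePx + intrPxMap
  list(nx = nx, ny = ny, nz = config@nDepth, dx = dx, dy = dy, pitch = pitch,
       margin = margin, r = r, bruchPx = bruchPx, hPx = hPx,
       rpeOuter = rpeOuter, bandPx = bandPx, bandTop = bandTop,
       intrBottom = intrBottom, intrPxMap = intrPxMap,
       melaninPxMap = melaninPxMap, lesions = lesions,
       footprints = footprints, tis = tis)
}

.closedFormVolume <- function(config) {
  a <- config@pedRadiusMm; H <- config@pedMaxHeightMm
  if (H <= 0) return(0)
  if (config@domeProfile == "spherical_cap") pi * H * (3 * a^2 + H^2) / 6
  else {
    s <- config@domeSigmaMm
    2 * pi * s^2 * H * (1 - exp(-a^2 / (2 * s^2)))
  }
}

.truthFromGeometry <- function(config, g, rpeMelVox = NULL, choMelVox = NULL) {
  hMm <- (g$bruchPx - g$rpeOuter) * g$pitch / 1000
  hMm[!g$margin] <- 0
  thickUm <- g$melaninPxMap * g$pitch
  part <- partitionRegions(hMm, g$margin, fraction = 0.7,
                           pixelAreaMm2 = g$dx * g$dy)
  new("PhantomTruth",
      bruch = matrix(as.numeric(g$bruchPx), g$nx, g$ny),
      rpeOuter = g$rpeOuter + 0, margin = g$margin, heightMapMm = hMm,
      pedAreaMm2 = sum(g$margin) * g$dx * g$dy,
      pedVolumeMm3 = .closedFormVolume(config),
      melaninThicknessUm = thickUm, rpe70Mask = thickUm >= 70,
      partition = part,
      choroidThicknessUm = g$tis$choroidThicknessPx * g$pitch,
      rpeMelaninVoxels = rpeMelVox, choroidMelaninVoxels = choMelVox)
}

#' Segmentation and ground truth without volume synthesis
#'
#' Computes the phantom's segmentation surfaces and full en-face ground truth
#' from the analytic geometry alone (no voxel volumes). This is the fast path
#' for morphometry studies at the full 512 x 256 grid.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return list with elements \code{segmentation}
#'   (\linkS4class{SegmentationSet}) and \code{truth}
#'   (\linkS4class{PhantomTruth}, voxel masks NULL).
#' @export
phantomTruth <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  methods::validObject(config)
  g <- .phantomGeometry(config)
  truth <- .truthFromGeometry(config, g)
  seg <- SegmentationSet(bruch = truth@bruch, rpeOuter = truth@rpeOuter,
                         margin = truth@margin)
  list(segmentation = seg, truth = truth)
}

#' Generate a multi-contrast OCT phantom
#'
#' Synthesizes the three co-registered contrasts (intensity, Stokes state,
#' flow) for the configured dome-shaped serous PED with planted melanin
#' lesions, together with the segmentation surfaces and exact ground truth.
#' Deterministic and bit-identical for a fixed \code{config@seed}.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @return list with elements \code{volume} (\linkS4class{MCOCTVolume}),
#'   \code{segmentation} (\linkS4class{SegmentationSet}) and \code{truth}
#'   (\linkS4class{PhantomTruth} including voxel-level melanin masks).
#' @export
generatePhantom <- function(config) {
  stopifnot(is(config, "PhantomConfig"))
  methods::validObject(config)
  g <- .phantomGeometry(config)
  tis <- g$tis
  nz <- g$nz; nx <- g$nx; ny <- g$ny
  d <- c(nz, nx, ny)

  zArr <- array(rep.int(seq_len(nz), nx * ny), d)
  expand <- function(m) array(rep(as.numeric(m), each = nz), d)
  rpeOuterArr <- expand(g$rpeOuter)
  bandTopArr <- expand(g$bandTop)

  bandMask <- zArr >= bandTopArr & zArr <= rpeOuterArr
  intrMask <- array(FALSE, d)
  for (fp in g$footprints) {
    if (fp$region != "intraretinal" || fp$px == 0L) next
    fpArr <- expand(fp$footprint) > 0
    bot <- expand(g$intrBottom)
    intrMask <- intrMask | (fpArr & zArr <= bot & zArr > bot - fp$px)
  }
  rpeMelanin <- bandMask | intrMask
  rm(bandMask, intrMask)
  choroid <- zArr > g$bruchPx & zArr <= g$bruchPx + tis$choroidThicknessPx
  fluid <- zArr > rpeOuterArr & zArr <= g$bruchPx
  retina <- zArr >= tis$retinaTopPx & zArr < bandTopArr & !fluid & !rpeMelanin
  belowChoroid <- zArr > g$bruchPx + tis$choroidThicknessPx
  rm(zArr, rpeOuterArr, bandTopArr)

  muArr <- array(tis$muBackgroundMmInv, d)
  muArr[retina] <- tis$muRetinaMmInv
  muArr[fluid] <- tis$muFluidMmInv
  muArr[choroid] <- tis$muChoroidMmInv
  muArr[rpeMelanin] <- tis$muMelaninMmInv
  muArr[belowChoroid] <- 0
  rm(fluid, retina, belowChoroid)

  deltaMm <- g$pitch / 1000
  dim(muArr) <- c(nz, nx * ny)
  cumAbove <- apply(muArr, 2, cumsum) - muArr    # optical depth above each voxel
  intensity <- array(muArr * exp(-2 * deltaMm * cumAbove), d)
  rm(muArr, cumAbove)

  out <- withSeed(config@seed, {
    noisy <- intensity * pmax(1 + stats::rnorm(length(intensity), 0, config@noiseSd), 0.05)
    noisy[intensity == 0] <- 0
    # polarization state: fixed (0,0,1) outside melanin, uniform on the
    # sphere inside melanin; one component at a time to bound peak memory
    mel <- rpeMelanin | choroid
    nMel <- sum(mel)
    v <- if (nMel > 0) {
      w <- matrix(stats::rnorm(3 * nMel), ncol = 3)
      w / sqrt(rowSums(w^2))
    } else matrix(numeric(0), 0, 3)
    ns <- config@noiseSd
    mkComp <- function(j, baseline) {
      u <- array(baseline, d)
      if (nMel > 0) u[mel] <- v[, j]
      u <- noisy * (u + stats::rnorm(length(noisy), 0, ns))
      u
    }
    s1 <- mkComp(1, 0)
    s2 <- mkComp(2, 0)
    s3 <- mkComp(3, 1)
    flow <- array(tis$flowBackground, d)
    flow[choroid] <- tis$flowChoroid
    flow <- clip01(flow + stats::rnorm(length(flow), 0, tis$flowNoiseSd))
    list(intensity = noisy, s1 = s1, s2 = s2, s3 = s3, flow = flow)
  })

  pixelSizeMm <- c(g$dx, g$dy)
  vol <- MCOCTVolume(intensity = out$intensity,
                     stokes = StokesVolume(out$intensity, out$s1, out$s2, out$s3),
                     flow = out$flow, axialPitchUm = g$pitch,
                     pixelSizeMm = pixelSizeMm,
                     metadata = list(seed = config@seed,
                                     configHash = contentHash(config),
                                     generator = "melanoct phantom"))
  truth <- .truthFromGeometry(config, g, rpeMelVox = rpeMelanin,
                              choMelVox = choroid)
  seg <- SegmentationSet(bruch = truth@bruch, rpeOuter = truth@rpeOuter,
                         margin = truth@margin)
  list(volume = vol, segmentation = seg, truth = truth)
}
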