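# Formats, configuration and the pipeline runner. Volumes and en-face maps
# travel as TIFF stacks with JSON sidecars (pitches, scale, provenance);
# tables as CSV. Nothing is read back without its sidecar metadata.

#' @include AllClasses.R phantom.R
NULL

#' Pipeline configuration
#'
#' Collects every threshold of the analysis alongside the phantom
#' configuration: DOPU cut (strict, default 0.8), F_RPE cut (inclusive,
#' default 0.15), RPE_70 thickness cutoff (inclusive, default 70 um), peak
#' height fraction (default 0.7), flow binarization threshold (default 0.5),
#' attenuation normalization reference (default 10 mm^-1), and the DOPU
#' kernel and noise-correction variance.
#'
#' @slot phantom a \linkS4class{PhantomConfig}.
#' @slot dopuCut,frpeCut,rpe70CutUm,peakFraction,flowCut,muRefMmInv scalars.
#' @slot dopuKernel integer pair (axial, lateral).
#' @slot noiseVariance DOPU noise-correction variance.
#' @export
setClass("PipelineConfig",
  representation(phantom = "PhantomConfig", dopuCut = "numeric",
                 frpeCut = "numeric", rpe70CutUm = "numeric",
                 peakFraction = "numeric", flowCut = "numeric",
                 muRefMmInv = "numeric", dopuKernel = "integer",
                 noiseVariance = "numeric"),
  validity = function(object) {
    if (object@dopuCut <= 0 || object@dopuCut > 1)
      return("dopuCut must lie in (0, 1]")
    if (object@frpeCut < 0 || object@frpeCut > 1)
      return("frpeCut must lie in [0, 1]")
    if (object@rpe70CutUm <= 0) return("rpe70CutUm must be positive")
    if (object@peakFraction < 0 || object@peakFraction > 1)
      return("peakFraction must lie in [0, 1]")
    if (object@flowCut <= 0 || object@flowCut >= 1)
      return("flowCut must lie in (0, 1)")
    if (object@muRefMmInv <= 0) return("muRefMmInv must be positive")
    if (length(object@dopuKernel) != 2L || any(object@dopuKernel < 1L) ||
        any(object@dopuKernel %% 2L == 0L))
      return("dopuKernel must be two odd positive integers")
    if (object@noiseVariance < 0) return("noiseVariance must be >= 0")
    TRUE
  })

#' @rdname PipelineConfig-class
#' @param phantom a \linkS4class{PhantomConfig} (default: instrument grid).
#' @param dopuCut,frpeCut,rpe70CutUm,peakFraction,flowCut,muRefMmInv thresholds.
#' @param dopuKernel DOPU kernel (axial, lateral).
#' @param noiseVariance DOPU noise-correction variance.
#' @export
pipelineConfig <- function(phantom = phantomConfig(), dopuCut = 0.8,
                           frpeCut = 0.15, rpe70CutUm = 70,
                           peakFraction = 0.7, flowCut = 0.5,
                           muRefMmInv = 10, dopuKernel = c(3L, 3L),
                           noiseVariance = 0)
  new("PipelineConfig", phantom = phantom, dopuCut = dopuCut,
      frpeCut = frpeCut, rpe70CutUm = rpe70CutUm, peakFraction = peakFraction,
      flowCut = flowCut, muRefMmInv = muRefMmInv,
      dopuKernel = as.integer(dopuKernel), noiseVariance = noiseVariance)

.configAsList <- function(config) {
  ph <- config@phantom
  list(thresholds = list(dopuCut = config@dopuCut, frpeCut = config@frpeCut,
                         rpe70CutUm = config@rpe70CutUm,
                         peakFraction = config@peakFraction,
                         flowCut = config@flowCut,
                         muRefMmInv = config@muRefMmInv,
                         dopuKernel = config@dopuKernel,
                         noiseVariance = config@noiseVariance),
       phantom = list(nAlines = ph@nAlines, nBscans = ph@nBscans,
                      nDepth = ph@nDepth, scanExtentMm = ph@scanExtentMm,
                      axialPitchUm = ph@axialPitchUm,
                      pedCenterMm = ph@pedCenterMm,
                      pedRadiusMm = ph@pedRadiusMm,
                      pedMaxHeightMm = ph@pedMaxHeightMm,
                      domeProfile = ph@domeProfile,
                      domeSigmaMm = ph@domeSigmaMm,
                      rpeBandThicknessUm = ph@rpeBandThicknessUm,
                      lesions = ph@lesions, noiseSd = ph@noiseSd,
                      seed = ph@seed, tissue = ph@tissue))
}

#' Write / read a pipeline configuration as JSON
#'
#' The round trip is lossless for every threshold, grid and lesion field.
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param path JSON file path.
#' @return \code{readPipelineConfig} returns a \linkS4class{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(.configAsList(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  ph <- j$phantom
  lesions <- lapply(ph$lesions, function(L) {
    if (!is.null(L$centerMm)) L$centerMm <- as.numeric(L$centerMm)
    L
  })
  phantom <- phantomConfig(nAlines = ph$nAlines, nBscans = ph$nBscans,
                           nDepth = ph$nDepth,
                           scanExtentMm = as.numeric(ph$scanExtentMm),
                           axialPitchUm = ph$axialPitchUm,
                           pedCenterMm = as.numeric(ph$pedCenterMm),
                           pedRadiusMm = ph$pedRadiusMm,
                           pedMaxHeightMm = ph$pedMaxHeightMm,
                           domeProfile = ph$domeProfile,
                           domeSigmaMm = ph$domeSigmaMm,
                           rpeBandThicknessUm = ph$rpeBandThicknessUm,
                           lesions = lesions, noiseSd = ph$noiseSd,
                           seed = ph$seed, tissue = ph$tissue)
  th <- j$thresholds
  pipelineConfig(phantom = phantom, dopuCut = th$dopuCut, frpeCut = th$frpeCut,
                 rpe70CutUm = th$rpe70CutUm, peakFraction = th$peakFraction,
                 flowCut = th$flowCut, muRefMmInv = th$muRefMmInv,
                 dopuKernel = as.integer(th$dopuKernel),
                 noiseVariance = th$noiseVariance)
}

.sidecarPath <- function(path) paste0(path, ".json")

.writeSidecar <- function(path, meta) {
  jsonlite::write_json(meta, .sidecarPath(path), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
}

.readSidecar <- function(path, required = character(0)) {
  sp <- .sidecarPath(path)
  if (!file.exists(sp))
    stopf("missing sidecar metadata '%s'; refusing to guess pitches", sp)
  meta <- jsonlite::read_json(sp, simplifyVector = TRUE)
  miss <- setdiff(required, names(meta))
  if (length(miss))
    stopf("sidecar '%s' lacks required field(s): %s", sp,
          paste(miss, collapse = ", "))
  meta
}

#' Write / read a 3-D volume as a multi-page TIFF with JSON sidecar
#'
#' Pages are B-scans (depth x fast). Data are stored as 32-bit float scaled
#' to [0, 1]; the scale, voxel pitches and provenance live in the sidecar.
#' Round trip is exact for binary masks and within 1e-6 relative for floats.
#'
#' @param x numeric 3-D array (depth x fast x slow).
#' @param path output .tif path (sidecar written at path.json).
#' @param axialPitchUm,pixelSizeMm voxel pitches.
#' @param meta extra provenance fields for the sidecar.
#' @return the path, invisibly; \code{readVolumeTiff} returns
#'   list(data, meta).
#' @export
writeVolumeTiff <- function(x, path, axialPitchUm, pixelSizeMm, meta = list()) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  offset <- min(x)
  scale <- max(x) - offset
  if (scale == 0) scale <- 1
  pages <- lapply(seq_len(dim(x)[3]), function(j) (x[, , j] - offset) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "LZW")
  .writeSidecar(path, c(list(kind = "volume", dim = dim(x), scale = scale,
                             offset = offset,
                             order = "depth,fast,slow",
                             axialPitchUm = axialPitchUm,
                             pixelSizeMm = pixelSizeMm,
                             version = as.character(utils::packageVersion("melanoct"))),
                        meta))
  invisible(path)
}

#' @rdname writeVolumeTiff
#' @export
readVolumeTiff <- function(path) {
  meta <- .readSidecar(path, required = c("dim", "scale", "axialPitchUm",
                                          "pixelSizeMm"))
  pages <- tiff::readTIFF(path, all = TRUE)
  off <- if (is.null(meta$offset)) 0 else meta$offset
  x <- array(0, as.integer(meta$dim))
  for (j in seq_along(pages)) x[, , j] <- pages[[j]] * meta$scale + off
  list(data = x, meta = meta)
}

#' Write / read an en-face map or mask as TIFF with JSON sidecar
#'
#' Float maps are stored as scaled 32-bit float; masks (`mask = TRUE`) as
#' 8-bit 0/1 with exact round trip.
#'
#' @param x numeric matrix (or logical for masks).
#' @param path output .tif path.
#' @param pixelSizeMm en-face pitch.
#' @param mask write as 8-bit binary mask.
#' @param meta extra sidecar fields (e.g. unit, axialPitchUm).
#' @return the path, invisibly; \code{readMapTiff} returns list(data, meta).
#' @export
writeMapTiff <- function(x, path, pixelSizeMm, mask = FALSE, meta = list()) {
  m <- if (is.logical(x)) x + 0 else x
  stopifnot(is.matrix(m))
  if (mask) {
    tiff::writeTIFF(m, path, bits.per.sample = 8L, compression = "LZW")
    scale <- 1; offset <- 0
  } else {
    offset <- min(m)
    scale <- max(m) - offset
    if (scale == 0) scale <- 1
    tiff::writeTIFF((m - offset) / scale, path, bits.per.sample = 32L,
                    compression = "LZW")
  }
  .writeSidecar(path, c(list(kind = if (mask) "mask" else "map",
                             dim = dim(m), scale = scale, offset = offset,
                             pixelSizeMm = pixelSizeMm,
                             version = as.character(utils::packageVersion("melanoct"))),
                        meta))
  invisible(path)
}

#' @rdname writeMapTiff
#' @export
readMapTiff <- function(path) {
  meta <- .readSidecar(path, required = c("kind", "scale", "pixelSizeMm"))
  off <- if (is.null(meta$offset)) 0 else meta$offset
  m <- tiff::readTIFF(path) * meta$scale + off
  if (meta$kind == "mask") m <- m > 0.5
  list(data = m, meta = meta)
}

#' Write / read a cohort table as CSV
#'
#' \code{readCohortCsv} validates that every analyzed column is present and
#' numeric, naming the offending row on malformed input.
#'
#' @param cohort data.frame (one row per eye).
#' @param path CSV path.
#' @return \code{readCohortCsv} returns the validated data.frame.
#' @export
writeCohortCsv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCohortCsv
#' @export
readCohortCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("maxHeightMm", "pedAreaMm2", "pedVolumeMm3", "slopeAreaRatio")
  miss <- setdiff(needed, names(df))
  if (length(miss))
    stopf("cohort CSV '%s' lacks column(s): %s", path,
          paste(miss, collapse = ", "))
  for (v in intersect(names(df), c(needed, grep("^rpe70", names(df), value = TRUE)))) {
    x <- suppressWarnings(as.numeric(df[[v]]))
    bad <- which(is.na(x) & !is.na(df[[v]]) | is.na(df[[v]]))
    if (length(bad))
      stopf("cohort CSV '%s': non-numeric or missing value in column '%s' at row %d",
            path, v, bad[1])
    df[[v]] <- x
  }
  df
}

#' Write the cohort analysis reports as CSV files
#'
#' Emits the descriptive-summary, simple-regression and stepwise tables of a
#' \code{\link{analyzeCohort}} result into a directory.
#'
#' @param analysis result of \code{\link{analyzeCohort}}.
#' @param dir output directory (created if needed).
#' @return character vector of file paths, invisibly.
#' @export
writeCohortReports <- function(analysis, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  p <- file.path(dir, "summary.csv")
  utils::write.csv(analysis$summary, p, row.names = FALSE); paths <- c(paths, p)
  p <- file.path(dir, "simple_regressions.csv")
  utils::write.csv(analysis$simple, p, row.names = FALSE); paths <- c(paths, p)
  step <- do.call(rbind, lapply(names(analysis$stepwise), function(resp) {
    rep <- analysis$stepwise[[resp]]
    full <- rep@fullCoefficients
    full$response <- resp
    full$selected <- full$term %in% rep@selected
    full
  }))
  p <- file.path(dir, "stepwise_full_models.csv")
  utils::write.csv(step, p, row.names = FALSE); paths <- c(paths, p)
  wil <- analysis$wilcoxonSlopeVsPeak
  p <- file.path(dir, "wilcoxon_slope_vs_peak.csv")
  utils::write.csv(data.frame(statistic = wil$statistic, p = wil$p,
                              n = wil$n, exact = wil$exact), p,
                   row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
}

#' Run the full single-eye pipeline
#'
#' Executes simulate -> DOPU -> attenuation -> flow binarization -> F_RPE ->
#' thickness maps -> morphometry -> RPE_70 on one phantom configuration.
#' With \code{outDir} set, all intermediates (volumes, maps, masks, results
#' CSV, rendered PNGs, the configuration and provenance JSON) are written;
#' reruns with the same configuration are byte-identical (provenance records
#' the configuration hash, seed and package version, never a timestamp).
#'
#' @param config a \linkS4class{PipelineConfig}.
#' @param outDir optional output directory.
#' @return a list bundle: phantom, dopu, attenuation, flowMask, frpe,
#'   chorioretinalMap, rpeMelaninMap, morphometry, rpe70, config.
#' @export
runPipeline <- function(config, outDir = NULL) {
  stopifnot(is(config, "PipelineConfig"))
  methods::validObject(config)
  ph <- .stage("simulate", generatePhantom(config@phantom))
  vol <- ph$volume
  pitch <- axialPitch(vol)
  psz <- pixelSize(vol)
  dop <- .stage("dopu", computeDopu(stokesVolume(vol),
                                    kernel = config@dopuKernel,
                                    noiseVariance = config@noiseVariance))
  att <- .stage("attenuation",
                computeAttenuation(intensityVolume(vol), pitch,
                                   muRefMmInv = config@muRefMmInv))
  fm <- .stage("flow", binarizeOcta(flowVolume(vol), config@flowCut))
  fr <- .stage("frpe", computeFrpe(att, dop, fm))
  cmap <- .stage("maps", chorioretinalMelaninMap(dop, config@dopuCut, pitch, psz))
  rmap <- .stage("maps", rpeMelaninMap(fr, config@frpeCut, pitch, psz))
  morph <- .stage("morphometry",
                  pedMorphometry(ph$segmentation, pitch, psz,
                                 peakFraction = config@peakFraction))
  r70 <- .stage("rpe70", {
    mask <- rpe70Mask(rmap, config@rpe70CutUm, marginMask(ph$segmentation))
    rpe70RegionStats(mask, morph@partition, config@rpe70CutUm)
  })
  bundle <- list(phantom = ph, dopu = dop, attenuation = att, flowMask = fm,
                 frpe = fr, chorioretinalMap = cmap, rpeMelaninMap = rmap,
                 morphometry = morph, rpe70 = r70, config = config)
  if (!is.null(outDir)) .stage("write", .writeBundle(bundle, outDir))
  invisible(bundle)
}

.writeBundle <- function(bundle, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  vol <- bundle$phantom$volume
  pitch <- axialPitch(vol)
  psz <- pixelSize(vol)
  prov <- list(seed = bundle$config@phantom@seed,
               configHash = contentHash(.configAsList(bundle$config)),
               version = as.character(utils::packageVersion("melanoct")))
  writePipelineConfig(bundle$config, file.path(outDir, "config.json"))
  jsonlite::write_json(prov, file.path(outDir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeVolumeTiff(intensityVolume(vol), file.path(outDir, "intensity.tif"),
                  pitch, psz, meta = prov)
  writeVolumeTiff(dopu(bundle$dopu), file.path(outDir, "dopu.tif"),
                  pitch, psz, meta = prov)
  writeVolumeTiff(frpe(bundle$frpe), file.path(outDir, "frpe.tif"),
                  pitch, psz, meta = prov)
  writeVolumeTiff(flowVolume(vol), file.path(outDir, "flow.tif"),
                  pitch, psz, meta = prov)
  writeMapTiff(mapValues(bundle$chorioretinalMap),
               file.path(outDir, "chorioretinal_melanin_um.tif"), psz,
               meta = c(prov, unit = "um"))
  writeMapTiff(mapValues(bundle$rpeMelaninMap),
               file.path(outDir, "rpe_melanin_um.tif"), psz,
               meta = c(prov, unit = "um"))
  writeMapTiff(mapValues(bundle$morphometry@heightMap),
               file.path(outDir, "height_mm.tif"), psz,
               meta = c(prov, unit = "mm"))
  writeMapTiff(marginMask(bundle$phantom$segmentation),
               file.path(outDir, "margin_mask.tif"), psz, mask = TRUE,
               meta = prov)
  writeMapTiff(peakMask(bundle$morphometry@partition),
               file.path(outDir, "peak_mask.tif"), psz, mask = TRUE,
               meta = prov)
  writeMapTiff(bundle$rpe70@mask, file.path(outDir, "rpe70_mask.tif"), psz,
               mask = TRUE, meta = prov)
  renderMap(bundle$rpeMelaninMap, file.path(outDir, "rpe_melanin_grey.png"),
            mode = "greyscale")
  renderMap(bundle$rpeMelaninMap, file.path(outDir, "rpe_melanin_color.png"),
            mode = "color_coded")
  m <- bundle$morphometry; r <- bundle$rpe70
  utils::write.csv(data.frame(
    maxHeightMm = m@maxHeightMm, pedAreaMm2 = m@pedAreaMm2,
    pedVolumeMm3 = m@pedVolumeMm3, slopeAreaRatio = m@slopeAreaRatio,
    rpe70AreaWholeMm2 = r@areaWholeMm2, rpe70AreaPeakMm2 = r@areaPeakMm2,
    rpe70AreaSlopeMm2 = r@areaSlopeMm2, rpe70RatioWhole = r@ratioWhole,
    rpe70RatioPeak = r@ratioPeak, rpe70RatioSlope = r@ratioSlope,
    pattern = r@pattern), file.path(outDir, "results.csv"),
    row.names = FALSE)
  invisible(outDir)
}
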