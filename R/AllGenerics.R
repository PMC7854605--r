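# Generics for the package's S4 accessors. Slots are never reached into
# directly by user code; these accessors are the stable surface.

#' @export
setGeneric("dopu", function(x) standardGeneric("dopu"))

#' @export
setGeneric("dopuKernel", function(x) standardGeneric("dopuKernel"))

#' @export
setGeneric("mu", function(x) standardGeneric("mu"))

#' @export
setGeneric("muNorm", function(x) standardGeneric("muNorm"))

#' @export
setGeneric("frpe", function(x) standardGeneric("frpe"))

#' @export
setGeneric("flowMask", function(x) standardGeneric("flowMask"))

#' @export
setGeneric("mapValues", function(x) standardGeneric("mapValues"))

#' @export
setGeneric("mapKind", function(x) standardGeneric("mapKind"))

#' @export
setGeneric("axialPitch", function(x) standardGeneric("axialPitch"))

#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @export
setGeneric("pixelArea", function(x) standardGeneric("pixelArea"))

#' @export
setGeneric("intensityVolume", function(x) standardGeneric("intensityVolume"))

#' @export
setGeneric("stokesVolume", function(x) standardGeneric("stokesVolume"))

#' @export
setGeneric("flowVolume", function(x) standardGeneric("flowVolume"))

#' @export
setGeneric("bruchSurface", function(x) standardGeneric("bruchSurface"))

#' @export
setGeneric("rpeOuterSurface", function(x) standardGeneric("rpeOuterSurface"))

#' @export
setGeneric("marginMask", function(x) standardGeneric("marginMask"))

#' @export
setGeneric("peakMask", function(x) standardGeneric("peakMask"))

#' @export
setGeneric("slopeMask", function(x) standardGeneric("slopeMask"))

#' @export
setGeneric("wholeMask", function(x) standardGeneric("wholeMask"))

#' @export
setGeneric("undefinedMask", function(x) standardGeneric("undefinedMask"))
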