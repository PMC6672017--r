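## Generics. Accessors are defined next to their classes' methods.

#' @export
setGeneric("nyquistFrequency", function(object, ...)
  standardGeneric("nyquistFrequency"))

#' @export
setGeneric("apertureCutoff", function(object, ...)
  standardGeneric("apertureCutoff"))

#' @export
setGeneric("sensorExtent", function(object, ...)
  standardGeneric("sensorExtent"))

#' @export
setGeneric("grainScale", function(object, ...)
  standardGeneric("grainScale"))

#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @export
setGeneric("images", function(object) standardGeneric("images"))

#' @export
setGeneric("pixelScale", function(object) standardGeneric("pixelScale"))

#' @export
setGeneric("nRealizations", function(object) standardGeneric("nRealizations"))

#' @export
setGeneric("exposureTimes", function(object) standardGeneric("exposureTimes"))

#' @export
setGeneric("muA", function(object) standardGeneric("muA"))

#' @export
setGeneric("muSPrime", function(object) standardGeneric("muSPrime"))

#' @export
setGeneric("anisotropy", function(object) standardGeneric("anisotropy"))

#' @export
setGeneric("muS", function(object) standardGeneric("muS"))

#' @export
setGeneric("meanFreePath", function(object) standardGeneric("meanFreePath"))

#' @export
setGeneric("diffuseReflectance", function(object)
  standardGeneric("diffuseReflectance"))

#' @export
setGeneric("estimateACF", function(x, ...) standardGeneric("estimateACF"))

#' @export
setGeneric("estimatePSD", function(x, ...) standardGeneric("estimatePSD"))

#' @export
setGeneric("radialAverage", function(x, ...) standardGeneric("radialAverage"))

#' @export
setGeneric("stationarityReport", function(x, ...)
  standardGeneric("stationarityReport"))

#' @export
setGeneric("applyMedium", function(x, h, ...) standardGeneric("applyMedium"))

#' @export
setGeneric("correctExposure", function(object, ...)
  standardGeneric("correctExposure"))

#' @export
setGeneric("responseParameters", function(object)
  standardGeneric("responseParameters"))

#' @export
setGeneric("phantomTable", function(object) standardGeneric("phantomTable"))
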