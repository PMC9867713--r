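#' @rdname ImageStack-class
#' @param x an object.
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname ImageStack-class
#' @param name channel name.
#' @export
setGeneric("getChannel", function(x, name) standardGeneric("getChannel"))

#' @rdname ImageStack-class
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))

#' @rdname ImageStack-class
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))

#' @rdname NucleusTable-class
#' @param x an object.
#' @export
setGeneric("nNuclei", function(x) standardGeneric("nNuclei"))

#' @rdname NucleusTable-class
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname NucleusTable-class
#' @export
setGeneric("nucleusData", function(x) standardGeneric("nucleusData"))

#' @rdname MarkerCalls-class
#' @param x an object.
#' @export
setGeneric("markerName", function(x) standardGeneric("markerName"))

#' @rdname MarkerCalls-class
#' @export
setGeneric("positiveCalls", function(x) standardGeneric("positiveCalls"))

#' @rdname MarkerCalls-class
#' @export
setGeneric("nPositive", function(x) standardGeneric("nPositive"))

#' @rdname MarkerCalls-class
#' @export
setGeneric("nTotal", function(x) standardGeneric("nTotal"))

#' @rdname MarkerCalls-class
#' @export
setGeneric("thresholdUsed", function(x) standardGeneric("thresholdUsed"))

#' @rdname RegionMask-class
#' @param x an object.
#' @export
setGeneric("regionMask", function(x) standardGeneric("regionMask"))

#' Disrupted area fraction in percent
#'
#' Recomputed from the mask pixels on every call, so the value is exactly
#' \code{100 * sum(mask) / length(mask)}.
#'
#' @param x a [RegionMask-class].
#' @return percent of pixels marked disrupted, in [0, 100].
#' @export
setGeneric("areaFraction", function(x) standardGeneric("areaFraction"))

#' @rdname RegionMask-class
#' @export
setGeneric("maskProvenance", function(x) standardGeneric("maskProvenance"))

#' @rdname RingBinning-class
#' @param x an object.
#' @export
setGeneric("ringMasks", function(x) standardGeneric("ringMasks"))

#' @rdname RingBinning-class
#' @export
setGeneric("ringLabels", function(x) standardGeneric("ringLabels"))

#' @rdname RingBinning-class
#' @export
setGeneric("ringIndexMap", function(x) standardGeneric("ringIndexMap"))
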