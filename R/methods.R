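#' Construct an ImageStack
#'
#' @param channels named list of numeric 2D matrices (or 3D \code{[y,x,z]}
#'   arrays) sharing one shape; intensities on the camera scale.
#' @param pixelSize physical pixel size in micrometres per pixel.
#' @param zStep z spacing in micrometres; required when channels are 3D.
#' @return an [ImageStack-class].
#' @examples
#' img <- matrix(0, 32, 32)
#' stk <- ImageStack(list(DAPI = img, ZO1 = img), pixelSize = 0.5)
#' channelNames(stk)
#' @export
ImageStack <- function(channels, pixelSize, zStep = NA_real_) {
  channels <- lapply(channels, function(x) {
    storage.mode(x) <- "double"
    x
  })
  new("ImageStack", channels = channels, pixelSize = as.numeric(pixelSize),
      zStep = as.numeric(zStep))
}

#' @rdname ImageStack-class
#' @export
setMethod("channelNames", "ImageStack", function(x) names(x@channels))

#' @rdname ImageStack-class
#' @export
setMethod("getChannel", "ImageStack", function(x, name) {
  if (!name %in% names(x@channels))
    stop(sprintf("channel '%s' not present (have: %s)", name,
                 paste(names(x@channels), collapse = ", ")), call. = FALSE)
  x@channels[[name]]
})

#' @rdname ImageStack-class
#' @export
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)

#' @rdname ImageStack-class
#' @export
setMethod("zStep", "ImageStack", function(x) x@zStep)

#' @rdname ImageStack-class
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@channels[[1L]]))

setMethod("show", "ImageStack", function(object) {
  d <- dim(object)
  cat("ImageStack:", paste(d, collapse = " x "),
      if (length(d) == 3L) "(y x x x z)" else "(y x x)", "\n")
  cat(" channels:", paste(names(object@channels), collapse = ", "), "\n")
  cat(sprintf(" pixel size: %g um/px", object@pixelSize))
  if (is.finite(object@zStep)) cat(sprintf(", z step: %g um", object@zStep))
  cat("\n")
})

#' Construct a NucleusTable
#'
#' Usually produced by [segmentNuclei()]; the constructor is exported so
#' that ground-truth tables from the simulator can enter the same
#' downstream path as segmented ones.
#'
#' @param labelMap integer matrix, 0 = background, labels 1..n.
#' @param records data.frame with columns label, row, col, area_um2.
#' @param pixelSize micrometres per pixel.
#' @return a [NucleusTable-class].
#' @export
NucleusTable <- function(labelMap, records, pixelSize) {
  storage.mode(labelMap) <- "integer"
  new("NucleusTable", labelMap = labelMap, records = records,
      pixelSize = as.numeric(pixelSize))
}

#' @rdname NucleusTable-class
#' @export
setMethod("nNuclei", "NucleusTable", function(x) nrow(x@records))

#' @rdname NucleusTable-class
#' @export
setMethod("labelMap", "NucleusTable", function(x) x@labelMap)

#' @rdname NucleusTable-class
#' @export
setMethod("nucleusData", "NucleusTable", function(x) x@records)

setMethod("show", "NucleusTable", function(object) {
  cat("NucleusTable:", nrow(object@records), "nuclei over",
      paste(dim(object@labelMap), collapse = " x "), "px\n")
  if (nrow(object@records)) {
    cat(sprintf(" area (um^2): median %.1f [%.1f, %.1f]\n",
                stats::median(object@records$area_um2),
                min(object@records$area_um2),
                max(object@records$area_um2)))
  }
})

#' Construct MarkerCalls
#'
#' @param marker marker channel name.
#' @param calls logical vector named by nucleus label.
#' @param threshold intensity threshold used.
#' @return a [MarkerCalls-class].
#' @export
MarkerCalls <- function(marker, calls, threshold) {
  new("MarkerCalls", marker = marker, calls = calls,
      threshold = as.numeric(threshold))
}

#' @rdname MarkerCalls-class
#' @export
setMethod("markerName", "MarkerCalls", function(x) x@marker)

#' @rdname MarkerCalls-class
#' @export
setMethod("positiveCalls", "MarkerCalls", function(x) x@calls)

#' @rdname MarkerCalls-class
#' @export
setMethod("nPositive", "MarkerCalls", function(x) sum(x@calls))

#' @rdname MarkerCalls-class
#' @export
setMethod("nTotal", "MarkerCalls", function(x) length(x@calls))

#' @rdname MarkerCalls-class
#' @export
setMethod("thresholdUsed", "MarkerCalls", function(x) x@threshold)

setMethod("show", "MarkerCalls", function(object) {
  cat(sprintf("MarkerCalls '%s': %d / %d positive (threshold %.1f)\n",
              object@marker, sum(object@calls), length(object@calls),
              object@threshold))
})

#' Construct a RegionMask
#'
#' @param mask logical matrix, TRUE = disrupted.
#' @param pixelSize micrometres per pixel.
#' @param provenance "auto", "manual" or "truth".
#' @return a [RegionMask-class].
#' @export
RegionMask <- function(mask, pixelSize, provenance = "manual") {
  mode(mask) <- "logical"
  new("RegionMask", mask = mask, provenance = provenance,
      pixelSize = as.numeric(pixelSize))
}

#' @rdname RegionMask-class
#' @export
setMethod("regionMask", "RegionMask", function(x) x@mask)

#' @rdname areaFraction
#' @export
setMethod("areaFraction", "RegionMask", function(x)
  100 * sum(x@mask) / length(x@mask))

#' @rdname RegionMask-class
#' @export
setMethod("maskProvenance", "RegionMask", function(x) x@provenance)

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask (%s): %.2f%% disrupted over %s px\n",
              object@provenance, 100 * sum(object@mask) / length(object@mask),
              paste(dim(object@mask), collapse = " x ")))
})

#' @rdname RingBinning-class
#' @export
setMethod("ringLabels", "RingBinning", function(x) x@labels)

#' @rdname RingBinning-class
#' @export
setMethod("ringIndexMap", "RingBinning", function(x) x@ringIndex)

#' @rdname RingBinning-class
#' @export
setMethod("ringMasks", "RingBinning", function(x) {
  out <- lapply(seq_along(x@labels), function(k) x@ringIndex == k)
  names(out) <- x@labels
  out
})

setMethod("show", "RingBinning", function(object) {
  n <- tabulate(object@ringIndex, nbins = length(object@labels))
  cat("RingBinning with", length(object@labels), "classes (px counts):\n")
  print(stats::setNames(n, object@labels))
})
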