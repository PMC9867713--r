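#' @import methods
NULL

#' Multichannel fluorescence image stack
#'
#' Container for a single imaged field: a set of named channels (2D
#' matrices, or 3D arrays \code{[y, x, z]} for confocal z-stacks) sharing
#' one pixel grid, together with the physical pixel size.  Every analysis
#' stage in the package consumes an \code{ImageStack}.
#'
#' Intensities are stored as non-negative numerics on the camera scale
#' (16-bit by convention, 0--65535).  Coordinates reported by downstream
#' functions are pixel-centered, 0-based \code{(row, col)}; physical
#' quantities are in micrometres via \code{pixelSize}.
#'
#' @slot channels named list of numeric matrices/arrays, identical dims.
#' @slot pixelSize physical pixel size in micrometres per pixel.
#' @slot zStep z-slice spacing in micrometres (NA for 2D stacks).
#'
#' @seealso [ImageStack()] for the constructor.
#' @export
setClass("ImageStack",
  representation(channels = "list", pixelSize = "numeric", zStep = "numeric"),
  prototype(channels = list(), pixelSize = 1, zStep = NA_real_))

setValidity("ImageStack", function(object) {
  ch <- object@channels
  if (length(ch) == 0L) return("at least one channel is required")
  if (is.null(names(ch)) || any(!nzchar(names(ch))) || anyDuplicated(names(ch)))
    return("channels must have unique non-empty names")
  d0 <- dim(ch[[1L]])
  for (nm in names(ch)) {
    x <- ch[[nm]]
    if (!is.numeric(x) || is.null(dim(x)) || !(length(dim(x)) %in% c(2L, 3L)))
      return(sprintf("channel '%s' must be a 2D matrix or 3D array", nm))
    if (!identical(dim(x), d0))
      return(sprintf("channel '%s' does not match the shape of channel '%s'",
                     nm, names(ch)[1L]))
    if (anyNA(x) || min(x) < 0)
      return(sprintf("channel '%s' has NA or negative intensities", nm))
  }
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    return("pixelSize must be a single positive number (um/px)")
  if (length(object@zStep) != 1L)
    return("zStep must be a single number or NA")
  if (length(d0) == 3L && (!is.finite(object@zStep) || object@zStep <= 0))
    return("3D channels require a positive zStep (um)")
  TRUE
})

#' Segmented nuclei with per-nucleus measurements
#'
#' Result of [segmentNuclei()]: an integer label map (0 = background,
#' nuclei labelled 1..n consecutively) and a per-nucleus record table with
#' pixel-centered 0-based centroids, areas in square micrometres and mean
#' intensities for any requested channels (columns \code{mean_<channel>}).
#'
#' @slot labelMap integer matrix, 0 background, labels 1..n.
#' @slot records data.frame with columns \code{label}, \code{row},
#'   \code{col}, \code{area_um2} and optional \code{mean_*} columns.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("NucleusTable",
  representation(labelMap = "matrix", records = "data.frame",
                 pixelSize = "numeric"))

setValidity("NucleusTable", function(object) {
  lm <- object@labelMap
  rec <- object@records
  n <- if (length(lm)) max(lm) else 0L
  if (!all(c("label", "row", "col", "area_um2") %in% names(rec)))
    return("records need columns label, row, col, area_um2")
  if (nrow(rec) != n) return("records must have one row per label")
  if (n > 0L) {
    if (!identical(sort(unique(as.integer(lm[lm > 0]))), seq_len(n)))
      return("labels must be consecutive positive integers 1..n")
    if (!identical(as.integer(rec$label), seq_len(n)))
      return("records$label must be 1..n in order")
    if (any(rec$area_um2 <= 0)) return("every nucleus area must be > 0")
    if (any(rec$row < 0 | rec$row > nrow(lm) - 1 |
            rec$col < 0 | rec$col > ncol(lm) - 1))
      return("centroids must lie inside the image")
  }
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Nuclear marker positivity calls
#'
#' Result of [callNuclearMarker()]: per-nucleus positive/negative calls
#' for one marker channel, with the automatic threshold that produced
#' them.
#'
#' @slot marker marker channel name.
#' @slot calls logical vector, one element per nucleus label (named).
#' @slot threshold intensity threshold used (camera scale).
#' @export
setClass("MarkerCalls",
  representation(marker = "character", calls = "logical",
                 threshold = "numeric"))

setValidity("MarkerCalls", function(object) {
  if (length(object@marker) != 1L || !nzchar(object@marker))
    return("marker must be a single non-empty name")
  if (length(object@calls) && is.null(names(object@calls)))
    return("calls must be named by nucleus label")
  if (anyNA(object@calls)) return("calls must be TRUE/FALSE, no NA")
  TRUE
})

#' Binary disrupted-epithelium region mask
#'
#' A binary mask over the imaged field marking regions where the
#' tight-junction network is disrupted (TRUE) versus organized epithelium
#' (FALSE), with its provenance: detected automatically, supplied
#' manually, or planted ground truth from the simulator.  The disrupted
#' area fraction is always recomputed from the pixels (see
#' [areaFraction()]), so it is exactly the pixel ratio.
#'
#' @slot mask logical matrix, TRUE = disrupted.
#' @slot provenance one of "auto", "manual", "truth".
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("RegionMask",
  representation(mask = "matrix", provenance = "character",
                 pixelSize = "numeric"))

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask) || anyNA(object@mask))
    return("mask must be a logical matrix without NA")
  if (!(object@provenance %in% c("auto", "manual", "truth")))
    return("provenance must be 'auto', 'manual' or 'truth'")
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})

#' Concentric distance-ring binning around disrupted regions
#'
#' Partition of the image into five disjoint classes by exact Euclidean
#' distance to the disrupted region: inside the region ("0"), then
#' half-open rings [0,30), [30,60), [60,90) and [90, Inf) micrometres
#' away ("+30", "+60", "+90", ">+90" by default edges).  The five masks
#' tile the image exactly.
#'
#' @slot ringIndex integer matrix with values 1..(length(edges)+1); 1 is
#'   the inside-disrupted class.
#' @slot edges increasing ring edges in micrometres, first element 0.
#' @slot labels one label per class.
#' @slot pixelSize micrometres per pixel.
#' @export
setClass("RingBinning",
  representation(ringIndex = "matrix", edges = "numeric",
                 labels = "character", pixelSize = "numeric"))

setValidity("RingBinning", function(object) {
  k <- length(object@edges) + 1L
  if (length(object@labels) != k)
    return("labels must have one entry per ring class")
  if (object@edges[1L] != 0 || is.unsorted(object@edges, strictly = TRUE))
    return("edges must start at 0 and be strictly increasing")
  v <- object@ringIndex
  if (!is.numeric(v) || anyNA(v) || min(v) < 1L || max(v) > k)
    return(sprintf("ringIndex values must be integers in 1..%d", k))
  if (object@pixelSize <= 0) return("pixelSize must be positive")
  TRUE
})
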