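# ImageJ-style mask construction: nuclei segmentation (median filter ->
# Huang threshold -> hole filling -> distance-transform watershed ->
# size filter), nuclear-marker positivity (rolling-ball background
# subtraction -> white top-hat -> Otsu -> fraction-of-pixels rule),
# junction-continuity disrupted-region detection, and per-cell apical
# surface measurement from the junction network.

.get2DChannel <- function(stack, name) {
  x <- getChannel(stack, name)
  if (length(dim(x)) != 2L)
    stop(sprintf("channel '%s' must be 2D for this analysis", name),
         call. = FALSE)
  x
}

#' Segment nuclei from the DAPI channel
#'
#' Median filtering, Huang automatic thresholding, hole filling, a
#' watershed split of touching nuclei seeded from the Euclidean distance
#' transform, and an area filter.  Per-nucleus centroids (0-based,
#' pixel-centered), areas in square micrometres, and mean intensities of
#' any requested channels are tabulated.
#'
#' @param stack an [ImageStack-class] with 2D channels.
#' @param nucleiChannel nuclei channel name (default "DAPI").
#' @param medianRadius median filter radius in pixels.
#' @param watershedTolerance minimum distance-map depth (px) between two
#'   basins for a split; larger values merge more aggressively.
#' @param sizeRangeUm2 keep nuclei with area inside this range (um^2).
#'   Debris below and clumps above are discarded.
#' @param measureChannels channel names whose per-nucleus mean intensity
#'   is recorded as \code{mean_<channel>} columns (default: all).
#' @return a [NucleusTable-class]; a blank image yields zero labels.
#' @export
segmentNuclei <- function(stack, nucleiChannel = "DAPI", medianRadius = 2L,
    watershedTolerance = 1, sizeRangeUm2 = c(25, 400),
    measureChannels = channelNames(stack)) {
  x <- .get2DChannel(stack, nucleiChannel)
  px <- pixelSize(stack)
  nr <- nrow(x); nc <- ncol(x)

  emptyTable <- function() NucleusTable(
    matrix(0L, nr, nc),
    cbind(data.frame(label = integer(), row = numeric(), col = numeric(),
                     area_um2 = numeric()),
          stats::setNames(as.data.frame(
            matrix(numeric(), 0L, length(measureChannels))),
            paste0("mean_", measureChannels))),
    px)

  if (max(x) <= min(x)) return(emptyTable())
  xs <- x
  if (medianRadius >= 1) {
    xs <- EBImage::medianFilter(x / 65535, as.integer(medianRadius)) * 65535
  }
  thr <- huangThreshold(xs)
  bin <- xs > thr
  if (!any(bin)) return(emptyTable())
  bin <- EBImage::fillHull(matrix(as.numeric(bin), nr, nc)) > 0
  dm <- EBImage::distmap(matrix(as.numeric(bin), nr, nc))
  lb <- EBImage::watershed(dm, tolerance = watershedTolerance, ext = 1)
  lb <- matrix(as.integer(lb), nr, nc)
  if (max(lb) == 0L) return(emptyTable())

  st <- labelStats(lb)
  areaUm2 <- st$n_px * px^2
  keep <- st$label[areaUm2 >= sizeRangeUm2[1L] & areaUm2 <= sizeRangeUm2[2L]]
  if (length(keep) == 0L) return(emptyTable())
  lb <- relabelConsecutive(lb, keep)
  st <- labelStats(lb)
  rec <- data.frame(label = st$label, row = st$row, col = st$col,
                    area_um2 = st$n_px * px^2)
  idx <- which(lb > 0L)
  lab <- lb[idx]
  for (ch in measureChannels) {
    v <- getChannel(stack, ch)[idx]
    rec[[paste0("mean_", ch)]] <-
      as.numeric(rowsum(v, lab)[, 1L]) / st$n_px
  }
  NucleusTable(lb, rec, px)
}

#' Morphological (rolling-ball style) background subtraction
#'
#' Estimates the slowly varying background as the grayscale opening of
#' the image with a flat disc structuring element of the given radius
#' and subtracts it, clipping at zero.  This is the flat-kernel
#' counterpart of ImageJ's rolling-ball method: structures wider than
#' the disc survive into the background and are removed, compact bright
#' structures are preserved.
#'
#' @param x numeric matrix of intensities.
#' @param radiusUm disc radius in micrometres.
#' @param pixelSizeUm pixel size (um/px).
#' @return background-subtracted matrix, same shape.
#' @export
subtractBackground <- function(x, radiusUm = 50, pixelSizeUm = 1) {
  r <- max(1L, round(radiusUm / pixelSizeUm))
  bg <- EBImage::opening(x / 65535, discBrush(r)) * 65535
  pmax(x - matrix(as.numeric(bg), nrow(x), ncol(x)), 0)
}

#' Call nuclear-marker-positive cells
#'
#' Reproduces the counting pipeline used for nuclear markers: rolling-
#' ball style background subtraction, white top-hat filtering, Otsu
#' automatic thresholding of the processed marker channel, and a
#' fraction-of-nucleus rule: a nucleus is positive when at least
#' \code{positiveFraction} of its pixels exceed the threshold.
#'
#' @param stack an [ImageStack-class].
#' @param nuclei a [NucleusTable-class] from [segmentNuclei()] (or
#'   [truthNuclei()]).
#' @param markerChannel marker channel name.
#' @param backgroundRadiusUm rolling-ball disc radius (um).
#' @param topHatRadiusUm white top-hat disc radius (um); should exceed
#'   the nucleus radius so nuclear blobs survive.
#' @param positiveFraction fraction of nucleus pixels that must exceed
#'   the threshold (default 0.5).
#' @return a [MarkerCalls-class]; with zero nuclei an empty call table.
#' @export
callNuclearMarker <- function(stack, nuclei, markerChannel,
    backgroundRadiusUm = 50, topHatRadiusUm = 12, positiveFraction = 0.5) {
  x <- .get2DChannel(stack, markerChannel)
  px <- pixelSize(stack)
  if (nNuclei(nuclei) == 0L)
    return(MarkerCalls(markerChannel, stats::setNames(logical(), character()),
                       NA_real_))
  proc <- subtractBackground(x, backgroundRadiusUm, px)
  rTH <- max(1L, round(topHatRadiusUm / px))
  proc <- EBImage::whiteTopHat(proc / 65535, discBrush(rTH)) * 65535
  proc <- matrix(as.numeric(proc), nrow(x), ncol(x))
  if (max(proc) <= 0) {
    calls <- stats::setNames(rep(FALSE, nNuclei(nuclei)),
                             nucleusData(nuclei)$label)
    return(MarkerCalls(markerChannel, calls, NA_real_))
  }
  thr <- otsuThreshold(proc)
  lb <- labelMap(nuclei)
  idx <- which(lb > 0L)
  lab <- lb[idx]
  above <- as.numeric(proc[idx] > thr)
  nTot <- tabulate(lab, nbins = nNuclei(nuclei))
  nAbove <- as.numeric(rowsum(above, lab)[, 1L])
  frac <- numeric(nNuclei(nuclei))
  frac[sort(unique(lab))] <- nAbove / nTot[sort(unique(lab))]
  calls <- stats::setNames(frac >= positiveFraction,
                           nucleusData(nuclei)$label)
  MarkerCalls(markerChannel, calls, thr)
}

#' Detect regions of disrupted junction organization
#'
#' Automated stand-in for the manual annotation of disrupted ZO1 zones:
#' the junction channel is binarized (Otsu), a sliding-window coverage
#' score measures the local density of junction pixels, and windows
#' whose coverage falls below a cutoff relative to the organized
#' epithelium's typical coverage are grouped, morphologically cleaned
#' and size-filtered into the disrupted mask.  A manually drawn mask can
#' be used instead via [loadManualMask()].
#'
#' The cutoff is \code{relCutoff} times a high quantile
#' (\code{refQuantile}) of the coverage score, so it adapts to junction
#' brightness and cell size; if essentially no junction signal is
#' present the whole field is reported disrupted.
#'
#' @param stack an [ImageStack-class].
#' @param junctionChannel junction channel name (default "ZO1").
#' @param windowUm sliding-window side (um); about 1.5 cell diameters
#'   works well.
#' @param relCutoff fraction of the reference coverage below which a
#'   window counts as disrupted.
#' @param refQuantile quantile of the coverage score used as the
#'   organized-epithelium reference.
#' @param minAreaUm2 discard disrupted components smaller than this.
#' @param cleanRadiusUm radius of the morphological closing/opening
#'   applied to the raw low-coverage mask.
#' @param threshold optional fixed binarization threshold for the
#'   junction channel; default Otsu.
#' @return a [RegionMask-class] with provenance "auto".
#' @export
detectDisruptedRegions <- function(stack, junctionChannel = "ZO1",
    windowUm = 24, relCutoff = 0.5, refQuantile = 0.9, minAreaUm2 = 500,
    cleanRadiusUm = 4, threshold = NULL) {
  x <- .get2DChannel(stack, junctionChannel)
  px <- pixelSize(stack)
  nr <- nrow(x); nc <- ncol(x)
  if (max(x) <= min(x)) {
    return(RegionMask(matrix(TRUE, nr, nc), px, provenance = "auto"))
  }
  thr <- if (is.null(threshold)) otsuThreshold(x) else threshold
  J <- matrix(as.numeric(x > thr), nr, nc)
  score <- boxMean(J, windowUm / px)
  ref <- stats::quantile(score, refQuantile, names = FALSE)
  if (ref < 0.01) {   # no credible junction network anywhere
    return(RegionMask(matrix(TRUE, nr, nc), px, provenance = "auto"))
  }
  low <- score < relCutoff * ref
  rClean <- max(1L, round(cleanRadiusUm / px))
  m <- matrix(as.numeric(low), nr, nc)
  m <- EBImage::closing(m, discBrush(rClean))
  m <- EBImage::opening(m, discBrush(rClean)) > 0
  m <- dropSmallComponents(m, minPx = ceiling(minAreaUm2 / px^2))
  RegionMask(matrix(m, nr, nc), px, provenance = "auto")
}

#' Load a manually drawn disrupted-region mask
#'
#' Reads a binary mask image (PNG or TIFF; any non-zero pixel is
#' disrupted), checks it against the stack's pixel grid and returns it
#' with provenance "manual".  The area fraction is always recomputed
#' from the pixels.
#'
#' @param path mask image file.
#' @param stack the [ImageStack-class] the mask annotates.
#' @return a [RegionMask-class] with provenance "manual".
#' @export
loadManualMask <- function(path, stack) {
  ext <- tolower(tools::file_ext(path))
  m <- if (ext == "png") png::readPNG(path) else tiff::readTIFF(path)
  if (length(dim(m)) == 3L) m <- m[, , 1L]
  d <- dim(stack)[1:2]
  if (!identical(dim(m), as.integer(d)) && !identical(dim(m), d))
    stop(sprintf("mask shape %s does not match image shape %s",
                 paste(dim(m), collapse = "x"), paste(d, collapse = "x")),
         call. = FALSE)
  RegionMask(m > 0, pixelSize(stack), provenance = "manual")
}

#' Measure per-cell apical surfaces from the junction network
#'
#' The ZO1-delimited apical surface of each cell: the junction channel
#' is binarized, cells are the connected components of the network's
#' complement, component labels are propagated across the junction
#' ridge (Voronoi-style) so that the ridge is shared between adjacent
#' cells, and areas are reported in square micrometres.  Cells touching
#' the image border are discarded, as are cells inside an optional
#' disrupted-region mask.
#'
#' @param stack an [ImageStack-class].
#' @param junctionChannel junction channel name.
#' @param exclude optional [RegionMask-class]; cells whose centroid lies
#'   inside it are dropped (the junction network is not measurable
#'   there).
#' @param threshold optional fixed binarization threshold; default Otsu.
#' @param minAreaUm2 discard sliver components below this area.
#' @param shareJunction if TRUE (default) the junction ridge pixels are
#'   split between the adjacent cells, recovering the full tessellation
#'   polygon areas; if FALSE each cell is the bare interior enclosed by
#'   the junction line.
#' @return data.frame with columns label, row, col (0-based centroid)
#'   and area_um2, one row per measured cell.
#' @export
measureApicalSurfaces <- function(stack, junctionChannel = "ZO1",
    exclude = NULL, threshold = NULL, minAreaUm2 = 10,
    shareJunction = TRUE) {
  x <- .get2DChannel(stack, junctionChannel)
  px <- pixelSize(stack)
  nr <- nrow(x); nc <- ncol(x)
  if (max(x) <= min(x))
    stop("junction channel is empty: no cells can be delimited",
         call. = FALSE)
  thr <- if (is.null(threshold)) otsuThreshold(x) else threshold
  J <- x > thr
  lb <- EBImage::bwlabel(matrix(as.numeric(!J), nr, nc))
  lb <- matrix(as.integer(lb), nr, nc)
  if (max(lb) == 0L)
    stop("junction network covers the whole field", call. = FALSE)
  if (shareJunction) {
    full <- EBImage::propagate(x / 65535, seeds = lb, lambda = 1e4)
    full <- matrix(as.integer(full), nr, nc)
  } else {
    full <- lb
  }
  st <- labelStats(full)
  # discard border-touching cells and, optionally, disrupted regions
  border <- unique(c(full[1L, ], full[nr, ], full[, 1L], full[, nc]))
  drop <- st$label %in% border
  if (!is.null(exclude)) {
    m <- regionMask(exclude)
    ri <- pmin(pmax(round(st$row) + 1L, 1L), nr)
    ci <- pmin(pmax(round(st$col) + 1L, 1L), nc)
    drop <- drop | m[cbind(ri, ci)]
  }
  st <- st[!drop & st$n_px * px^2 >= minAreaUm2, , drop = FALSE]
  data.frame(label = seq_len(nrow(st)), row = st$row, col = st$col,
             area_um2 = st$n_px * px^2)
}
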