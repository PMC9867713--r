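# Internal helpers shared across modules.

# Run code with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Odd-sized flat disc brush with the given radius in pixels (>= 1).
discBrush <- function(radiusPx) {
  size <- 2L * max(1L, round(radiusPx)) + 1L
  EBImage::makeBrush(size, shape = "disc")
}

# Sliding-window mean of a 2D image with zero padding, normalized by the
# number of in-image pixels in each window (so borders are unbiased).
boxMean <- function(x, windowPx) {
  w <- max(3L, 2L * floor(windowPx / 2) + 1L)  # odd
  k <- matrix(1, w, w)
  num <- EBImage::filter2(x, k, boundary = 0)
  den <- EBImage::filter2(matrix(1, nrow(x), ncol(x)), k, boundary = 0)
  num / den
}

# Exact Euclidean distance (in pixels) from every pixel to the nearest
# TRUE pixel of `mask`; 0 inside the mask.  Thin wrapper over EBImage's
# exact distance transform, kept separate so tests can compare it against
# a brute-force oracle.
distanceToMask <- function(mask) {
  if (!any(mask)) stop("mask is empty: distance undefined", call. = FALSE)
  if (all(mask)) return(matrix(0, nrow(mask), ncol(mask)))
  d <- EBImage::distmap(matrix(as.numeric(!mask), nrow(mask), ncol(mask)))
  matrix(as.numeric(d), nrow(mask), ncol(mask))
}

# Keep only connected components of `mask` with at least `minPx` pixels.
dropSmallComponents <- function(mask, minPx) {
  if (!any(mask) || minPx <= 1) return(mask)
  lb <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lb <- matrix(as.integer(lb), nrow(mask), ncol(mask))
  sizes <- tabulate(lb[lb > 0L])
  keep <- which(sizes >= minPx)
  matrix(lb %in% keep, nrow(mask), ncol(mask))
}

# Centroids (0-based, pixel-centered) and pixel counts per label of an
# integer label map.  Returns a data.frame ordered by label 1..n.
labelStats <- function(labelMap) {
  idx <- which(labelMap > 0L)
  lab <- labelMap[idx]
  n <- max(labelMap)
  rows <- ((idx - 1L) %% nrow(labelMap))        # 0-based row
  cols <- ((idx - 1L) %/% nrow(labelMap))       # 0-based col
  cnt <- tabulate(lab, nbins = n)
  data.frame(
    label = seq_len(n),
    row = as.numeric(rowsum(rows, lab)[, 1L]) / cnt,
    col = as.numeric(rowsum(cols, lab)[, 1L]) / cnt,
    n_px = cnt)
}

# Relabel an integer label map so the surviving labels are 1..n,
# dropping labels not in `keep`.
relabelConsecutive <- function(labelMap, keep) {
  lut <- integer(max(labelMap) + 1L)
  lut[keep + 1L] <- seq_along(keep)
  matrix(lut[labelMap + 1L], nrow(labelMap), ncol(labelMap))
}
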