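# Radial-profile quantification of circular micropatterned colonies
# (2D gastruloids): colony localization, per-colony radial intensity
# profiles, and control-normalized quartile-band aggregation.

#' Locate a micropatterned colony
#'
#' Finds the colony in a field containing a single circular colony:
#' Otsu-thresholds the nuclei channel, fills holes, keeps the largest
#' connected component, and reports its centroid and the radius of the
#' minimal circle around it (the maximum centroid-to-foreground-pixel
#' distance).
#'
#' @param stack an [ImageStack-class].
#' @param nucleiChannel nuclei channel name.
#' @param nominalDiameterUm expected colony diameter (um); a foreground
#'   covering less than \code{minFill} of the nominal disk area is
#'   rejected as a failed/partial colony.
#' @param minFill minimum foreground / nominal-disk area ratio.
#' @return list: \code{center} (0-based (row, col) px),
#'   \code{radius_um}.
#' @export
locateColony <- function(stack, nucleiChannel = "DAPI",
                         nominalDiameterUm = 700, minFill = 0.1) {
  x <- .get2DChannel(stack, nucleiChannel)
  px <- pixelSize(stack)
  if (max(x) <= min(x))
    stop("blank nuclei channel: no colony found", call. = FALSE)
  thr <- otsuThreshold(x)
  fg <- EBImage::fillHull(matrix(as.numeric(x > thr), nrow(x), ncol(x))) > 0
  lb <- EBImage::bwlabel(matrix(as.numeric(fg), nrow(x), ncol(x)))
  lb <- matrix(as.integer(lb), nrow(x), ncol(x))
  if (max(lb) == 0L) stop("no foreground: no colony found", call. = FALSE)
  sizes <- tabulate(lb[lb > 0L])
  big <- which.max(sizes)
  nominalPx <- pi * (nominalDiameterUm / 2 / px)^2
  if (sizes[big] < minFill * nominalPx)
    stop(sprintf(
      "foreground covers %.1f%% of the nominal colony disk (< %.0f%%): failed or partial colony",
      100 * sizes[big] / nominalPx, 100 * minFill), call. = FALSE)
  idx <- which(lb == big)
  rows <- (idx - 1L) %% nrow(x)
  cols <- (idx - 1L) %/% nrow(x)
  ctr <- c(mean(rows), mean(cols))
  radiusUm <- sqrt(max((rows - ctr[1L])^2 + (cols - ctr[2L])^2)) * px
  list(center = ctr, radius_um = radiusUm)
}

#' Radial intensity profile of a colony channel
#'
#' Bins the pixels inside the colony disk into equal-width annuli over
#' [0, radius] and reports the mean channel intensity per annulus.
#' Pixels beyond the radius are excluded (not zero-filled), so edge
#' bins are not diluted by background.
#'
#' @param stack an [ImageStack-class].
#' @param channel channel to profile.
#' @param center colony center, 0-based (row, col) px (from
#'   [locateColony()] or ground truth).
#' @param radiusUm colony radius (um).
#' @param nBins number of annuli (>= 4).
#' @return data.frame with one row per annulus: \code{bin},
#'   \code{r_um} (bin center), \code{r_frac} (r/R),
#'   \code{mean_intensity}, \code{n_pixels}; attributes \code{channel},
#'   \code{center}, \code{radius_um} carry the geometry.
#' @export
radialProfile <- function(stack, channel, center, radiusUm, nBins = 50L) {
  x <- .get2DChannel(stack, channel)
  px <- pixelSize(stack)
  stopifnot(radiusUm > 0, nBins >= 4L)
  if (center[1L] < 0 || center[1L] > nrow(x) - 1 ||
      center[2L] < 0 || center[2L] > ncol(x) - 1)
    stop("colony center lies outside the image", call. = FALSE)
  rr <- rep(seq_len(nrow(x)) - 1, times = ncol(x))
  cc <- rep(seq_len(ncol(x)) - 1, each = nrow(x))
  rUm <- sqrt((rr - center[1L])^2 + (cc - center[2L])^2) * px
  keep <- rUm <= radiusUm
  w <- radiusUm / nBins
  bin <- pmin(floor(rUm[keep] / w) + 1L, nBins)   # [a, b) annuli, r = R closed
  v <- as.numeric(x)[keep]
  n <- tabulate(bin, nbins = nBins)
  s <- numeric(nBins)
  s[sort(unique(bin))] <- as.numeric(rowsum(v, bin)[, 1L])
  out <- data.frame(bin = seq_len(nBins), r_um = (seq_len(nBins) - 0.5) * w,
                    r_frac = (seq_len(nBins) - 0.5) / nBins,
                    mean_intensity = ifelse(n > 0L, s / n, NA_real_),
                    n_pixels = n)
  attr(out, "channel") <- channel
  attr(out, "center") <- center
  attr(out, "radius_um") <- radiusUm
  out
}

#' Aggregate colony profiles and normalize to the control maximum
#'
#' Per radial bin, computes the mean and the 1st/3rd quartiles across
#' colonies for the test and control sets, then divides every curve by
#' the maximum of the control set's mean profile, so the control mean
#' peaks at exactly 1.  Test and control profiles must share binning.
#'
#' @param profiles list of per-colony profiles from [radialProfile()]
#'   (one channel).
#' @param controlProfiles list of control-condition profiles for the
#'   same channel and binning; pass \code{profiles} itself to normalize
#'   a control-only set.
#' @param condition,controlCondition labels for the output.
#' @return data.frame: condition, bin, r_um, r_frac, mean, q1, q3
#'   (all normalized), n_colonies, normalization_factor.
#' @export
aggregateProfiles <- function(profiles, controlProfiles,
                              condition = "test",
                              controlCondition = "control") {
  stopifnot(length(profiles) >= 1L, length(controlProfiles) >= 1L)
  ref <- controlProfiles[[1L]]
  sameBinning <- function(p) identical(p$r_um, ref$r_um)
  if (!all(vapply(profiles, sameBinning, logical(1L))) ||
      !all(vapply(controlProfiles, sameBinning, logical(1L))))
    stop("all profiles must share the same radial binning", call. = FALSE)
  asMat <- function(ps) do.call(cbind, lapply(ps, `[[`, "mean_intensity"))
  M <- asMat(profiles)
  Mc <- asMat(controlProfiles)
  ctrlMean <- rowMeans(Mc)
  norm <- max(ctrlMean, na.rm = TRUE)
  if (!is.finite(norm) || norm <= 0)
    stop("control mean profile is zero: normalization undefined",
         call. = FALSE)
  summarize <- function(M, label) {
    data.frame(condition = label, bin = ref$bin, r_um = ref$r_um,
               r_frac = ref$r_frac,
               mean = rowMeans(M) / norm,
               q1 = apply(M, 1L, stats::quantile, 0.25) / norm,
               q3 = apply(M, 1L, stats::quantile, 0.75) / norm,
               n_colonies = ncol(M), normalization_factor = norm)
  }
  rbind(summarize(Mc, controlCondition),
        if (identical(profiles, controlProfiles)) NULL
        else summarize(M, condition))
}
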