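# Concentric distance-ring statistics around disrupted regions: the
# core spatial statistic relating marker positivity to distance from
# zones of disrupted tight junctions.

#' Build concentric distance-ring masks around a disrupted region
#'
#' Computes the exact Euclidean distance transform from the disrupted
#' mask and partitions the image into the inside-disrupted class ("0")
#' plus half-open rings [0,30), [30,60), [60,90), [90,Inf) micrometres
#' away by default.  The resulting classes are pairwise disjoint and
#' tile the image exactly.
#'
#' @param region a [RegionMask-class] (TRUE = disrupted).
#' @param edgesUm ring edges in micrometres; must start at 0 and
#'   increase.  Edges \code{c(0, 30, 60, 90)} give the five classes
#'   "0", "+30", "+60", "+90", ">+90".
#' @return a [RingBinning-class].  An empty disrupted mask is an error
#'   (there is no reference structure to measure distance from); a mask
#'   covering the whole image is valid and leaves all outer rings empty
#'   (a warning flags it).
#' @examples
#' m <- matrix(FALSE, 64, 64); m[28:36, 28:36] <- TRUE
#' rb <- makeRingMasks(RegionMask(m, pixelSize = 5), edgesUm = c(0, 30, 60, 90))
#' table(ringIndexMap(rb))
#' @export
makeRingMasks <- function(region, edgesUm = c(0, 30, 60, 90)) {
  if (edgesUm[1L] != 0 || is.unsorted(edgesUm, strictly = TRUE))
    stop("edgesUm must start at 0 and be strictly increasing", call. = FALSE)
  mask <- regionMask(region)
  px <- region@pixelSize
  if (!any(mask))
    stop("empty disrupted mask: no reference structure for distances",
         call. = FALSE)
  k <- length(edgesUm) + 1L
  labels <- c("0", paste0("+", edgesUm[-1L]), paste0(">+", max(edgesUm)))
  if (all(mask)) {
    warning("disrupted mask covers the whole image: all rings are empty")
    idx <- matrix(1L, nrow(mask), ncol(mask))
  } else {
    dUm <- distanceToMask(mask) * px
    idx <- ifelse(mask, 1L, 2L + findInterval(dUm, edgesUm[-1L]))
  }
  new("RingBinning", ringIndex = matrix(as.integer(idx), nrow(mask),
                                        ncol(mask)),
      edges = edgesUm, labels = labels, pixelSize = px)
}

#' Per-ring positive-cell fractions
#'
#' Assigns every nucleus to the ring containing its centroid and tallies
#' the percentage of marker-positive nuclei per ring: the
#' positivity-versus-distance profile.  Empty rings report NA (not 0).
#'
#' @param nuclei a [NucleusTable-class].
#' @param calls a [MarkerCalls-class] whose labels match \code{nuclei}.
#' @param rings a [RingBinning-class] on the same pixel grid.
#' @return data.frame with one row per ring: \code{bin} (label),
#'   \code{bin_index} (0-based), \code{n_cells}, \code{n_positive},
#'   \code{fraction_percent}.
#' @export
binPositiveFractions <- function(nuclei, calls, rings) {
  rec <- nucleusData(nuclei)
  cl <- positiveCalls(calls)
  if (!identical(as.character(rec$label), names(cl)))
    stop("marker calls do not match the nucleus labels", call. = FALSE)
  idxMap <- ringIndexMap(rings)
  if (!identical(dim(idxMap), dim(labelMap(nuclei))))
    stop("ring binning and nucleus table are on different pixel grids",
         call. = FALSE)
  ri <- pmin(pmax(round(rec$row) + 1L, 1L), nrow(idxMap))
  ci <- pmin(pmax(round(rec$col) + 1L, 1L), ncol(idxMap))
  ring <- idxMap[cbind(ri, ci)]
  k <- length(ringLabels(rings))
  nCells <- tabulate(ring, nbins = k)
  nPos <- tabulate(ring[cl], nbins = k)
  frac <- ifelse(nCells > 0L, 100 * nPos / nCells, NA_real_)
  data.frame(bin = ringLabels(rings), bin_index = seq_len(k) - 1L,
             n_cells = nCells, n_positive = nPos,
             fraction_percent = frac)
}

#' Fit the positivity-versus-distance slope
#'
#' Ordinary least squares of the per-ring positive percentage against
#' distance, the statistic summarized as the slope \emph{m} in the
#' figures.  The default abscissa is the bin index (0..4); bin centers
#' in micrometres are available via \code{xConvention = "bin_center_um"}
#' (the open last bin uses one half bin-width beyond its lower edge, and
#' the inside-disrupted class sits at 0).
#'
#' @param profile data.frame from [binPositiveFractions()]; NA bins are
#'   excluded, at least two usable bins are required.
#' @param xConvention "bin_index" or "bin_center_um".
#' @param edgesUm ring edges (um), used only for bin centers.
#' @param level confidence level for the slope interval.
#' @return one-row data.frame: \code{m}, \code{intercept},
#'   \code{r_squared}, \code{m_se}, \code{m_ci_lo}, \code{m_ci_hi},
#'   \code{n_bins}, \code{x_convention}.  A perfectly flat profile has
#'   slope 0 and r_squared 1 (the fit is exact).
#' @examples
#' pr <- data.frame(bin = c("0","+30","+60","+90",">+90"), bin_index = 0:4,
#'                  n_cells = rep(100L, 5), n_positive = c(100, 88, 76, 64, 52),
#'                  fraction_percent = c(100, 88, 76, 64, 52))
#' fitDistanceSlope(pr)   # m = -12 exactly
#' @export
fitDistanceSlope <- function(profile,
    xConvention = c("bin_index", "bin_center_um"),
    edgesUm = c(0, 30, 60, 90), level = 0.95) {
  xConvention <- match.arg(xConvention)
  ok <- !is.na(profile$fraction_percent)
  if (sum(ok) < 2L)
    stop("need at least two rings with cells to fit a slope", call. = FALSE)
  if (xConvention == "bin_index") {
    x <- profile$bin_index[ok]
  } else {
    w <- diff(edgesUm)[length(edgesUm) - 1L]
    centers <- c(0, (edgesUm[-length(edgesUm)] + edgesUm[-1L]) / 2,
                 max(edgesUm) + w / 2)
    x <- centers[profile$bin_index[ok] + 1L]
  }
  y <- profile$fraction_percent[ok]
  fit <- stats::lm(y ~ x)
  co <- stats::coef(fit)
  ssTot <- sum((y - mean(y))^2)
  ssRes <- sum(stats::residuals(fit)^2)
  r2 <- if (ssTot <= .Machine$double.eps * length(y) * max(1, mean(y)^2)) {
    1    # flat or perfectly collinear profile: the fit is exact
  } else {
    1 - ssRes / ssTot
  }
  exactFit <- ssRes <= .Machine$double.eps * length(y) *
    max(1, mean(y)^2)
  if (exactFit) {
    se <- 0
    ci <- c(unname(co["x"]), unname(co["x"]))
  } else {
    se <- tryCatch(summary(fit)$coefficients["x", "Std. Error"],
                   error = function(e) NA_real_)
    ci <- tryCatch(stats::confint(fit, "x", level = level),
                   error = function(e) c(NA_real_, NA_real_))
  }
  data.frame(m = unname(co["x"]), intercept = unname(co["(Intercept)"]),
             r_squared = min(max(r2, 0), 1), m_se = unname(se),
             m_ci_lo = ci[1L], m_ci_hi = ci[2L], n_bins = sum(ok),
             x_convention = xConvention)
}

#' Organized/disrupted area-fraction time course
#'
#' Tabulates the disrupted area percentage of a sequence of region
#' masks over time, and its complement, the organized percentage --
#' the quantity tracked during tight-junction formation kinetics.
#'
#' @param masks list of \code{list(time = , mask = )} entries, each mask
#'   a [RegionMask-class]; times must be strictly increasing.
#' @param organized if TRUE (default) the \code{percent} column reports
#'   organized area, otherwise disrupted area.
#' @return data.frame: time, disrupted_percent, organized_percent,
#'   percent (the requested one).
#' @export
areaFractionTimecourse <- function(masks, organized = TRUE) {
  times <- vapply(masks, function(m) as.numeric(m$time), numeric(1L))
  if (anyDuplicated(times)) stop("duplicate time points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("time points must be strictly increasing", call. = FALSE)
  disr <- vapply(masks, function(m) areaFraction(m$mask), numeric(1L))
  out <- data.frame(time = times, disrupted_percent = disr,
                    organized_percent = 100 - disr)
  out$percent <- if (organized) out$organized_percent else
    out$disrupted_percent
  out
}
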