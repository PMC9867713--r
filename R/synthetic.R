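# Seeded synthetic-image generators with planted ground truth.
#
# The monolayer generator emulates a confluent hiPSC epithelial sheet:
# nuclei on a jittered lattice, a ZO1 junction network along the Voronoi
# boundaries of the nucleus positions, irregular patches where the
# network fragments into foci (or is erased), and a nuclear marker whose
# per-cell positivity probability is a planted function of the cell's
# distance ring around the disrupted patches.  The colony generator
# emulates circular micropatterned 2D-gastruloid colonies with concentric
# fate domains.

# Jittered-lattice nucleus centers.  Continuous coordinates: pixel (r,c)
# has its center at (r - 0.5, c - 0.5).
.seedLattice <- function(nr, nc, spacingPx, jitterFrac) {
  Gr <- floor(nr / spacingPx)
  Gc <- floor(nc / spacingPx)
  if (Gr < 2L || Gc < 2L)
    stop("infeasible packing: cell diameter too large for the field",
         call. = FALSE)
  sr <- nr / Gr
  sc <- nc / Gc
  gi <- rep(seq_len(Gr), times = Gc)
  gj <- rep(seq_len(Gc), each = Gr)
  seedR <- (gi - 0.5) * sr + stats::runif(Gr * Gc, -1, 1) * jitterFrac * sr
  seedC <- (gj - 0.5) * sc + stats::runif(Gr * Gc, -1, 1) * jitterFrac * sc
  list(row = pmin(pmax(seedR, 0.25), nr - 0.25),
       col = pmin(pmax(seedC, 0.25), nc - 0.25),
       Gr = Gr, Gc = Gc, sr = sr, sc = sc)
}

# Raster Voronoi assignment: for every pixel, the nearest lattice seed.
# The search covers the 3x3 block of neighbouring lattice cells (which
# is exhaustive for jitter < 0.32: a seed two cells away is at least
# (2 - 0.5 - j) pitches away while the own-cell seed is at most
# (0.5 + j) * sqrt(2)), widening to 5x5 for larger jitter.  The lattice
# is padded with far-away dummy seeds so no bounds checks are needed.
# Returns the label map and the distance to the nearest seed in pixels
# (used to render nuclei).
.nearestSeed <- function(nr, nc, lat, jitterFrac) {
  pad <- if (jitterFrac <= 0.32) 1L else 2L
  Gr <- lat$Gr; Gc <- lat$Gc
  Grp <- Gr + 2L * pad
  PR <- matrix(1e9, Grp, Gc + 2L * pad)
  PC <- matrix(1e9, Grp, Gc + 2L * pad)
  PR[pad + seq_len(Gr), pad + seq_len(Gc)] <- lat$row
  PC[pad + seq_len(Gr), pad + seq_len(Gc)] <- lat$col
  pr <- rep(seq_len(nr) - 0.5, times = nc)
  pc <- rep(seq_len(nc) - 0.5, each = nr)
  base <- (pmin(pmax(ceiling(pr / lat$sr), 1L), Gr) + pad) +
          (pmin(pmax(ceiling(pc / lat$sc), 1L), Gc) + pad - 1L) * Grp
  best <- rep(Inf, nr * nc)
  lab <- integer(nr * nc)
  for (dj in -pad:pad) {
    for (di in -pad:pad) {
      sIdx <- base + di + dj * Grp
      dr <- pr - PR[sIdx]
      dc <- pc - PC[sIdx]
      d2 <- dr * dr + dc * dc
      w <- d2 < best
      best[w] <- d2[w]
      lab[w] <- sIdx[w]
    }
  }
  li <- ((lab - 1L) %% Grp) + 1L - pad
  lj <- ((lab - 1L) %/% Grp) + 1L - pad
  list(label = matrix(li + (lj - 1L) * Gr, nr, nc),
       distPx = matrix(sqrt(best), nr, nc))
}

# Irregular disrupted patches: union of Gaussian bumps at random centers
# plus smoothed noise, thresholded at the field quantile that yields the
# requested pixel fraction exactly.
.disruptionMask <- function(nr, nc, frac, nPatches) {
  if (frac <= 0) return(matrix(FALSE, nr, nc))
  if (frac >= 1) return(matrix(TRUE, nr, nc))
  sig <- sqrt(frac * nr * nc / (pi * nPatches))
  prow <- stats::runif(nPatches, 0.1 * nr, 0.9 * nr)
  pcol <- stats::runif(nPatches, 0.1 * nc, 0.9 * nc)
  rr <- rep(seq_len(nr) - 0.5, times = nc)
  cc <- rep(seq_len(nc) - 0.5, each = nr)
  field <- rep(0, nr * nc)
  for (p in seq_len(nPatches)) {
    d2 <- (rr - prow[p])^2 + (cc - pcol[p])^2
    field <- pmax(field, exp(-d2 / (2 * sig^2)))
  }
  noise <- EBImage::gblur(matrix(stats::rnorm(nr * nc), nr, nc),
                          sigma = max(2, sig / 3))
  noise <- as.numeric(noise) / stats::sd(noise)
  field <- field + 0.15 * noise
  thr <- stats::quantile(field, 1 - frac, names = FALSE)
  matrix(field > thr, nr, nc)
}

.clipCamera <- function(x, noiseSd) {
  if (noiseSd > 0) x <- x + stats::rnorm(length(x), 0, noiseSd)
  matrix(pmin(pmax(round(x), 0), 65535), nrow(x), ncol(x))
}

#' Simulate a confluent epithelial monolayer with planted ground truth
#'
#' Generates a multichannel field (DAPI, ZO1, one nuclear marker) of a
#' confluent epithelial sheet whose junction channel traces the Voronoi
#' boundaries of the nucleus lattice, with irregular patches of disrupted
#' junctions covering a requested area fraction, and per-cell marker
#' positivity drawn from planted per-ring probabilities.  Identical
#' arguments and seed give bit-identical output.
#'
#' @param fieldSize image size in pixels, \code{c(rows, cols)}.
#' @param pixelSizeUm physical pixel size (um/px).
#' @param cellDiameterUm mean cell diameter (um); sets the lattice pitch.
#' @param disruptedFraction target fraction of the field covered by
#'   disrupted patches, in [0, 1]; the planted mask hits it exactly (to
#'   within one pixel quantile discretization).
#' @param nPatches number of planted patch centers (patches may merge).
#' @param markerProbByRing positivity probabilities: length 4 (rings
#'   0-30 / 30-60 / 60-90 / >90 um, cells inside the disrupted zone
#'   sharing the first entry) or length 5 (first entry = cells inside
#'   the disrupted zone, then the four rings).
#' @param markerName name of the marker channel (e.g. "BRACH", "pSMAD15").
#' @param disruptionStyle "foci" fragments the junction network inside
#'   patches into scattered bright puncta; "erased" removes it entirely.
#' @param noiseSd Gaussian read-noise SD (camera counts).
#' @param ringEdgesUm ring edges in micrometres (first must be 0).
#' @param nucleusRadiusUm rendered nucleus radius (um).
#' @param junctionWidthUm rendered junction line width (um).
#' @param jitterFrac lattice jitter as a fraction of the pitch, < 0.5.
#' @param seed RNG seed; the caller's RNG state is left untouched.
#' @return a list with elements \code{stack} (an [ImageStack-class]) and
#'   \code{truth}: \code{mask} (a [RegionMask-class], provenance
#'   "truth"), \code{labelMap} (integer Voronoi cell map), \code{cells}
#'   (data.frame: label, row, col (0-based centroid px), area_um2,
#'   dist_um, ring_index 0-3, distance_class, positive), and \code{spec}
#'   (the arguments, for sidecar serialization).
#' @examples
#' sim <- simulateMonolayer(fieldSize = c(128, 128), cellDiameterUm = 14,
#'                          disruptedFraction = 0.3, seed = 2)
#' areaFraction(sim$truth$mask)
#' @export
simulateMonolayer <- function(fieldSize = c(512L, 512L), pixelSizeUm = 1,
    cellDiameterUm = 15, disruptedFraction = 0.4, nPatches = 3L,
    markerProbByRing = c(0.9, 0.7, 0.5, 0.3), markerName = "BRACH",
    disruptionStyle = c("foci", "erased"), noiseSd = 150,
    ringEdgesUm = c(0, 30, 60, 90), nucleusRadiusUm = 0.3 * cellDiameterUm,
    junctionWidthUm = 1.2, jitterFrac = 0.28, seed = 1L) {
  disruptionStyle <- match.arg(disruptionStyle)
  stopifnot(length(fieldSize) == 2L, fieldSize >= 16L, pixelSizeUm > 0,
            cellDiameterUm > 0, nPatches >= 1L, noiseSd >= 0,
            jitterFrac >= 0, jitterFrac < 0.5)
  if (disruptedFraction < 0 || disruptedFraction > 1)
    stop("disruptedFraction must be in [0, 1]", call. = FALSE)
  if (!length(markerProbByRing) %in% c(4L, 5L) ||
      any(markerProbByRing < 0 | markerProbByRing > 1))
    stop("markerProbByRing needs 4 or 5 probabilities in [0, 1]",
         call. = FALSE)
  if (ringEdgesUm[1L] != 0 || is.unsorted(ringEdgesUm, strictly = TRUE))
    stop("ringEdgesUm must start at 0 and increase", call. = FALSE)
  nr <- as.integer(fieldSize[1L]); nc <- as.integer(fieldSize[2L])
  spacingPx <- cellDiameterUm / pixelSizeUm
  if (spacingPx < 4)
    stop("infeasible packing: cell diameter below 4 px at this pixel size",
         call. = FALSE)

  withSeed(seed, {
    lat <- .seedLattice(nr, nc, spacingPx, jitterFrac)
    vor <- .nearestSeed(nr, nc, lat, jitterFrac)
    labelMap <- vor$label
    nCells <- lat$Gr * lat$Gc

    mask <- .disruptionMask(nr, nc, disruptedFraction, nPatches)

    # per-cell geometry and ring assignment (by centroid)
    st <- labelStats(labelMap)
    if (any(mask) && !all(mask)) {
      distUm <- distanceToMask(mask) * pixelSizeUm
    } else if (all(mask)) {
      distUm <- matrix(0, nr, nc)
    } else {
      distUm <- matrix(Inf, nr, nc)
    }
    ri <- pmin(pmax(round(st$row) + 1L, 1L), nr)
    ci <- pmin(pmax(round(st$col) + 1L, 1L), nc)
    cellDist <- distUm[cbind(ri, ci)]
    inside <- mask[cbind(ri, ci)]
    innerEdges <- ringEdgesUm[-1L]
    ringIdx <- findInterval(cellDist, innerEdges)       # 0..3
    klass <- ifelse(inside, 1L, 2L + ringIdx)           # 1..5
    classLabels <- c("0", paste0("+", innerEdges), paste0(">+", max(innerEdges)))
    p <- if (length(markerProbByRing) == 5L) markerProbByRing[klass]
         else markerProbByRing[ringIdx + 1L]
    positive <- stats::rbinom(nCells, 1L, p) == 1L

    # render channels
    rn <- nucleusRadiusUm / pixelSizeUm
    nucleusLabelMap <- labelMap * (vor$distPx <= rn)
    blob <- exp(-(vor$distPx / rn)^4)
    dapi <- 300 + 20000 * blob
    posPix <- matrix(positive[labelMap], nr, nc)
    markerImg <- 300 + 18000 * blob * posPix

    edge <- (labelMap != labelMap[c(2:nr, nr), ]) |
            (labelMap != labelMap[, c(2:nc, nc)])
    halfW <- junctionWidthUm / pixelSizeUm / 2
    if (halfW >= 1) {
      edge <- EBImage::dilate(matrix(as.numeric(edge), nr, nc),
                              discBrush(halfW)) > 0
    }
    network <- edge & !mask
    if (disruptionStyle == "foci" && any(mask)) {
      inMask <- which(mask)
      nFoci <- max(1L, round(0.004 * length(inMask)))
      foci <- matrix(FALSE, nr, nc)
      foci[sample(inMask, min(nFoci, length(inMask)))] <- TRUE
      foci <- EBImage::dilate(matrix(as.numeric(foci), nr, nc),
                              discBrush(1)) > 0
      network <- network | (foci & mask)
    }
    zo1 <- 300 + 25000 * network

    stack <- ImageStack(
      stats::setNames(list(.clipCamera(dapi, noiseSd),
                           .clipCamera(zo1, noiseSd),
                           .clipCamera(markerImg, noiseSd)),
                      c("DAPI", "ZO1", markerName)),
      pixelSize = pixelSizeUm)

    cells <- data.frame(
      label = st$label, row = st$row, col = st$col,
      area_um2 = st$n_px * pixelSizeUm^2,
      dist_um = cellDist, ring_index = ringIdx,
      distance_class = factor(classLabels[klass], levels = classLabels),
      positive = positive)

    list(stack = stack,
         truth = list(
           mask = RegionMask(mask, pixelSizeUm, provenance = "truth"),
           labelMap = labelMap,
           nucleusLabelMap = nucleusLabelMap,
           cells = cells,
           spec = list(fieldSize = c(nr, nc), pixelSizeUm = pixelSizeUm,
                       cellDiameterUm = cellDiameterUm,
                       disruptedFraction = disruptedFraction,
                       nPatches = nPatches,
                       markerProbByRing = markerProbByRing,
                       markerName = markerName,
                       disruptionStyle = disruptionStyle,
                       noiseSd = noiseSd, ringEdgesUm = ringEdgesUm,
                       nucleusRadiusUm = nucleusRadiusUm,
                       junctionWidthUm = junctionWidthUm,
                       jitterFrac = jitterFrac, seed = seed)))
  })
}

#' Ground-truth nuclei and marker calls from a simulated monolayer
#'
#' Convenience adapters turning the simulator's planted truth into the
#' same containers the segmentation stage produces, so the spatial
#' statistics can be exercised against exact ground truth.
#'
#' @param sim result of [simulateMonolayer()].
#' @return \code{truthNuclei}: a [NucleusTable-class] built from the
#'   planted cell lattice; \code{truthCalls}: a [MarkerCalls-class] with
#'   the planted positivity.
#' @export
truthNuclei <- function(sim) {
  cells <- sim$truth$cells
  NucleusTable(sim$truth$nucleusLabelMap,
               data.frame(label = cells$label, row = cells$row,
                          col = cells$col, area_um2 = cells$area_um2),
               pixelSize = pixelSize(sim$stack))
}

#' @rdname truthNuclei
#' @export
truthCalls <- function(sim) {
  cells <- sim$truth$cells
  MarkerCalls(sim$truth$spec$markerName,
              stats::setNames(cells$positive, cells$label),
              threshold = NA_real_)
}

#' Simulate a time course of epithelial reorganization
#'
#' Emulates tight-junction formation kinetics after reseeding: at each
#' requested time point a monolayer is generated whose planted disrupted
#' fraction is one minus the requested organized fraction.
#'
#' @param organizedFractionByTime named numeric vector: names are time
#'   points (hours), values the organized area fraction in [0, 1];
#'   times must be strictly increasing with no duplicates.
#' @param ... further arguments passed to [simulateMonolayer()]
#'   (\code{disruptedFraction} and \code{seed} are set internally).
#' @param seed base seed; time point k uses \code{seed + k}.
#' @return list with one element per time point:
#'   \code{list(time, stack, truth)}.
#' @export
simulateTimecourse <- function(organizedFractionByTime, ..., seed = 1L) {
  org <- organizedFractionByTime
  times <- as.numeric(names(org))
  if (anyNA(times)) stop("names must be numeric time points", call. = FALSE)
  if (anyDuplicated(times)) stop("duplicate time points", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE))
    stop("time points must be strictly increasing", call. = FALSE)
  if (any(org < 0 | org > 1))
    stop("organized fractions must be in [0, 1]", call. = FALSE)
  lapply(seq_along(org), function(k) {
    sim <- simulateMonolayer(disruptedFraction = 1 - org[[k]],
                             seed = seed + k, ...)
    list(time = times[k], stack = sim$stack, truth = sim$truth)
  })
}

.checkFateDomains <- function(fateDomains) {
  stopifnot(all(c("channel", "inner", "outer", "intensity") %in%
                names(fateDomains)))
  if (any(fateDomains$inner < 0 | fateDomains$outer > 1 |
          fateDomains$inner >= fateDomains$outer))
    stop("fate domains need 0 <= inner < outer <= 1", call. = FALSE)
  for (ch in unique(fateDomains$channel)) {
    d <- fateDomains[fateDomains$channel == ch, , drop = FALSE]
    d <- d[order(d$inner), , drop = FALSE]
    if (nrow(d) > 1L && any(d$inner[-1L] < d$outer[-nrow(d)]))
      stop(sprintf("overlapping fate domains on channel '%s'", ch),
           call. = FALSE)
  }
  invisible(TRUE)
}

# Step-function intensity of a channel's planted domains at radius
# fraction rfrac (half-open [inner, outer), outer = 1 closed).
.domainIntensity <- function(fateDomains, ch, rfrac) {
  out <- numeric(length(rfrac))
  d <- fateDomains[fateDomains$channel == ch, , drop = FALSE]
  for (i in seq_len(nrow(d))) {
    hit <- rfrac >= d$inner[i] &
           (rfrac < d$outer[i] | (d$outer[i] == 1 & rfrac <= 1))
    out[hit] <- out[hit] + d$intensity[i]
  }
  out
}

#' Simulate micropatterned 2D-gastruloid colonies
#'
#' Each colony is a disk of the stated diameter (700 um by default, the
#' embryo-scale micropattern size) whose fate channels carry concentric
#' intensity domains specified as radius fractions, plus Gaussian read
#' noise.  The DAPI channel is a uniform nuclear disk used for colony
#' localization.  The planted noise-free radial step profiles are
#' returned as ground truth.
#'
#' @param nColonies number of colonies to generate.
#' @param diameterUm colony diameter (um).
#' @param pixelSizeUm pixel size (um/px).
#' @param fateDomains data.frame(channel, inner, outer, intensity) with
#'   radius fractions 0 <= inner < outer <= 1; domains on the same
#'   channel must not overlap.
#' @param dapiIntensity nuclear-channel plateau inside the disk.
#' @param noiseSd Gaussian read-noise SD (camera counts).
#' @param centerJitterPx per-colony uniform jitter of the colony center.
#' @param marginFrac extra field margin around the disk.
#' @param seed RNG seed.
#' @return list: \code{stacks} (list of [ImageStack-class]),
#'   \code{truth} with \code{domains}, \code{profiles} (data.frame
#'   channel, r_frac, intensity on a fine grid), \code{centers} (matrix
#'   of 0-based (row, col) centers), \code{radiusUm}, and \code{spec}.
#' @export
simulateColonies <- function(nColonies = 8L, diameterUm = 700,
    pixelSizeUm = 2,
    fateDomains = data.frame(
      channel = c("SOX2", "BRACH"),
      inner = c(0, 0.75), outer = c(0.5, 1),
      intensity = c(12000, 15000)),
    dapiIntensity = 8000, noiseSd = 300, centerJitterPx = 0,
    marginFrac = 0.1, seed = 1L) {
  stopifnot(nColonies >= 1L, diameterUm > 0, pixelSizeUm > 0, noiseSd >= 0)
  .checkFateDomains(fateDomains)
  Rpx <- diameterUm / 2 / pixelSizeUm
  side <- ceiling(2 * Rpx * (1 + marginFrac))
  chNames <- unique(fateDomains$channel)

  withSeed(seed, {
    centers <- matrix(0, nColonies, 2L)
    stacks <- vector("list", nColonies)
    for (k in seq_len(nColonies)) {
      ctr <- side / 2 + stats::runif(2L, -centerJitterPx, centerJitterPx)
      rr <- rep(seq_len(side) - 0.5, times = side)
      cc <- rep(seq_len(side) - 0.5, each = side)
      r <- sqrt((rr - ctr[1L])^2 + (cc - ctr[2L])^2)
      rfrac <- r / Rpx
      disk <- rfrac <= 1
      chans <- list(DAPI = .clipCamera(
        matrix(dapiIntensity * disk, side, side), noiseSd))
      for (ch in chNames) {
        v <- .domainIntensity(fateDomains, ch, rfrac) * disk
        chans[[ch]] <- .clipCamera(matrix(v, side, side), noiseSd)
      }
      stacks[[k]] <- ImageStack(chans, pixelSize = pixelSizeUm)
      centers[k, ] <- ctr - 0.5   # 0-based pixel-centered
    }
    grid <- seq(0, 1, by = 0.005)
    profiles <- do.call(rbind, lapply(chNames, function(ch)
      data.frame(channel = ch, r_frac = grid,
                 intensity = .domainIntensity(fateDomains, ch, grid))))
    list(stacks = stacks,
         truth = list(domains = fateDomains, profiles = profiles,
                      centers = centers, radiusUm = diameterUm / 2,
                      spec = list(nColonies = nColonies,
                                  diameterUm = diameterUm,
                                  pixelSizeUm = pixelSizeUm,
                                  dapiIntensity = dapiIntensity,
                                  noiseSd = noiseSd,
                                  centerJitterPx = centerJitterPx,
                                  marginFrac = marginFrac, seed = seed)))
  })
}
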