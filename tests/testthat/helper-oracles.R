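# Independent oracles and small fixture builders used across the suite.
# Each oracle is deliberately written as the naive definition of the
# quantity, independent of the package's implementation path.

# Brute-force O(N*M) Euclidean distance (px) from every pixel to the
# nearest TRUE pixel of `mask`.
bruteDistance <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  mr <- (idx - 1L) %% nr
  mc <- (idx - 1L) %/% nr
  pr <- rep(seq_len(nr) - 1L, times = nc)
  pc <- rep(seq_len(nc) - 1L, each = nr)
  best <- rep(Inf, nr * nc)
  for (k in seq_along(idx)) {
    d2 <- (pr - mr[k])^2 + (pc - mc[k])^2
    best <- pmin(best, d2)
  }
  matrix(sqrt(best), nr, nc)
}

# Exhaustive Otsu search: every candidate gray level, class statistics
# recomputed from the raw pixel values.
otsuOracle <- function(x) {
  v <- floor(as.numeric(x))
  cand <- sort(unique(v))
  cand <- cand[cand < max(v)]
  sb <- vapply(cand, function(t) {
    lo <- v[v <= t]; hi <- v[v > t]
    w0 <- length(lo) / length(v)
    w0 * (1 - w0) * (mean(lo) - mean(hi))^2
  }, numeric(1L))
  cand[which.max(sb)]
}

# Exhaustive Huang fuzzy-entropy search over a binned histogram,
# entropies accumulated gray level by gray level.
huangOracle <- function(x, bins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / bins
  g <- pmin(floor((v - lo) / width), bins - 1L)
  h <- tabulate(g + 1L, nbins = bins)
  lev <- 0:(bins - 1L)
  C <- max(lev[h > 0]) - min(lev[h > 0])
  S <- function(u) ifelse(u <= 0 | u >= 1, 0,
                          -u * log(u) - (1 - u) * log(1 - u))
  ent <- rep(Inf, bins)
  for (t in seq_len(bins)) {
    in0 <- lev <= lev[t]
    if (!any(h[in0] > 0) || !any(h[!in0] > 0)) next
    mu0 <- sum(h[in0] * lev[in0]) / sum(h[in0])
    mu1 <- sum(h[!in0] * lev[!in0]) / sum(h[!in0])
    e <- 0
    for (gg in which(h > 0)) {
      mu <- if (lev[gg] <= lev[t]) mu0 else mu1
      u <- 1 / (1 + abs(lev[gg] - mu) / C)
      e <- e + h[gg] * S(u)
    }
    ent[t] <- e
  }
  lo + lev[which.min(ent)] * width + width
}

# Closed-form simple least squares.
olsOracle <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = b, intercept = mean(y) - b * mean(x))
}

# Random blob mask: union of random disks.
blobMask <- function(nr, nc, nDisks = 8L, rRange = c(4, 12)) {
  m <- matrix(FALSE, nr, nc)
  pr <- rep(seq_len(nr) - 1L, times = nc)
  pc <- rep(seq_len(nc) - 1L, each = nr)
  for (k in seq_len(nDisks)) {
    cr <- stats::runif(1, 0, nr - 1)
    cc <- stats::runif(1, 0, nc - 1)
    r <- stats::runif(1, rRange[1L], rRange[2L])
    m <- m | matrix((pr - cr)^2 + (pc - cc)^2 <= r^2, nr, nc)
  }
  m
}

# A disk-of-radius-r mask centered in an nr x nc field.
diskMask <- function(nr, nc, r, center = c((nr - 1) / 2, (nc - 1) / 2)) {
  pr <- rep(seq_len(nr) - 1L, times = nc)
  pc <- rep(seq_len(nc) - 1L, each = nr)
  matrix((pr - center[1L])^2 + (pc - center[2L])^2 <= r^2, nr, nc)
}

# Tiny ImageStack with the given named channel matrices.
miniStack <- function(..., pixelSize = 1) {
  ImageStack(list(...), pixelSize = pixelSize)
}
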