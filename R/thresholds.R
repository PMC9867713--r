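#' Otsu automatic threshold by exhaustive histogram search
#'
#' Builds the intensity histogram at the requested number of gray levels
#' and returns the level maximizing the between-class variance
#' \eqn{\omega_0 \omega_1 (\mu_0 - \mu_1)^2} over every possible split.
#' Pixels with value \code{<= threshold} are background, \code{>
#' threshold} foreground.  The default covers the full 16-bit camera
#' range, so the search is exhaustive over all 65,536 gray levels.
#'
#' @param x numeric matrix/array of non-negative intensities.
#' @param levels number of integer gray levels (default 65536 for 16-bit
#'   data); intensities are truncated into 0..(levels-1).
#' @return the threshold as a gray level (same scale as \code{x}); among
#'   ties the lowest maximizing level is returned.
#' @examples
#' x <- c(rnorm(500, 1000, 50), rnorm(500, 5000, 200))
#' otsuThreshold(pmax(round(x), 0))
#' @export
otsuThreshold <- function(x, levels = 65536L) {
  g <- pmin(pmax(floor(as.numeric(x)), 0), levels - 1L)
  h <- tabulate(g + 1L, nbins = levels)
  n <- sum(h)
  if (n == 0L) stop("empty image", call. = FALSE)
  lev <- 0:(levels - 1L)
  w <- cumsum(h) / n              # class-0 mass for threshold t = lev
  m <- cumsum(h * lev) / n        # partial first moment
  mt <- m[levels]
  valid <- w > 0 & w < 1
  if (!any(valid)) return(lev[which.max(h)])  # constant image
  sb <- rep(-Inf, levels)
  sb[valid] <- (mt * w[valid] - m[valid])^2 / (w[valid] * (1 - w[valid]))
  lev[which.max(sb)]
}

#' Huang automatic threshold by fuzzy-entropy minimization
#'
#' Implements the minimum-fuzzy-entropy criterion of Huang and Wang: for
#' each candidate split the two class means define a fuzzy membership
#' \eqn{u(g) = 1 / (1 + |g - \mu_c| / C)} (with \eqn{C} the intensity
#' range) and the threshold minimizing the total Shannon entropy of the
#' memberships is returned.  The search is exhaustive over a binned
#' histogram of the image's intensity range (256 bins by default, the
#' granularity at which ImageJ evaluates Huang's criterion), and the
#' selected bin is mapped back to the intensity scale of \code{x}.
#'
#' @param x numeric matrix/array of non-negative intensities.
#' @param bins number of histogram bins for the search.
#' @return threshold on the scale of \code{x}; pixels \code{> threshold}
#'   are foreground.
#' @export
huangThreshold <- function(x, bins = 256L) {
  v <- as.numeric(x)
  lo <- min(v); hi <- max(v)
  if (hi <= lo) return(lo)  # constant image: nothing above threshold
  width <- (hi - lo) / bins
  g <- pmin(floor((v - lo) / width), bins - 1L)   # bin index 0..bins-1
  h <- tabulate(g + 1L, nbins = bins)
  lev <- 0:(bins - 1L)
  W0 <- cumsum(h)
  M0 <- cumsum(h * lev)
  n <- W0[bins]; mtot <- M0[bins]
  Crange <- max(lev[h > 0]) - min(lev[h > 0])
  ent <- rep(Inf, bins)
  shannon <- function(u) {
    s <- numeric(length(u))
    ok <- u > 0 & u < 1
    s[ok] <- -u[ok] * log(u[ok]) - (1 - u[ok]) * log(1 - u[ok])
    s
  }
  for (t in which(W0 > 0 & W0 < n)) {       # t is 1-based: classes <= lev[t]
    mu0 <- M0[t] / W0[t]
    mu1 <- (mtot - M0[t]) / (n - W0[t])
    u <- ifelse(lev <= lev[t],
                1 / (1 + abs(lev - mu0) / Crange),
                1 / (1 + abs(lev - mu1) / Crange))
    ent[t] <- sum(h * shannon(u))
  }
  tbest <- which.min(ent)
  lo + lev[tbest] * width + width  # upper edge of the chosen bin
}
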