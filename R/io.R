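# TIFF image and mask I/O.  Multichannel fields are written as
# multi-page 16-bit TIFFs with a JSON sidecar carrying channel names,
# pixel size and any generator metadata (spec + seed), so a written
# stack round-trips without external configuration.

#' Write an ImageStack to a multi-page TIFF with a JSON sidecar
#'
#' One TIFF page per channel, 16-bit; the sidecar (\code{<path>.json})
#' records channel names, pixel size and optional metadata such as the
#' generator spec and seed.
#'
#' @param stack a 2D [ImageStack-class].
#' @param path output TIFF path.
#' @param meta optional named list stored under \code{meta} in the
#'   sidecar.
#' @return \code{path}, invisibly.
#' @export
writeImageStack <- function(stack, path, meta = list()) {
  if (length(dim(stack)) != 2L)
    stop("only 2D stacks are written as multi-page TIFF", call. = FALSE)
  pages <- lapply(channelNames(stack), function(ch)
    getChannel(stack, ch) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(channels = as.list(channelNames(stack)),
               pixel_size_um = pixelSize(stack))
  if (length(meta)) side$meta <- meta
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read an ImageStack from a multi-page TIFF
#'
#' Channel names and pixel size come from the JSON sidecar written by
#' [writeImageStack()] when present, otherwise from the arguments.
#'
#' @param path TIFF file.
#' @param channels channel names in page order (overrides the sidecar).
#' @param pixelSizeUm pixel size (overrides the sidecar).
#' @return an [ImageStack-class].
#' @export
readImageStack <- function(path, channels = NULL, pixelSizeUm = NULL) {
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (is.null(channels)) channels <- side$channels
    if (is.null(pixelSizeUm)) pixelSizeUm <- side$pixel_size_um
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (is.null(channels))
    channels <- paste0("ch", seq_along(pages))
  if (is.null(pixelSizeUm))
    stop("pixelSizeUm not given and no sidecar found", call. = FALSE)
  if (length(channels) != length(pages))
    stop(sprintf("%d channel names for %d TIFF pages", length(channels),
                 length(pages)), call. = FALSE)
  ImageStack(stats::setNames(pages, channels), pixelSize = pixelSizeUm)
}

#' Write a RegionMask as a PNG image
#'
#' Disrupted pixels are white; re-loadable with [loadManualMask()], and
#' the round trip preserves the area fraction exactly.
#'
#' @param mask a [RegionMask-class].
#' @param path output PNG path.
#' @return \code{path}, invisibly.
#' @export
writeRegionMask <- function(mask, path) {
  png::writePNG(regionMask(mask) * 1, path)
  invisible(path)
}
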