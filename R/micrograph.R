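#' Multi-channel fluorescence micrograph
#'
#' Lightweight container for a registered multi-channel 2-D image. Channels
#' are integer-valued grey-level matrices (native bit depth, default 16-bit)
#' sharing one shape; the physical pixel size carries the calibration from
#' pixels to micrometres.
#'
#' @param channels Named list of numeric matrices (grey levels), all with the
#'   same dimensions. Conventional names are `"actin"` (phalloidin),
#'   `"dapi"` (nuclei) and `"marker"` (e.g. Egr3).
#' @param pixel_size Pixel size in micrometres per pixel (> 0).
#' @param bit_depth Bits per sample of the acquisition (default 16).
#' @param provenance Optional free-form origin tag (source path or
#'   generator seed).
#'
#' @return An object of class `micrograph`.
#' @examples
#' mg <- micrograph(list(actin = matrix(0, 8, 8)), pixel_size = 0.65)
#' dim(mg$channels$actin)
#' @export
micrograph <- function(channels, pixel_size, bit_depth = 16L,
                       provenance = NULL) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop("`channels` must be a non-empty named list of matrices")
  }
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop("all channels must be matrices")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1L) {
    stop("all channels must share the same shape")
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number (um/px)")
  }
  structure(
    list(channels = channels, pixel_size = pixel_size,
         bit_depth = as.integer(bit_depth), provenance = provenance),
    class = "micrograph"
  )
}

#' @export
print.micrograph <- function(x, ...) {
  d <- dim(x$channels[[1]])
  cat(sprintf(
    "<micrograph> %d x %d px (%.1f x %.1f um), %d-bit\n  channels: %s\n",
    d[1], d[2], d[1] * x$pixel_size, d[2] * x$pixel_size, x$bit_depth,
    paste(names(x$channels), collapse = ", ")
  ))
  if (!is.null(x$provenance)) cat("  provenance:", format(x$provenance), "\n")
  invisible(x)
}

# Fetch a channel or fail with a named error (segmentation and intensity
# stages must not silently fall back to another channel).
get_channel <- function(mg, name) {
  stopifnot(inherits(mg, "micrograph"))
  ch <- mg$channels[[name]]
  if (is.null(ch)) {
    stop(sprintf("micrograph has no '%s' channel (present: %s)", name,
                 paste(names(mg$channels), collapse = ", ")), call. = FALSE)
  }
  ch
}

#' Write a micrograph as 16-bit TIFF files
#'
#' One single-channel TIFF per channel, named `<prefix>_<channel>.tif`.
#'
#' @param mg A [micrograph()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Invisibly, the written paths.
#' @export
write_micrograph <- function(mg, dir, prefix = "field") {
  stopifnot(inherits(mg, "micrograph"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mx <- 2^mg$bit_depth - 1
  paths <- character(0)
  for (nm in names(mg$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    EBImage::writeImage(EBImage::Image(mg$channels[[nm]] / mx), p,
                        type = "tiff", bits.per.sample = 16L)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Read single-channel TIFF/PNG images into a micrograph
#'
#' @param paths Named character vector of image paths; names become channel
#'   names.
#' @param pixel_size Pixel size in um/px.
#' @param bit_depth Bits per sample used to rescale intensities back to
#'   integer grey levels (default 16).
#' @return A [micrograph()].
#' @export
read_micrograph <- function(paths, pixel_size, bit_depth = 16L) {
  if (is.null(names(paths)) || any(!nzchar(names(paths)))) {
    stop("`paths` must be named by channel")
  }
  mx <- 2^bit_depth - 1
  channels <- lapply(paths, function(p) {
    img <- EBImage::readImage(p)
    if (length(dim(img)) > 2L) img <- img[, , 1]
    round(as.matrix(EBImage::imageData(img)) * mx)
  })
  micrograph(channels, pixel_size, bit_depth = bit_depth,
             provenance = unname(paths[1]))
}
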