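#' Calibrate the background threshold from a primary-negative image
#'
#' The background threshold is the smallest integer grey level T such
#' that at most 1\% of the initially positive pixels (grey level above 0)
#' of a primary-negative image remain above T — i.e. thresholding at T
#' removes at least 99\% of positive pixel coverage. An all-zero image
#' calibrates to T = 0.
#'
#' @param x A single-channel [micrograph()] (its `marker` or only
#'   channel), or a grey-level matrix.
#' @param channel Channel to use when `x` is a micrograph.
#' @return Object of class `intensity_calibration`: `threshold` (integer
#'   grey level), `removed_fraction` (fraction of positive pixels at or
#'   below the threshold, >= 0.99 by construction when positives exist),
#'   `n_positive`, `bit_depth`, `source`.
#' @examples
#' img <- matrix(rep(1:100, each = 10), 25, 40)
#' calibrate_background(img)$threshold  # 99
#' @export
calibrate_background <- function(x, channel = "marker") {
  src <- NULL
  bit_depth <- 16L
  if (inherits(x, "micrograph")) {
    src <- x$provenance
    bit_depth <- x$bit_depth
    x <- if (length(x$channels) == 1L) x$channels[[1]] else
      get_channel(x, channel)
  }
  v <- as.integer(x)
  if (any(v < 0)) stop("grey levels must be non-negative integers")
  pos <- v[v > 0L]
  n_pos <- length(pos)
  if (n_pos == 0L) {
    thr <- 0L
    removed <- 1
  } else {
    allowed <- floor(0.01 * n_pos)
    # count of pixels above t, for every integer t, via a top-down
    # cumulative histogram; T = smallest t with above(t) <= allowed
    tab <- tabulate(pos, nbins = max(pos))
    above <- rev(cumsum(rev(tab)))      # above[t] = #(pos >= t) ...
    above_t <- c(above[-1], 0L)          # ... shift: #(pos > t), t = 1..max
    thr <- if (n_pos <= allowed) 0L else
      as.integer(which(above_t <= allowed)[1])
    removed <- sum(pos <= thr) / n_pos
  }
  structure(list(threshold = thr, removed_fraction = removed,
                 n_positive = n_pos, bit_depth = bit_depth, source = src),
            class = "intensity_calibration")
}

#' @export
print.intensity_calibration <- function(x, ...) {
  cat(sprintf(
    "<intensity_calibration> threshold %d (removes %.2f%% of %d positive px)\n",
    x$threshold, 100 * x$removed_fraction, x$n_positive))
  invisible(x)
}

#' Remove background fluorescence from an image
#'
#' Masking semantics: pixels at or below the calibrated threshold are set
#' to 0; pixels above keep their original value. (Coverage and
#' per-nucleus intensity count and sum signal *above* background, which
#' masking implements exactly; values are not shifted.)
#'
#' @param x Grey-level matrix or [micrograph()] (marker channel).
#' @param calibration An [calibrate_background()] result, or an integer
#'   threshold.
#' @param channel Channel used when `x` is a micrograph.
#' @return Corrected grey-level matrix.
#' @export
subtract_background <- function(x, calibration, channel = "marker") {
  if (inherits(x, "micrograph")) {
    if (inherits(calibration, "intensity_calibration") &&
        !is.null(calibration$bit_depth) &&
        calibration$bit_depth != x$bit_depth) {
      stop(sprintf("bit depth mismatch: image is %d-bit, calibration %d-bit",
                   x$bit_depth, calibration$bit_depth))
    }
    x <- if (length(x$channels) == 1L) x$channels[[1]] else
      get_channel(x, channel)
  }
  thr <- if (inherits(calibration, "intensity_calibration")) {
    calibration$threshold
  } else calibration
  x[x <= thr] <- if (is.integer(x)) 0L else 0
  x
}

#' Marker coverage of an image
#'
#' Percentage of image pixels expressing above background: 100 x
#' (non-zero pixels) / (total pixels) of a background-corrected image.
#'
#' @param corrected Background-corrected grey-level matrix
#'   ([subtract_background()]).
#' @return Coverage in percent.
#' @export
coverage <- function(corrected) {
  100 * sum(corrected > 0) / length(corrected)
}

#' Marker intensity per nucleus
#'
#' Total image pixel intensity above background divided by the total
#' image nuclei count; normalising to nuclei number removes the effect of
#' differing nuclei counts between conditions on a predominantly nuclear
#' marker. Optionally expressed as fold over a control mean.
#'
#' @param corrected Background-corrected grey-level matrix.
#' @param n_nuclei Total nuclei in the image (> 0; 0 yields `NA`).
#' @param control_mean Optional control-group mean of the same quantity;
#'   when given, `fold = value / control_mean`.
#' @return List with `value` (grey-level sum per nucleus) and `fold`
#'   (`NA` when no control mean is supplied).
#' @export
intensity_per_nucleus <- function(corrected, n_nuclei, control_mean = NULL) {
  if (n_nuclei <= 0) {
    warning("nuclei count is zero; intensity per nucleus undefined")
    return(list(value = NA_real_, fold = NA_real_))
  }
  value <- sum(as.numeric(corrected)) / n_nuclei
  fold <- if (is.null(control_mean)) NA_real_ else value / control_mean
  list(value = value, fold = fold)
}

#' Mean marker intensity over a myotube mask
#'
#' @param corrected Background-corrected grey-level matrix.
#' @param mask Logical mask of the instance, or a label matrix together
#'   with `id`.
#' @param id Instance label when `mask` is a label matrix.
#' @return Mean corrected grey level over the mask.
#' @export
myotube_mean_intensity <- function(corrected, mask, id = NULL) {
  m <- if (!is.null(id)) mask == id else mask > 0
  if (!any(m)) stop("empty instance mask")
  mean(corrected[m])
}

#' Percentage of marker-positive nuclei
#'
#' A nucleus is marker-positive iff at least `positive_fraction` of its
#' footprint pixels are non-zero in the background-corrected marker image
#' (operationalising the overlap of marker signal with the DAPI channel).
#' Footprints are discs of `diameter` around each centroid.
#'
#' @param corrected Background-corrected marker matrix.
#' @param centroids data.frame with `row`, `col` ([detect_nuclei()]
#'   output).
#' @param diameter Nucleus footprint diameter in um.
#' @param pixel_size Pixel size in um/px.
#' @param positive_fraction Fraction of footprint pixels that must be
#'   positive (default 0.5).
#' @return List with `pct` (100 x positives / nuclei) and `positive`
#'   (per-nucleus logical).
#' @export
positive_nuclei_pct <- function(corrected, centroids, diameter = 10,
                                pixel_size = 0.65, positive_fraction = 0.5) {
  n <- nrow(centroids)
  if (n == 0L) stop("need at least one nucleus")
  r_px <- diameter / (2 * pixel_size)
  nr <- nrow(corrected); nc <- ncol(corrected)
  pos <- logical(n)
  for (k in seq_len(n)) {
    r0 <- centroids$row[k]; c0 <- centroids$col[k]
    rs <- max(1L, as.integer(floor(r0 - r_px))):min(nr, as.integer(ceiling(r0 + r_px)))
    cs <- max(1L, as.integer(floor(c0 - r_px))):min(nc, as.integer(ceiling(c0 + r_px)))
    d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
    foot <- corrected[rs, cs][d2 <= r_px^2]
    pos[k] <- mean(foot > 0) >= positive_fraction
  }
  list(pct = 100 * sum(pos) / n, positive = pos)
}
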