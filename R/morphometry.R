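#' Segment myotube candidates from the actin channel
#'
#' Connected components of the thresholded actin (phalloidin) channel with
#' area at or above `min_area`. Thresholding is Otsu by default (the
#' original measurements were manual tracings; a global threshold is the
#' reproducible counterpart). Deterministic for fixed inputs.
#'
#' @param mg A [micrograph()] with an `actin` channel.
#' @param min_area Minimum candidate area in um^2 (default 50).
#' @param threshold `"otsu"` or a numeric grey level.
#' @return An object of class `myotube_candidates`: list with `labels`
#'   (integer label matrix, 0 = background, ids relabelled 1..n after area
#'   filtering), `table` (data.frame: `id`, `area_um2`) and `pixel_size`.
#' @examples
#' f <- generate_field(condition_params("control", noise_sd = 0), seed = 2,
#'                     fov_shape = c(256, 256))
#' cand <- segment_myotubes(f$micrograph)
#' nrow(cand$table)
#' @export
segment_myotubes <- function(mg, min_area = 50, threshold = "otsu") {
  actin <- get_channel(mg, "actin")
  mx <- 2^mg$bit_depth - 1
  thr <- if (identical(threshold, "otsu")) {
    if (max(actin) == min(actin)) {
      mx + 1  # flat channel: nothing segmentable
    } else {
      EBImage::otsu(EBImage::Image(actin / mx), range = c(0, 1),
                    levels = 256L) * mx
    }
  } else if (is.numeric(threshold)) {
    threshold
  } else {
    stop("`threshold` must be \"otsu\" or a numeric grey level")
  }
  bw <- actin > thr
  labels <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(bw * 1)))
  labels <- matrix(as.integer(labels), nrow(actin), ncol(actin))
  if (max(labels) > 0L) {
    px <- tabulate(labels, nbins = max(labels))
    keep <- which(px * mg$pixel_size^2 >= min_area)
    remap <- integer(max(labels))
    remap[keep] <- seq_along(keep)
    labels <- matrix(ifelse(labels > 0L, remap[pmax(labels, 1L)], 0L),
                     nrow(labels), ncol(labels))
    areas <- px[keep] * mg$pixel_size^2
  } else {
    areas <- numeric(0)
  }
  structure(list(labels = labels,
                 table = data.frame(id = seq_along(areas),
                                    area_um2 = areas),
                 pixel_size = mg$pixel_size),
            class = "myotube_candidates")
}

#' @export
print.myotube_candidates <- function(x, ...) {
  cat(sprintf("<myotube_candidates> %d candidates, %.2f um/px\n",
              nrow(x$table), x$pixel_size))
  invisible(x)
}

#' Detect nuclei in the DAPI channel
#'
#' Blob detection: Gaussian smoothing, Otsu thresholding, then local
#' intensity maxima separated by at least `min_diameter`. Touching nuclei
#' are declumped by counting maxima, so a clump yields one centroid per
#' resolvable intensity peak. Deterministic for fixed input.
#'
#' @param mg A [micrograph()] with a `dapi` channel.
#' @param min_diameter Minimum resolvable nucleus diameter in um
#'   (default 7); maxima closer than this are merged (brightest kept).
#' @return data.frame with columns `id`, `row`, `col` (pixel centroids).
#' @export
detect_nuclei <- function(mg, min_diameter = 7) {
  dapi <- get_channel(mg, "dapi")
  mx <- 2^mg$bit_depth - 1
  if (max(dapi) == min(dapi)) {
    return(data.frame(id = integer(0), row = numeric(0), col = numeric(0)))
  }
  d_px <- min_diameter / mg$pixel_size
  img <- EBImage::Image(dapi / mx)
  sm <- EBImage::gblur(img, sigma = max(d_px / 4, 1), boundary = "replicate")
  thr <- EBImage::otsu(sm, range = c(0, 1), levels = 256L)
  # local maxima: pixels equal to the grey-scale dilation over a disc
  sz <- 2L * as.integer(floor(d_px / 2)) + 1L
  mxf <- EBImage::dilate(sm, EBImage::makeBrush(max(sz, 3L), "disc"))
  smm <- EBImage::imageData(sm)
  ismax <- smm >= EBImage::imageData(mxf) & smm > thr
  ismax[c(1:2, nrow(ismax) - 1:0), ] <- FALSE  # border guard
  ismax[, c(1:2, ncol(ismax) - 1:0)] <- FALSE
  cand <- which(ismax, arr.ind = TRUE)
  if (nrow(cand) == 0L) {
    return(data.frame(id = integer(0), row = numeric(0), col = numeric(0)))
  }
  val <- smm[cand]
  ord <- order(val, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  # greedy non-maximum suppression at min_diameter (ties/plateaus merge)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (i == 1L) { keep[1] <- TRUE; next }
    kept <- cand[keep, , drop = FALSE]
    keep[i] <- all((kept[, 1] - cand[i, 1])^2 +
                     (kept[, 2] - cand[i, 2])^2 >= d_px^2)
  }
  out <- cand[keep, , drop = FALSE]
  data.frame(id = seq_len(nrow(out)), row = out[, 1], col = out[, 2])
}

#' Assign nuclei to myotube candidates
#'
#' A nucleus belongs to a candidate iff its centroid pixel lies inside the
#' candidate's mask (mask pixels are inclusive of the boundary). Each
#' nucleus is assigned to at most one mask; with overlapping masks (only
#' possible when `candidates` is a list of logical masks) a nucleus whose
#' centroid falls in two masks is assigned to neither and flagged.
#'
#' @param candidates A [segment_myotubes()] result, an integer label
#'   matrix, or a list of logical mask matrices (which may overlap).
#' @param centroids data.frame with `row`, `col` columns
#'   ([detect_nuclei()] output).
#' @return data.frame with one row per candidate: `id`, `nuclei`. The
#'   per-nucleus assignment (`NA` = background or overlap conflict) is in
#'   attribute `"assignment"`; conflicted nucleus indices in
#'   attribute `"overlap_flagged"`.
#' @export
assign_nuclei <- function(candidates, centroids) {
  if (inherits(candidates, "myotube_candidates")) {
    labels <- candidates$labels
  } else if (is.matrix(candidates)) {
    labels <- candidates
  } else if (is.list(candidates)) {
    return(.assign_nuclei_masks(candidates, centroids))
  } else {
    stop("`candidates` must be a segmentation, label matrix or mask list")
  }
  n_obj <- max(labels, 0L)
  lab_at <- if (nrow(centroids)) {
    labels[cbind(pmin(pmax(as.integer(round(centroids$row)), 1L), nrow(labels)),
                 pmin(pmax(as.integer(round(centroids$col)), 1L), ncol(labels)))]
  } else integer(0)
  counts <- tabulate(lab_at[lab_at > 0L], nbins = n_obj)
  out <- data.frame(id = seq_len(n_obj), nuclei = counts)
  attr(out, "assignment") <- ifelse(lab_at > 0L, lab_at, NA_integer_)
  attr(out, "overlap_flagged") <- integer(0)
  out
}

.assign_nuclei_masks <- function(masks, centroids) {
  n_obj <- length(masks)
  n_nuc <- nrow(centroids)
  assignment <- rep(NA_integer_, n_nuc)
  flagged <- integer(0)
  for (k in seq_len(n_nuc)) {
    r <- as.integer(round(centroids$row[k]))
    c <- as.integer(round(centroids$col[k]))
    inside <- which(vapply(masks, function(m) {
      r >= 1 && c >= 1 && r <= nrow(m) && c <= ncol(m) && isTRUE(m[r, c] > 0)
    }, logical(1)))
    if (length(inside) == 1L) {
      assignment[k] <- inside
    } else if (length(inside) > 1L) {
      flagged <- c(flagged, k)  # overlap conflict: assigned to neither
    }
  }
  counts <- tabulate(assignment[!is.na(assignment)], nbins = n_obj)
  out <- data.frame(id = seq_len(n_obj), nuclei = counts)
  attr(out, "assignment") <- assignment
  attr(out, "overlap_flagged") <- flagged
  out
}

#' Filter candidates by the myotube definition
#'
#' A myotube is a single actin-defined fibre containing three or more
#' nuclei; candidates below `min_nuclei` are excluded with a reason.
#'
#' @param counts data.frame with `id` and `nuclei` columns
#'   ([assign_nuclei()] output, possibly merged with other per-candidate
#'   columns).
#' @param min_nuclei Minimum nuclei per retained myotube (default 3).
#' @return List with `retained` and `excluded` data.frames; `excluded`
#'   gains a `reason` column.
#' @examples
#' filter_myotubes(data.frame(id = 1:5, nuclei = 1:5))$retained$id
#' @export
filter_myotubes <- function(counts, min_nuclei = 3) {
  stopifnot(all(c("id", "nuclei") %in% names(counts)))
  keep <- counts$nuclei >= min_nuclei
  excluded <- counts[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- sprintf("fewer than %d nuclei (%d)", min_nuclei,
                               excluded$nuclei)
  } else {
    excluded$reason <- character(0)
  }
  list(retained = counts[keep, , drop = FALSE], excluded = excluded)
}
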