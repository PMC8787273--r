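#' Medial-axis width profile of a myotube
#'
#' Local fibre width along the medial axis: twice the Euclidean
#' distance-transform value at each skeleton point, in micrometres. The
#' skeleton's end segments (`trim_frac` of the path at each tip, default
#' 5\%) are excluded to avoid thinning-tip artefacts, and any point whose
#' inscribed width disc touches another instance's mask is excluded, so
#' diameters are only read where they are not interfered with by an
#' overlapping myotube.
#'
#' @param mask Logical/0-1 matrix of one myotube instance.
#' @param pixel_size Pixel size in um/px.
#' @param labels Optional label matrix of *all* instances in the field
#'   (used for the overlap-interference exclusion).
#' @param id Label of this instance within `labels`.
#' @param trim_frac Fraction of skeleton points dropped at each end.
#' @return data.frame with `row`, `col`, `width_um` for each retained
#'   medial-axis point, ordered along the axis. Zero rows with attribute
#'   `"unmeasurable" = TRUE` when the skeleton is shorter than 3 points.
#' @export
width_profile <- function(mask, pixel_size, labels = NULL, id = NULL,
                          trim_frac = 0.05) {
  mask <- mask > 0
  if (!any(mask)) stop("empty mask")
  empty <- data.frame(row = integer(0), col = integer(0),
                      width_um = numeric(0))

  # operate on the instance bounding box (1-px pad keeps the background
  # border the distance transform needs)
  rng <- apply(which(mask, arr.ind = TRUE), 2L, range)
  r0 <- max(rng[1, 1] - 1L, 1L); r1 <- min(rng[2, 1] + 1L, nrow(mask))
  c0 <- max(rng[1, 2] - 1L, 1L); c1 <- min(rng[2, 2] + 1L, ncol(mask))
  sub <- mask[r0:r1, c0:c1, drop = FALSE]

  sk <- skeletonize(sub)
  path <- skeleton_path(sk)
  if (nrow(path) < 2L) {
    # compact (near-circular) masks thin down to one or two pixels; the
    # medial axis degenerates to the centre, where the width disc is the
    # inscribed disc. Report that single width twice (max = min there).
    if (nrow(path) == 1L) path <- path[c(1L, 1L), , drop = FALSE]
    else {
      attr(empty, "unmeasurable") <- TRUE
      return(empty)
    }
  }
  dm <- EBImage::imageData(EBImage::distmap(EBImage::Image(sub * 1)))
  w_px <- 2 * dm[path]

  trim <- ceiling(trim_frac * nrow(path))
  keep <- seq_len(nrow(path)) > trim & seq_len(nrow(path)) <= nrow(path) - trim
  if (sum(keep) >= 2L) {  # keep short axes untrimmed rather than empty
    path <- path[keep, , drop = FALSE]
    w_px <- w_px[keep]
  }

  if (!is.null(labels) && !is.null(id) && length(w_px)) {
    # widen the crop so neighbouring instances within one inscribed-disc
    # radius are visible to the interference check
    pad <- as.integer(ceiling(max(w_px) / 2)) + 2L
    R0 <- max(r0 - pad, 1L); C0 <- max(c0 - pad, 1L)
    R1 <- min(r1 + pad, nrow(labels)); C1 <- min(c1 + pad, ncol(labels))
    lab_sub <- labels[R0:R1, C0:C1, drop = FALSE]
    others <- lab_sub > 0L & lab_sub != id
    if (any(others)) {
      # distance from every pixel to the nearest other-instance pixel
      d_other <- EBImage::imageData(EBImage::distmap(EBImage::Image((!others) * 1)))
      shift <- cbind(path[, "row"] + (r0 - R0), path[, "col"] + (c0 - C0))
      clear <- d_other[shift] > w_px / 2 + 1
      path <- path[clear, , drop = FALSE]
      w_px <- w_px[clear]
    }
  }
  if (nrow(path) < 2L) {
    attr(empty, "unmeasurable") <- TRUE
    return(empty)
  }
  data.frame(row = path[, "row"] + (r0 - 1L), col = path[, "col"] + (c0 - 1L),
             width_um = w_px * pixel_size)
}

#' Diameter difference ratio of a width profile
#'
#' DDR = largest diameter / smallest diameter along the fibre. The
#' classification statistic separating linear from fusiform (bag)
#' myotubes.
#'
#' @param profile A [width_profile()] result, or a numeric vector of
#'   widths.
#' @return DDR (>= 1).
#' @examples
#' compute_ddr(c(20, 5))
#' @export
compute_ddr <- function(profile) {
  w <- if (is.data.frame(profile)) profile$width_um else profile
  if (length(w) < 2L) stop("width profile needs at least 2 retained points")
  if (min(w) <= 0) stop("degenerate mask: minimum width is zero")
  max(w) / min(w)
}

#' Derive DDR classification thresholds from training myotubes
#'
#' From manually classified training fibres, the per-class mean and sample
#' standard deviation (n - 1 denominator) of the DDR define the class
#' ranges: linear cutoff = linear mean + 1 SD, bag cutoff = bag mean - 1
#' SD. The band in between is left unassigned. Fails loudly when the two
#' populations are not separable (linear cutoff at or above bag cutoff).
#'
#' @param linear_ddrs,bag_ddrs Numeric vectors of training DDRs (>= 2
#'   values each).
#' @return Object of class `ddr_thresholds` with fields `linear_mean`,
#'   `linear_sd`, `bag_mean`, `bag_sd`, `linear_cutoff`, `bag_cutoff`.
#' @examples
#' thr <- derive_thresholds(c(1.44, 1.81, 2.18), c(2.71, 4.03, 5.35))
#' c(thr$linear_cutoff, thr$bag_cutoff)
#' @export
derive_thresholds <- function(linear_ddrs, bag_ddrs) {
  if (length(linear_ddrs) < 2L || length(bag_ddrs) < 2L) {
    stop("need at least 2 training DDR values per class")
  }
  if (any(c(linear_ddrs, bag_ddrs) < 1)) stop("DDR values must be >= 1")
  thr <- list(linear_mean = mean(linear_ddrs),
              linear_sd = stats::sd(linear_ddrs),
              bag_mean = mean(bag_ddrs),
              bag_sd = stats::sd(bag_ddrs))
  thr$linear_cutoff <- thr$linear_mean + thr$linear_sd
  thr$bag_cutoff <- thr$bag_mean - thr$bag_sd
  if (thr$linear_cutoff >= thr$bag_cutoff) {
    stop(sprintf(
      "populations not separable: linear cutoff %.3f >= bag cutoff %.3f",
      thr$linear_cutoff, thr$bag_cutoff))
  }
  if (thr$bag_cutoff <= 0) stop("bag cutoff must be positive")
  structure(thr, class = "ddr_thresholds")
}

#' Construct thresholds directly from summary statistics
#'
#' Convenience constructor when the per-class mean and SD are already
#' known (e.g. from a reported training-set table) rather than raw values.
#'
#' @param linear_mean,linear_sd,bag_mean,bag_sd Class summaries.
#' @return A `ddr_thresholds` object (see [derive_thresholds()]).
#' @export
ddr_thresholds <- function(linear_mean, linear_sd, bag_mean, bag_sd) {
  # delegate through symmetric triples realising the requested mean/SD
  derive_thresholds(linear_mean + c(-linear_sd, 0, linear_sd),
                    bag_mean + c(-bag_sd, 0, bag_sd))
}

#' @export
print.ddr_thresholds <- function(x, ...) {
  cat(sprintf(
    paste0("<ddr_thresholds>\n  linear: %.2f +/- %.2f  (linear iff DDR <= %.2f)\n",
           "  bag:    %.2f +/- %.2f  (bag iff DDR >= %.2f)\n",
           "  unassigned band: (%.2f, %.2f)\n"),
    x$linear_mean, x$linear_sd, x$linear_cutoff,
    x$bag_mean, x$bag_sd, x$bag_cutoff, x$linear_cutoff, x$bag_cutoff))
  invisible(x)
}

#' Classify myotubes by DDR
#'
#' DDR at or below the linear cutoff is linear; at or above the bag
#' cutoff is bag; strictly between the cutoffs is unassigned (both
#' boundaries inclusive to their named class).
#'
#' @param ddr Numeric vector of DDR values (>= 1).
#' @param thresholds A `ddr_thresholds` object.
#' @return Factor with levels `linear`, `unassigned`, `bag`.
#' @examples
#' thr <- ddr_thresholds(1.81, 0.37, 4.03, 1.32)
#' classify_ddr(c(2.18, 2.5, 2.71), thr)
#' @export
classify_ddr <- function(ddr, thresholds) {
  stopifnot(inherits(thresholds, "ddr_thresholds"))
  if (any(is.na(ddr)) || any(ddr < 1)) {
    stop("DDR values must be >= 1 and non-missing")
  }
  eps <- 1e-9  # boundary inclusivity robust to floating-point cutoffs
  out <- ifelse(ddr <= thresholds$linear_cutoff + eps, "linear",
                ifelse(ddr >= thresholds$bag_cutoff - eps, "bag",
                       "unassigned"))
  factor(out, levels = c("linear", "unassigned", "bag"))
}

#' Field-level myogenic summary
#'
#' Class percentages over retained myotubes, fusion efficiency (nuclei
#' within myotubes / total image nuclei x 100), counts per field, mean
#' myotube area per myonucleus, and per-class nuclei-per-myotube means.
#'
#' @param instances data.frame of retained myotubes with columns `class`,
#'   `nuclei`, `area_um2` (e.g. from [measure_field()]).
#' @param total_nuclei Total nuclei detected in the field (>= nuclei in
#'   instances).
#' @param include_unassigned Include unassigned myotubes in the class
#'   percentage denominator (default `TRUE`).
#' @return One-row data.frame: `myotubes_per_fov`, `nuclei_per_fov`,
#'   `bag_pct`, `linear_pct`, `unassigned_pct`, `fusion_efficiency`,
#'   `mean_area_per_nucleus`, `nuclei_per_linear`, `nuclei_per_bag`.
#'   Fusion efficiency is `NA` when `total_nuclei` is zero.
#' @export
summarise_field <- function(instances, total_nuclei,
                            include_unassigned = TRUE) {
  stopifnot(all(c("class", "nuclei", "area_um2") %in% names(instances)))
  n <- nrow(instances)
  fused <- sum(instances$nuclei)
  if (total_nuclei < fused) {
    stop("`total_nuclei` cannot be below the nuclei inside myotubes")
  }
  cls <- as.character(instances$class)
  denom <- if (include_unassigned) n else sum(cls != "unassigned")
  pct <- function(what) {
    if (denom == 0L) NA_real_ else 100 * sum(cls == what) / denom
  }
  mean_or_na <- function(x) if (length(x)) mean(x) else NA_real_
  data.frame(
    myotubes_per_fov = n,
    nuclei_per_fov = total_nuclei,
    bag_pct = pct("bag"),
    linear_pct = pct("linear"),
    unassigned_pct = if (include_unassigned) pct("unassigned") else NA_real_,
    fusion_efficiency = if (total_nuclei == 0L) NA_real_ else
      100 * fused / total_nuclei,
    mean_area_per_nucleus = mean_or_na(instances$area_um2 / instances$nuclei),
    nuclei_per_linear = mean_or_na(instances$nuclei[cls == "linear"]),
    nuclei_per_bag = mean_or_na(instances$nuclei[cls == "bag"]))
}

#' Full morphometry of one micrograph
#'
#' Orchestrates segmentation, nuclei detection and assignment, the
#' three-or-more-nuclei myotube filter, width profiling, DDR computation
#' and classification, and the field summary.
#'
#' @param mg A [micrograph()] with `actin` and `dapi` channels.
#' @param thresholds A `ddr_thresholds` object.
#' @param min_area,threshold Passed to [segment_myotubes()].
#' @param min_nuclei Passed to [filter_myotubes()].
#' @param min_diameter Passed to [detect_nuclei()].
#' @param trim_frac Passed to [width_profile()].
#' @param include_unassigned Passed to [summarise_field()].
#' @return List of class `field_measurement`: `instances` (per-myotube
#'   `id`, `d_max`, `d_min`, `ddr`, `class`, `nuclei`, `area_um2`),
#'   `summary` ([summarise_field()] row), `nuclei` (detected centroids),
#'   `excluded` (candidates dropped, with reasons) and `candidates` (the
#'   segmentation, for downstream intensity measurements).
#' @export
measure_field <- function(mg, thresholds, min_area = 50, threshold = "otsu",
                          min_nuclei = 3, min_diameter = 7,
                          trim_frac = 0.05, include_unassigned = TRUE) {
  cand <- segment_myotubes(mg, min_area = min_area, threshold = threshold)
  nuc <- detect_nuclei(mg, min_diameter = min_diameter)
  counts <- assign_nuclei(cand, nuc)
  counts <- merge(cand$table, counts, by = "id")
  flt <- filter_myotubes(counts, min_nuclei = min_nuclei)
  excluded <- flt$excluded

  rows <- list()
  for (i in seq_len(nrow(flt$retained))) {
    id <- flt$retained$id[i]
    prof <- width_profile(cand$labels == id, mg$pixel_size,
                          labels = cand$labels, id = id,
                          trim_frac = trim_frac)
    if (isTRUE(attr(prof, "unmeasurable")) || nrow(prof) < 2L) {
      excluded <- rbind(excluded,
                        data.frame(flt$retained[i, c("id", "area_um2", "nuclei")],
                                   reason = "unmeasurable skeleton"))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      id = id, d_max = max(prof$width_um), d_min = min(prof$width_um),
      ddr = compute_ddr(prof), nuclei = flt$retained$nuclei[i],
      area_um2 = flt$retained$area_um2[i])
  }
  instances <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = integer(0), d_max = numeric(0), d_min = numeric(0),
               ddr = numeric(0), nuclei = integer(0), area_um2 = numeric(0))
  instances$class <- if (nrow(instances)) {
    classify_ddr(instances$ddr, thresholds)
  } else {
    factor(character(0), levels = c("linear", "unassigned", "bag"))
  }
  structure(list(
    instances = instances,
    summary = summarise_field(instances, total_nuclei = nrow(nuc),
                              include_unassigned = include_unassigned),
    nuclei = nuc, excluded = excluded, candidates = cand),
    class = "field_measurement")
}

#' @export
print.field_measurement <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<field_measurement> %d myotubes (%0.1f%% bag), %d nuclei, ",
           "fusion efficiency %0.1f%%\n"),
    s$myotubes_per_fov, s$bag_pct %||% NA, s$nuclei_per_fov,
    s$fusion_efficiency))
  invisible(x)
}

#' Match measured instances to generator ground truth
#'
#' Links each ground-truth myotube of a [generate_field()] result to the
#' segmentation label covering its recorded centre, so measured and true
#' per-instance quantities can be compared.
#'
#' @param field A `synthetic_field`.
#' @param candidates A [segment_myotubes()] result on the same field.
#' @return The ground-truth table with a `label` column (`NA` when the
#'   centre pixel is background, e.g. for a dropped instance).
#' @export
match_instances <- function(field, candidates) {
  gt <- field$ground_truth
  labels <- if (inherits(candidates, "myotube_candidates")) {
    candidates$labels
  } else candidates
  gt$label <- if (nrow(gt)) {
    mid_col <- as.integer(round((gt$col_start + gt$col_end) / 2))
    v <- labels[cbind(as.integer(round(gt$row_centre)), mid_col)]
    ifelse(v > 0L, v, NA_integer_)
  } else integer(0)
  gt
}
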