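#' Generate a synthetic fluorescence field with ground truth
#'
#' Renders one field of view of a simulated myotube culture: actin
#' (phalloidin), nuclei (DAPI) and marker (Egr3) channels, together with a
#' ground-truth table recording, for every rendered myotube, its true
#' class, DDR, nuclei count, area and marker intensity. Linear myotubes
#' are rendered as gently tapered tubes with nuclei spread along the axis;
#' bag myotubes as fusiform shapes (Gaussian equatorial bulge spanning
#' roughly the central third) with nuclei clustered at the equator.
#' Unfused mononuclear cells fill the remaining space so that the
#' nuclei-in-myotubes fraction matches the fusion efficiency in
#' expectation. Regenerating with the same parameters and seed is
#' bit-identical.
#'
#' @param params A [condition_params()] object.
#' @param seed Integer seed; all randomness derives from it.
#' @param fov_shape Field size in pixels, `c(rows, cols)`.
#' @param render If `FALSE`, skip channel rasterisation and return ground
#'   truth only (fast path for distributional tests).
#' @return An object of class `synthetic_field`: a list with elements
#'   `micrograph` ([micrograph()] or `NULL`), `ground_truth` (one row per
#'   rendered myotube; `ddr_true` is the realised DDR of the rasterised
#'   width profile, `ddr_drawn` the value sampled from the class
#'   distribution before width quantisation), `nuclei` (one row per
#'   nucleus: position, owning
#'   myotube id or `NA` if unfused, marker positivity), `params`, `seed`,
#'   `fov_shape`, and `n_dropped` (myotubes that did not fit the field).
#' @examples
#' f <- generate_field(condition_params("control"), seed = 1,
#'                     fov_shape = c(256, 256))
#' f$ground_truth[, c("id", "class", "ddr_true", "nuclei")]
#' @export
generate_field <- function(params, seed, fov_shape = c(768, 768),
                           render = TRUE) {
  stopifnot(inherits(params, "condition_params"))
  validate_condition_params(params)
  fov_shape <- as.integer(fov_shape)
  if (length(fov_shape) != 2L || any(fov_shape < 64L)) {
    stop("`fov_shape` must be two pixel dimensions of at least 64")
  }
  ps <- params$pixel_size
  if (min(fov_shape) * ps < 3 * params$mean_width) {
    stop("field of view too small to hold a single fibre")
  }
  with_seed(seed, .generate_field_impl(params, seed, fov_shape, render))
}

#' Analytic fibre width profile
#'
#' Width (um) of a rendered fibre at axial positions `t_um` relative to
#' the equator: `w(t) = w_min + (w_max - w_min) * exp(-t^2 / (2 sigma^2))`
#' with `sigma = length/8`, so the equatorial bulge spans roughly the
#' central third of the fibre. Linear myotubes use the same closed form
#' at their (small) drawn DDR, which renders as a gently tapered tube.
#'
#' @param t_um Axial positions relative to the fibre centre (um).
#' @param length_um Fibre length (um).
#' @param w_min,w_max Pole and equator widths (um).
#' @return Width in um at each `t_um`.
#' @export
fibre_width_um <- function(t_um, length_um, w_min, w_max) {
  sig <- length_um / 8
  w_min + (w_max - w_min) * exp(-t_um^2 / (2 * sig^2))
}

# mean of the unit bulge over the fibre length (analytic, used to convert
# a target mean width into w_min at a given DDR)
.bulge_mean_factor <- function() sqrt(2 * pi) / 8 * (2 * stats::pnorm(4) - 1)

.generate_field_impl <- function(params, seed, fov_shape, render) {
  ps <- params$pixel_size
  nr <- fov_shape[1]; nc <- fov_shape[2]

  total_nuclei <- stats::rpois(1L, params$nuclei_per_fov_mean)
  n_myo <- stats::rpois(1L, params$myotubes_per_fov)
  fused_target <- stats::rbinom(1L, total_nuclei, params$fusion_efficiency)
  if (n_myo > 0L && fused_target < 3L * n_myo) {
    n_myo <- fused_target %/% 3L  # not enough nuclei to satisfy >=3 each
  }

  gt <- data.frame(id = integer(0), class = character(0),
                   ddr_true = numeric(0), ddr_drawn = numeric(0),
                   nuclei = integer(0),
                   area_um2 = numeric(0), marker_intensity = numeric(0),
                   length_um = numeric(0), w_min_um = numeric(0),
                   w_max_um = numeric(0), row_centre = numeric(0),
                   col_start = integer(0), col_end = integer(0))
  nuclei_df <- data.frame(id = integer(0), fibre_id = integer(0),
                          row = numeric(0), col = numeric(0),
                          positive = logical(0))
  n_dropped <- 0L
  fibres <- list()

  if (n_myo > 0L) {
    is_bag <- stats::rbinom(n_myo, 1L, params$bag_fraction) == 1L
    cls <- ifelse(is_bag, "bag", "linear")
    ddr <- vapply(seq_len(n_myo), function(i) {
      mu <- if (is_bag[i]) params$bag_ddr_mean else params$linear_ddr_mean
      sdv <- if (is_bag[i]) params$bag_ddr_sd else params$linear_ddr_sd
      repeat {
        d <- stats::rnorm(1L, mu, sdv)
        if (d > 1) return(d)
      }
    }, numeric(1))
    m_w <- pmin(pmax(stats::rnorm(n_myo, params$mean_width,
                                  params$mean_width_sd),
                     0.6 * params$mean_width), 1.6 * params$mean_width)

    # allocate fused nuclei: gamma-weighted multinomial with class-mean
    # weights (negative-binomial-like overdispersion via nb_dispersion)
    mu_n <- ifelse(is_bag, params$nuclei_per_bag_mean,
                   params$nuclei_per_linear_mean)
    g <- stats::rgamma(n_myo, shape = params$nb_dispersion,
                       rate = params$nb_dispersion / mu_n)
    cnt <- as.integer(stats::rmultinom(1L, fused_target, g / sum(g)))
    while (any(cnt < 3L)) {
      i <- which.min(cnt); j <- which.max(cnt)
      cnt[i] <- cnt[i] + 1L; cnt[j] <- cnt[j] - 1L
    }

    bm <- .bulge_mean_factor()
    w_min <- m_w / (1 + bm * (ddr - 1))
    # keep poles measurable (floor at 10 px) and snap the pole width to
    # the renderable even-pixel grid so the flat pole region rasterises
    # at one exact width; the drawn DDR is preserved by scaling the bulge
    w_min <- pmax(w_min, 10 * ps)
    w_min <- 2 * ps * round(w_min / (2 * ps))
    w_max <- ddr * w_min
    m_eff <- w_min * (1 + bm * (ddr - 1))
    len_um <- pmin(pmax(params$area_per_nucleus_mean * cnt / m_eff,
                        pmax(70, 6 * w_max)),
                   0.9 * nc * ps)

    # vertical slot packing (non-overlapping placement); fibres that do
    # not fit are dropped and their nuclei returned to the unfused pool
    ord <- sample.int(n_myo)
    gap_px <- 12L
    cursor <- 1L
    for (i in ord) {
      slot <- as.integer(ceiling(w_max[i] / ps)) + gap_px
      if (cursor + slot > nr) { n_dropped <- n_dropped + 1L; next }
      yc <- cursor + slot / 2 + stats::runif(1L, -2, 2)
      len_px <- as.integer(round(len_um[i] / ps))
      len_px <- min(len_px, nc - 8L)
      x0 <- as.integer(stats::runif(1L, 4L, nc - len_px - 3L))
      fibres[[length(fibres) + 1L]] <- list(
        idx = i, class = cls[i], ddr = ddr[i], cnt = cnt[i],
        w_min = w_min[i], w_max = w_max[i], len_um = len_px * ps,
        yc = yc, x0 = x0, len_px = len_px)
      cursor <- cursor + slot
    }
  }

  # rasterised extent of every placed fibre (row count per column is the
  # rounded width in px, so the rendered mask realises the true profile)
  occ <- matrix(0L, nr, nc)  # instance labels, ground-truth ids
  col_heights <- vector("list", length(fibres))
  for (fi in seq_along(fibres)) {
    f <- fibres[[fi]]
    cols <- f$x0 + seq_len(f$len_px) - 1L
    t_um <- (seq_len(f$len_px) - (f$len_px + 1) / 2) * ps
    w_um <- fibre_width_um(t_um, f$len_um, f$w_min, f$w_max)
    # even row counts: the distance transform then recovers the rendered
    # width exactly at the medial axis (2 * k/2 = k)
    k <- pmax(2L, 2L * as.integer(round(w_um / (2 * ps))))
    top <- as.integer(floor(f$yc - k / 2)) + 1L
    bot <- top + k - 1L
    top <- pmax(top, 1L); bot <- pmin(bot, nr)
    col_heights[[fi]] <- k
    for (u in seq_along(cols)) occ[top[u]:bot[u], cols[u]] <- fi
    fibres[[fi]]$cols <- cols
    fibres[[fi]]$w_um <- w_um
    fibres[[fi]]$area_um2 <- sum(k) * ps^2
    # the realised DDR of the rasterised profile (width quantisation can
    # shift it slightly off the drawn value); end caps are excluded as in
    # the measurement convention. This is the instance truth.
    tr <- ceiling(0.05 * length(k))
    kc <- k[(tr + 1L):(length(k) - tr)]
    fibres[[fi]]$ddr_real <- max(kc) / min(kc)
    fibres[[fi]]$top <- top
    fibres[[fi]]$bot <- bot
  }

  # ---- nuclei placement (hard-core: centres >= nucleus_diameter apart) ----
  d_px <- params$nucleus_diameter / ps
  placed <- matrix(numeric(0), ncol = 2)
  place_ok <- function(r, c) {
    if (r < 3 || c < 3 || r > nr - 2 || c > nc - 2) return(FALSE)
    if (nrow(placed) == 0L) return(TRUE)
    all((placed[, 1] - r)^2 + (placed[, 2] - c)^2 >= d_px^2)
  }
  nuc_rows <- numeric(0); nuc_cols <- numeric(0)
  nuc_fibre <- integer(0); nuc_pos <- logical(0)

  for (fi in seq_along(fibres)) {
    f <- fibres[[fi]]
    pf <- params$positive_nuclei_fraction_by_type[[f$class]]
    n_i <- f$cnt
    sx <- if (f$class == "bag") f$len_px / 10 else NA
    for (k in seq_len(n_i)) {
      sxk <- sx
      for (att in 1:400) {
        if (f$class == "bag") {
          if (att %% 60 == 0) sxk <- sxk * 1.5  # relax clustering if crowded
          xo <- stats::rnorm(1L, f$len_px / 2, sxk)
        } else {
          xo <- f$len_px * (k - 0.5) / n_i +
            stats::rnorm(1L, 0, f$len_px / (4 * n_i))
        }
        xo <- min(max(xo, 1), f$len_px)
        u <- as.integer(round(xo))
        half_h <- (f$bot[u] - f$top[u]) / 2
        slack <- max(half_h - 0.45 * d_px, 0.5)
        r <- (f$top[u] + f$bot[u]) / 2 + stats::rnorm(1L, 0, slack / 2)
        r <- min(max(r, f$top[u] + 1), f$bot[u] - 1)
        c <- f$x0 + u - 1L
        if (place_ok(r, c)) break
      }
      placed <- rbind(placed, c(r, c))
      nuc_rows <- c(nuc_rows, r); nuc_cols <- c(nuc_cols, c)
      nuc_fibre <- c(nuc_fibre, fi)
      nuc_pos <- c(nuc_pos, stats::runif(1L) < pf)
    }
  }

  n_unfused <- max(total_nuclei - length(nuc_rows), 0L)
  pf_un <- params$positive_nuclei_fraction_by_type[["linear"]]
  free_margin <- 1.2 * d_px
  for (k in seq_len(n_unfused)) {
    for (att in 1:400) {
      r <- stats::runif(1L, 4, nr - 3)
      c <- stats::runif(1L, 4, nc - 3)
      ri <- as.integer(round(r)); ci <- as.integer(round(c))
      # keep the whole unfused cell body clear of fibre masks so the
      # actin blob cannot merge with a myotube component
      win <- as.integer(ceiling(1.6 * 5.5 / ps))
      near_fibre <- any(occ[max(1, ri - win):min(nr, ri + win),
                            max(1, ci - win):min(nc, ci + win)] > 0L)
      if (!near_fibre && place_ok(r, c)) break
    }
    placed <- rbind(placed, c(r, c))
    nuc_rows <- c(nuc_rows, r); nuc_cols <- c(nuc_cols, c)
    nuc_fibre <- c(nuc_fibre, NA_integer_)
    nuc_pos <- c(nuc_pos, stats::runif(1L) < pf_un)
  }

  if (length(fibres)) {
    gt <- data.frame(
      id = seq_along(fibres),
      class = vapply(fibres, `[[`, character(1), "class"),
      ddr_true = vapply(fibres, `[[`, numeric(1), "ddr_real"),
      ddr_drawn = vapply(fibres, `[[`, numeric(1), "ddr"),
      nuclei = vapply(fibres, `[[`, integer(1), "cnt"),
      area_um2 = vapply(fibres, `[[`, numeric(1), "area_um2"),
      marker_intensity = params$marker_intensity_by_type[
        vapply(fibres, `[[`, character(1), "class")],
      length_um = vapply(fibres, `[[`, numeric(1), "len_um"),
      w_min_um = vapply(fibres, `[[`, numeric(1), "w_min"),
      w_max_um = vapply(fibres, `[[`, numeric(1), "w_max"),
      row_centre = vapply(fibres, `[[`, numeric(1), "yc"),
      col_start = vapply(fibres, function(f) f$x0, integer(1)),
      col_end = vapply(fibres, function(f) f$x0 + f$len_px - 1L, integer(1)),
      row.names = NULL)
  }
  if (length(nuc_rows)) {
    nuclei_df <- data.frame(id = seq_along(nuc_rows), fibre_id = nuc_fibre,
                            row = nuc_rows, col = nuc_cols,
                            positive = nuc_pos)
  }

  mg <- NULL
  if (render) {
    mg <- .render_channels(params, fibres, occ, nuclei_df, nr, nc,
                           provenance = sprintf("generate_field(seed=%d)",
                                                seed))
  }

  structure(list(micrograph = mg, ground_truth = gt, nuclei = nuclei_df,
                 params = params, seed = seed, fov_shape = fov_shape,
                 n_dropped = n_dropped),
            class = "synthetic_field")
}

# additive Gaussian blob, clipped to a window of +/- rad_px
.add_blob <- function(mat, r0, c0, sigma_px, amp, rad_px) {
  nr <- nrow(mat); nc <- ncol(mat)
  rs <- max(1L, as.integer(floor(r0 - rad_px))):min(nr, as.integer(ceiling(r0 + rad_px)))
  cs <- max(1L, as.integer(floor(c0 - rad_px))):min(nc, as.integer(ceiling(c0 + rad_px)))
  blob <- amp * exp(-outer((rs - r0)^2, (cs - c0)^2, "+") / (2 * sigma_px^2))
  mat[rs, cs] <- mat[rs, cs] + blob
  mat
}

# set a disc of radius rad_px to zero (marker punch-out at negative nuclei)
.punch_disc <- function(mat, r0, c0, rad_px) {
  nr <- nrow(mat); nc <- ncol(mat)
  rs <- max(1L, as.integer(floor(r0 - rad_px))):min(nr, as.integer(ceiling(r0 + rad_px)))
  cs <- max(1L, as.integer(floor(c0 - rad_px))):min(nc, as.integer(ceiling(c0 + rad_px)))
  d2 <- outer((rs - r0)^2, (cs - c0)^2, "+")
  sub <- mat[rs, cs]
  sub[d2 <= rad_px^2] <- 0
  mat[rs, cs] <- sub
  mat
}

.render_channels <- function(params, fibres, occ, nuclei_df, nr, nc,
                             provenance) {
  ps <- params$pixel_size
  mx <- 2^params$bit_depth - 1
  actin <- matrix(0, nr, nc)
  dapi <- matrix(0, nr, nc)
  marker <- matrix(0, nr, nc)

  # actin: fibres at actin_level with mild per-fibre brightness variation
  for (fi in seq_along(fibres)) {
    lev <- params$actin_level * stats::runif(1L, 0.85, 1.1)
    actin[occ == fi] <- lev
  }
  # marker cytoplasm: per-class relative intensity
  for (fi in seq_along(fibres)) {
    m <- params$marker_intensity_by_type[[fibres[[fi]]$class]]
    marker[occ == fi] <- m * params$marker_gain
  }

  d_px <- params$nucleus_diameter / ps
  sig_n <- d_px / 5
  cell_r <- 5.5 / ps  # unfused cell body radius (um -> px)
  if (nrow(nuclei_df)) {
    for (k in seq_len(nrow(nuclei_df))) {
      r <- nuclei_df$row[k]; c <- nuclei_df$col[k]
      dapi <- .add_blob(dapi, r, c, sig_n, params$dapi_level, d_px)
      if (is.na(nuclei_df$fibre_id[k])) {
        # unfused mononuclear cell: small actin body around the nucleus
        actin <- .add_blob(actin, r, c, cell_r / 2,
                           0.8 * params$actin_level, cell_r)
      }
    }
    # marker positivity: negative nuclei punched out of the cytoplasmic
    # signal; positive nuclei receive a nuclear-localised marker blob
    for (k in seq_len(nrow(nuclei_df))) {
      r <- nuclei_df$row[k]; c <- nuclei_df$col[k]
      if (nuclei_df$positive[k]) {
        marker <- .add_blob(marker, r, c, sig_n,
                            params$nuclear_marker_level, d_px)
      } else {
        marker <- .punch_disc(marker, r, c, d_px / 2)
      }
    }
  }

  finish <- function(m) {
    if (params$noise_sd > 0) {
      m <- m + stats::rnorm(length(m), 0, params$noise_sd)
    }
    matrix(as.integer(pmin(pmax(round(m), 0), mx)), nr, nc)
  }
  micrograph(list(actin = finish(actin), dapi = finish(dapi),
                  marker = finish(marker)),
             pixel_size = ps, bit_depth = params$bit_depth,
             provenance = provenance)
}

#' @export
print.synthetic_field <- function(x, ...) {
  cat(sprintf(
    "<synthetic_field> seed %d, %d x %d px, %d myotubes (%d bag), %d nuclei%s\n",
    x$seed, x$fov_shape[1], x$fov_shape[2], nrow(x$ground_truth),
    sum(x$ground_truth$class == "bag"), nrow(x$nuclei),
    if (is.null(x$micrograph)) " [not rendered]" else ""))
  invisible(x)
}

#' Generate a primary-negative calibration image
#'
#' A single-channel image of pure background/autofluorescence noise with
#' no structures, emulating a control stain that omits the primary
#' antibody. Used to calibrate the background threshold
#' ([calibrate_background()]).
#'
#' @param seed Integer seed.
#' @param fov_shape Image size in pixels, `c(rows, cols)`.
#' @param noise_scale Noise amplitude in grey levels. For the
#'   `"gaussian"` model this is the SD of zero-mean additive noise
#'   (negatives clipped to 0, so positive pixels are half-normal); for
#'   `"uniform"` pixels are drawn uniformly from the integers
#'   `1:noise_scale` (all pixels strictly positive). `noise_scale = 0`
#'   yields an all-zero image under either model.
#' @param model Noise distribution, `"gaussian"` (default) or `"uniform"`.
#' @param pixel_size,bit_depth Image calibration, as in [micrograph()].
#' @return A [micrograph()] with a single `marker` channel.
#' @examples
#' pn <- generate_primary_negative(1, c(64, 64), noise_scale = 100,
#'                                 model = "uniform")
#' range(pn$channels$marker)
#' @export
generate_primary_negative <- function(seed, fov_shape = c(768, 768),
                                      noise_scale = 0.02 * (2^16 - 1),
                                      model = c("gaussian", "uniform"),
                                      pixel_size = 0.65, bit_depth = 16L) {
  model <- match.arg(model)
  if (noise_scale < 0) stop("`noise_scale` must be >= 0")
  fov_shape <- as.integer(fov_shape)
  mx <- 2^bit_depth - 1
  n <- prod(fov_shape)
  vals <- with_seed(seed, {
    if (noise_scale == 0) {
      integer(n)
    } else if (model == "gaussian") {
      as.integer(pmin(pmax(round(stats::rnorm(n, 0, noise_scale)), 0), mx))
    } else {
      as.integer(sample.int(as.integer(noise_scale), n, replace = TRUE))
    }
  })
  micrograph(list(marker = matrix(vals, fov_shape[1], fov_shape[2])),
             pixel_size = pixel_size, bit_depth = bit_depth,
             provenance = sprintf("generate_primary_negative(seed=%d)", seed))
}
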