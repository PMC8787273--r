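test_that("segmentation finds rendered fibres and merges touching masks", {
  blank <- micrograph(list(actin = matrix(0L, 64, 64),
                           dapi = matrix(0L, 64, 64)), 0.65)
  expect_equal(nrow(segment_myotubes(blank)$table), 0L)

  p <- condition_params("control", noise_sd = 0)
  f <- generate_field(p, seed = 21)
  cand <- segment_myotubes(f$micrograph)
  expect_equal(nrow(cand$table), nrow(f$ground_truth))

  # two fibres rendered touching collapse into one candidate
  a <- matrix(0L, 100, 200)
  a[20:40, 20:180] <- 30000L
  a[40:60, 20:180] <- 30000L
  mg <- micrograph(list(actin = a, dapi = matrix(0L, 100, 200)), 0.65)
  expect_equal(nrow(segment_myotubes(mg)$table), 1L)

  expect_error(segment_myotubes(micrograph(list(dapi = a), 0.65)),
               "no 'actin' channel")
})

test_that("nuclei detection counts rendered nuclei and declumps by maxima", {
  blank <- micrograph(list(dapi = matrix(0L, 64, 64)), 0.65)
  expect_equal(nrow(detect_nuclei(blank)), 0L)

  p <- condition_params("control", noise_sd = 0)
  for (s in c(31, 32)) {
    f <- generate_field(p, seed = s)
    expect_equal(nrow(detect_nuclei(f$micrograph)), nrow(f$nuclei))
  }

  # two blobs closer than min_diameter merge into a single centroid
  d <- matrix(0, 80, 80)
  blob <- function(m, r0, c0) {
    for (i in 1:80) for (j in 1:80) {
      m[i, j] <- m[i, j] + 30000 * exp(-((i - r0)^2 + (j - c0)^2) / (2 * 9))
    }
    m
  }
  d <- blob(blob(d, 40, 38), 40, 44)  # 6 px apart < 7 um at 0.65 um/px
  mg <- micrograph(list(dapi = round(d)), 0.65)
  expect_equal(nrow(detect_nuclei(mg)), 1L)
})

test_that("nucleus assignment is inclusive of mask borders and flags overlap", {
  labels <- matrix(0L, 20, 20)
  labels[5:10, 5:10] <- 1L
  none <- assign_nuclei(labels, data.frame(row = numeric(0),
                                           col = numeric(0)))
  expect_equal(none$nuclei, 0L)

  border <- assign_nuclei(labels, data.frame(row = 5, col = 5))
  expect_equal(border$nuclei[border$id == 1], 1L)

  m1 <- matrix(FALSE, 20, 20); m1[5:12, 5:12] <- TRUE
  m2 <- matrix(FALSE, 20, 20); m2[10:16, 10:16] <- TRUE
  res <- assign_nuclei(list(m1, m2),
                       data.frame(row = c(11, 6, 15), col = c(11, 6, 15)))
  expect_equal(res$nuclei, c(1L, 1L))          # conflicted nucleus dropped
  expect_equal(attr(res, "overlap_flagged"), 1L)
  expect_true(is.na(attr(res, "assignment")[1]))

  # generated field: per-instance counts equal ground truth
  p <- condition_params("control", noise_sd = 0)
  f <- generate_field(p, seed = 33)
  cand <- segment_myotubes(f$micrograph)
  counts <- assign_nuclei(cand, detect_nuclei(f$micrograph))
  gt <- match_instances(f, cand)
  matched <- merge(gt, counts, by.x = "label", by.y = "id")
  expect_equal(matched$nuclei.y, matched$nuclei.x)
})

test_that("myotube filter keeps exactly the three-or-more-nuclei structures", {
  res <- filter_myotubes(data.frame(id = 1:5, nuclei = 1:5))
  expect_equal(nrow(res$retained), 3L)
  expect_equal(res$retained$id, 3:5)
  expect_match(res$excluded$reason, "fewer than 3")

  expect_equal(nrow(filter_myotubes(
    data.frame(id = 1:4, nuclei = rep(2L, 4)))$retained), 0L)
  allpass <- data.frame(id = 1:3, nuclei = c(3L, 7L, 12L))
  expect_identical(filter_myotubes(allpass)$retained, allpass)
})

test_that("width profiles agree with the perpendicular-scan oracle", {
  # rectangle 100 x 10 px at 1 um/px: every width is 10 um
  m <- rect_mask(30, 120, 11:20, 11:110)
  prof <- width_profile(m, 1)
  expect_true(all(prof$width_um == 10))
  expect_equal(compute_ddr(prof), 1)

  # elongated ellipses: medial-axis widths within 1 px of the column scan
  for (ab in list(c(60, 12), c(80, 16), c(100, 18))) {
    e <- ellipse_mask(ab[1], ab[2])
    prof <- width_profile(e, 1)
    oracle <- colscan_width(e, prof$col)
    expect_lte(max(abs(prof$width_um - oracle)), 1)
  }

  # perfect disc: degenerate axis, max ~ min, DDR -> 1
  prof <- width_profile(disc_mask(15), 1)
  expect_lt(abs(compute_ddr(prof) - 1), 0.05)

  # analytic fusiform with w_max 20, w_min 5 um
  fm <- fusiform_mask(5, 20, 160, ps = 0.5)
  expect_lt(abs(compute_ddr(width_profile(fm, 0.5)) - 4) / 4, 0.1)

  expect_error(width_profile(matrix(0L, 5, 5), 1), "empty mask")
})

test_that("DDR is scale invariant and monotone in the equatorial bulge", {
  d1 <- compute_ddr(width_profile(fusiform_mask(6, 18, 120, ps = 1), 1))
  d2 <- compute_ddr(width_profile(fusiform_mask(6, 18, 120, ps = 0.5), 0.5))
  expect_lt(abs(d1 - d2) / d2, 0.05)

  dd <- vapply(seq(8, 28, by = 4), function(wm) {
    compute_ddr(width_profile(fusiform_mask(5, wm, 180, ps = 0.5), 0.5))
  }, numeric(1))
  expect_true(all(diff(dd) >= 0))
})

test_that("measured DDR matches generator ground truth on noiseless fields", {
  p <- condition_params("control", noise_sd = 0, bag_fraction = 0.4)
  errs <- c()
  for (s in 1:3) {
    f <- generate_field(p, seed = 50 + s)
    cand <- segment_myotubes(f$micrograph)
    gt <- match_instances(f, cand)
    for (j in seq_len(nrow(gt))) {
      if (is.na(gt$label[j])) next
      prof <- width_profile(cand$labels == gt$label[j],
                            f$micrograph$pixel_size,
                            labels = cand$labels, id = gt$label[j])
      if (nrow(prof) < 2) next
      errs <- c(errs, (compute_ddr(prof) - gt$ddr_true[j]) / gt$ddr_true[j])
    }
  }
  expect_gt(length(errs), 10)
  expect_lte(max(abs(errs)), 0.10)
})

test_that("compute_ddr arithmetic and degenerate inputs", {
  expect_equal(compute_ddr(c(7, 7, 7)), 1)
  expect_equal(compute_ddr(c(20, 5)), 4)
  expect_error(compute_ddr(c(3)), "at least 2")
  expect_error(compute_ddr(c(0, 5)), "degenerate")
})

test_that("threshold derivation reproduces the training-set arithmetic", {
  thr <- derive_thresholds(c(1.44, 1.81, 2.18), c(2.71, 4.03, 5.35))
  expect_equal(thr$linear_mean, 1.81)
  expect_equal(thr$linear_sd, 0.37)
  expect_equal(thr$bag_mean, 4.03)
  expect_equal(thr$bag_sd, 1.32)
  expect_equal(thr$linear_cutoff, 2.18)
  expect_equal(thr$bag_cutoff, 2.71)

  # summary-statistic constructor is equivalent
  thr2 <- ddr_thresholds(1.81, 0.37, 4.03, 1.32)
  expect_equal(thr2$linear_cutoff, thr$linear_cutoff)
  expect_equal(thr2$bag_cutoff, thr$bag_cutoff)

  expect_error(derive_thresholds(c(2.0, 3.0), c(3.0, 3.4)),
               "not separable")
  expect_error(derive_thresholds(1.8, c(3, 4)), "at least 2")
})

test_that("classification boundaries are inclusive to their class", {
  thr <- paper_thresholds()
  expect_equal(as.character(classify_ddr(2.18, thr)), "linear")
  expect_equal(as.character(classify_ddr(2.71, thr)), "bag")
  expect_equal(as.character(classify_ddr(2.50, thr)), "unassigned")
  expect_equal(as.character(classify_ddr(c(1, 5), thr)), c("linear", "bag"))
  expect_error(classify_ddr(0.8, thr), ">= 1")
})

test_that("field summary computes the documented morphometrics", {
  inst <- data.frame(class = c("bag", "linear", "linear", "unassigned"),
                     nuclei = c(10L, 15L, 12L, 10L),
                     area_um2 = c(6000, 4500, 3600, 2000))
  s <- summarise_field(inst, total_nuclei = 100)
  expect_equal(s$fusion_efficiency, 47)
  expect_equal(s$bag_pct + s$linear_pct + s$unassigned_pct, 100)
  expect_equal(s$bag_pct, 25)

  one <- summarise_field(data.frame(class = "linear", nuclei = 10L,
                                    area_um2 = 6000), total_nuclei = 20)
  expect_equal(one$mean_area_per_nucleus, 600)

  none <- summarise_field(inst[0, ], total_nuclei = 0)
  expect_true(is.na(none$fusion_efficiency))
  expect_error(summarise_field(inst, total_nuclei = 10), "cannot be below")
})

test_that("field-level parameter recovery works on a small batch", {
  thr <- paper_thresholds()
  p <- condition_params("control")
  fe <- nuc <- c()
  for (s in 1:6) {
    f <- generate_field(p, seed = 400 + s)
    m <- measure_field(f$micrograph, thr)
    fe <- c(fe, m$summary$fusion_efficiency)
    nuc <- c(nuc, m$summary$nuclei_per_fov)
  }
  expect_lt(abs(mean(fe) - 46.88), 10)
  expect_lt(abs(mean(nuc) - 104.8), 15)
})
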