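test_that("background calibration implements the minimal 99% rule", {
  expect_equal(calibrate_background(matrix(0L, 10, 10))$threshold, 0L)

  # 1,000 positive pixels valued 1..100, ten each -> T = 99 (10 remain)
  img <- matrix(rep(1:100, each = 10), 25, 40)
  cal <- calibrate_background(img)
  expect_equal(cal$threshold, 99L)
  expect_gte(cal$removed_fraction, 0.99)

  # minimality against the brute-force oracle on random images
  set.seed(11)
  for (i in 1:15) {
    v <- matrix(c(rpois(300, sample(3:40, 1)),
                  sample.int(sample(50:200, 1), 100, replace = TRUE)),
                20, 20)
    cal <- calibrate_background(v)
    expect_equal(cal$threshold, brute_threshold(v))
    pos <- v[v > 0]
    expect_lte(sum(pos > cal$threshold), floor(0.01 * length(pos)))
    if (cal$threshold > 0) {
      expect_gt(sum(pos > cal$threshold - 1), floor(0.01 * length(pos)))
    }
  }
})

test_that("background subtraction masks below-threshold pixels only", {
  img <- matrix(c(0L, 5L, 10L, 200L, 3000L, 7L), 2, 3)
  expect_identical(subtract_background(img, 0L), img)

  gone <- subtract_background(img, 5000L)
  expect_true(all(gone == 0))

  corr <- subtract_background(img, 10L)
  expect_equal(sum(corr), 200 + 3000)   # above-threshold sum preserved
  expect_equal(corr[img <= 10], rep(0L, 4))

  mg8 <- micrograph(list(marker = matrix(10L, 4, 4)), 0.65, bit_depth = 8L)
  cal16 <- calibrate_background(generate_primary_negative(1, c(32, 32)))
  expect_error(subtract_background(mg8, cal16), "bit depth mismatch")
})

test_that("coverage counts above-background pixels and is monotone", {
  expect_equal(coverage(matrix(0, 10, 10)), 0)
  half <- matrix(c(0, 7), 10, 10)
  expect_equal(coverage(half), 50)

  img <- matrix(sample.int(100, 400, replace = TRUE), 20, 20)
  covs <- vapply(c(0, 10, 30, 60, 90),
                 function(t) coverage(subtract_background(img, t)),
                 numeric(1))
  expect_true(all(diff(covs) <= 0))
})

test_that("intensity per nucleus normalises the corrected sum", {
  expect_equal(intensity_per_nucleus(matrix(0, 5, 5), 10)$value, 0)
  img <- matrix(0, 10, 10); img[1:4, 1] <- 250
  expect_equal(intensity_per_nucleus(img, 10)$value, 100)
  expect_equal(intensity_per_nucleus(img, 10, control_mean = 100)$fold, 1)
  expect_warning(res <- intensity_per_nucleus(img, 0), "undefined")
  expect_true(is.na(res$value))

  # invariant to adding pixels at or below the background threshold
  cal <- calibrate_background(matrix(rep(1:100, each = 10), 25, 40))
  base <- matrix(0L, 25, 40); base[1, 1] <- 5000L
  more <- base; more[2, 1:10] <- cal$threshold
  v1 <- intensity_per_nucleus(subtract_background(base, cal), 5)$value
  v2 <- intensity_per_nucleus(subtract_background(more, cal), 5)$value
  expect_equal(v1, v2)
})

test_that("per-myotube mean intensity reflects the class contrast", {
  img <- matrix(0, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[3:6, 3:6] <- TRUE
  expect_equal(myotube_mean_intensity(img, mask), 0)
  img[mask] <- 1234
  expect_equal(myotube_mean_intensity(img, mask), 1234)
  expect_error(myotube_mean_intensity(img, matrix(FALSE, 10, 10)), "empty")

  p <- condition_params("nrg1", noise_sd = 0)
  f <- generate_field(p, seed = 61)
  cand <- segment_myotubes(f$micrograph)
  gt <- match_instances(f, cand)
  vals <- vapply(seq_len(nrow(gt)), function(j) {
    if (is.na(gt$label[j])) return(NA_real_)
    myotube_mean_intensity(f$micrograph$channels$marker, cand$labels,
                           id = gt$label[j])
  }, numeric(1))
  lin <- vals[gt$class == "linear"]; bag <- vals[gt$class == "bag"]
  expect_gt(length(lin), 0)
  expect_gt(length(bag), 0)
  expect_gt(mean(bag, na.rm = TRUE), mean(lin, na.rm = TRUE))
})

test_that("positive-nucleus percentage recovers the generator setting", {
  centro <- data.frame(row = c(20, 40), col = c(20, 40))
  zero <- matrix(0, 60, 60)
  expect_equal(positive_nuclei_pct(zero, centro)$pct, 0)
  expect_equal(positive_nuclei_pct(zero + 5, centro)$pct, 100)
  expect_error(positive_nuclei_pct(zero, centro[0, ]), "at least one")

  p <- condition_params("control", noise_sd = 0,
                        positive_nuclei_fraction_by_type =
                          c(linear = 0.5, bag = 0.5))
  f <- generate_field(p, seed = 71)
  res <- positive_nuclei_pct(f$micrograph$channels$marker, f$nuclei)
  expect_equal(res$pct, 100 * mean(f$nuclei$positive))
  expect_identical(res$positive, f$nuclei$positive)
})

test_that("paired-seed fields recover the per-nucleus intensity fold", {
  cal <- calibrate_background(generate_primary_negative(99, c(768, 768)))
  ipn <- function(cond, seeds) {
    vapply(seeds, function(s) {
      f <- generate_field(condition_params(cond), seed = s)
      corr <- subtract_background(f$micrograph, cal)
      intensity_per_nucleus(corr, nrow(f$nuclei))$value
    }, numeric(1))
  }
  seeds <- 1:6
  fold <- mean(ipn("nrg1", seeds)) / mean(ipn("control", seeds))
  expect_lt(abs(fold - 3.51) / 3.51, 0.15)

  # treated coverage exceeds control coverage on paired seeds
  cov1 <- function(cond, s) {
    f <- generate_field(condition_params(cond), seed = s)
    coverage(subtract_background(f$micrograph, cal))
  }
  for (s in 1:3) expect_gt(cov1("nrg1", s), cov1("control", s))
})
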