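test_that("primer QC applies the efficiency, r2 and melt rules", {
  p <- data.frame(gene = c("Csnk2a2", "lowE", "r2edge", "melt"),
                  efficiency = c(97.9, 89.9, 100, 100),
                  r2 = c(0.99, 0.99, 0.95, 0.99),
                  single_peak = c(TRUE, TRUE, TRUE, FALSE))
  res <- qc_filter_primers(p)
  expect_equal(res$pass, c(TRUE, FALSE, FALSE, FALSE))
  expect_match(res$reason[2], "efficiency")
  expect_match(res$reason[3], "r2")        # r2 = 0.95 exactly fails (strict)
  expect_match(res$reason[4], "melt")
  # inclusive efficiency bounds
  edge <- qc_filter_primers(data.frame(gene = c("lo", "hi"),
                                       efficiency = c(90, 115),
                                       r2 = 0.99, single_peak = TRUE))
  expect_true(all(edge$pass))
})

test_that("the bundled primer table passes QC in full", {
  tab <- primer_table()
  expect_equal(nrow(tab), 18L)
  res <- qc_filter_primers(tab)
  expect_true(all(res$pass))
  expect_true(all(tab$efficiency >= 90 & tab$efficiency <= 115))
  expect_true("Csnk2a2" %in% tab$gene)
})

test_that("delta-delta-Ct arithmetic and identities", {
  mk <- function(genes_ct, cond, samp, plate = 1) {
    do.call(rbind, lapply(names(genes_ct), function(g) {
      data.frame(sample = samp, condition = cond, plate = plate, gene = g,
                 ct1 = genes_ct[[g]], ct2 = genes_ct[[g]],
                 ct3 = genes_ct[[g]])
    }))
  }
  # gene Ct identical to reference everywhere -> all folds 1
  ct <- rbind(mk(c(Csnk2a2 = 22, A = 22), "control", "c1"),
              mk(c(Csnk2a2 = 23, A = 23), "treated", "t1"))
  ex <- relative_expression(ct)
  expect_equal(ex$fold_change, rep(1, 2))

  # treated delta-Ct exactly one cycle below control -> fold 2
  ct2 <- rbind(mk(c(Csnk2a2 = 20, A = 26), "control", "c1"),
               mk(c(Csnk2a2 = 20, A = 25), "treated", "t1"))
  ex2 <- relative_expression(ct2)
  expect_equal(ex2$fold_change[ex2$condition == "treated"], 2)

  # plate-constant Ct offsets cancel
  ct3 <- ct2
  ct3[, c("ct1", "ct2", "ct3")] <- ct3[, c("ct1", "ct2", "ct3")] + 1.7
  expect_equal(relative_expression(ct3)$fold_change, ex2$fold_change)

  # missing reference drops the sample with a warning; no control errors
  ct4 <- rbind(ct2, mk(c(A = 24), "treated", "t2"))
  expect_warning(ex4 <- relative_expression(ct4), "reference")
  expect_false("t2" %in% ex4$sample)
  expect_error(
    relative_expression(mk(c(Csnk2a2 = 20, A = 24), "treated", "t1")),
    "control")
})

test_that("zero-noise tables round-trip arbitrary folds exactly", {
  set.seed(99)
  folds <- stats::setNames(round(exp(runif(6, log(0.1), log(10))), 4),
                           paste0("g", 1:6))
  ct <- generate_ct_table(folds, n_samples = 3, ct_noise_sd = 0, seed = 8)
  ex <- relative_expression(ct)
  for (g in names(folds)) {
    got <- ex$fold_change[ex$gene == g & ex$condition == "treated"]
    expect_equal(unique(round(got, 10)), round(folds[[g]], 10))
  }
  blot <- generate_blot_table(folds, n_repeats = 3, seed = 9)
  r <- adjusted_relative_density(blot)
  for (g in names(folds)) {
    got <- r$fold[r$target == g & r$condition == "treated"]
    expect_equal(unique(round(got, 10)), round(folds[[g]], 10))
  }
})

test_that("Myh proportions linearise delta-Ct shares per sample", {
  ex <- data.frame(sample = "s1", gene = paste0("Myh", 1:4),
                   delta_ct = rep(5, 4))
  expect_equal(myh_proportions(ex)$proportion_pct, rep(25, 4))

  ex2 <- data.frame(sample = "s1", gene = c("Myh1", "Myh4"),
                    delta_ct = c(5, 4))
  pr <- myh_proportions(ex2)
  expect_equal(pr$proportion_pct[pr$gene == "Myh4"], 200 / 3,
               tolerance = 1e-10)
  expect_equal(pr$proportion_pct[pr$gene == "Myh1"], 100 / 3,
               tolerance = 1e-10)
  expect_equal(sum(pr$proportion_pct), 100)

  # invariant to the reference-gene choice (a per-sample delta-Ct shift)
  ex3 <- ex2; ex3$delta_ct <- ex3$delta_ct + 2.3
  expect_equal(myh_proportions(ex3)$proportion_pct, pr$proportion_pct)

  # undetected isoforms excluded and listed
  ex4 <- rbind(ex2, data.frame(sample = "s1", gene = "Myh15",
                               delta_ct = NA))
  pr4 <- myh_proportions(ex4)
  expect_equal(attr(pr4, "undetected"), "Myh15")
  expect_equal(sum(pr4$proportion_pct), 100)
  expect_error(myh_proportions(data.frame(sample = "s1", gene = "Myh15",
                                          delta_ct = NA)), "Myh")
})

test_that("adjusted relative density self-normalises to control lanes", {
  lanes <- data.frame(lane = 1:4, condition = c("control", "control",
                                                "treated", "treated"),
                      target = "X",
                      band_density = c(100, 120, 55, 55),
                      gapdh_density = c(100, 120, 100, 100))
  r <- adjusted_relative_density(lanes)
  expect_equal(mean(r$fold[r$condition == "control"]), 1)
  expect_equal(r$fold[r$condition == "treated"], c(0.55, 0.55))
  lanes$gapdh_density[1] <- 0
  expect_error(adjusted_relative_density(lanes), "loading-control")
})

test_that("viability folds are blank-corrected and shift-invariant", {
  a <- data.frame(condition = c("control", "control", "treated", "treated"),
                  rfu = c(1000, 1000, 1150, 1150))
  v <- viability_fold(a)
  expect_equal(v$fold[v$condition == "treated"], 1.15)
  expect_equal(v$fold[v$condition == "control"], 1)

  a2 <- rbind(a, data.frame(condition = "blank", rfu = c(200, 200)))
  ab <- a2
  ab$rfu <- ab$rfu + 300  # constant offset on every reading and blank
  expect_equal(viability_fold(ab)$fold, viability_fold(a2)$fold)

  asy <- generate_assay_table(fold = 1.15, n_wells = 6, noise_sd = 0,
                              seed = 2)
  v2 <- viability_fold(asy)
  expect_equal(v2$fold[v2$condition == "treated"], 1.15)
})
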