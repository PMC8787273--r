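test_that("the normality gate chooses the documented branch", {
  set.seed(5)
  g <- gated_two_group_test(rnorm(9, 10, 1), rnorm(9, 12, 1))
  expect_equal(g$test, "t_test")
  expect_true(g$normal)

  set.seed(6)
  h <- gated_two_group_test(exp(rnorm(30, 0, 1.6)), exp(rnorm(30, 1, 1.6)))
  expect_equal(h$test, "mann_whitney")
  expect_false(h$normal)

  same <- gated_two_group_test(rep(4, 5), rep(4, 5))
  expect_equal(same$p_value, 1)
  expect_equal(same$estimate, 0)

  expect_error(gated_two_group_test(1:2, 1:5), "n >= 3")
})

test_that("the sqrt transform is applied before the gate and the test", {
  set.seed(7)
  x <- rnorm(20, 9, 1); y <- rnorm(20, 11, 1)
  direct <- gated_two_group_test(x, y)
  squared <- gated_two_group_test(x^2, y^2, transform = "sqrt")
  expect_equal(squared$test, direct$test)
  expect_equal(squared$p_value, direct$p_value)
  expect_equal(unname(squared$shapiro_p), unname(direct$shapiro_p))
  # group means are reported on the original (untransformed) scale
  expect_equal(squared$groups$mean, c(mean(x^2), mean(y^2)))
  expect_error(gated_two_group_test(c(-1, 2, 3), 1:3, transform = "sqrt"),
               "non-negative")
})

test_that("two-way ANOVA handles the treatment x type design", {
  set.seed(8)
  d <- expand.grid(rep = 1:10, treatment = c("ctl", "trt"),
                   type = c("linear", "bag"))
  d$v <- rnorm(nrow(d), 5, 1)  # no effects anywhere
  a <- two_way_anova_tukey(d$v, d$treatment, d$type)
  expect_true(all(a$anova$p_value > 0.05))
  expect_equal(nrow(a$cell_means), 4L)

  # empty cell fails with the cell named
  keep <- !(d$treatment == "trt" & d$type == "bag")
  expect_error(two_way_anova_tukey(d$v[keep], d$treatment[keep],
                                   d$type[keep]), "trt.*bag")
  expect_error(two_way_anova_tukey(-d$v, d$treatment, d$type,
                                   transform = "sqrt"), "non-negative")
})

test_that("ANOVA on study-structured intensities finds the main effects", {
  cells <- list(c("ctl", "linear", 0.88, 0.94, 52),
                c("ctl", "bag", 1.85, 1.62, 9),
                c("trt", "linear", 2.50, 2.88, 47),
                c("trt", "bag", 6.13, 5.51, 26))
  n_eff <- 0; n_int <- 0; runs <- 8
  for (s in 1:runs) {
    set.seed(800 + s)
    d <- do.call(rbind, lapply(cells, function(cl) {
      v <- rnorm(as.integer(cl[5]), as.numeric(cl[3]), as.numeric(cl[4]))
      data.frame(treatment = cl[1], type = cl[2], v = pmax(v, 0))
    }))
    a <- two_way_anova_tukey(d$v, d$treatment, d$type, transform = "sqrt")
    p <- setNames(a$anova$p_value, a$anova$term)
    if (p[["treatment"]] < 0.05 && p[["type"]] < 0.05) n_eff <- n_eff + 1
    if (p[["treatment:type"]] > 0.05) n_int <- n_int + 1
  }
  expect_gt(n_eff, runs / 2)   # both main effects usually significant
  expect_gt(n_int, runs / 2)   # interaction usually not
})

test_that("negative-binomial count model reports rate ratios", {
  d <- expand.grid(i = 1:20, treatment = c("ctl", "trt"),
                   type = c("linear", "bag"))
  eq <- nuclei_count_model(rep(6L, nrow(d)), d$treatment, d$type)
  expect_equal(eq$terms$rate_ratio[grep("type", eq$terms$term)], 1)

  expect_error(nuclei_count_model(c(1.5, 2, 3), rep("a", 3), rep("x", 3)),
               "integers")

  # doubling every count (both class means double) leaves the type rate
  # ratio essentially unchanged
  base <- ifelse(d$type == "bag", 8L, 5L) +
    rep(c(-2L, -1L, 0L, 1L, 2L), length.out = nrow(d))
  r1 <- nuclei_count_model(base, d$treatment, d$type)
  r2 <- nuclei_count_model(2L * base, d$treatment, d$type)
  rr1 <- r1$terms$rate_ratio[grep("type", r1$terms$term)]
  rr2 <- r2$terms$rate_ratio[grep("type", r2$terms$term)]
  expect_lt(abs(log(rr2 / rr1)), 0.02)
})

test_that("study-structured counts show a type but no treatment effect", {
  cells <- list(c("ctl", "linear", 5.48, 60), c("ctl", "bag", 8.09, 11),
                c("trt", "linear", 6.10, 40), c("trt", "bag", 8.33, 33))
  n_type <- 0; n_trt_ns <- 0; runs <- 8
  for (s in 1:runs) {
    set.seed(300 + s)
    d <- do.call(rbind, lapply(cells, function(cl) {
      data.frame(treatment = cl[1], type = cl[2],
                 count = rnbinom(as.integer(cl[4]), size = 6,
                                 mu = as.numeric(cl[3])))
    }))
    m <- nuclei_count_model(d$count, d$treatment, d$type)
    p <- setNames(m$terms$p_value, m$terms$term)
    if (p[[grep("type", names(p), value = TRUE)]] < 0.05) n_type <- n_type + 1
    if (p[[grep("treatment", names(p), value = TRUE)]] > 0.05) {
      n_trt_ns <- n_trt_ns + 1
    }
  }
  expect_gt(n_type, runs / 2)
  expect_gt(n_trt_ns, runs / 2)
})
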