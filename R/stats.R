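#' Normality-gated two-group comparison
#'
#' The decision procedure used for two-group outcomes: values are
#' (optionally) square-root transformed, each group is checked for
#' normality with the Shapiro-Wilk test, and the comparison is a
#' two-sided Student's t-test when both groups pass the gate
#' (p > `normality_alpha` in both) or a Mann-Whitney (Wilcoxon rank-sum)
#' test otherwise. The gate's outcome is recorded so every reported p
#' value is traceable to the branch that produced it.
#'
#' @param x,y Numeric vectors for the two groups (each n >= 3).
#' @param transform `"none"` or `"sqrt"` (applied before the gate and the
#'   test; sqrt requires non-negative data).
#' @param normality_alpha Gate level for Shapiro-Wilk, default 0.05.
#' @param var_equal Pooled-variance t-test (default `TRUE`, the classical
#'   Student's test); set `FALSE` for Welch.
#' @param group_names Labels used in the output.
#' @return Object of class `spindle_stat`: `test` (chosen branch),
#'   `statistic`, `p_value`, `stars`, `shapiro_p` (per group),
#'   `normal` (gate result), `groups` (n, mean, SEM on the original
#'   scale), `estimate` (difference of transformed means), `transform`.
#' @examples
#' r <- gated_two_group_test(rnorm(9, 10), rnorm(9, 12))
#' r$test
#' @export
gated_two_group_test <- function(x, y, transform = c("none", "sqrt"),
                                 normality_alpha = 0.05, var_equal = TRUE,
                                 group_names = c("control", "treated")) {
  transform <- match.arg(transform)
  if (length(x) < 3L || length(y) < 3L) {
    stop("each group needs n >= 3 (normality check undefined below that)")
  }
  groups <- data.frame(
    group = group_names, n = c(length(x), length(y)),
    mean = c(mean(x), mean(y)), sem = c(sem(x), sem(y)))
  tx <- switch(transform, none = x, sqrt = {
    if (any(c(x, y) < 0)) stop("sqrt transform requires non-negative data")
    sqrt(x)
  })
  ty <- switch(transform, none = y, sqrt = sqrt(y))

  const <- function(v) length(unique(v)) == 1L
  sh_x <- if (const(tx)) NA_real_ else stats::shapiro.test(tx)$p.value
  sh_y <- if (const(ty)) NA_real_ else stats::shapiro.test(ty)$p.value
  # identical constant groups carry no distributional evidence; treat as
  # passing the gate so the (degenerate) t-test branch reports no effect
  normal <- isTRUE((is.na(sh_x) || sh_x > normality_alpha) &&
                     (is.na(sh_y) || sh_y > normality_alpha))
  if (normal) {
    if (const(c(tx, ty))) {
      res <- list(statistic = 0, p.value = 1)
      test <- "t_test"
    } else {
      ht <- stats::t.test(tx, ty, var.equal = var_equal)
      res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      test <- "t_test"
    }
  } else {
    ht <- suppressWarnings(stats::wilcox.test(tx, ty, exact = FALSE))
    res <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
    test <- "mann_whitney"
  }
  structure(list(
    test = test, statistic = res$statistic, p_value = res$p.value,
    stars = p_stars(res$p.value),
    shapiro_p = stats::setNames(c(sh_x, sh_y), group_names),
    normal = normal, groups = groups,
    estimate = mean(ty) - mean(tx), transform = transform),
    class = "spindle_stat")
}

#' @export
print.spindle_stat <- function(x, ...) {
  cat(sprintf("<spindle_stat> %s (gate: %s), p = %.4g %s\n",
              x$test, if (x$normal) "normal" else "non-normal",
              x$p_value, x$stars))
  print(x$groups, row.names = FALSE)
  invisible(x)
}

#' Two-way ANOVA with Tukey post hoc
#'
#' Treatment x myotube-type analysis of a continuous outcome (e.g.
#' per-myotube marker intensity), optionally square-root transformed
#' before fitting. Main effects and the interaction use type-II sums of
#' squares (cells are typically unbalanced), and all pairwise cell
#' comparisons are Tukey-adjusted.
#'
#' @param values Numeric outcome.
#' @param treatment,type Factors (>= 2 levels each); every crossed cell
#'   must be non-empty.
#' @param transform `"none"` or `"sqrt"`.
#' @return List of class `spindle_anova`: `anova` (term, df, F, p,
#'   stars), `tukey` (pairwise contrasts with Tukey-adjusted p),
#'   `cell_means` (n, mean, SEM per cell on the original scale),
#'   `transform`.
#' @export
two_way_anova_tukey <- function(values, treatment, type,
                                transform = c("none", "sqrt")) {
  transform <- match.arg(transform)
  treatment <- factor(treatment); type <- factor(type)
  if (nlevels(treatment) < 2L || nlevels(type) < 2L) {
    stop("both factors need at least 2 levels")
  }
  tab <- table(treatment, type)
  if (any(tab == 0L)) {
    empty <- which(tab == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty design cell: treatment '%s' x type '%s'",
                 rownames(tab)[empty[1]], colnames(tab)[empty[2]]))
  }
  v <- switch(transform, none = values, sqrt = {
    if (any(values < 0)) stop("sqrt transform requires non-negative data")
    sqrt(values)
  })
  d <- data.frame(v = v, treatment = treatment, type = type)
  fit <- stats::lm(v ~ treatment * type, data = d)
  an <- car::Anova(fit, type = 2)
  an_df <- data.frame(term = rownames(an), df = an$Df, f = an$`F value`,
                      p_value = an$`Pr(>F)`, row.names = NULL)
  an_df <- an_df[an_df$term != "Residuals", , drop = FALSE]
  an_df$stars <- p_stars(an_df$p_value)

  emm <- emmeans::emmeans(fit, ~ treatment * type)
  tk <- as.data.frame(emmeans::contrast(emm, method = "pairwise",
                                        adjust = "tukey"))
  tk$stars <- p_stars(tk$p.value)

  agg_n <- stats::aggregate(values, list(treatment = treatment, type = type),
                            FUN = length)
  agg_m <- stats::aggregate(values, list(treatment = treatment, type = type),
                            FUN = mean)
  agg_s <- stats::aggregate(values, list(treatment = treatment, type = type),
                            FUN = sem)
  cells <- data.frame(agg_n[, 1:2], n = agg_n$x, mean = agg_m$x,
                      sem = agg_s$x)
  structure(list(anova = an_df, tukey = tk, cell_means = cells,
                 transform = transform),
            class = "spindle_anova")
}

#' @export
print.spindle_anova <- function(x, ...) {
  cat(sprintf("<spindle_anova> (transform: %s)\n", x$transform))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Negative-binomial model for nuclei-per-myotube counts
#'
#' Counts of myonuclei per myotube are overdispersed relative to Poisson;
#' the model is a log-link negative-binomial regression with treatment
#' and myotube-type terms (dispersion estimated by maximum likelihood).
#' Reported effects are rate ratios.
#'
#' @param counts Non-negative integer counts.
#' @param treatment,type Factors.
#' @return List of class `spindle_nb`: `terms` (term, rate ratio, z, p,
#'   stars), `theta` (estimated NB size), `fit` (the `glm.nb` object).
#' @export
nuclei_count_model <- function(counts, treatment, type) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("`counts` must be non-negative integers")
  }
  d <- data.frame(count = as.integer(counts), treatment = factor(treatment),
                  type = factor(type))
  # ML theta estimation diverges on equi- or under-dispersed data; the
  # Poisson limit (theta -> Inf) is then the fitted model
  fit <- tryCatch(suppressWarnings(MASS::glm.nb(count ~ treatment + type,
                                                data = d)),
                  error = function(e) NULL)
  theta <- if (is.null(fit)) Inf else fit$theta
  if (is.null(fit)) {
    fit <- stats::glm(count ~ treatment + type, data = d,
                      family = stats::poisson())
  }
  sm <- summary(fit)$coefficients
  terms <- data.frame(term = rownames(sm), rate_ratio = exp(sm[, "Estimate"]),
                      z = sm[, "z value"], p_value = sm[, "Pr(>|z|)"],
                      row.names = NULL)
  terms$stars <- p_stars(terms$p_value)
  structure(list(terms = terms, theta = theta, fit = fit),
            class = "spindle_nb")
}

#' @export
print.spindle_nb <- function(x, ...) {
  cat(sprintf("<spindle_nb> theta = %.2f\n", x$theta))
  print(x$terms, row.names = FALSE)
  invisible(x)
}
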