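#' Generate a qPCR Ct table realising requested fold changes
#'
#' Emits control and treated sample Ct triplicates such that the expected
#' fold change recovered by the delta-delta-Ct pipeline
#' ([relative_expression()]) equals the requested fold for every gene.
#' Construction is in cycle space: the reference gene has a fixed Ct, each
#' target gene a per-gene baseline Ct, and treated samples have their
#' target Ct lowered by `log2(fold)` cycles. Per-sample offsets are
#' applied to *all* wells of a sample (they cancel through the reference),
#' and Gaussian replicate noise of `ct_noise_sd` cycles is added per well.
#' With `ct_noise_sd = 0` the pipeline round-trips each fold exactly.
#'
#' @param fold_changes Named numeric vector, gene -> fold (> 0). Must not
#'   contain the reference gene.
#' @param reference_gene Reference (housekeeping) gene id, default
#'   `"Csnk2a2"`.
#' @param n_samples Samples per condition (default 9: three experimental
#'   repeats, each with three technical repeats, treated as n).
#' @param ct_noise_sd Replicate noise SD in cycles.
#' @param seed Integer seed.
#' @param plate Plate id recorded in the table.
#' @param sample_sd SD of the per-sample global Ct offset (cycles);
#'   cancels in the pipeline, defaults to 0.
#' @return A data.frame with columns `sample`, `condition`, `plate`,
#'   `gene`, `ct1`, `ct2`, `ct3`.
#' @examples
#' ct <- generate_ct_table(c(Egr3 = 3.5), n_samples = 3,
#'                         ct_noise_sd = 0, seed = 1)
#' head(ct)
#' @export
generate_ct_table <- function(fold_changes, reference_gene = "Csnk2a2",
                              n_samples = 9, ct_noise_sd = 0.15, seed = 1,
                              plate = 1L, sample_sd = 0) {
  if (is.null(names(fold_changes)) || any(!nzchar(names(fold_changes)))) {
    stop("`fold_changes` must be a named vector (gene -> fold)")
  }
  if (any(fold_changes <= 0)) stop("fold changes must be > 0")
  if (reference_gene %in% names(fold_changes)) {
    stop("`reference_gene` must not appear in `fold_changes`")
  }
  genes <- names(fold_changes)
  with_seed(seed, {
    baseline <- stats::setNames(stats::runif(length(genes), 24, 30), genes)
    ref_ct <- 20
    rows <- list()
    for (cond in c("control", "treated")) {
      for (s in seq_len(n_samples)) {
        samp_id <- sprintf("%s_%02d", cond, s)
        offset <- stats::rnorm(1L, 0, sample_sd)
        mean_cts <- c(
          stats::setNames(ref_ct, reference_gene),
          baseline - if (cond == "treated") log2(fold_changes) else 0
        ) + offset
        for (g in names(mean_cts)) {
          reps <- mean_cts[[g]] + stats::rnorm(3L, 0, ct_noise_sd)
          rows[[length(rows) + 1L]] <- data.frame(
            sample = samp_id, condition = cond, plate = plate, gene = g,
            ct1 = reps[1], ct2 = reps[2], ct3 = reps[3])
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a western-blot density table realising requested folds
#'
#' Band and loading-control (GAPDH) densities per lane such that the
#' adjusted relative density method ([adjusted_relative_density()])
#' recovers the requested fold per target in expectation; exactly so at
#' zero noise.
#'
#' @param adjusted_folds Named numeric vector, target -> fold (> 0).
#' @param n_repeats Lanes (biological repeats) per condition, default 3.
#' @param seed Integer seed.
#' @param noise_cv Multiplicative log-normal noise CV applied to band and
#'   loading densities independently (default 0).
#' @return A data.frame with columns `lane`, `condition`, `target`,
#'   `band_density`, `gapdh_density`.
#' @examples
#' generate_blot_table(c(MyHC3 = 0.27), n_repeats = 2, seed = 1)
#' @export
generate_blot_table <- function(adjusted_folds, n_repeats = 3, seed = 1,
                                noise_cv = 0) {
  if (is.null(names(adjusted_folds)) || any(!nzchar(names(adjusted_folds)))) {
    stop("`adjusted_folds` must be a named vector (target -> fold)")
  }
  if (any(adjusted_folds <= 0)) stop("folds must be > 0")
  with_seed(seed, {
    sdlog <- sqrt(log(1 + noise_cv^2))
    rows <- list()
    for (tg in names(adjusted_folds)) {
      base_ratio <- stats::runif(1L, 0.5, 2)
      for (cond in c("control", "treated")) {
        fold <- if (cond == "treated") adjusted_folds[[tg]] else 1
        for (l in seq_len(n_repeats)) {
          gapdh <- 1000 * stats::runif(1L, 0.7, 1.3)
          if (noise_cv > 0) gapdh <- gapdh * stats::rlnorm(1L, -sdlog^2 / 2, sdlog)
          band <- base_ratio * fold * gapdh
          if (noise_cv > 0) band <- band * stats::rlnorm(1L, -sdlog^2 / 2, sdlog)
          rows[[length(rows) + 1L]] <- data.frame(
            lane = sprintf("%s_%s_%d", tg, cond, l), condition = cond,
            target = tg, band_density = band, gapdh_density = gapdh)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Generate a viability (resazurin) assay plate table
#'
#' Relative-fluorescence readings for media-only blanks, control and
#' treated wells such that blank-corrected treated/control fold equals
#' `fold` in expectation ([viability_fold()] recovers it).
#'
#' @param fold Treated vs control fold after blank correction.
#' @param n_wells Wells per condition.
#' @param blank_rfu Mean media-only background signal.
#' @param signal_rfu Mean blank-corrected control signal.
#' @param noise_sd Additive Gaussian noise SD on each reading.
#' @param seed Integer seed.
#' @return A data.frame with columns `well`, `condition`, `rfu`;
#'   blank wells have `condition == "blank"`.
#' @export
generate_assay_table <- function(fold = 1.15, n_wells = 9, blank_rfu = 200,
                                 signal_rfu = 1000, noise_sd = 0, seed = 1) {
  if (fold <= 0) stop("`fold` must be > 0")
  with_seed(seed, {
    mk <- function(cond, mean_rfu, n) data.frame(
      well = sprintf("%s_%02d", cond, seq_len(n)), condition = cond,
      rfu = mean_rfu + stats::rnorm(n, 0, noise_sd))
    rbind(mk("blank", blank_rfu, 3L),
          mk("control", blank_rfu + signal_rfu, n_wells),
          mk("treated", blank_rfu + fold * signal_rfu, n_wells))
  })
}
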