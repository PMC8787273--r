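#' Quality-control filter for qPCR primer pairs
#'
#' A primer pair is retained when its amplification efficiency lies in
#' [90, 115]\% (bounds inclusive), its standard-curve r^2 exceeds 0.95
#' (strict), and its melt curve shows a single peak. Each rejection is
#' annotated with the rule(s) it failed.
#'
#' @param primers data.frame with columns `gene`, `efficiency` (percent),
#'   `r2`, `single_peak` (logical). Extra columns pass through.
#' @param efficiency_range Inclusive efficiency bounds, default
#'   `c(90, 115)`.
#' @param r2_min Strict lower bound on r^2, default 0.95.
#' @return The input with logical `pass` and character `reason` columns
#'   (empty string when passing).
#' @examples
#' qc_filter_primers(data.frame(gene = "Csnk2a2", efficiency = 97.9,
#'                              r2 = 0.99, single_peak = TRUE))$pass
#' @export
qc_filter_primers <- function(primers, efficiency_range = c(90, 115),
                              r2_min = 0.95) {
  stopifnot(all(c("gene", "efficiency", "r2", "single_peak") %in%
                  names(primers)))
  reasons <- vapply(seq_len(nrow(primers)), function(i) {
    r <- character(0)
    e <- primers$efficiency[i]
    if (is.na(e) || e < efficiency_range[1] || e > efficiency_range[2]) {
      r <- c(r, sprintf("efficiency %.1f%% outside [%g, %g]", e,
                        efficiency_range[1], efficiency_range[2]))
    }
    if (is.na(primers$r2[i]) || primers$r2[i] <= r2_min) {
      r <- c(r, sprintf("r2 %.3f not above %g", primers$r2[i], r2_min))
    }
    if (!isTRUE(primers$single_peak[i])) {
      r <- c(r, "melt curve lacks a single peak")
    }
    paste(r, collapse = "; ")
  }, character(1))
  primers$pass <- !nzchar(reasons)
  primers$reason <- reasons
  primers
}

#' Bundled primer reference table
#'
#' Loads the package's qPCR primer table (sequences, accession codes and
#' measured amplification efficiencies for the 18 assayed mouse genes;
#' the r^2 and melt-peak columns record the nominal pass status all
#' retained assays met).
#'
#' @return data.frame with columns `gene`, `forward`, `reverse`,
#'   `efficiency`, `r2`, `single_peak`, `accession`.
#' @export
primer_table <- function() {
  p <- system.file("extdata", "primers_qpcr.csv", package = "spindlemorph",
                   mustWork = TRUE)
  utils::read.csv(p, stringsAsFactors = FALSE)
}

#' Relative gene expression by the delta-delta-Ct method
#'
#' Triplicate Ct values are averaged per well set; delta Ct = mean Ct of
#' the gene minus mean Ct of the reference gene within the same sample
#' and plate; delta-delta Ct subtracts the mean delta Ct of the control
#' samples on the same plate (per gene); fold change = 2^(-delta-delta
#' Ct), i.e. expression relative to the experimental control mean of each
#' plate. Replicate SDs above `replicate_sd_warn` cycles are flagged.
#'
#' @param ct data.frame with columns `sample`, `condition`, `plate`,
#'   `gene`, `ct1`, `ct2`, `ct3` ([generate_ct_table()] schema).
#' @param reference_gene Reference gene id (default `"Csnk2a2"`); must be
#'   present for every sample/plate (samples lacking it are dropped with
#'   a warning).
#' @param control_label Condition label of the control group.
#' @param efficiencies Optional named vector of primer efficiencies
#'   (percent). When supplied, the per-gene amplification factor
#'   `1 + efficiency/100` replaces 2 in the exponentiation
#'   (efficiency-corrected mode; off by default).
#' @param replicate_sd_warn Triplicate SD (cycles) above which a QC
#'   warning is recorded, default 0.5.
#' @return data.frame with one row per sample x gene: `sample`,
#'   `condition`, `plate`, `gene`, `mean_ct`, `ct_sd`, `delta_ct`,
#'   `delta_delta_ct`, `fold_change`, `replicate_flag`.
#' @examples
#' ct <- generate_ct_table(c(Egr3 = 3.5), n_samples = 3, ct_noise_sd = 0,
#'                         seed = 1)
#' ex <- relative_expression(ct)
#' unique(ex$fold_change[ex$condition == "treated"])
#' @export
relative_expression <- function(ct, reference_gene = "Csnk2a2",
                                control_label = "control",
                                efficiencies = NULL,
                                replicate_sd_warn = 0.5) {
  need <- c("sample", "condition", "plate", "gene", "ct1", "ct2", "ct3")
  stopifnot(all(need %in% names(ct)))
  if (!any(ct$condition == control_label)) {
    stop(sprintf("no samples with control label '%s'", control_label))
  }
  reps <- as.matrix(ct[, c("ct1", "ct2", "ct3")])
  bad <- reps <= 0 | reps > 40
  if (any(bad, na.rm = TRUE)) {
    warning(sprintf("%d Ct replicate(s) outside (0, 40] cycles",
                    sum(bad, na.rm = TRUE)))
  }
  ct$mean_ct <- rowMeans(reps, na.rm = TRUE)
  ct$ct_sd <- apply(reps, 1L, stats::sd, na.rm = TRUE)
  ct$replicate_flag <- !is.na(ct$ct_sd) & ct$ct_sd > replicate_sd_warn

  key <- interaction(ct$sample, ct$plate, drop = TRUE)
  ref_rows <- ct$gene == reference_gene
  ref_ct <- stats::setNames(ct$mean_ct[ref_rows],
                            as.character(key[ref_rows]))
  has_ref <- as.character(key) %in% names(ref_ct)
  if (!all(has_ref)) {
    warning(sprintf(
      "dropping %d sample(s) lacking the reference gene '%s'",
      length(unique(key[!has_ref])), reference_gene))
    ct <- ct[has_ref, , drop = FALSE]
    key <- key[has_ref]
  }
  ct$delta_ct <- ct$mean_ct - ref_ct[as.character(key)]

  out <- ct[ct$gene != reference_gene, , drop = FALSE]
  out$delta_delta_ct <- NA_real_
  for (pl in unique(out$plate)) {
    sel_pl <- out$plate == pl
    if (!any(out$condition[sel_pl] == control_label)) {
      stop(sprintf("plate '%s' has no control samples", pl))
    }
    for (g in unique(out$gene[sel_pl])) {
      sel <- sel_pl & out$gene == g
      ctrl_mean <- mean(out$delta_ct[sel & out$condition == control_label])
      out$delta_delta_ct[sel] <- out$delta_ct[sel] - ctrl_mean
    }
  }
  base <- rep(2, nrow(out))
  if (!is.null(efficiencies)) {
    hit <- efficiencies[out$gene]
    base <- ifelse(is.na(hit), 2, 1 + hit / 100)
  }
  out$fold_change <- base^(-out$delta_delta_ct)
  rownames(out) <- NULL
  out[, c("sample", "condition", "plate", "gene", "mean_ct", "ct_sd",
          "delta_ct", "delta_delta_ct", "fold_change", "replicate_flag")]
}

#' Proportional myosin heavy chain composition
#'
#' Per sample, each detected Myh isoform's delta-Ct is linearised as
#' 2^(-delta Ct) and expressed as a percentage of the summed linearised
#' expression over all detected Myh isoforms in that sample — the
#' proportional representation of Myh expression. Undetected isoforms
#' (missing delta Ct) are excluded and listed in the `"undetected"`
#' attribute.
#'
#' @param expression [relative_expression()] output (needs `sample`,
#'   `gene`, `delta_ct`).
#' @param myh_genes Character vector of Myh gene ids; default: every gene
#'   whose id starts with `"Myh"`.
#' @return data.frame `sample`, `condition` (if present), `gene`,
#'   `proportion_pct`; proportions sum to 100 within each sample.
#' @examples
#' ex <- data.frame(sample = "s1", gene = c("Myh1", "Myh4"),
#'                  delta_ct = c(5, 4))
#' myh_proportions(ex)$proportion_pct  # 33.33 / 66.67
#' @export
myh_proportions <- function(expression, myh_genes = NULL) {
  stopifnot(all(c("sample", "gene", "delta_ct") %in% names(expression)))
  if (is.null(myh_genes)) {
    myh_genes <- unique(grep("^Myh", expression$gene, value = TRUE))
  }
  sub <- expression[expression$gene %in% myh_genes, , drop = FALSE]
  undetected <- unique(sub$gene[is.na(sub$delta_ct)])
  sub <- sub[!is.na(sub$delta_ct), , drop = FALSE]
  if (nrow(sub) == 0L) stop("no detectable Myh isoforms")
  if (length(unique(sub$gene)) < 2L) {
    stop("need at least 2 detected Myh isoforms for a proportional share")
  }
  sub$lin <- 2^(-sub$delta_ct)
  tot <- stats::aggregate(lin ~ sample, data = sub, FUN = sum)
  names(tot)[2] <- "total"
  sub <- merge(sub, tot, by = "sample")
  sub$proportion_pct <- 100 * sub$lin / sub$total
  keep <- intersect(c("sample", "condition", "gene", "proportion_pct"),
                    names(sub))
  out <- sub[order(sub$sample, sub$gene), keep, drop = FALSE]
  rownames(out) <- NULL
  attr(out, "undetected") <- undetected
  out
}

#' Western-blot adjusted relative density
#'
#' Two-step normalisation: each lane's target band density is divided by
#' its loading-control (GAPDH) density, and the lane ratio is then
#' expressed relative to the mean ratio of the control lanes of the same
#' target.
#'
#' @param lanes data.frame with columns `lane`, `condition`, `target`,
#'   `band_density`, `gapdh_density` ([generate_blot_table()] schema).
#' @param control_label Condition label of the control lanes.
#' @return The input plus `ratio` and `fold` columns.
#' @examples
#' b <- generate_blot_table(c(MyHC3 = 0.27), seed = 1)
#' unique(round(adjusted_relative_density(b)$fold, 10))
#' @export
adjusted_relative_density <- function(lanes, control_label = "control") {
  need <- c("lane", "condition", "target", "band_density", "gapdh_density")
  stopifnot(all(need %in% names(lanes)))
  if (any(lanes$gapdh_density <= 0)) {
    stop("zero or negative loading-control density")
  }
  lanes$ratio <- lanes$band_density / lanes$gapdh_density
  lanes$fold <- NA_real_
  for (tg in unique(lanes$target)) {
    sel <- lanes$target == tg
    ctrl <- sel & lanes$condition == control_label
    if (!any(ctrl)) {
      stop(sprintf("target '%s' has no control lanes", tg))
    }
    lanes$fold[sel] <- lanes$ratio[sel] / mean(lanes$ratio[ctrl])
  }
  lanes
}

#' Viability fold change from blank-corrected fluorescence readings
#'
#' Readings are corrected to the media-only blank mean; each condition's
#' fold is its mean corrected signal over the control mean.
#'
#' @param readings data.frame with `condition` and `rfu` columns;
#'   rows with `condition == blank_label` are the media-only blanks (no
#'   blanks present means no correction).
#' @param control_label,blank_label Condition labels.
#' @return data.frame `condition`, `mean_corrected_rfu`, `fold`.
#' @examples
#' a <- generate_assay_table(fold = 1.15, seed = 1)
#' viability_fold(a)
#' @export
viability_fold <- function(readings, control_label = "control",
                           blank_label = "blank") {
  stopifnot(all(c("condition", "rfu") %in% names(readings)))
  blank_mean <- if (any(readings$condition == blank_label)) {
    mean(readings$rfu[readings$condition == blank_label])
  } else 0
  exp_rows <- readings[readings$condition != blank_label, , drop = FALSE]
  if (!any(exp_rows$condition == control_label)) {
    stop(sprintf("no '%s' readings", control_label))
  }
  exp_rows$corrected <- exp_rows$rfu - blank_mean
  agg <- stats::aggregate(corrected ~ condition, data = exp_rows, FUN = mean)
  names(agg)[2] <- "mean_corrected_rfu"
  ctrl <- agg$mean_corrected_rfu[agg$condition == control_label]
  if (ctrl <= 0) stop("control mean is not positive after blank correction")
  agg$fold <- agg$mean_corrected_rfu / ctrl
  agg
}
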