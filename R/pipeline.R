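#' Run the full synthetic two-arm analysis pipeline
#'
#' Orchestrates simulate -> morphometry -> intensity -> expression ->
#' stats into one reproducible run: trains DDR thresholds on a simulated
#' control training set (or uses supplied thresholds), generates and
#' measures `n_fields` fields per arm, calibrates and measures the marker
#' channel against a primary negative, quantifies synthetic qPCR /
#' western / viability tables, and applies the statistical decision
#' procedure to the field-level and per-myotube outcomes. A single
#' top-level seed is fanned out deterministically to per-stage child
#' seeds (`stage_seed = (seed * 1000 + stage_index) mod (2^31 - 1)`), so
#' re-running with the same seed and configuration reproduces the report
#' exactly.
#'
#' @param seed Top-level integer seed.
#' @param n_fields Fields of view per arm (default 9, three experimental
#'   repeats with three technical repeats each).
#' @param conditions Named list of two [condition_params()] objects
#'   (first is the control arm).
#' @param fov_shape Field size in pixels.
#' @param thresholds Optional `ddr_thresholds`; when `NULL` they are
#'   derived from a simulated training set of `n_training` myotubes per
#'   class measured from control fields.
#' @param n_training Training myotubes per class (default 10).
#' @param stages Character vector of stages to run (subset of
#'   `"simulate"`, `"morphometry"`, `"intensity"`, `"expression"`,
#'   `"stats"`; later stages require earlier ones).
#' @param qpcr_folds,blot_folds Named fold-change vectors for the
#'   synthetic expression tables; defaults reproduce the study's
#'   measured fold changes.
#' @param viability_fold_setting Treated viability fold (default 1.15).
#' @param out_dir Optional directory; when given, per-field summaries,
#'   expression tables, stats tables and the configuration are written
#'   as CSV/YAML.
#' @return List of class `spindle_run` with elements `config`,
#'   `thresholds`, `fields` (per-field [summarise_field()] rows with arm
#'   labels), `instances` (per-myotube measurements, arm-labelled),
#'   `intensity`, `expression`, `stats`.
#' @export
run_pipeline <- function(seed = 1,
                         n_fields = 9,
                         conditions = list(control = condition_params("control"),
                                           nrg1 = condition_params("nrg1")),
                         fov_shape = c(768, 768),
                         thresholds = NULL,
                         n_training = 10,
                         stages = c("simulate", "morphometry", "intensity",
                                    "expression", "stats"),
                         qpcr_folds = c(Egr3 = 3.5, Myod1 = 1.49,
                                        Myh1 = 0.49, Myh2 = 0.51,
                                        Myh3 = 0.76, Myh4 = 2.17,
                                        Myh6 = 0.44, Myh7 = 0.58,
                                        Myh8 = 0.16, Etv4 = 2.88),
                         blot_folds = c(MyHC3 = 0.27, MyHC8 = 0.43,
                                        MyHC6 = 0.54, Egr3 = 2.24),
                         viability_fold_setting = 1.15,
                         out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  stopifnot(length(conditions) == 2L, !is.null(names(conditions)))
  child <- function(k) as.integer((as.numeric(seed) * 1000 + k) %%
                                    (2^31 - 1))
  arms <- names(conditions)
  run <- list(config = list(seed = seed, n_fields = n_fields,
                            fov_shape = fov_shape, arms = arms,
                            stages = stages))

  # --- simulate -------------------------------------------------------
  fields <- NULL
  if ("simulate" %in% stages) {
    fields <- lapply(seq_along(arms), function(a) {
      lapply(seq_len(n_fields), function(i) {
        generate_field(conditions[[a]], seed = child(100 * a + i),
                       fov_shape = fov_shape)
      })
    })
    names(fields) <- arms
    run$ground_truth <- do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(seq_len(n_fields), function(i) {
        gt <- fields[[a]][[i]]$ground_truth
        if (nrow(gt)) cbind(arm = a, field = i, gt) else NULL
      }))
    }))
  }

  # --- thresholds + morphometry --------------------------------------
  measurements <- NULL
  if ("morphometry" %in% stages) {
    if (is.null(fields)) stop("morphometry requires the simulate stage")
    if (is.null(thresholds)) {
      thresholds <- train_thresholds(conditions[[1]], seed = child(9),
                                     n_per_class = n_training,
                                     fov_shape = fov_shape)
    }
    measurements <- lapply(arms, function(a) {
      lapply(fields[[a]], function(f) measure_field(f$micrograph, thresholds))
    })
    names(measurements) <- arms
    run$fields <- do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(seq_len(n_fields), function(i) {
        cbind(arm = a, field = i, measurements[[a]][[i]]$summary)
      }))
    }))
    run$instances <- do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(seq_len(n_fields), function(i) {
        inst <- measurements[[a]][[i]]$instances
        if (nrow(inst)) cbind(arm = a, field = i, inst) else NULL
      }))
    }))
  }
  run$thresholds <- thresholds

  # --- intensity ------------------------------------------------------
  if ("intensity" %in% stages) {
    if (is.null(measurements)) stop("intensity requires morphometry")
    pn <- generate_primary_negative(child(7), fov_shape,
                                    noise_scale = conditions[[1]]$noise_sd)
    calib <- calibrate_background(pn)
    per_field <- do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(seq_len(n_fields), function(i) {
        mg <- fields[[a]][[i]]$micrograph
        corr <- subtract_background(mg, calib)
        meas <- measurements[[a]][[i]]
        ipn <- intensity_per_nucleus(corr, nrow(meas$nuclei))
        pos <- positive_nuclei_pct(corr, meas$nuclei,
                                   pixel_size = mg$pixel_size)
        data.frame(arm = a, field = i, coverage_pct = coverage(corr),
                   intensity_per_nucleus = ipn$value,
                   positive_nuclei_pct = pos$pct)
      }))
    }))
    ctrl_mean <- mean(per_field$intensity_per_nucleus[per_field$arm == arms[1]])
    per_field$fold_vs_control <- per_field$intensity_per_nucleus / ctrl_mean
    run$intensity <- list(calibration = calib, per_field = per_field)
    # per-myotube marker means for the two-way ANOVA
    run$myotube_intensity <- do.call(rbind, lapply(arms, function(a) {
      do.call(rbind, lapply(seq_len(n_fields), function(i) {
        mg <- fields[[a]][[i]]$micrograph
        corr <- subtract_background(mg, calib)
        meas <- measurements[[a]][[i]]
        inst <- meas$instances
        if (!nrow(inst)) return(NULL)
        vals <- vapply(inst$id, function(id) {
          myotube_mean_intensity(corr, meas$candidates$labels, id = id)
        }, numeric(1))
        data.frame(arm = a, field = i, id = inst$id,
                   class = as.character(inst$class), intensity = vals)
      }))
    }))
  }

  # --- expression -----------------------------------------------------
  if ("expression" %in% stages) {
    ct <- generate_ct_table(qpcr_folds, n_samples = n_fields,
                            ct_noise_sd = 0.15, seed = child(5))
    expr <- relative_expression(ct)
    blot <- generate_blot_table(blot_folds, n_repeats = 3, seed = child(6),
                                noise_cv = 0.05)
    assay <- generate_assay_table(fold = viability_fold_setting,
                                  n_wells = n_fields, noise_sd = 10,
                                  seed = child(8))
    run$expression <- list(
      ct_table = ct, records = expr,
      myh = myh_proportions(expr),
      blot = adjusted_relative_density(blot),
      viability = viability_fold(assay),
      primers = qc_filter_primers(primer_table()))
  }

  # --- stats ----------------------------------------------------------
  if ("stats" %in% stages) {
    if (is.null(run$fields)) stop("stats requires morphometry")
    st <- list()
    bag_ctrl <- run$fields$bag_pct[run$fields$arm == arms[1]]
    bag_trt <- run$fields$bag_pct[run$fields$arm == arms[2]]
    if (sum(!is.na(bag_ctrl)) >= 3 && sum(!is.na(bag_trt)) >= 3) {
      st$bag_pct <- gated_two_group_test(bag_ctrl[!is.na(bag_ctrl)],
                                         bag_trt[!is.na(bag_trt)],
                                         group_names = arms)
    }
    inst <- run$instances
    inst_cl <- inst[inst$class != "unassigned", , drop = FALSE]
    if (nrow(inst_cl) && all(table(inst_cl$arm, inst_cl$class) > 0)) {
      st$nuclei_counts <- nuclei_count_model(inst_cl$nuclei, inst_cl$arm,
                                             inst_cl$class)
    }
    if (!is.null(run$myotube_intensity)) {
      mi <- run$myotube_intensity
      mi <- mi[mi$class != "unassigned", , drop = FALSE]
      if (nrow(mi) && all(table(mi$arm, mi$class) > 0)) {
        st$egr3_anova <- two_way_anova_tukey(mi$intensity, mi$arm, mi$class,
                                             transform = "sqrt")
      }
    }
    run$stats <- st
  }

  if (!is.null(out_dir)) .write_run(run, out_dir)
  structure(run, class = "spindle_run")
}

#' Derive DDR thresholds from a simulated training set
#'
#' Generates control-condition fields and accumulates measured DDR values
#' for myotubes of known true class (matched through the ground truth)
#' until `n_per_class` training values per class are available, then
#' calls [derive_thresholds()]. Mirrors a manual training set of
#' identified linear and bag myotubes.
#'
#' @param params A [condition_params()] object (training uses its
#'   condition; bag examples are rare in controls, so a boosted bag
#'   fraction of at least 0.3 is used for training fields).
#' @param seed Integer seed.
#' @param n_per_class Training myotubes per class (default 10).
#' @param fov_shape Field size in px.
#' @param max_fields Safety cap on generated training fields.
#' @return A `ddr_thresholds` object.
#' @export
train_thresholds <- function(params, seed = 1, n_per_class = 10,
                             fov_shape = c(768, 768), max_fields = 60) {
  tr_params <- condition_params(
    params$condition, bag_fraction = max(params$bag_fraction, 0.3),
    noise_sd = params$noise_sd)
  lin <- numeric(0); bag <- numeric(0)
  for (i in seq_len(max_fields)) {
    f <- generate_field(tr_params, seed = seed * 100 + i,
                        fov_shape = fov_shape)
    cand <- segment_myotubes(f$micrograph)
    gt <- match_instances(f, cand)
    for (j in seq_len(nrow(gt))) {
      if (is.na(gt$label[j])) next
      prof <- width_profile(cand$labels == gt$label[j],
                            f$micrograph$pixel_size,
                            labels = cand$labels, id = gt$label[j])
      if (isTRUE(attr(prof, "unmeasurable")) || nrow(prof) < 2L) next
      d <- compute_ddr(prof)
      if (gt$class[j] == "bag" && length(bag) < n_per_class) {
        bag <- c(bag, d)
      } else if (gt$class[j] == "linear" && length(lin) < n_per_class) {
        lin <- c(lin, d)
      }
    }
    if (length(lin) >= n_per_class && length(bag) >= n_per_class) break
  }
  if (length(lin) < 2L || length(bag) < 2L) {
    stop("could not accumulate enough training myotubes")
  }
  derive_thresholds(lin, bag)
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(run$config, file.path(out_dir, "config.yaml"))
  if (!is.null(run$thresholds)) {
    yaml::write_yaml(unclass(run$thresholds),
                     file.path(out_dir, "ddr_thresholds.yaml"))
  }
  wr <- function(x, f) if (!is.null(x)) {
    utils::write.csv(x, file.path(out_dir, f), row.names = FALSE)
  }
  wr(run$fields, "field_summaries.csv")
  wr(run$instances, "myotube_instances.csv")
  wr(run$intensity$per_field, "intensity_per_field.csv")
  wr(run$myotube_intensity, "myotube_intensity.csv")
  wr(run$expression$records, "expression_records.csv")
  wr(run$expression$myh, "myh_proportions.csv")
  wr(run$expression$blot, "blot_folds.csv")
  wr(run$expression$viability, "viability_folds.csv")
  invisible(out_dir)
}

#' @export
print.spindle_run <- function(x, ...) {
  cat(sprintf("<spindle_run> seed %d, %d fields/arm (%s)\n",
              x$config$seed, x$config$n_fields,
              paste(x$config$arms, collapse = " vs ")))
  if (!is.null(x$fields)) {
    agg <- stats::aggregate(cbind(bag_pct, fusion_efficiency,
                                  nuclei_per_fov) ~ arm, data = x$fields,
                            FUN = mean, na.rm = TRUE)
    print(agg, row.names = FALSE)
  }
  invisible(x)
}
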