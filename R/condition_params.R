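#' Condition parameters for the synthetic field generator
#'
#' Bundles the statistical settings that define one experimental arm
#' (control or neuregulin-1 treated) of a simulated differentiation
#' experiment: how many myotubes and nuclei a field of view contains, what
#' fraction of myotubes carry the fusiform "bag" morphology, the
#' diameter-difference-ratio (DDR) distributions of the two classes, how
#' nuclei distribute over myotubes, and how the marker (Egr3) channel is
#' lit per class. Defaults for both arms reproduce the study conditions
#' of the underlying experiment (8-day differentiated C2C12 cultures,
#' with and without 100 ng/ml Nrg-1).
#'
#' @param condition `"control"` or `"nrg1"`; selects the default set.
#' @param ... Named overrides of any default listed below.
#'
#' @details Core fields (per arm): `bag_fraction` (proportion of myotubes
#' with bag morphology), `myotubes_per_fov` (Poisson mean),
#' `nuclei_per_fov_mean` (Poisson mean of all nuclei in a field),
#' `fusion_efficiency` (expected fraction of nuclei residing inside
#' myotubes), `linear_ddr_mean`/`linear_ddr_sd` and
#' `bag_ddr_mean`/`bag_ddr_sd` (true-DDR normal distributions, truncated
#' at > 1), `nuclei_per_linear_mean`/`nuclei_per_bag_mean` (per-myotube
#' nuclei count means), `nb_dispersion` (shared negative-binomial size;
#' variance is about twice the mean at these counts),
#' `area_per_nucleus_mean` (um^2 of myotube area per myonucleus, sets
#' fibre length), `marker_intensity_by_type` (relative marker intensity
#' per class) and `positive_nuclei_fraction_by_type` (probability that a
#' nucleus is marker-positive, per class; unfused cells use the linear
#' value).
#'
#' Rendering fields (shared defaults): `pixel_size` (0.65 um/px),
#' `mean_width` (expected mean fibre width, um), `nucleus_diameter`
#' (10 um), `noise_sd` (additive Gaussian noise SD, grey levels; default
#' 2\% of the 16-bit range), `actin_level`, `dapi_level`, `marker_gain`
#' (grey levels per relative intensity unit), `nuclear_marker_level`
#' (grey levels added over a positive nucleus) and `bit_depth`.
#'
#' @return A validated list of class `condition_params`.
#' @examples
#' p <- condition_params("control")
#' p$bag_fraction
#' condition_params("nrg1", noise_sd = 0)$noise_sd
#' @export
condition_params <- function(condition = c("control", "nrg1"), ...) {
  condition <- match.arg(condition)
  base <- list(
    condition = condition,
    # shared rendering defaults
    pixel_size = 0.65,
    mean_width = 16,
    mean_width_sd = 2.4,
    nucleus_diameter = 10,
    noise_sd = 0.02 * (2^16 - 1),
    actin_level = 30000,
    dapi_level = 30000,
    marker_gain = 8000,
    nuclear_marker_level = 20000,
    bit_depth = 16L,
    nb_dispersion = 6,
    linear_ddr_mean = 1.81, linear_ddr_sd = 0.37,
    bag_ddr_mean = 4.03, bag_ddr_sd = 1.32
  )
  arm <- if (condition == "control") {
    list(
      bag_fraction = 0.0852,
      myotubes_per_fov = 8.33,
      nuclei_per_fov_mean = 104.8,
      fusion_efficiency = 0.4688,
      nuclei_per_linear_mean = 5.48,
      nuclei_per_bag_mean = 8.09,
      area_per_nucleus_mean = 645.3,
      marker_intensity_by_type = c(linear = 0.88, bag = 1.85),
      positive_nuclei_fraction_by_type = c(linear = 0.486, bag = 0.55)
    )
  } else {
    list(
      bag_fraction = 0.4161,
      myotubes_per_fov = 9.22,
      nuclei_per_fov_mean = 136.3,
      fusion_efficiency = 0.4741,
      nuclei_per_linear_mean = 6.10,
      nuclei_per_bag_mean = 8.33,
      area_per_nucleus_mean = 537.9,
      marker_intensity_by_type = c(linear = 2.50, bag = 6.13),
      positive_nuclei_fraction_by_type = c(linear = 0.60, bag = 0.721)
    )
  }
  p <- utils::modifyList(c(base, arm), list(...))
  validate_condition_params(p)
  structure(p, class = "condition_params")
}

validate_condition_params <- function(p) {
  prop <- c("bag_fraction", "fusion_efficiency")
  for (f in prop) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      stop(sprintf("`%s` must be a proportion in [0, 1]", f))
    }
  }
  pos <- c("myotubes_per_fov", "nuclei_per_fov_mean", "linear_ddr_sd",
           "bag_ddr_sd", "linear_ddr_mean", "bag_ddr_mean",
           "nuclei_per_linear_mean", "nuclei_per_bag_mean", "nb_dispersion",
           "area_per_nucleus_mean", "pixel_size", "mean_width",
           "nucleus_diameter")
  for (f in pos) {
    if (!is.numeric(p[[f]]) || p[[f]] <= 0) {
      stop(sprintf("`%s` must be a positive number", f))
    }
  }
  if (p$linear_ddr_mean >= p$bag_ddr_mean) {
    stop("`linear_ddr_mean` must be below `bag_ddr_mean`")
  }
  if (p$noise_sd < 0) stop("`noise_sd` must be >= 0")
  for (f in c("marker_intensity_by_type", "positive_nuclei_fraction_by_type")) {
    v <- p[[f]]
    if (!all(c("linear", "bag") %in% names(v))) {
      stop(sprintf("`%s` needs entries 'linear' and 'bag'", f))
    }
  }
  pf <- p$positive_nuclei_fraction_by_type
  if (any(pf < 0 | pf > 1)) {
    stop("`positive_nuclei_fraction_by_type` entries must be in [0, 1]")
  }
  if (p$bag_fraction > 0 && p$myotubes_per_fov <= 0) {
    stop("degenerate parameters: positive `bag_fraction` with no myotubes")
  }
  invisible(p)
}

#' @export
print.condition_params <- function(x, ...) {
  cat(sprintf(
    paste0("<condition_params: %s>\n",
           "  bag fraction %.3f | myotubes/FOV %.2f | nuclei/FOV %.1f | ",
           "fusion eff. %.3f\n",
           "  DDR linear N(%.2f, %.2f^2), bag N(%.2f, %.2f^2)\n"),
    x$condition, x$bag_fraction, x$myotubes_per_fov, x$nuclei_per_fov_mean,
    x$fusion_efficiency, x$linear_ddr_mean, x$linear_ddr_sd,
    x$bag_ddr_mean, x$bag_ddr_sd))
  invisible(x)
}
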