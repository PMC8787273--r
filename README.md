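# spindlemorph

Quantification of intrafusal **bag myotubes** in cultured skeletal
muscle. When differentiating C2C12 myoblasts are treated with
neuregulin-1 (Nrg-1, mimicking Ia afferent innervation), a
subpopulation of myotubes acquires the fusiform morphology of muscle
spindle bag fibres — a bulging equatorial region with clustered nuclei —
and upregulates the intrafusal transcription factor Egr3. This package
implements the full quantification workflow for such experiments, for
muscle and neuromuscular tissue-engineering labs working with
fluorescence micrographs and standard assay tables:

* **Morphometry** — myotube segmentation (actin/phalloidin), nuclei
  detection (DAPI), the ≥ 3-nuclei myotube definition, medial-axis
  width profiles, and classification by the **diameter difference
  ratio**, DDR = d_max / d_min. Training myotubes of known class give
  per-class mean and sample SD; a myotube is *linear* if
  DDR ≤ mean_lin + SD_lin, *bag* if DDR ≥ mean_bag − SD_bag, and
  *unassigned* in between. Field summaries report bag/linear
  percentages, fusion efficiency (nuclei inside myotubes / total
  nuclei), nuclei and myotube counts, and myotube area per myonucleus.
* **Marker intensity** — background calibration from a primary-negative
  image (smallest integer threshold removing ≥ 99 % of positive pixel
  coverage), masking subtraction, image coverage, intensity per
  nucleus, per-myotube mean intensity and Egr3-positive-nucleus
  percentage.
* **Expression** — ΔCt / 2^−ΔΔCt relative expression against Csnk2a2
  with primer QC (efficiency 90–115 %, r² > 0.95, single melt peak),
  proportional Myh isoform composition, western-blot adjusted relative
  density, and blank-corrected viability folds.
* **Statistics** — the Shapiro-Wilk-gated t-test / Mann-Whitney
  procedure, square-root-transformed two-way ANOVA (type II) with Tukey
  post hoc, and negative-binomial regression for nuclei counts.
* **Synthetic data** — a seeded generator rendering multi-channel
  fields with known ground truth (classes, DDRs, nuclei, marker
  intensities), plus Ct/blot/assay table generators that realise any
  requested fold change exactly at zero noise. Every stage of the
  pipeline is validated against it.

## Worked example

```r
library(spindlemorph)

# classification thresholds from a reference training summary
thr <- ddr_thresholds(1.81, 0.37, 4.03, 1.32)
thr
#> <ddr_thresholds>
#>   linear: 1.81 +/- 0.37  (linear iff DDR <= 2.18)
#>   bag:    4.03 +/- 1.32  (bag iff DDR >= 2.71)
#>   unassigned band: (2.18, 2.71)

# a synthetic Nrg-1 field, measured end to end
f <- generate_field(condition_params("nrg1"), seed = 1)
m <- measure_field(f$micrograph, thr)
m$summary[, c("myotubes_per_fov", "bag_pct", "fusion_efficiency",
              "nuclei_per_fov")]
#>   myotubes_per_fov  bag_pct fusion_efficiency nuclei_per_fov
#> 1               13 46.15385             43.75            128

# Egr3 gene fold change from a zero-noise Ct table
ct <- generate_ct_table(c(Egr3 = 3.5), n_samples = 3, ct_noise_sd = 0,
                        seed = 1)
ex <- relative_expression(ct)
unique(ex$fold_change[ex$condition == "treated"])
#> [1] 3.5
```

The field summary reads: thirteen retained myotubes in this field of
view, 46 % classified as bag (the treated condition drives bag
formation up from the ~8.5 % control baseline), 44 % of all nuclei
reside inside myotubes (fusion efficiency), and 128 nuclei were
detected. The Ct
round trip shows the ΔΔCt pipeline recovering a requested 3.5-fold
Egr3 induction exactly in the absence of replicate noise.

`run_pipeline(seed = 1)` chains simulation → morphometry → intensity →
expression → statistics for a two-arm experiment and writes CSV/YAML
reports; `inst/scripts/spindlemorph.R` wraps it for the shell.

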