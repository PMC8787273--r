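---
title: "Quantifying intrafusal bag myotubes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying intrafusal bag myotubes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spindlemorph)
```

## The problem

Muscle spindles sense stretch through specialised intrafusal fibres.
Nuclear *bag* fibres are fusiform — a bulging equatorial region with
clustered nuclei — whereas ordinary (extrafusal-like) *linear* myotubes
have near-uniform width and nuclei arranged along the axis. When C2C12
myoblasts are differentiated with neuregulin-1 (Nrg-1), a mimic of Ia
afferent signalling, a subpopulation of myotubes acquires the bag
morphology and upregulates the intrafusal transcription factor Egr3.
`spindlemorph` implements the quantification that turns micrographs and
assay tables from such an experiment into numbers: morphological
classification, calibrated marker intensity, relative expression, and
the statistical decision procedure. A synthetic-field generator with
known ground truth makes every stage testable without any microscope.

## Diameter difference ratio (DDR)

A *myotube* is a single actin-defined fibre containing at least three
nuclei; structures below that are excluded (unfused or partially fused
cells). For each myotube the package computes a full width profile:
the mask is thinned to its medial axis (Zhang–Suen), ordered along the
skeleton's graph diameter, and the local width at each axis point is
twice the Euclidean distance-transform value times the pixel size. The
classification statistic is

$$\mathrm{DDR} = \frac{d_{\max}}{d_{\min}},$$

the largest over the smallest diameter along the fibre. Two numerical
safeguards operationalise how diameters are measured in practice:

* **End caps.** 5 % of the skeleton at each tip is discarded
  (`trim_frac`); thinning produces unstable stubs at blunt fibre ends.
* **Interference.** An axis point is dropped when its inscribed width
  disc touches another instance's mask, so diameters are only read
  where no overlapping myotube interferes.

The measurement was originally a manual two-calliper protocol; the
profile-based definition is a reproducible superset of it (it measures
everywhere, then takes the extremes). Width is defined perpendicular to
the local medial axis; with a degenerate axis (a near-circular mask
thins to one point) the single inscribed-disc width is reported, giving
the expected DDR of 1 for a disc.

Class boundaries come from a small manually classified training set
(default 10 myotubes per class — the training-set description is
ambiguous about 10 total versus 10 per class; per class is the default
and it is configurable). With per-class mean and *sample* SD (n − 1,
matching the small training n):

* linear cutoff = linear mean + 1 SD,
* bag cutoff = bag mean − 1 SD,
* the open interval between them is *unassigned*,

and both boundary values belong to their named class (a DDR equal to
the linear cutoff is linear; equal to the bag cutoff is bag). With the
reference training summary (1.81 ± 0.37 and 4.03 ± 1.32) this yields
cutoffs 2.18 and 2.71. Threshold derivation fails loudly when the
cutoffs cross ("populations not separable"). Field summaries include
unassigned myotubes in the class-percentage denominator by default
(configurable), since how they were handled originally is not stated.

```{r thresholds}
thr <- ddr_thresholds(1.81, 0.37, 4.03, 1.32)
thr
classify_ddr(c(2.18, 2.5, 2.71), thr)
```

## Marker (Egr3) intensity

Background is calibrated from a *primary negative* image (no primary
antibody): the threshold is the smallest integer grey level T such that
at most 1 % of initially positive pixels (grey level > 0) remain above
T — thresholding at T removes at least 99 % of positive pixel coverage.
Correction is *masking*: pixels at or below T are set to zero and
pixels above keep their value, because every downstream quantity counts
or sums signal *above* background (shifting values would change the
sums). Quantities:

* **coverage** — positive pixels over total pixels, in percent;
* **intensity per nucleus** — summed corrected intensity over the total
  nuclei count (the marker is predominantly nuclear and nuclei counts
  differ between conditions, so per-nucleus normalisation removes that
  confound), optionally folded over a control mean;
* **per-myotube mean intensity** — mean corrected grey level over an
  instance mask, for the treatment × type ANOVA;
* **positive-nucleus percentage** — a nucleus is positive when at least
  half of its footprint (default `positive_fraction = 0.5`, reported
  and configurable) is non-zero after correction.

Thresholds are integers on the native bit depth, without sub-level
interpolation; one calibration serves all images acquired with the same
camera and settings.

## Expression quantification

Relative expression uses the ΔCt / 2^−ΔΔCt scheme: triplicate Ct values
are averaged (triplicate SD > 0.5 cycles is flagged), ΔCt is taken
against the reference gene Csnk2a2 within the same sample and plate,
ΔΔCt against the control-group mean ΔCt of the same plate, and fold =
2^−ΔΔCt. Plate-constant offsets cancel by construction. Primer pairs
enter the analysis only with amplification efficiency in [90, 115] %
(inclusive), standard-curve r² strictly above 0.95, and a single melt
peak; the bundled `primer_table()` records the 18 assayed genes.
Efficiency is recorded but by default not used to correct folds; an
efficiency-corrected mode (per-gene base 1 + E/100 instead of 2) is
available but off, matching the plain 2^−ΔΔCt convention.

Proportional myosin composition linearises each detected Myh isoform as
2^−ΔCt and expresses it as a share of the per-sample total. Summing
linearised values (not raw ΔCt cycles) is the only reading under which
"proportion of total Myh expression" is well defined; undetected
isoforms (e.g. Myh15 at very low expression) are excluded and listed.
The share is invariant to the reference-gene choice, which cancels in
the ratio.

Western blots use the adjusted relative density method as a two-step
ratio: band over loading control (GAPDH) per lane, then over the mean
control-lane ratio per target. Viability readings are corrected to
media-only blanks, then folded over the control mean.

## Statistical decision procedure

Two-group outcomes pass through a normality gate: Shapiro–Wilk per
group (α = 0.05, applied *after* any transform); both groups passing
selects a two-sided Student's t-test (pooled variance by default, Welch
by flag), otherwise a Mann–Whitney test. The branch taken, per-group
Shapiro p-values, n, and means ± SEM are carried in the result so every
p-value is traceable. Marker-intensity data are square-root transformed
before the gate and the ANOVA (the transform restores approximate
normality for right-skewed intensity data); the transform flag is
exposed on both the two-group and ANOVA paths since it is ambiguous
which intensity endpoints were transformed originally.

The treatment × myotube-type ANOVA uses type-II sums of squares —
cells are unbalanced (e.g. 52/9/47/26 myotubes per cell), and type II
tests each main effect adjusted for the other without imposing an
ordering — with Tukey-adjusted all-pairwise comparisons on the cell
means. Nuclei-per-myotube counts are overdispersed, so they are
modelled by log-link negative-binomial regression with treatment and
type terms; the dispersion is estimated by maximum likelihood, and on
equi- or under-dispersed inputs the fit falls back to the Poisson limit
(θ → ∞). Stars follow the \*\*\* p < 0.001, \*\* p < 0.01, \* p < 0.05
convention.

## The synthetic-field generator

`generate_field()` renders one field of view (default 768 × 768 px at
0.65 µm/px — a typical widefield camera/objective combination; the
source imaging system's pixel pitch is not stated) with actin, DAPI and
marker channels plus a ground-truth table. Its defaults *are* the study
conditions:

| parameter | control | Nrg-1 | units |
|---|---|---|---|
| bag fraction | 0.0852 | 0.4161 | proportion of myotubes |
| myotubes / FOV | 8.33 | 9.22 | Poisson mean |
| nuclei / FOV | 104.8 | 136.3 | Poisson mean |
| fusion efficiency | 0.4688 | 0.4741 | proportion of nuclei |
| linear DDR | N(1.81, 0.37²) | same | truncated > 1 |
| bag DDR | N(4.03, 1.32²) | same | truncated > 1 |
| nuclei per linear / bag myotube | 5.48 / 8.09 | 6.10 / 8.33 | NB means |
| area per nucleus | 645.3 | 537.9 | µm² |
| marker intensity linear / bag | 0.88 / 1.85 | 2.50 / 6.13 | relative |
| positive nuclei linear / bag | 0.486 / 0.55 | 0.60 / 0.721 | proportion |

Only the control-linear (48.6 %) and treated-bag (72.1 %) positive
fractions are reported quantities; the other two cells were not
significantly different and are fixed once at intermediate values.

**Geometry.** Every fibre is a horizontal tube with the closed-form
width profile `w(t) = w_min + (w_max − w_min)·exp(−t²/2σ²)`, σ = L/8,
so a bag fibre's bulge spans roughly the central third. Linear
myotubes use the *same* profile at their (small) drawn DDR: their DDR
distribution has mean 1.81, which renders as a gently tapered tube; a
hard "≤10 % taper" rule would cap their true DDR near 1.1 and
contradict the class distribution the classification is trained on.
Fibre length comes from the area-per-nucleus setting (length = area
per nucleus × nuclei count / mean width), floored at 6 × the bulge
width so the apex curvature stays gentle relative to the inscribed
disc, and capped at 90 % of the field width. Nuclei are 10-µm Gaussian
blobs (nuclear size is not specified in the source; 10 µm is typical
for C2C12 myonuclei) placed with a hard-core minimum centre separation
of one nucleus diameter — clustered at the equator for bag fibres
(σ = L/10 axially, relaxed when crowded), evenly spaced with jitter for
linear fibres. Unfused mononuclear cells (small actin bodies with one
nucleus) fill free space, kept clear of fibre masks so components never
merge; they exercise the three-nuclei filter downstream.

**Bookkeeping that makes recovery exact.** Total nuclei are Poisson at
the field mean; the fused subset is a Binomial thinning at the fusion
efficiency (so recovered fusion efficiency is unbiased); fused nuclei
are allocated to fibres by a gamma-weighted multinomial with class-mean
weights and a shared dispersion (θ = 6, giving variance ≈ 2 × mean at
these counts — no dispersion estimate is reported for the original
fits), then adjusted to at least 3 per fibre. The reference field-level
means are not mutually consistent to high precision (myotubes/FOV ×
nuclei-per-myotube ÷ nuclei/FOV does not exactly equal the printed
fusion efficiency), so the generator targets nuclei/FOV, fusion
efficiency and bag fraction exactly and lets the per-class nuclei means
be approximate.

**Rendering and noise.** Column heights are quantised to *even* pixel
counts, so the distance transform recovers the rendered width exactly
at the medial axis; the pole width is snapped to that grid (floored at
10 px) and the bulge scaled to preserve the drawn DDR. Ground truth
records the realised DDR of the rasterised profile over the same
central 90 % the measurement uses (`ddr_true`) alongside the sampled
value (`ddr_drawn`). Noise is additive Gaussian on 16-bit grey levels,
SD = 2 % of the dynamic range — enough that background calibration is
non-trivial (the calibrated threshold lands near 2.6 SD) while Otsu
segmentation stays robust. The marker channel is cytoplasmic intensity
(per-type mean × gain, 8000 grey levels per unit) with marker-negative
nuclei punched out and positive nuclei given a fixed nuclear blob
(20 000 grey levels — the minimum that lets an isolated positive
nucleus clear the background threshold over half its footprint). With
these settings the expected treated/control intensity-per-nucleus fold
is ≈ 3.5 by construction of the per-type means and nuclei counts.

**What the generator does not emulate:** point-spread blur, uneven
illumination, chromatic shift, out-of-focus debris, fibre curvature and
branching, and 3-D structure. Passing recovery tests therefore shows
the *measurement chain* is correct and unbiased under the assumed
statistical structure — not that segmentation would survive real
micrograph artefacts, where manual curation or stronger segmentation
models may be needed.

## Degenerate inputs and tie-breaks

* All-zero calibration images calibrate to T = 0; an image with no
  positive pixels is its own (empty) calibration.
* A zero total-nucleus count makes fusion efficiency and per-nucleus
  intensity undefined; both are reported missing rather than zero.
* Boundary DDR values are inclusive to their class with a 10⁻⁹
  tolerance so floating-point cutoff arithmetic cannot flip a boundary
  case.
* Nuclei maxima ties on smoothing plateaus are merged greedily,
  brightest first, at the minimum-diameter separation.
* Skeletons shorter than two points flag the instance unmeasurable and
  exclude it from DDR statistics; one-point (disc-like) skeletons
  report the inscribed width.
* An overlapping-mask nucleus (only possible with explicit mask lists)
  is assigned to neither mask and flagged.

## Validation scale

The package's own checks run at desk scale, chosen to exercise the
full chain while keeping the suite quick: 50 fields per arm at the
default 768² px for parameter recovery, 2 000 null simulations for the
type-I calibration of the gated test, 8 seeded replicates for the
ANOVA/NB study-structure simulations, and small constructed masks for
the width-measurement oracle. The acceptance script recomputes the
analytically forced quantities (DDR cutoffs, background-calibration
removal) in seconds.

## Known limitations

* Horizontal, non-overlapping fibre placement means overlap-exclusion
  logic is exercised mainly through constructed fixtures, not the
  generator's default output.
* Classification truncation (the ±1 SD unassigned band) removes ~15 %
  of each class; recovered bag fractions are computed over classified
  myotubes, where the truncation is close to symmetric. Including
  unassigned myotubes in the denominator (the reporting default)
  deflates percentages slightly relative to ground truth.
* Technical repeats are treated as n, reproducing the original
  replication convention without endorsing it; a mixed-effects
  extension would be the principled alternative.
* The two-calliper manual measurement can see oblique diameters; the
  medial-axis convention is strictly perpendicular and will differ on
  strongly curved fibres.
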