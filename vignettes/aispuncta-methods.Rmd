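---
title: "Quantifying AIS enrichment of receptor puncta: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying AIS enrichment of receptor puncta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aispuncta)
```

## The measurement problem

Certain GABA~A~ receptor α-subunits aggregate into clusters on the axon
initial segment (AIS), the ankyrin-G-positive domain where action
potentials initiate. The degree of this enrichment differs between brain
areas and subunits, and quantifying it from immunofluorescence requires a
chain of image-analysis decisions: how the diffuse background is removed,
how "a punctum" is defined, which detections count as receptor clusters,
and how a region's punctum load is compared with a matched control region.

`aispuncta` implements that chain as a reproducible pipeline:

1. **Background subtraction** — rolling-ball (grayscale opening by a
   spherical-cap structuring element, default radius 50 px at ~64 nm/px).
2. **Binarization** — triangle auto-threshold on a 256-bin histogram,
   suited to sparse fluorescence whose histogram peaks near one extreme.
3. **Particle analysis** — connected components (default 8-connectivity)
   within each region of interest, gated to 0.05–10.00 µm² area and
   0.10–1.00 circularity.
4. **Per-ROI morphometry** — cluster count, density, mean size, percent
   area; an ROI with no retained clusters has density 0 and *missing*
   mean size (the zero-puncta rule).
5. **Enrichment ratio** — the mean percent area over AIS ROIs divided by
   the mean percent area over congruent non-AIS ROIs. This ratio of means
   is the reported statistic; per-pair ratios are auxiliary output only,
   because on skewed data the mean of ratios drifts upward by the Jensen
   gap.
6. **Colocalization** — Pearson correlation of intensities (optionally
   restricted to pixels above Costes auto-thresholds) and Manders overlap
   fractions M1/M2 computed on binarized channels, all restricted to ROIs.
7. **Inference** — two-way ANOVA (location × brain area, Type III sums of
   squares under sum-to-zero contrasts), Bonferroni planned comparisons,
   one-way ANOVA of enrichment ratios with Tukey–Kramer post-hocs, and
   Bonferroni-corrected two-sample t-tests for coefficient families.

ROIs are exchanged as integer label-mask TIFFs plus a CSV sidecar
(`label, location_class, brain_area, pair_id`); each AIS region is paired
with a contour-congruent non-AIS region (equal pixel count, disjoint
masks). The ImageJ `.roi` binary format is deliberately unsupported: label
masks are lossless, language-neutral and trivially testable.

## Numerical choices

**Rolling ball.** The background is the grayscale opening of the image by
a ball of radius *r* in both the spatial and intensity directions:
erosion `min_s f(x+s) − b(s)` followed by dilation, with
`b(s) = sqrt(r² − |s|²)`. No down-scaling shortcut is used — the opening
is exact, and the test suite asserts bit-exact agreement with an
independent shift-accumulate oracle. At image borders the element is
restricted to valid pixels (equivalent to padding with ±∞). The output is
clipped at 0 and never exceeds the input.

**Triangle threshold.** The histogram spans `[min, max]` of the scoped
pixels in 256 equal bins. The chord runs from the peak bin to the
farthest non-empty bin on the *longer* tail (tie → higher-intensity
tail); the threshold bin maximizes perpendicular distance from that chord
in raw (bin, count) coordinates, ties resolving to the lowest bin. The
threshold value is the upper edge of the selected bin, and "above
threshold" is strict, so every foreground pixel is strictly brighter than
the threshold. A constant image yields an empty mask.

**Costes auto-threshold.** The unnamed auto-threshold used before
thresholded intensity correlation is implemented as the Costes
bisection: an orthogonal (total least squares) regression of channel B on
channel A over the ROI, then the candidate threshold descends along A
(with the paired B threshold from the regression line) until the Pearson
correlation of the *sub-threshold* pixels first reaches ≤ 0. If it never
does (e.g. B = A), the thresholds fall below the minimum and every pixel
is retained. A `FIXED` mode accepting explicit thresholds is available.

**Perimeter and circularity.** Circularity is `4πA/P²`, capped at 1.
The perimeter comes from Moore chain tracing of the outer boundary
through pixel centres with weights 0.948 (orthogonal step) and 1.340
(diagonal step) — the calibrated form of the 1/√2 chain estimator. The
naive estimator overstates smooth perimeters by ~5–8%, which would push
rasterized discs below circularity 0.9; the calibrated weights recover a
radius-40 disc's circumference to about 0.1%. Interior holes do not
contribute (traced-outline convention). Few-pixel particles can exceed
circularity 1 before the cap — the cap mirrors the behaviour of the
common particle-analysis tools and the closed upper gate of 1.00.
Clusters straddling an ROI border are clipped to the ROI before
measurement, which restricts quantification strictly to the region at
the cost of biasing clipped clusters' circularity.

**Density unit.** Densities are reported per 100 µm² of ROI area. The
denominator is an explicit configuration choice (`per_um2`), not an
inferred convention: group means alone cannot disambiguate it, and
per-100-µm² yields numbers of the magnitude practitioners report for
receptor clusters.

**Type III sums of squares.** ROI counts per design cell are unequal in
practice, so the factorial ANOVA uses Type III sums of squares under
sum-to-zero contrasts — computed directly as the residual-SS increase
when a term's columns are dropped from the full model matrix. For
balanced data this reduces exactly to the textbook decomposition (tested
against a closed-form oracle to 1e-8), and on unbalanced data it agrees
with `car::Anova(type = 3)` to 1e-10. Degenerate fits with zero residual
variance report missing F statistics with a warning rather than failing,
so pathological synthetic inputs cannot crash a pipeline run. Missing
responses (the missing mean sizes of empty ROIs) are dropped listwise.

**Studentized range.** Tukey–Kramer p-values use `stats::ptukey` with
`q = |m_i − m_j| / sqrt(MSE/2 · (1/n_i + 1/n_j))`; the test suite checks
`ptukey` against an independent double-quadrature of the distribution's
defining integral to 1e-4 and the whole procedure against `TukeyHSD`.

**Pooling.** Per-ROI measurements are pooled across images as independent
observations, and the denominator degrees of freedom follow that
convention. This replicates the field's common practice but ignores the
nesting of ROIs within images and animals — a known source of
pseudo-replication that mixed-effects models would address; we document
rather than model it (a deliberate non-goal).

## The synthetic-scene generator

Because no raw imagery ships with typical studies of this kind, every
stage is validated on synthetic scenes with planted ground truth
(`generate_scene()`):

* **AIS trajectories** are cubic splines through heading-jittered
  waypoints; the AnkG channel is the ribbon of width `ais_width_um`
  (default 1 µm) along each trajectory.
* **Subunit puncta** are placed along trajectories in a
  beads-along-a-string arrangement (evenly spaced arc positions with
  jitter, lateral scatter inside the ribbon) at
  `ais_puncta_density_per_100um2` (default 30), and as a diffuse field
  inside the congruent non-AIS control regions (default 10) plus an
  ambient field elsewhere. Placement is hard-core (centres separated by
  the sum of radii plus a gap), so planted puncta never merge.
* **Non-AIS ROIs** are exact translated copies of each AIS ribbon,
  placed in trajectory-free territory — preserving the congruence
  constraint of paired-contour designs. Admissible translations are
  found by rejection sampling with an exact FFT cross-correlation
  fallback, so placement fails only when genuinely infeasible.
* **Partner channels** (gephyrin-, vGAT-like) receive an apposed punctum
  for a Bernoulli(`coloc_fraction_*`) subset of subunit puncta, offset by
  ~0.1 µm with sides alternating along the trajectory (a 2D rendering of
  the spiralling apposition around the AIS), plus partner-only ambient
  puncta.
* **Rendering**: puncta are hard discs (pixel centre within radius) with
  an error-function edge of width `psf_sigma_um`, on a flat background
  plus a random-direction linear gradient, then Poisson shot noise and
  Gaussian read noise. A knockout scene (`generate_ko_scene()`) is
  identical except that one channel's puncta are independently retained
  with probability `residual_fraction`.

Ground truth records the rasterized footprint of every punctum before
noise, per-ROI planted densities/sizes/percent areas, and the planted
enrichment ratio (ratio of planted mean percent areas). Planted totals
are drawn by stochastic rounding of density × area and apportioned to
regions by largest remainder, so the realized totals stay tight around
their expectations and the planted ratio is sharply defined.

**What the generator does not emulate.** Edges are rendered nearly sharp
(default `psf_sigma_um = 0.01`, ≈ 0.16 px at 64 nm), far below a real
confocal PSF (σ ≈ 0.1 µm). This is deliberate: with a wide PSF the
suprathreshold footprint of a punctum depends strongly on the threshold,
and "true size" stops being a well-defined planted quantity. Passing the
recovery tests therefore demonstrates that the measurement chain is
correct and unbiased on resolvable structures — not that size estimates
on heavily blurred real data are threshold-independent (they are not;
the semi-quantitative caveat of intensity-based cluster sizing applies).
Likewise absent: tissue autofluorescence structure, chromatic shifts,
and 3D effects — scenes are single optical sections by design.

**Non-AIS field placement.** Diffuse-field puncta are planted wholly
inside the control ROIs (and ambient puncta are excluded from a margin
zone around all ROIs). Otherwise puncta straddling control-ROI borders
would be clipped by measurement while AIS beads are not, introducing an
asymmetric bias into the enrichment ratio that is a property of the
simulation geometry, not of the measurement chain being validated.

## Validation studies and problem sizes

The packaged studies (`recover_enrichment()`, `recover_density_size()`,
`ko_independence()`, `measure_m1()`, `type1_calibration()`) define the
package's standard self-validation, with sizes chosen to keep a full run
at desk scale:

* Enrichment recovery: ratios {1, 2, 3, 5} planted via densities
  (AIS 24 per 100 µm²), 50 congruent ROI pairs per condition rendered as
  two 640² scenes at 128 nm/px, rolling-ball radius 8 px (≈ 1 µm). The
  coarser raster preserves the physical geometry (1 µm ribbons, 0.2 µm²
  puncta) at a quarter of the pixel load; recovery is asserted to median
  error ≤ 15% over 20 seeds per ratio.
* Density/size recovery: 512² scenes at the native 64 nm/px, densities
  up to 40 per 100 µm²; ≤ 10% error in the sharp/noise-free regime,
  ≤ 20% under the full noise model (the PSF skirt above a low threshold
  inflates measured sizes by roughly 10% there — measured, documented,
  inside the band).
* Knockout: thinning the subunit channel to 5% residual must remove
  ≥ 90% of its measured AIS density while the partner channel stays
  within 15% of control.
* Colocalization: mean binary M1 over ROIs must increase strictly across
  planted apposition fractions {0, 0.25, 0.5, 0.75, 1} (20 seeds/level).
* Calibration: 1000 null replicates of the 2 × 6 layout must give
  per-effect and any-pair type-I error within [0.035, 0.065] at α = 0.05.

## Known limitations

* Merged real-world puncta are not split (no watershed); at planted
  densities ≳ 40 per 100 µm² with free (non-hard-core) placement,
  merging would deflate counts and inflate sizes.
* The enrichment ratio is a descriptive contrast between an AIS region
  and a neuropil control; it does not correct for differences in
  antibody accessibility or acquisition settings between channels.
* Intensity statistics are semi-quantitative: laser power and gain are
  adjusted per exposure in typical acquisitions, so absolute intensities
  (and intensity-weighted Manders, provided but off by default) are not
  comparable across images.
* ROI-within-image nesting is not modelled (see *Pooling* above).
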