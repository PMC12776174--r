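---
title: "Quantifying compositional deviation in single-cell placental histology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying compositional deviation in single-cell placental histology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep-learning pipelines for placental H&E slides emit, for every detected
nucleus, a position, one of 11 cell-type labels, and one of 9
tissue-structure labels. `placomp` takes over from there: it turns these
per-nucleus prediction tables into slide-level densities and compositions,
quantifies how far each slide's composition deviates from a healthy
reference, locates spatial clusters of any target class, and runs the
group-level statistics that compare lesioned, apparently normal, and control
slides. Because clinical slides at this resolution are rarely shareable, the
package also ships a synthetic slide generator with the statistical
structure the analysis assumes, so every stage is testable end to end.

## The deviation model

Compositions live on the simplex: a slide's cell-type composition
$p = (p_1, \dots, p_k)$ with $\sum_i p_i = 1$ carries only relative
information, so Euclidean geometry on the raw proportions is misleading.
The package works in centred log-ratio (CLR) coordinates,

$$\mathrm{clr}(p)_i = \ln \frac{p_i}{g(p)}, \qquad
g(p) = \Big(\prod_{i=1}^k p_i\Big)^{1/k},$$

and measures deviation with the Aitchison distance, the Euclidean distance
between CLR vectors:

$$d_A(p, q) = \sqrt{\sum_{i=1}^k \big(\mathrm{clr}(p)_i -
\mathrm{clr}(q)_i\big)^2}.$$

This metric is scale-invariant (computing compositions from counts or from
7× the counts gives the same distance) and permutation-equivariant, and a
unit of distance corresponds to a fold-change pattern across components
rather than an absolute shift — appropriate when a rare cell type doubling
matters as much as a dominant one drifting.

A slide is called *significantly deviant* when its distance to the mean
healthy reference composition exceeds a threshold calibrated from healthy
spatial variation: each control slide is split into three regions along the
chorionic-to-basal axis, region compositions are computed, and 10,000
bootstrap draws of pairs of distinct healthy regions give a null
distribution of $d_A$ under normal heterogeneity. The threshold is the 95th
percentile of that null. Leave-one-out recomputation of group significance
rates quantifies the stability of each reported percentage.

## Choices the data do not pin down

Several details of this procedure are genuinely open; the package fixes
them explicitly, records every choice in its outputs, and exposes
alternatives:

* **Zero replacement.** Zero counts occur (avascular villi are near-absent
  in healthy tissue) and the CLR needs strictly positive parts. The default
  is multiplicative replacement with $\delta = 0.5 / n$ where $n$ is the
  total count behind the composition — half a count, scaled so nonzero
  parts shrink proportionally before re-closure. A pseudocount strategy is
  available (`clr(p, "pseudocount", delta)`). Thresholds depend on this
  choice, which is why it is written into `thresholds.json`.
* **Bootstrap pairing.** The default `any_distinct` samples uniformly over
  all unordered pairs of distinct healthy regions, same-slide pairs
  included, because intra-slide heterogeneity is part of the healthy null;
  `cross_slide_only` restricts to pairs from different slides and typically
  lowers the threshold.
* **Reference mean.** `arithmetic` (component-wise mean then closure) is the
  default reading of "mean composition"; `clr_mean` (the compositional
  geometric mean) is the purist alternative and available as an option.
* **Quantile definition.** The 95th percentile uses linear interpolation
  between order statistics (R type 7), pinned for reproducibility.
* **Region splitting.** Regions are equal-count (quantile cuts of the
  axis projection, ties to the lower region) rather than equal-length, which
  guarantees nonempty regions of comparable statistical power. The axis is
  the unit vector between the plate-class centroids, falling back to the
  longer bounding-box axis when a slide has fewer than 10 records of either
  plate class.
* **Control scoring.** Control slides contribute to the reference *and* are
  scored against it, with no leave-one-out correction — the plain reading of
  the procedure being reproduced; a holdout variant can be built from
  `build_reference()` on subsets.

## The quantification stages

The pre-analysis pipeline has a fixed order: deduplication → syncytial-knot
post-processing → tissue-area estimation (on all records) → plate exclusion
→ compositions, densities, regions.

* **Deduplication** (`dedup_points`) removes duplicate detections within a
  4-pixel radius by greedy suppression in descending confidence, ties broken
  by (y, x). The operation is idempotent and order-independent.
* **Knot post-processing** (`postprocess_syncytial_knots`): syncytial knots
  are nuclear aggregates, so isolated knot predictions are implausible and
  are relabelled syncytiotrophoblast. "Isolated" means a connected component
  of the radius graph smaller than `min_cluster = 2` at radius 200 px
  (~22 µm, one classification-crop width — the natural interaction scale of
  this pipeline; the radius is configurable and logged because no canonical
  value exists).
* **Tissue area** (`estimate_tissue_area`) counts non-overlapping patches
  (default 1600×1200 px, mirroring the detection tiling) containing at
  least one nucleus; patch boxes are half-open, so a record exactly on a
  boundary belongs to exactly one patch. Area estimation runs *before*
  plate exclusion — nuclei of any class mark tissue as opposed to
  background — while compositions and densities use the post-exclusion
  parenchymal records, which is the analysis population.
* **Calibration**: the only physical constant is 0.1109 µm/px; all
  conversions go through it (`px_to_um`).

## Local autocorrelation

For a target class $t$, the map value at grid point $i$ is
$LA(i) = \frac{1}{n_i} \sum_{j \in N_i} \delta_j$ with $N_i$ the cells
within 200 µm of the grid centre and $\delta_j$ the indicator of class
$t$. The grid is read as a fixed 150×150 partition of the records' bounding
box (the alternative reading — squares of 150 px — is available by setting
`nx`/`ny` accordingly), grid squares with fewer than 5 cells are masked, and
the neighbourhood search is exact: tests require equality with an
$O(\text{grid} \times n)$ brute-force scan. Gaussian smoothing
(`smooth_gaussian`, default σ = 1.5 grid cells) is mask-aware — masked
squares contribute zero weight and stay masked — and is applied only for
visualisation; exported CSV matrices are unsmoothed by default.

## What the synthetic generator emulates — and what it does not

`generate_slide()` produces nuclei by a homogeneous Poisson process at
5,000 nuclei/mm² over a 30,000×25,000 px canvas (≈9.2 mm², ≈46,000 nuclei —
a desk-scale stand-in for clinical slides that carry over a million), with:

* horizontal chorionic/basal plate bands (8% of slide height each), giving
  the plate-to-plate axis a vertical ground truth that the region
  segmentation must recover;
* a clustered structure field: 400 random seed points whose Voronoi cells
  are assigned to structure classes under quotas that make realised nuclei
  counts match the abundance weights by construction (terminal-villi
  dominant, near-zero avascular villi), with per-structure linear gradients
  along the vertical axis (stem villi −0.3 towards the basal plate,
  terminal villi +0.15) modelling normal spatial heterogeneity;
* structure-conditional cell mixtures (syncytiotrophoblast-dominant villous
  rows, decidual-cell-dominant basal plate, leukocyte-enriched fibrin);
* focal lesions as unions of discs whose radius is bisection-calibrated
  against an occupancy grid so realised coverage tracks the requested
  fraction, with multiplicative fold-changes applied to mixtures inside the
  discs; and organ-wide *field effects* applied everywhere, used alone for
  "no apparent lesion" slides and shared (up to a log-normal patient
  exponent) between paired slides of one patient.

All composition parameters are **synthetic**: no quantitative healthy
composition table exists to validate them against, so they are chosen to
match qualitative descriptions (dominant cell and structure classes,
directions of lesion effects) and are tuning knobs, not measurements. The
generator also does not attempt biological lesion shapes (discs suffice to
test focal-versus-field separation and spatial cluster detection), H&E
rendering, or detection-error realism (confidences are Beta(8, 2) draws).
Inside a lesion, structure labels are resampled independently from the
focal-adjusted marginal — the disc itself provides the spatial cluster, and
sub-lesion texture is out of scope. Consequently, passing parameter-recovery
tests demonstrates that the machinery detects the kinds of effects the
analysis targets at realistic magnitudes; it does not certify performance on
real slides, whose heterogeneity is richer.

## Validation experiments and problem sizes

The test suite validates each operation against an independent oracle
(brute-force greedy suppression, union-find components, exhaustive pair
enumeration for the bootstrap, $O(\text{grid} \times n)$ LA scans,
enumeration of Mann-Whitney assignments) and runs parameter-recovery
experiments at these sizes, chosen to give clear statistical separation at
desk scale: 20 control slides for the null, 8 lesion slides per coverage
level on a {5, 10, 25, 50, 75}% grid with 2× focal fold-changes on three
cell components, 40 fresh healthy slides for the false-positive rate, and
12 paired patients for the field-effect analysis, all at ≈46,000 nuclei per
slide. Expected behaviour, reproduced by `tests/testthat/test-acceptance.R`
and `scripts/acceptance.R`: healthy flag rates near zero, lesion flag rates
strictly higher, mean distance increasing monotonically with coverage,
positive patient-paired correlation, and fibrin LA concentrated inside
infarction discs.

## Degenerate inputs and numerical conventions

Empty record sets yield zero tissue area (a QC failure, not a crash) and
an error for compositions; a bootstrap over identical regions returns
threshold 0, which then flags every slide at positive distance; a constant
input to a rank correlation returns a first-class "not computable" result
rather than `r = 0`; Bonferroni rejects family sizes smaller than the number
of tests. Correlations default to Spearman with Pearson available — the two
conventions coexist in practice and the choice is recorded in every report.
All randomness flows from explicit seeds; reports, tables, figures, and
thresholds are byte-identical across reruns with the same configuration.

## Limitations

The healthy reference and its thresholds are functions of the control set:
with few controls they are noisy, and the package intentionally reports
leave-one-out ranges rather than pretending stability. Structure-side
thresholds are driven by rare structure classes whose region counts can hit
zero, making them conservative; this mirrors the zero-replacement
sensitivity discussed above. Real-data effects not modelled by the
generator — scanner batch effects, artefacts, irregular tissue outlines —
must be handled by the QC exclusion list in the configuration.
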