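---
title: "Methods and design decisions in dvpflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design decisions in dvpflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dvpflow)
```

# What the package models

Deep visual proteomics (DVP) couples three stages: (i) classification of
segmented nuclei in an immunohistochemistry (IHC) image, (ii) laser
microdissection (LMD) of contours drawn around the selected cells, and
(iii) ultra-sensitive label-free proteomics of the pooled material.
`dvpflow` implements the computational side of such a workflow for a
CDX2-stained colorectal tissue setting — three stain classes (`CDX2++`,
`CDX2+` epithelial; `CDX2-` stromal) collected in triplicate wells and
compared across three patient outcome groups (`C`, `HDA`, `NMN`) — and
ships a synthetic-data module so that every stage can be exercised and
tested with known ground truth.

# Nuclei classification

**Normalization.** RGB channel means are rescaled per image and per
channel so the 1st percentile maps to 0 and the 99th to 1 (clipped).
Percentile anchoring is robust to debris pixels; a constant channel is a
degenerate scale and normalizes to 0.5 by definition, which keeps
downstream arithmetic total.

**Outlier removal.** The summed RGB intensity of each nucleus is z-scored
within its image and the extreme 5% — 2.5% per tail by empirical
z-quantile — is removed. We read the intensity cutoff as two-tailed
because staining artifacts produce both over-dark debris and washed-out
ghosts; a one-tailed variant is a trivial configuration change. With
zero within-image variance the z-score is undefined and nothing is
removed (conservative keep).

**Stain score.** DAB (the brown IHC chromogen) is red-dominant and
hematoxylin (the blue counterstain) blue-dominant in brightfield RGB, so
we score each nucleus with the chromatic ratio
`(R − B) / (R + B + 1)` on raw channel means. The `+1` keeps the score
finite and inside (−1, 1). Published descriptions of such classifiers
typically state only that intensities, ratios and form features were
used; the concrete ratio and the thresholds below are this package's own
declared choices, exposed in `classifier_config()`.

**Gating.** Non-outlier nuclei with score ≥ 0.25 are `CDX2++`, scores in
[0.05, 0.25) are `CDX2+`. Weakly stained nuclei are only called stromal
(`CDX2-`) if their morphology agrees — area below 40 µm² or eccentricity
≥ 0.75 — since stromal nuclei (fibroblasts, lymphocytes) are smaller or
more elongated than round columnar epithelial nuclei. Everything else is
`unclassified`, the fourth group: weak staining on epithelial morphology
is ambiguous and should not be dissected. Interval boundaries are
half-open with the lower edge inclusive, so a score exactly on a
threshold goes to the higher class.

# Spatial quantification and microdissection geometry

Region polygons are simple polygons in pixel coordinates (origin
top-left). Cell-to-region assignment uses an edge-inclusive
winding-number test with first-match-wins on overlapping regions —
deterministic and declaration-ordered; the remainder of the tissue is the
implicit `whole_tissue` region. Class-by-region tables report, for each
class, the percentage of its cells per region (rows sum to 100 before
rounding), the convention that matches statements like "52% of all
strongly stained cells lie in the high-dysplasia region".

Cutting contours are dilated outward by a fixed micron offset
(conventionally 2 µm, to take a rim of cytoplasm along with the nucleus).
The offset polygon is the Minkowski sum of the contour with a disc:
edges shift along their outward normals, convex corners receive round
joins (arcs sampled at ≤ π/16 rad), reflex corners the intersection of
the adjacent offset edges. This is exact for convex contours and correct
for concave ones as long as the offset is small relative to the
concavity — the regime of micron-scale offsets on cell-scale shapes; no
global self-intersection cleanup is attempted.

Sampling pools a fixed number of shapes (default 1000) per class and
replicate, without replacement, and assigns each pool to a well of a
384-well plate while skipping rows A/P and columns 1/24, where
evaporation and edge effects degrade low-input samples. Contours are
exported as an LMD-style XML dialect (three verbatim calibration points,
`ShapeCount`, per-shape `PointCount`/`CapID`/`X_i`/`Y_i`) with vertex
coordinates rounded half-away-from-zero to integers; the schema is
self-defined and documented by `export_lmd()`, and the write→read round
trip is exact for integer coordinates.

# The statistics stack

**Valid-value filter.** A protein is kept when some group quantifies it
in at least `ceil(0.7 · n_g)` samples. We use the ceiling because a 2/3
triplicate is 66.7% < 70%; the alternative (rounding, which would accept
2/3) is a one-line change but not the default.

**Imputation.** Missing values are drawn per sample column from
`Normal(m − 1.5·s, (0.3·s)²)`, with `m`, `s` the observed column moments
— the downshifted-normal model for values censored by the detection
limit (missing not at random). Per-column moments match sample-wise
missingness of low-input data; a whole-matrix mode exists behind
`per_column = FALSE`. Observed values are never altered and the
imputation mask is returned.

**Moderated statistics.** The two-sample statistic is
`d = (x̄_a − x̄_b)/(se_pooled + s0)` with the SAM fudge constant `s0`
(default 0.1) entering additively on the standard-error scale; the
multi-sample statistic is `F' = MSB/(√MSW + s0)²`. At `s0 = 0` both
reduce exactly to the classical pooled t and one-way F, which the test
suite verifies against `t.test()` and `aov()` to 1e-9.

**Permutation FDR.** Sample-to-group labels are permuted globally (250
draws by default, seeded). For each candidate cutoff among the observed
|d| the FDR estimate is the mean permutation count of `|d*| ≥ Δ` over
the observed count, with π0 fixed at 1 (conservative), capped at 1, then
monotonized so that a larger |d| never receives a larger q-value.
Perseus's exact estimator is not published in detail; the SAM-style mean
estimator is our declared choice.

**Units of replication.** Tests treat replicates as independent samples,
as triplicate-level volcano analyses conventionally do; this
pseudo-replicates patients, so `aggregate_by_patient()` offers a
patient-mean mode for sensitivity analyses.

CVs (`100·sd/mean`) are computed on unimputed linear intensities only —
imputed values would deflate replicate variability. Clustering defaults
to Euclidean distance with average linkage on row-z-scored values; PCA
is a mean-centered SVD with samples as observations; rank-abundance
sorts by descending group mean with lexicographic tie-breaks; and
over-representation of user-supplied gene sets uses the upper-tail
hypergeometric test with Benjamini–Hochberg adjustment, a desk-scale
substitute for database-backed GO/GSEA enrichment (out of scope here).

# The synthetic-data module

The generator emulates, with one root seed feeding labelled sub-streams
(`derive_seed()`):

* **Nuclei**: a three-class Gaussian mixture over RGB means, area and
  eccentricity. Defaults place `CDX2++` at brown-like (165, 110, 60),
  `CDX2+` intermediate (150, 120, 100) and `CDX2-` at hematoxylin-like
  (90, 85, 140) with channel SD 6, stromal nuclei at 60% of the
  epithelial area and eccentricity 0.8 vs 0.55. These are stand-ins
  chosen to look like DAB/hematoxylin brightfield statistics, not fits
  to any real data set. A seeded 5% of nuclei get five-fold inflated
  channel SDs, giving the intensity-outlier filter genuine artifacts to
  remove.
* **Regions**: disjoint rectangles jittered on a grid, or any layout the
  caller provides.
* **Protein matrices**: per-protein log2 baselines `N(22, 2.5²)`,
  planted group effects, replicate noise `N(0, 0.5²)` over the default
  3 groups × 3 patients × 3 replicates design, and logistic
  missing-not-at-random censoring (slope −0.8 per log2 unit, midpoint
  17, ceiling 0.6) so that low-abundance proteins go missing more often.

What the generator does *not* emulate: spatial correlation between
neighbouring nuclei, per-patient batch structure, peptide-to-protein
rollup, non-Gaussian intensity tails, or compositional effects between
cell classes. Passing tests therefore demonstrate correctness of the
algorithms under the stated models, not performance on real tissue.

# Numerical choices and degenerate inputs

* Degenerate normalization scale → 0.5; zero within-image intensity SD →
  no outlier removed; zero variance with `s0 = 0` → statistic `NA` with
  a warning; `s0 > 0` keeps everything finite.
* Undefined statistics never enter the significance set (|d| treated as
  0 in the permutation machinery).
* Ties: boundary stain scores go to the higher class; equal abundances
  rank lexicographically by protein id; overlapping regions resolve by
  declaration order.
* All vertex coordinates are integers in the LMD export
  (half-away-from-zero), making round trips exact.

# Problem sizes

The shipped tests and the acceptance script use 10,000 nuclei for
classifier recovery, 1,000-protein matrices (20 repeats for the
null-calibration study, 250 permutations each), 2⁹ exhaustive
missingness patterns for the filter oracle, 1,000 random points and
1,000 × 64-vertex contours for the geometry checks, and a
3,000-cell / 300-protein configuration for end-to-end determinism —
sizes at which every property under test is already well resolved.

# Known limitations

* The classifier thresholds are declared defaults, not reconstructions
  of any published criteria; real deployments should calibrate them per
  stain batch.
* Polygon offsetting does not resolve global self-intersections that
  arise for offsets comparable to concave feature size.
* The permutation FDR assumes exchangeable samples under the null;
  strong patient effects violate this, which is why the patient
  aggregation mode exists.
* Frame mismatches between cell coordinates and region polygons cannot
  be detected and silently mislabel cells.
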