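---
title: "Methods: spatial quantification of tumor microniches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatial quantification of tumor microniches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## Scope and model

`microniche` quantifies the spatial organization of pancreatic ductal
adenocarcinoma (PDAC) microniches from *segmented* whole-slide-image
exports: the inputs are cell tables (one row per detected cell, coordinates
in micrometres), region and invasion-front annotations (GeoJSON), rasterized
stain-intensity fields, and barcode count tables. Tissue segmentation and
cell detection are upstream products, not something this package attempts.

The biological setting: PDAC grows both in its archetypical desmoplastic
stroma and inside pancreatic lobules, where tumor cells meet acinar cells,
acinar-to-ductal metaplasia (ADM), ducts and islets. The package measures
what tumor cells touch (contact calling), how niche composition changes
with distance from the lobular invasion front, how marker phenotypes
(classical vs basal panels) differ between compartments, how stromal
markers such as NGFR organize in concentric layers and gradients around
tumor regions, and how clonal lineage barcodes distribute across samples.

All coordinates are micrometres in image convention (origin top-left, y
increasing downward); distances and areas are convention-independent.

## Contact calling

A tumor cell is "in contact with" a tissue class when at least one target
of that class (a class-labeled cell or a class-region polygon) lies at
Euclidean distance strictly less than the contact radius from the tumor
cell's centroid. The default radius is 20 um and the inequality is strict:
the upstream rule includes a target only when the distance "was less than
20 um", so a target at exactly 20.0 um is *not* a contact. A tumor cell
inside a class polygon is at distance 0 and always contacts it. Classes
outside the closed vocabulary (tumor, acinar, adm, duct, islet, fibrosis,
immune, nerve, vessel, other) map to `other` rather than erroring,
mirroring how unidentifiable contacts were assigned upstream.

Two summary statistics are deliberately both reported, because per-panel
conventions differ: (a) per-class *fractions* of tumor cells with at least
one contact (a cell counts toward every class it touches, so fractions can
sum to more than 1), and (b) normalized *shares* of all contacts (sums
to 1). Front-distance profiles bin cells into half-open intervals
`[0, w), [w, 2w), ...` (default `w` = 10 um; the source plots continuous
distance with a 50 um zoom, so the width is configuration, not a claim);
empty bins report `NA`, never a fabricated 0, and cells without a front
distance are excluded and counted.

## Geometry

No polygon library with buffering support is assumed; the primitives are
implemented in-package and each is verified against a brute-force oracle
in the test suite:

* **Distance to an annotation** is the exact point-to-segment minimum over
  the geometry's segments; polygons return 0 for interior/boundary points,
  and points inside holes get their positive distance to the surrounding
  ring.
* **Fixed-radius neighbor queries** use the strict `<` predicate and are
  required (and tested) to be set-identical to exhaustive enumeration.
* **Concentric stromal layers** ("annuli") are built by successive outward
  polygon offsetting with round joins at convex vertices (arc sagitta
  tolerance 0.1 um) and miter joins at reflex vertices. This is exact for
  convex bases — ring k of a convex polygon with perimeter P has area
  `P*w + pi*w^2*(2k-1)`, the Minkowski-sum closed form the acceptance
  suite checks to 0.5% — and correct for gently concave bases; a base too
  non-convex for the requested width makes the offset self-intersect and
  raises an error rather than silently producing a wrong ring. Cells are
  assigned to rings by the half-open distance rule (`[0,w)` inner,
  `[w,2w)` middle, ...), which is resolution-independent and agrees with
  the ring polygons up to the arc tolerance. The default width, 15 um,
  approximates one stromal cell diameter.
* **Disk intensity means** average all pixels whose centers fall inside
  the disk, after clamping negative pixel values (an upstream artefact) to
  zero. Pixel-center membership is unambiguous at the default 0.92 um
  pixel size. The upstream protocol states a "circular area (diameter
  50 um)" in one place and a "50 um radius area" in another; the radius is
  therefore an explicit parameter everywhere, defaulting to 25 um (the
  Methods reading).

## Phenotype statistics

Marker-positive fractions are computed per ROI over tumor cells;
positivity is either given per cell or derived as
`intensity >= threshold` with explicit per-marker thresholds (upstream
these were set per slide by eye; this package refuses to guess). Missing
measurements stay `NA` — the only imputation is fraction 0 for ROIs
explicitly declared completely negative, matching the upstream convention.

The compartment comparison first averages ROI fractions per tumor and
compartment, then applies a two-tailed *paired* Wilcoxon signed-rank test
across tumors, BH-corrected within the marker family (the six-marker panel
is one family, matching per-panel correction upstream). Zero differences
are dropped per the signed-rank convention; a marker whose pairs are all
identical reports `NA` with a flag rather than a misleading p = 1.

The Simpson (Gini-Simpson) index is the probability that two ROIs drawn
without replacement differ in positive fraction. Continuous fractions
almost never tie, so "differ" is made operational by decile binning
(`n_bins = 10`, configurable); a raw-value variant is provided
(`binned = FALSE`) since the upstream binning is unstated. The index is
`1 - sum(n_i (n_i - 1)) / (N (N - 1))` over bin counts.

ROI clustering uses Euclidean distance between ROI columns and Ward
linkage (`ward.D2`) after median-imputing missing values per marker; the
upstream metric/linkage are unstated, so these common defaults are fixed
and configurable consequences are left to the caller. Columns are
pre-sorted by ROI id before clustering, making the dendrogram invariant to
input order (the documented tie-break).

Subtype calls label an ROI basal/classical when the corresponding fraction
difference exceeds delta = 0.05, else indeterminate (excluded); the
upstream "predominant subtype" rule is qualitative, so delta is explicit.
The 2x2 subtype-by-compartment table gets an uncorrected two-sided Pearson
chi-squared test (`NA` on zero margins) and a two-sided Fisher exact test.

Kruskal-Wallis tests use the tie-corrected statistic; Dunn post-hoc z
tests compare mean ranks with the pooled tie-corrected variance and BH
correction across the pairwise family. Fully tied data report H = 0,
p = 1.

## Stromal profiles

Layer enrichment is computed on cells (not area), matching the upstream
positive-cell fractions, with optional pre-filters: a nuclear-circularity
cut (default 0.85 when enabled; the exact upstream cut is unpublished) to
enrich for stromal morphology, and removal of cells positive for a tumor
marker. The intensity gradient analysis includes only tumor cells in
direct fibrosis contact (nearest fibrosis < 20 um), measures the
disk-mean intensity around each, and reports a rolling mean with the
per-window *sample* SD over front distance. The window is a 25 um
centered interval evaluated at each included cell, requiring at least 20
cells (both configurable; the upstream window is unstated). Reference
means for acinar and ADM cells are computed identically but without front
conditioning. Positive-area fractions threshold clamped pixel values
strictly (`> threshold`) inside a region by pixel-center containment.

## Clonality

The pipeline starts at the barcode x sample count table. Order of
operations — normalize, threshold, hop-filter — is fixed and documented
because the upstream order is unstated: (1) each sample is scaled to a
reference depth (default: mean of sample totals) and rounded half-up
("rounded to integers" upstream does not specify the rule); (2) counts
below 1000 are zeroed (the upstream "arbitrary read count threshold");
(3) index hopping is removed per barcode by zeroing counts below
`hop_fraction` (default 0.05) of the barcode's maximum across samples —
the simplest deterministic rule that reaches the upstream end state of
near-universal single-sample presence, since bleed-through is a small
multiplicative leak from the dominant sample. The filter never touches
the maximal sample and is idempotent. Summaries report per-sample clone
frequencies, the top-clone fraction with a monoclonality flag at 0.99
(at least 99% of cells sharing one barcode), and the cross-sample
uniqueness fraction.

## The synthetic cohort generator

The clinical imaging data behind the source study are restricted-access,
so every pipeline stage is exercised against generated cohorts whose
parameters are *planted* and recorded in a truth manifest. The stated
world the defaults encode:

* 299-864 tumor cells per ROI (uniform), the upstream annotation rule;
* paired lobular and stromal ROIs per tumor; stromal ROIs contain no
  acinar/ADM/islet cells;
* marker positivity Bernoulli per tumor cell with an ROI-level mean drawn
  from a Beta distribution around the compartment mean (classical markers
  0.45 lobule / 0.15 stroma, basal markers mirrored, between-ROI sd 0.05)
  — the study reports only observed fractions, so the hierarchy
  (tumor -> compartment -> ROI -> cell) is a modeling choice any monotone
  compartment effect would satisfy;
* ADM placement density multiplied by `exp(-d_front / 50 um)` on the
  exocrine side of the front — the study gives no generative model, any
  monotone front enrichment suffices for testing;
* NGFR fields `baseline - decay * distance + noise`, floored at 0
  (default baseline 100, decay 1 per um, noise sd 5, pixel 0.92 um);
* stage-dependent exocrine AMY/KRT19 composition with double positives
  peaking at mild/moderate atrophy and ductal commitment dominating
  end-stage;
* inner-layer myCAF enrichment 0.6/0.2/0.2;
* near-clonal barcode tables (two monoclonal samples at >= 99%, one
  two-clone, one five-clone sample, depth 1e5) with Poisson index-hopping
  at rate 0.002 of the source count.

Geometry is a convenience: ROIs are gently star-shaped polygons and
fronts lightly bent polylines; nothing downstream depends on lobule shape
realism. The generator does not emulate staining chemistry, scanner
artefacts, segmentation errors, or spatially correlated noise — a green
test therefore establishes algorithmic correctness against planted
structure, not robustness to upstream segmentation failure modes.

A single RNG stream is derived from the config seed, with per-ROI
sub-seeds derived deterministically so cohorts are bitwise-reproducible.

For power and type-I studies that need hundreds of cohorts, spatial cell
placement is wastefully slow, so `simulate_fraction_cohort()` plants the
same compartment-shift model directly at the ROI-fraction level (per-tumor
stromal mean `0.4 + N(0, 0.05)`, per-tumor lobule shift `N(+-0.3, 0.1)`,
per-ROI jitter sd 0.05, binomial cell sampling at 299-864 cells). The
acceptance suite runs the paired test on 200 such cohorts (power of the
shifted markers, raw-p type-I calibration of null markers at alpha = 0.05
— BH-adjusted null rejection inside a family containing real effects is
not a calibrated 5% quantity) and Ward clustering on 50 (adjusted Rand
index against true compartments).

## Numerical choices and degenerate inputs

* Strict `<` at every radius; boundary equality excluded by design.
* Arc tolerance 0.1 um for offsets; offsets that self-intersect error.
* Rounding half-up after depth normalization.
* Beta moment-matching clamps variance below the feasible maximum;
  degenerate dispersion returns the mean.
* Empty bins/layers/lobules report `NA` plus a count, never 0.
* `NA` handling is never silent: dropped tumors, excluded cells and
  removed read mass are returned alongside results.

## Known limitations

* Polygon offsetting is not a general boolean-geometry engine: strongly
  non-convex bases (offset self-intersection) and base polygons closer
  than the total layer width are rejected, not resolved by union.
* Contacts are 2D; no correction for section thickness or geodesic
  (within-tissue) distance.
* The clonality hop filter is the relative-maximum rule; studies with
  balanced multi-sample clones would need a different model.
* The paper's headline cohort numbers (e.g., compartment p-values,
  adjacency percentages, coexpression overlaps) depend on restricted
  clinical data and are not reproduced or asserted anywhere in this
  package.
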