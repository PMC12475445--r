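# microniche

Spatial quantification of tumor microniches from segmented whole-slide-image
exports of pancreatic cancer tissue.

Pancreatic ductal adenocarcinoma (PDAC) grows in two very different
microenvironments: the archetypical desmoplastic stroma, and invaded
pancreatic lobules where tumor cells sit next to acinar cells, cells
undergoing acinar-to-ductal metaplasia (ADM), ducts and islets. Comparing
these niches quantitatively requires a chain of unglamorous but exacting
steps downstream of segmentation — strict fixed-radius contact calling,
invasion-front distance profiles, compartment-paired marker statistics,
concentric stromal-layer enrichment, intensity gradients, and lineage-
barcode clonality filtering. `microniche` implements that chain as a
tested, reusable R package for anyone with cell tables, region annotations
and intensity rasters exported from a digital pathology platform (e.g.
QuPath CSV + GeoJSON).

Because clinical WSI data of this kind are typically restricted-access, the
package ships a ground-truthed **synthetic tissue generator**: cohorts with
planted compartment effects, front enrichment, intensity gradients, layer
enrichment and near-clonal barcode tables, so that every analysis stage is
testable end to end with no data download.

## The statistics at the core

* **Contacts**: tumor cell *i* contacts class *c* iff
  `min_j d(x_i, t_j) < r` over targets of class *c* (default `r = 20` µm,
  strictly). Reported per class as the fraction of tumor cells with ≥ 1
  contact, and as normalized shares of all contacts.
* **Paired compartment test**: per marker, tumor-level compartment means of
  ROI positive fractions; two-tailed paired Wilcoxon signed-rank across
  tumors; Benjamini–Hochberg across the marker family.
* **Simpson (Gini–Simpson) diversity** over binned per-ROI fractions:
  `D = 1 − Σ nᵢ(nᵢ−1) / (N(N−1))` — the probability two random ROIs differ.
* **Stromal layers**: outward annuli of width 15 µm built by polygon
  offsetting; ring *k* of a convex base with perimeter *P* has area
  `P·w + π·w²(2k−1)`, which the tests verify against the construction.
* **Gradients**: disk-mean intensity (radius 25 µm, negatives clamped to 0)
  around fibrosis-contacting tumor cells, rolling mean ± SD over distance
  to the invasion front.
* **Clonality**: depth normalization → 1000-count floor → per-barcode
  relative-maximum index-hop filter (`count < 0.05 · max` zeroed) →
  clone frequencies, monoclonality at ≥ 0.99, cross-sample uniqueness.

See `vignettes/microniche-methods.Rmd` for assumptions, parameter
rationale, and what the synthetic cohorts do and do not establish.

## Worked example

```r
library(microniche)

cfg    <- synthetic_config(seed = 42, n_tumors = 3, rois_per_compartment = 2)
cohort <- generate_cohort(cfg)

ct <- call_contacts(cohort$cells, cohort$regions, radius_um = 20)
subset(contact_fractions(ct, group_by = "compartment"),
       tissue_class %in% c("fibrosis", "adm", "nerve"))
#>     group tissue_class n_cells fraction  share
#>  2 lobule          adm    3229   0.0771 0.0635
#>  5 lobule     fibrosis    3229   0.7312 0.6024
#>  7 lobule        nerve    3229   0.0000 0.0000
#> 11 stroma          adm    3352   0.0000 0.0000
#> 14 stroma     fibrosis    3352   0.9931 0.4070
#> 16 stroma        nerve    3352   0.3983 0.1632
```

Fibrosis is the dominant contact in both compartments but less so in
lobules, where ADM contacts appear; nerve contacts are stromal-only — the
planted niche structure, recovered by the pipeline.

```r
head(subset(composition_by_front_distance(ct, bin_width_um = 25),
            tissue_class == "adm"), 2)
#>    bin_start bin_end   n tissue_class fraction
#>  2         0      25 439          adm    0.554
#> 11        25      50 464          adm    0.013
```

ADM contact is concentrated at the invasion front (55% of tumor cells in
the first 25 µm vs 1% beyond), reflecting the planted exponential front
enrichment.

```r
res <- paired_compartment_test(build_fraction_matrix(cohort$cells))
res[, c("marker", "mean_lobule", "mean_stroma", "p_adj")]
#>   marker mean_lobule mean_stroma p_adj
#> 1 MUC5AC       0.407       0.172  0.25
#> 3   KRT5       0.130       0.414  0.25
#> ...
```

Classical markers (MUC5AC, CDX2) are higher in lobules, basal markers
(KRT5, KRT17, HMGA2, CA125) in stroma; with only 3 tumors the paired
Wilcoxon cannot go below p = 0.25 — the acceptance suite shows ≥ 95% power
at the realistic 30-tumor scale.

```r
bc <- generate_barcode_counts(cfg)
s  <- clone_summary(filter_index_hopping(preprocess_counts(bc$counts)))
s$per_sample
#>   sample total top_clone_fraction n_clones monoclonal
#> 1     M1 99527             1.0000        1       TRUE
#> 2     M2 99239             1.0000        1       TRUE
#> 3     M3 99999             0.7004        3      FALSE
#> 4     M4 99978             0.3503        6      FALSE
s$uniqueness_fraction
#> [1] 1
```

After filtering, every barcode is present in exactly one sample
(uniqueness 1.0) and the planted clone structure (two monoclonal mice, a
two-clone and a five-clone tumor) is recovered.

## Command line

```sh
Rscript inst/cli/microniche simulate  --config cfg.yaml --seed 7 --out cohort/
Rscript inst/cli/microniche contacts  --cells cohort/cells.csv \
    --annotations cohort/regions.geojson --radius 20 --out out/
Rscript inst/cli/microniche clonality --counts counts.csv \
    --min-count 1000 --hop-fraction 0.05 --out out/
```

Also available: `phenotype`, `layers`, `gradient` (see `?microniche_cli`).

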