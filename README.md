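# barcodegap

Evaluation of DNA barcode (COI) reference libraries: barcode-gap statistics,
library-based identification tests, BIN-style clustering, and category effect
models — with a seeded simulator so the whole pipeline can be exercised
without downloading data.

## The problem

A DNA barcode reference library identifies unknown specimens by matching
their ~658 bp COI sequence against curated, expert-identified sequences. The
approach works when a *barcode gap* exists: for each species, the maximum
intraspecific K2P distance stays below the minimum distance to its nearest
heterospecific neighbour (NN). Regional libraries raise a practical question:
how well does a library sampled in one region (say, a densely sampled
national campaign with 3–4 specimens per species) identify specimens
collected far away (1–2 specimens per species from a region ~1600 km
distant)? Extending geographic coverage can only raise intraspecific maxima
and lower interspecific minima, so the gap can narrow — this package
quantifies by how much, and whether identification survives it.

`barcodegap` is aimed at barcoding campaigns and taxonomists who have (a) an
aligned FASTA of barcodes and (b) a specimen metadata table, and want the
standard battery of library diagnostics in reproducible, scriptable form.

## What it computes

* **K2P distances** with pairwise deletion:
  `d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)`, where `P` and `Q` are the
  transition and transversion proportions among sites where both sequences
  are unambiguous. Saturated or low-overlap pairs are reported as undefined,
  never clamped.
* **Per-species gap statistics**: max/mean intraspecific distance,
  nearest-neighbour species and distance, barcode-gap flag, a
  diagnosability call (single-linkage isolation: the species' internal
  minimum-spanning-tree chain must stay strictly tighter than its minimum
  interspecific distance), and threshold censuses (fractions of species
  below 1%, 2%, …).
* **Partition comparison**: every statistic recomputed on the
  reference-region subset vs the pooled two-region data.
* **Identification tests**: each query-region specimen identified against
  the reference-region library by nearest neighbour or best-close-match,
  with correct/incorrect/no-id/ambiguous verdicts and rates.
* **RESL-lite clustering**: single-linkage pre-clustering at 2.2%, Markov
  clustering refinement, silhouette acceptance; then per-species
  concordance classes (match / merge / split / mixture) and regional split
  patterns.
* **Category effect models**: Gaussian mixed model with a family-level
  random intercept, optional per-category residual variances
  (heteroscedastic), sample size as covariate, and likelihood-ratio tests —
  e.g. does distribution type (continuous / fragmented / disjunct /
  migratory) shift intraspecific divergence?
* **Synthetic libraries**: a K80 simulator that reproduces the two-region
  design (nested taxonomy, category-specific divergences, deep splits in a
  configurable fraction of species, migratory species with near-zero
  divergence) plus a ground-truth table for recovery tests.

## Worked example

```r
library(barcodegap)

cfg <- scenario_config("study_like", seed = 42)   # 200 species, two regions
lib <- generate_library(cfg)
res <- run_barcode_pipeline(lib$dataset)
res
#> Barcode-library evaluation: 993 specimens, 200 species
#>   diagnosable: 93.0%; mean max intra 1.53%; mean NN 5.86%
#>   clusters: 224; concordance match/merge/split/mixture: 176/0/24/0
#>   identification correct rate: 100.0%
```

The summary says: of 200 simulated species, 93% carry a diagnostic barcode;
intraspecific maxima average 1.53% against a 5.86% mean distance to the
nearest neighbour (the barcode gap); RESL-lite finds 224 clusters, with 176
species mapping 1:1 onto a cluster and 24 splitting (the simulator injected
deep splits into 12% of species); and every query-region specimen was
correctly identified from the reference-region library.

Per-species detail and the census of intraspecific maxima:

```r
head(res$gap_stats[, c("species", "max_intra", "nn_species", "nn_dist", "gap_present")], 3)
#>   species        max_intra nn_species     nn_dist gap_present
#> 1 Genus0101 sp01     0.765 Genus0101 sp03    4.24 TRUE
#> 2 Genus0101 sp02     0.766 Genus0101 sp03    8.96 TRUE
#> 3 Genus0101 sp03     1.07  Genus0101 sp01    4.24 TRUE

res$census
#>   bin   count fraction
#> 1 =0        2     0.01
#> 2 <1      118     0.59
#> 3 <2      176     0.88
#> 4 >=2      24     0.12
```

With real data, replace the simulated dataset by
`read_barcode_dataset("barcodes.fasta", "specimens.tsv")` — the FASTA headers
carry specimen ids, and the TSV supplies species, genus, family, region and
(optionally) distribution category and dispersal class per specimen.
`plot_barcode_gap()`, `plot_partition_comparison()` and friends give the
standard figures; `tidy()`/`glance()` work on distance matrices and model
fits.

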