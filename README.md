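# lysoflux

Coordinate upregulation of lysosomal/autophagic genes is a recurring
signature of inflamed, obese adipose tissue, and identifying which gene sits
at the hub of that transcriptional program is a network question as much as
a differential-expression question. `lysoflux` implements the full analysis
arc as a tested R package, for computational biologists who want each stage
as a callable, seeded, validated function rather than a one-off script:

- **Differential expression on counts** — median-of-ratios normalization
  and a per-gene negative-binomial Wald test
  (Var = μ + αμ², moment dispersion shrunk to a mean–dispersion trend),
  gated by explicit fold-change/FDR thresholds
  (defaults FC > 1.2 or < 0.833 at FDR < 0.2).
- **Gene-set operations** — Venn-style intersection with a curated focus
  list, per-sample composite z-scores compared by Mann–Whitney U, ΔΔCT
  relative quantification (2^(−ΔΔCT), reference-gene normalized).
- **Short-time-series profile clustering** — all (2c+1)^(T−1) − 1
  unit-change model profiles (26 for a 4-time-point course with c = 1),
  nearest-template assignment of anchored series, and per-profile
  permutation significance.
- **Enrichment** — hypergeometric (Fisher-exact) term over-representation
  and permutation GSEA (signal-to-noise ranking, weighted running sum,
  phenotype or gene-set permutation).
- **Co-expression network** — Pearson correlations with exact t-test
  p-values, one joint BH-FDR cut on all pairs (edges at FDR < 0.05), and
  hub ranking by k-core coreness with degree and gene-id tie breaks.
- **Synthetic-data generators** — negative-binomial cohorts with planted
  fold changes, time courses planted into model profiles, and
  latent-factor co-expression modules with a designated hub, each emitting
  a truth table so recovery is scored end to end.

A config-driven `run_pipeline()` chains the stages with per-stage seeds
derived from one global seed and writes a checksum manifest, so a whole
analysis is reproduced by a single integer.

## Worked example

```r
library(lysoflux)

cfg <- default_pipeline_config()
cfg$seed <- 42L
manifest <- run_pipeline(cfg, output_dir = "lysoflux_run")
#> simulate: 1000 genes x 20 samples (counts), 60 planted DEGs
#> diffexp: 1000 genes tested -> 61 up, 16 down
#> overlap: 77 DEGs, 60 in focus set
#> zscore: Mann-Whitney p = 0.000157 on the focus composite
#> profiles: 26 model profiles, 4 significant (fdr < 0.05)
#> enrichment: 20 terms tested, 1 with fdr < 0.05
#> gsea: 10 sets, 4 with p < 0.05
#> network: 49 edges at fdr < 0.05; top hub g0001 (coreness 7)

read_results_table("lysoflux_run/recovery.tsv")
#>                 metric       value
#> 1      deg_sensitivity 1.00000e+00
#> 2      deg_false_calls 1.70000e+01
#> 3     profile_recovery 9.91667e-01
#> 4 hub_rank_of_true_hub 1.00000e+00
#> 5          zscore_mw_p 1.57052e-04
#> 6      signal_term_fdr 3.69288e-32
#> 7    signal_set_gsea_p 4.97512e-03
```

Reading the funnel: of 1000 simulated genes, 60 carried a planted 4-fold
change; the gated DE test called 77 genes, recovering all 60 planted ones
(`deg_sensitivity = 1`) with 17 extra calls — expected, since the default
gate controls FDR at the deliberately permissive 0.2. The focus-set
composite z-score separates the groups (Mann–Whitney p ≈ 1.6e-4), the
planted term dominates enrichment (FDR ≈ 4e-32), profile clustering
recovers 99.2% of planted time-course labels, and the planted hub is
ranked 1 in the co-expression network (coreness 7, degree 11 in this run).
Re-running with the same config reproduces byte-identical tables
(`manifest$files` checksums match).

Individual stages are ordinary functions, e.g.

```r
u <- enumerate_profiles(T = 4, c = 1)   # 26 model profiles
deg <- classify_deg(test_differential(counts, annotation),
                    deg_gates(1.2, 0.833, 0.2, "fdr"))
hubs <- rank_hubs(build_network(mat, fdr_max = 0.05))
```

A thin CLI wrapper lives at `inst/scripts/lysoflux.R`
(`Rscript inst/scripts/lysoflux.R run --config inst/extdata/example_config.yaml`).

## Scope

The pipeline starts at a count (or log2 intensity) matrix; read alignment
and quantification are upstream of it. Gene identifiers are opaque
case-sensitive strings — no symbol mapping. See
`vignettes/lysoflux-methods.Rmd` for the statistical models, parameter
defaults and the design decisions behind them.
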