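# temark

Benchmarking toolkit for transposable-element (TE) read mapping and
quantification.

TE families consist of many near-identical genomic copies, so reads
originating from them are inherently ambiguous: an aligner must drop them,
pick one position, or report all of them, and a quantifier must turn those
reports into per-family counts. `temark` measures the consequences of each
choice under fully controlled conditions:

* **Annotation** — parse RepeatMasker `.out` files, pair LTR/internal
  records via a three-tier dictionary, and merge fragmented records into
  copies (gap strictly < 1000 bp).
* **Toy genome** — plant TE families of controlled divergence (a proxy for
  age), truncation and annotation fragmentation into a random background,
  with exact truth tables, plus a brute-force per-family mappability oracle.
* **Simulation** — Illumina-like 2x100 bp pairs (fragment 200 ± 20 bp, 10X,
  linear error ramp 0.001 → 0.01) with an exact origin sidecar, TE-overlap
  filtering, and a matched single-end library.
* **Micro-aligner** — exhaustive mismatch-only search with explicit
  `unique` / `random` / `multi` best-stratum reporting, SAM output, and
  paired-end rescue.
* **Evaluation** — mapping percentage and a hit-weighted true-positive rate
  (`w = min(1, congruent/NH)`, congruence = chrom + strand + start ± 5 bp),
  per library and per family; PE-vs-SE gains; metadata rank correlation.
* **Quantification** — five counting modes (`unique`, `random`,
  `fraction_hits`, `fraction_families`, `total`) scored against the true
  abundance (R² and per-family estimate/truth ratios).

## Worked example

The one-command demo generates a 145 kb toy genome with four planted
families — `TOY_L1_young` (15 copies, divergence 0.005), `TOY_L1_mid` (6
copies, 0.05, 5'-truncated), `TOY_L1_old` (6 copies, 0.15) and a
`TOY_ERV` LTR element — then simulates, aligns, evaluates and quantifies:

```r
library(temark)
res <- run_demo(dir = "demo_out", seed = 1)
res$summary
#> # A tibble: 6 × 5
#>   mode   library mapping_pct tp_rate r_squared
#>   <chr>  <chr>         <dbl>   <dbl>     <dbl>
#> 1 unique PE             80.4    99.8     0.776
#> 2 unique SE             67.2    99.6     0.776
#> 3 random PE             99.5    84.0     1.000
#> 4 random SE             99.7    71.2     1.000
#> 5 multi  PE             99.5    83.7    NA
#> 6 multi  SE             99.7    71.0    NA
```

The benchmark trade-off in two rows: unique reporting maps fewer units but
almost every reported position is right; random/multi reporting maps nearly
everything while the hit-weighted TP rate drops because ambiguous units
spread weight over wrong positions.

Family resolution shows the age gradient — the young, near-identical family
is the hard one, and pairing rescues a large share of it:

```r
res$family_metrics_unique   # PE, unique mode
#>   scope        n_units n_mapped mapping_pct tp_rate low_confidence
#> 1 TOY_ERV-int      563      558        99.1   100   FALSE
#> 2 TOY_L1_mid       448      444        99.1   100   FALSE
#> 3 TOY_L1_old       696      694        99.7   100   FALSE
#> 4 TOY_L1_young    2068     1339        64.7    99.5 FALSE

res$gain_unique[res$gain_unique$scope == "TOY_L1_young",
                c("scope", "mapping_pct_pe", "mapping_pct_se",
                  "gain_mapping_pct")]
#>   scope        mapping_pct_pe mapping_pct_se gain_mapping_pct
#> 1 TOY_L1_young           64.7           42.7             22.0
```

Quantification (on the single-end multi-mode alignments; see the vignette
for why unique-mode underestimation is a single-read-span phenomenon under
best-stratum reporting):

```r
dplyr::select(res$comparisons, -data)
#>   r_squared     n mode              log10_scale
#> 1     0.776     4 unique            FALSE
#> 2     1.000     4 random            FALSE
#> 3     1.000     4 fraction_hits     FALSE
#> 4     1.000     4 fraction_families FALSE
#> 5     0.986     4 total             FALSE

res$comparisons$data[[1]]   # unique mode, estimate vs truth
#>   subfamily    estimated family       class  true ratio zero_truth
#> 1 TOY_ERV-int        493 TOY_ERV      LTR     563 0.876 FALSE
#> 2 TOY_L1_mid         415 TOY_L1_mid   LINE    448 0.926 FALSE
#> 3 TOY_L1_old         658 TOY_L1_old   LINE    696 0.945 FALSE
#> 4 TOY_L1_young       803 TOY_L1_young LINE   2068 0.388 FALSE
```

Unique-mode counting recovers only 39% of the young family while leaving
the old family near truth (ratio 0.945); random and fractional counting
recover all families with R² ≈ 1. Plots: `plot_tp_vs_mapping(res$metrics)`,
`plot_family_mappability(res$family_metrics_unique)` and
`autoplot(compare_abundance(...))`.

All numbers above are the actual output of `run_demo(seed = 1)`; identical
seeds give byte-identical outputs.

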