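# heterotag

Hybrid-vs-parent differential expression from digital gene expression
(DGE) tag profiling, for breeders and transcriptomicists studying
heterosis (hybrid vigor) in designs with a cross, its reciprocal cross,
and sexed libraries — the classic silkworm (*Bombyx mori*) setting of two
parental lines, 8 libraries, and economic traits such as cocoon shell
weight.

The package covers the whole analysis path:

1. **Tag reference** — every CATG (NlaIII) site with enough downstream
   bases yields a tag (CATG + 17 bases by default); sites are ranked from
   the 3' end, the rank-1 tag being the canonical DGE tag of the gene
   (`build_tag_index()`).
2. **Counting** — exact-match mapping of clean tags to genes; ambiguous
   tags excluded and reported (`map_tags()`), plus saturation curves and
   copy-number distributions.
3. **Normalisation** — TPM: `count / total clean tags x 1e6`
   (`tpm_normalize()`), and presence/absence Venn partitioning across
   libraries (`venn_partition()`, `shared_genes()`).
4. **Gene-action patterns** — fold differences are binary logs of TPM
   ratios of F1 to each parent; folds `>= 2` or `<= -2` are significant,
   and the 3x3 grid of (vs-female, vs-male) calls gives nine patterns:

   |          | male: UP | male: N | male: DOWN |
   |----------|----------|---------|------------|
   | **female: UP**   | OPS | OF | MAF |
   | **female: N**    | OM  | ND | UM  |
   | **female: DOWN** | FAM | UF | UPS |

   (`classify_patterns()`), with cross/reciprocal consistent-trend genes
   (`consistent_patterns()`).
5. **Heterosis correlation** — mid-parent heterosis
   `H% = (F1 - MP)/MP x 100` per trait and group
   (`heterosis_table()`), correlated with pattern proportions across
   groups; p-values from the regression F-test `F = r^2(n-2)/(1-r^2)`
   (`correlate_patterns_traits()`), starred at 0.05/0.01 two-tailed.

A seeded synthetic-data generator (`sim_config()`,
`simulate_dge_experiment()`) plants known gene-action classes and
pattern-trait correlations so every stage can be validated end to end
with no external data. See the methods vignette
(`vignettes/heterosis-dge.Rmd`) for the model, its assumptions, and the
design decisions (planted fold windows, compositional TPM shift, coupled
labels across sexes).

## Worked example

```r
library(heterotag)

cfg <- sim_config(seed = 42)          # 1,000 genes, 8 libraries, 50,000 tags each
run <- run_heterosis_pipeline(config = cfg)
run
#> heterotag pipeline run (simulation input, 8 libraries, seed 42)
#>   1000 genes indexed (840 with CATG site), 3360 pattern calls, 6 consistent-trend genes
```

840 of the 1,000 simulated genes carry a CATG site (the site-free rest
are invisible to the assay); each of the four (combination, sex) groups
classifies its 840 detected genes, giving 3,360 pattern calls. The
per-group pattern mix:

```r
pattern_summary(run$calls) |> dplyr::filter(group == "cross_male") |> dplyr::arrange(dplyr::desc(n))
#>   group      pattern     n denominator   prop
#> 1 cross_male ND        464         840 0.552
#> 2 cross_male UM        100         840 0.119
#> 3 cross_male OPS        67         840 0.0798
#> 4 cross_male OF         63         840 0.075
#> 5 cross_male UPS        46         840 0.0548
```

i.e. 55% of cross-male genes show no 4-fold difference from either
parent; 12% sit significantly below the male parent only (UM, a
dominance pattern), 8% above both parents (OPS, overdominance). Against
the planted ground truth the classifier recovers 97.6% of the non-ND
labels:

```r
recovery_vs_truth(run)$overall_non_nd
#> [1] 0.976
```

Correlating pattern proportions with mid-parent trait heterosis over the
four groups reproduces the familiar traits-by-patterns table, starred by
the F-test:

```r
run$correlations
#> Pattern-trait Pearson correlations over 4 groups (h_mid)
#>   trait               OPS    UPS     UF     UM      ...
#> 1 pupal_weight        -0.127 -0.723  0.745  -0.805  ...
#> 3 whole_cocoon_weight 0.130  -0.969* 0.750  -0.988* ...
```

With only n = 4 observations these correlations are fragile by design;
the object carries `n` with every p-value, and `tidy()` / `glance()` give
programmatic access. `autoplot()` methods exist for pattern summaries,
saturation curves, copy-number distributions and the correlation matrix.

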