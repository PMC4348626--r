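---
title: "Gene-action patterns and trait heterosis from DGE tag libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-action patterns and trait heterosis from DGE tag libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The method

Digital gene expression (DGE) tag profiling counts short cDNA tags anchored
at the 3'-most NlaIII restriction site (CATG) of each transcript. A tag is
the CATG anchor plus a fixed number of downstream bases (17 by default,
the standard 21-bp Illumina DGE tag; the assay itself does not fix the
length, so it is configurable). Tag counts per gene, divided by the
library's total clean tags and scaled by one million, give TPM
(transcripts per million clean tags):

$$\mathrm{TPM}(g, \ell) = \frac{\text{tags of } g \text{ in } \ell}{\text{total clean tags of } \ell} \times 10^6 .$$

The experimental design is two parental silkworm lines, their cross and
the reciprocal cross, with sexed libraries: per combination one library
for each parent and one for each F1 sex, eight in all. For every
(combination, sex) group the fold differences are binary logarithms of
TPM ratios of the F1 to each parent,

$$f_F = \log_2 \frac{\mathrm{TPM}_{F1}}{\mathrm{TPM}_{P_F}}, \qquad
  f_M = \log_2 \frac{\mathrm{TPM}_{F1}}{\mathrm{TPM}_{P_M}},$$

and folds at or beyond $\pm 2$ (a 4-fold change) are significant. Each
side is therefore UP, DOWN or N, and the $3\times3$ grid defines nine
mutually exclusive, exhaustive gene-action patterns: ND (no difference),
OPS/UPS (over/under both parents — over- and underdominance), OF/OM/UF/UM
(dominance: above or below one parent only, named for the parent the F1
differs from), and MAF/FAM (additive: between the parents). The grid
formalisation is ours; it is the unique 9-way partition matching the
pattern names. MAF is oriented as "male > F1 > female" by default and the
orientation is configurable, since the names alone do not fix it.

Genes carrying the same non-ND label in the cross and the reciprocal
cross of the same sex, in both sexes, are the consistent-trend genes
(`consistent_patterns()`; per-sex and all-group rules are options).
Finally, for each trait the mid-parent heterosis
$H\% = (F1 - MP)/MP \times 100$, $MP = (P_1 + P_2)/2$ (better-parent mode
available) is correlated across groups with each pattern's proportion;
the p-value is the regression F-test $F = r^2(n-2)/(1-r^2)$ on $(1, n-2)$
df, identical to the two-tailed t-test of $r$. With the standard design
there are only $n = 4$ groups, so these correlations are fragile by
construction; the package refuses $n < 3$ and reports $n$ with every
p-value, and cells with constant proportions are flagged rather than
given a fabricated value. No multiple-testing correction is applied,
as in the threshold-based DGE analyses this procedure comes from.

## What the simulator emulates

`sim_config()` + `simulate_dge_experiment()` generate the full study:
random transcripts (300–1500 bp) of which 16% lack a CATG site (mirroring
a reference of 14,623 genes with 12,264 site-bearing ones), planted
gene-action labels per (combination, sex) group, eight tag libraries of
50,000 clean-tag copies each drawn by multinomial sampling with
multiplicative log-normal noise (sigma 0.1) per gene and library, 1% of
copies from non-3'-most sites (reproducing the ~99% first-site
statistic), and trait tables whose mid-parent heterosis is linearly
coupled to planted pattern proportions.

Key modelling choices, and why:

* **Planted effect sizes.** Significant folds are drawn from windows
  comfortably beyond the cut-off: 3.25–3.75 log2 for over/underdominance
  and dominance, 4.25–4.75 for the additive patterns, and null sides
  within ±0.4. Every planted fold clears the ±2 threshold by at least the
  configured `margin` (0.5 log2 by default); the windows sit further out
  because at 50,000 copies over 1,000 genes the average gene receives
  only ~50 tags and a fold estimated from a handful of counts has an sd
  of several tenths of a log2 unit. The defaults were fixed by a
  prospective design study before the validation suite was written.

* **Compositional shift (the reason the additive/dominance windows are
  where they are).** TPM is relative: each library is normalised by its
  own total. If the F1 library carries more up-regulated mass than a
  parent, every TPM fold against that parent is shifted down by the log
  mass ratio. The shift grows with the differential-expression share, and
  for a transcriptome where ~25–30% of genes are 10-fold up-regulated the
  realisable TPM fold hits a hard ceiling near 2.5 — no planted absolute
  fold can exceed it. The generator therefore defaults to a moderate DE
  share (ND 56–66% per group), which keeps the shift at ~0.2–0.3 log2.
  Planted folds are exact on the absolute-mean scale (the classifier
  applied to noise-free mean ratios reproduces every label); on the TPM
  scale they carry this small, documented shift. Real DGE data has the
  same property, which is worth remembering when interpreting fold
  thresholds on deeply unbalanced transcriptomes.

* **Abundance model.** Baseline relative abundances are log-normal
  (sdlog 0.35) left-truncated at 0.6 so that planted classes concern
  genes quantifiable at the configured depth; a gene expected to receive
  3 tags cannot carry a recoverable 4-fold call at any margin. The
  untruncated heavy-tailed regime of shallow DGE libraries — where
  distinct tag types are dominated by the 1–4 copy class — is available
  via `baseline_floor = 0` with a larger `baseline_sdlog`, and that is
  the regime the copy-number-distribution checks use.

* **Coupled labels across sexes.** The two F1 sexes of a combination are
  compared against the *same* two parental libraries, so the parental
  log2 difference implied by one sex's label constrains the other's:
  "no difference" in one sex is geometrically incompatible with a strong
  single-parent dominance call in the other (their feasible parental
  differences do not overlap). Labels are therefore sampled jointly —
  the first sex (rotated at random per gene) from the group's
  proportions, the second restricted to compatible labels — and the
  *realised* labels are the ground truth that downstream trait planting
  and recovery checks use. This coupling is a property of the shared
  parental-library design itself, not of the simulator.

* **Trait noise.** By default the Gaussian noise added to planted trait
  heterosis is orthogonalised against the pattern proportions, so the
  planted correlation is the exact sample correlation (the
  `mvrnorm(empirical = TRUE)` construction). The naive alternative leaves
  the well-known small-sample bias of the sample correlation
  ($E[\tanh^{-1} r] \approx \tanh^{-1}\rho + \rho/(2(n-1))$), which at
  $n = 12$ is larger than the Monte-Carlo error of hundreds of
  replicates. Population-mode sampling is available with
  `trait_empirical = FALSE`.

* **Reproducibility.** One root seed; every stage (reference, planting,
  each library, traits) draws from its own derived substream, so adding
  a library never perturbs earlier ones, and identical configs produce
  byte-identical outputs.

## What passing checks do and do not show

The validation suite demonstrates that the pipeline's bookkeeping is
exact (copy conservation, TPM column sums, Venn partitions, the 9-label
grid against an independent oracle, parent-swap symmetry) and that on the
planted conditions the classifier recovers ≥95% of non-ND labels at full
depth, degrading monotonically as depth falls (74% at 5,000 copies, 89%
at 15,000, ~98% at 50,000 on the default seed). It does not show that
real libraries behave this way: the generator plants clean multiplicative
effects with a guaranteed margin, a single library per condition, no
replicate or dispersion structure, no sequencing error, and no
mismatch-tolerant mapping. Genes near the threshold, overdispersed
counts, and compositional shifts larger than the defaults will all lower
real-data recovery in ways the planted ground truth cannot expose.

## Numerical choices and degenerate inputs

* TPM floor 1.0 before ratios keeps folds finite; genes undetected in all
  three libraries of a comparison are excluded rather than floored.
* Thresholds are inclusive (`>= 2`, `<= -2`), matching "fold changes
  <=-2 or >=2 were considered significant" on the log2 scale.
* Ambiguous tags (matching more than one gene) are excluded from counts
  and reported; the assay's literature states no resolution rule.
* Mapping is exact-match only; mismatch-tolerant alignment is out of
  scope.
* Saturation subsampling is without replacement with an explicit seed.
* Pattern proportions use all classified genes (including ND) as the
  denominator by default (`denominator = "non_nd"` switches to DE-only).
* Zero-variance proportion columns and constant traits yield flagged NA
  correlations; parental trait values must be positive for heterosis
  rates to be defined.

## Problem sizes

The shipped validation runs use 1,000 genes and 50,000 tag copies per
library for the recovery and first-site checks (the standard study
condition), 120–200 genes for bookkeeping and oracle comparisons, and
200–500 replicates for correlation recovery — sizes chosen so the whole
suite exercises every stage end to end in well under half an hour on a
single core.

## Limitations

The package reproduces the analysis procedure, not any particular
dataset: real DGE libraries, trait replicates, and annotation-dependent
steps (GO/KEGG) are out of scope. The n=4 correlation design is reported
faithfully but is statistically fragile; treat its p-values as
descriptive. The compositional ceiling discussed above is an intrinsic
property of relative-abundance fold thresholds and applies to any
reanalysis with this method.
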