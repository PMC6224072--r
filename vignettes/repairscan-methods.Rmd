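---
title: "Methods: zygosity/rarity variant selection and its functional validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: zygosity/rarity variant selection and its functional validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repairscan)
```

## Scope and model

`repairscan` operates downstream of variant calling. Its unit of data is a
per-sample variant record (gene, position, read support, VAF, optional
population MAF, consequence class, optional deleteriousness score and LOH
flag); its endpoint is a per-sample drug IC50 (mitomycin C in the
motivating application — lower IC50 means more sensitive, i.e. more likely
repair-defective). The pipeline has four stages, each a pure function of
the previous one:

1. **Call-level QC** (`apply_call_filters()`, `remove_panel_of_normals()`,
   `restrict_consequences()`): SNVs need depth ≥ 10, ≥ 4 variant reads and
   VAF ≥ 0.10; indels need ≥ 10 variant reads with no VAF condition (the
   depth requirement applies to both kinds). SNVs within 1 base of a
   retained indel in the same sample are discarded as alignment artifacts;
   variants recurring in all supplied normal samples are treated as
   capture/sequencing artifacts; analyses are restricted to
   non-synonymous exonic plus essential splice-site classes.
2. **Selection** (`vaf_select()`, `maf_select()`, `score_select()`):
   zygosity via `vaf >= t`, rarity via `maf <= m` with MAF-less variants
   always retained, and a generic score filter for comparison with
   deleteriousness-based prioritization. All comparisons are inclusive,
   matching the conventional notation "VAF ≥ 0.8", "MAF ≤ 1%". The
   filters act on disjoint fields, so they commute and are idempotent.
3. **Association** (`assign_status()`, `ranksum_association()`, `ppv()`,
   `sweep_association()`): a sample is *pathway-mutated* iff ≥ 1 retained
   variant lies in any pathway gene. Significance is the two-sided
   Wilcoxon rank-sum test on IC50; the PPV is the fraction of mutated
   samples among the `top_k = 10` most sensitive.
4. **Cohort analyses**: the all-pathway screen with redundancy pruning
   (`screen_pathways()`, `prune_correlated()`) and the tumor
   TSG-vs-oncogene zygosity enrichment (`zygosity_enrichment()`).

## Statistical choices

**Rank-sum test.** When both groups have ≤ 10 samples the p-value is
computed by exhaustive enumeration of all `choose(n1 + n2, n1)` label
assignments using mid-ranks, so ties are handled exactly; with mid-ranks
the null mean of the rank sum is `n1 (N + 1) / 2` regardless of ties, and
the two-sided p is the fraction of assignments at least as far from that
mean as observed. For larger groups the tie-corrected normal approximation
(`stats::wilcox.test`, `exact = FALSE`) is used. The test suite checks the
exact branch against an independent brute-force enumeration and against
R's exact Wilcoxon distribution in the tie-free case. Tests are omitted —
reported as `NA`, never as an error — when either group has fewer than
`min_group = 2` samples.

**PPV.** The sentence defining the PPV admits two readings. We divide by
the number of *mutated* samples (not by `top_k`), because only that
reading makes the label-randomized null constant at
`top_k / n = 10/29 ≈ 0.3` irrespective of how many samples are mutated —
which is how the control behaves. The alternative reading is available via
`ppv(..., denominator = "top_k")`. "Most sensitive" means lowest IC50;
ties spanning the top-k boundary are broken by a stable sort on sample id
(deterministic) and reported with a message.

**Random gene-set null.** `random_gene_sets()` draws genes without
replacement until the cumulative target length falls within ±10% of the
target (the tolerance is a parameter; "similar size" is not otherwise
quantified). Sets exclude the tested pathway's own genes so the null is
not contaminated by true signal. Draws restart from a stated seed and are
fully reproducible.

**Pruning.** Mutation profiles are 0/1 vectors over samples, so Pearson
correlation equals the phi coefficient. Pruning processes rows greedily in
ascending-p order (omitted rows last): each surviving row removes all
later rows correlated at ρ ≥ 0.75 with it. This makes every survivor the
strongest association in its redundancy neighborhood, guarantees the
globally smallest p always survives, and `pruned_by` always names a
survivor. A constant profile (all or no samples mutated) has no defined
correlation; it is treated as redundant only with an *identical* profile.
The greedy rule is verified against an independent
extract-minimum reference on small collections. Pruned rows are flagged,
never dropped.

**Fisher test.** The pooled class-by-zygosity 2×2 table is tested with
`stats::fisher.test`, whose two-sided rule (sum of all tables with
probability ≤ observed at fixed margins) is checked against a direct
hypergeometric enumeration in the tests; the odds ratio is the
conditional MLE. For the published pooled counts 37/68 vs 1/11 the
homozygous-fraction ratio is 5.99 (≈ 6-fold) and the two-sided p is
0.0073; note that a one-sided test gives ≈ 0.005, which is the likelier
source of the stricter bound sometimes quoted for that table — the
package reports the computed two-sided value.

**Homozygosity in tumors.** Raw tumor VAF is confounded by purity, so a
record counts as homozygous when its LOH flag is `TRUE` *or* its VAF is
≥ 0.8; records without a flag fall back to the VAF rule alone. The OR
(rather than flag-only) rule is deliberate: germline homozygous variants
sit at VAF ≈ 1 at any purity and carry no LOH flag, yet are plainly
homozygous. LOH flags are consumed as input (produced upstream by an
allele-specific copy-number method, or by the simulator); the package
does not infer LOH.

## The synthetic generators

The generators define the conditions under which the pipeline is
validated; their defaults are fixed, not tuned per analysis.

**Cell-line panel** (`simulate_panel()`): 29 samples, 556 genes of which
20 form the planted pathway, gene lengths log-uniform on 500–10,000 bases
(so length-matching is non-trivial). VAF modes are truncated normals:
heterozygous 0.50 (sd 0.07), homozygous 0.95 (sd 0.04) — separated by
more than four standard deviations, so a 0.8 threshold classifies
zygosity with ≥ 99% accuracy; read counts are then binomially resampled at
negative-binomial depth (mean 247), which adds realistic shot noise
without closing the trough between the modes. 25% of background variants
are homozygous; 70% of variants carry a population MAF drawn from a
70/30 mixture of a common component (uniform 0.05–0.5) and a rare tail
(log-uniform 1e-4–0.01), spanning both sides of the 1% rarity criterion.
Each of the 10 defective samples gets ≥ 1 planted pathway variant
(homozygous mode, MAF absent or < 1%); IC50 is lognormal with the
defective location one natural-log unit below the proficient one
(sd 0.4 on the log scale) — a detectable but not overwhelming effect at
n = 29. No effect magnitude is published in reusable numeric form, so
this is a convention chosen once.

Proficient samples receive decoy *heterozygous* pathway variants
(Poisson, mean 1.5 per sample) whose MAF is an even mixture of common
SNPs and rare-or-absent annotations. The mixture matters: a screen that
keeps the MAF ≤ 1% filter but drops the VAF filter retains the
rare/non-SNP half of the decoys, mislabelling proficient samples as
mutated and diluting the association — reproducing the qualitative
failure of zygosity-blind selection. Purely common decoys would be
removed by the MAF filter alone and could not produce that contrast.

**Tumor cohort** (`simulate_tumors()`): 56 samples with purity uniform on
[0.3, 0.9]; 6 TSGs vs 10 oncogenes; per-gene-per-sample LOH probability
0.5 vs 0.1; germline variants homozygous with probability 0.15. VAF
follows the purity mixture
`(u·c_v + (1−u)·g_v) / (u·c_t + (1−u)·2)`, with `c_v = c_t = 1` under
LOH, giving the three characteristic modes: 0.5 (heterozygous),
`1/(2−u)` (LOH-shifted intermediate) and 1 (homozygous). LOH flags are
set truthfully from the simulated events.

**Null panel** (`simulate_null_panel()`): background variants spread over
*all* genes with no zygosity/rarity bias and a single IC50 distribution,
so any gene set's mutation status is independent of the drug ranking —
the substrate for type-I-error and null-PPV checks.

What the generators do **not** emulate: mapping and calling artifacts
(beyond what the QC filters consume), inter-gene LD, mutational
signatures, subclonal architecture and intra-tumor heterogeneity, copy
number beyond single-allele LOH, and any relation between deleteriousness
scores and function (scores are simulated uncorrelated, which is what
makes the score-sweep a negative control). Passing tests therefore show
internal correctness and statistical calibration under these idealized
conditions, not performance on real cohorts.

## Problem sizes in the test suite

The suite validates at the study's own scale where that is cheap
(29-sample panels, 56-sample cohorts, 10,000 random sets) and uses
20–50 seed replicates for the qualitative generator-level claims
(planted-pathway recovery, null calibration at a 5 × 4 threshold grid,
1,000 equal-rate Fisher simulations). The full suite runs in well under
two minutes on one CPU.

## Known limitations

* The adjacency rule removes SNVs within a fixed window (default 1 base)
  of a *retained* indel; indels that themselves failed QC do not trigger
  removal. Real indel-adjacent artifact patterns may be wider.
* Panel-of-normals matching is exact on `chrom:pos:ref:alt`; no fuzzy
  indel matching.
* One MAF reference population per run; multi-population annotations are
  out of scope.
* The screen applies no multiple-testing correction across pathways or
  thresholds, mirroring the exploratory usage it reproduces; feed the
  p-values to `p.adjust()` if error control is needed.
* Pruning eligibility is purely correlation-driven; no special handling
  of pathways represented by few captured genes.
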