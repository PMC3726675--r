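---
title: "Multi-domain candidate-gene prioritization: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-domain candidate-gene prioritization: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(szprior)
library(dplyr)
```

## The problem and the model

Schizophrenia association studies face a selection problem before a single
genotype is read: thousands of genes sit under the linkage peaks of a family
study, and only a few hundred fit on a custom genotyping array. `szprior`
implements a prioritization-and-evaluation pipeline for exactly this
situation.

Each gene $g$ in the linkage-region universe receives one p-value per
evidence domain:

* **Expression** — a differential-expression meta-analysis p-value,
  FDR-corrected (Benjamini–Hochberg step-up by default).
* **Network proximity** — the minimum number of unweighted steps in a
  protein–protein interaction (PPI) graph from $g$ to any of a small set of
  established susceptibility seed genes, converted to a rank-based p-value
  (fewest steps best).
* **Literature** — the number of term *categories* (disease states,
  neurotransmitters, neuronal features, brain development, brain structures)
  with at least one positive literature hit, converted to a rank-based
  p-value (most categories best).

The combined score is
$S_g = -\log_{10} p^{expr}_g - \log_{10} p^{ppi}_g - \log_{10} p^{lit}_g$,
and genes are ranked by descending $S_g$. Two gene sets are then selected
for genotyping: a *hypothesis* set (all genes annotated "nervous system
development" or "brain development") and a *rank* set (top-ranked genes
added greedily under a SNP budget). Their overlap defines three analysis
categories: 1 = both, 2 = hypothesis only, 3 = rank only.

Downstream, per-SNP association p-values are summarized per category
(observed vs. expected counts below 0.05 and 0.005), category enrichment is
tested against random same-size gene sets drawn from genome-wide GWAS
universes with SNP-count matching, and candidate SNPs are meta-analyzed
across studies with the inverse-variance fixed-effects model and a
heterogeneity screen ($p_{het} < 0.05$ removed).

## Rank-based p-values and ties

A domain whose evidence is ordinal (steps, category counts) is mapped to
probabilities by $p_i = \text{midrank}_i / N$: ties share the mean of the
ranks they span, so $\sum_i \text{midrank}_i = N(N+1)/2$ always, every $p$
lies in $(0, 1]$, and the best untied item gets $1/N$. The alternative
convention $\text{midrank}/(N+1)$ is available through the `method`
argument of `rank_to_pvalue()`. Genes unreachable from every seed (or
absent from the network) are treated as worse than any finite step count
and share the worst midrank; genes absent from the expression table get
$p^{expr} = 1$ (no evidence), counted in a warning. Final ranking ties are
broken by lexicographic gene id so reruns are reproducible.

We default to Benjamini–Hochberg for the expression FDR because it is
deterministic and parameter-free; a Storey-style estimate with fixed
$\lambda = 0.5$ (`storey_qvalues()`) is provided for fidelity to pipelines
that use the q-value of the null-proportion family.

## The budget walk

`select_rank_based()` walks the ranking from best to worst, adding every
gene whose tag-SNP count fits the remaining budget; too-large genes are
skipped and the walk continues (skip-and-continue maximizes inclusion under
the stated budget). Hypothesis genes consume no budget — their SNPs are
pre-allocated — and belong to the rank set only down to the *cutoff*, the
rank of the deepest budget-consuming addition. Without that cutoff rule,
free hypothesis genes would keep joining the rank set arbitrarily far down
the ranking and the "hypothesis only" category could collapse to empty,
which contradicts how a finite array is actually filled.

One caution: skip-and-continue selection is not monotone in the budget — a
slightly larger budget can afford an expensive high-ranked gene and thereby
drop several cheaper lower-ranked ones. `snps_used` is monotone; the
selected set is not. This is a property of the greedy rule, not a bug.

## Enrichment simulations and SNP-count matching

For each category, `simulate_gene_sets()` draws same-size random gene sets
from a genome-wide GWAS universe and summarizes four metrics per set: total
SNP count, minimum p, and counts of SNPs with $p < 0.05$ and $p < 0.005$.
Significance is the plus-one empirical p-value $(r + 1)/n$, where $r$
counts simulations as or more extreme than the observed value ("$\ge$" for
counts, "$\le$" for minimum p); it is never 0 and never below $1/n$.

Gene size and SNP density vary enormously, so random sets are biased
relative to a deliberately SNP-dense observed set.
`snp_count_match_filter()` sorts simulations by descending SNP count and
retains the smallest top-$K$ from the grid
$\{500, 1000, 2000, 5000, 10000, 20000, 50000\}$ whose retained counts are
two-sidedly compatible with the observed count. Compatibility uses the
mid-tie fraction $(\#\{>\} + \tfrac12\#\{=\})/K \in [0.025, 0.975]$ — i.e.
the observed count must sit inside the central 95% of the retained counts.
The mid-tie convention is what makes the degenerate case of constant
simulated counts equal to the observed count (fraction $\tfrac12$) come out
compatible, as it plainly should. If no grid value is compatible, all
simulations are used and the result is flagged; the report carries both the
unfiltered and the matched empirical p-values.

Whether matching should be done per category or once for the "All" union is
not determined by the design we emulate; we match per category, since each
category's observed SNP count is the quantity its own simulations must be
compatible with.

## Fixed-effects meta-analysis

`fe_meta()` pools study effects with weights $w_i = 1/se_i^2$:
$\hat\beta = \sum w_i b_i / \sum w_i$, $se = (\sum w_i)^{-1/2}$. Cochran's
$Q = \sum w_i (b_i - \hat\beta)^2$ is referred to $\chi^2_{k-1}$
(asymptotic; no small-$k$ correction), and
$I^2 = \max(0, (Q - (k-1))/Q) \times 100$, defined as 0 when $Q = 0$ so the
division never runs first. Studies must agree on the effect allele by
label; mismatches are an error, never silently flipped — allele
harmonization is an explicit preprocessing responsibility. SNPs reported by
a single study pass through with missing heterogeneity statistics rather
than being dropped.

```{r meta-example}
m <- fe_meta(tibble::tibble(study = c("gain", "nongain", "isc"),
                            beta = c(0.08, 0.05, 0.11),
                            se = c(0.04, 0.05, 0.06)))
glance(m)
```

## The synthetic world

No real genotype or evidence data ships with the package (the originals are
access-controlled), so `sim_config()` + `simulate_inputs()` generate every
input with controllable planted signal. The defaults state the emulated
design once:

| parameter | default | why |
|---|---|---|
| `n_genes` | 3819 | genes under the linkage peaks of the emulated study |
| `n_linkage_regions` | 26 | its autosomal linkage peaks (NPL max $\ge 2.0$) |
| `n_literature_terms` | 29 | search terms behind the literature screen ($3819 \times 29 = 110{,}751$ searches) |
| `n_literature_categories` | 5 | the five term categories listed above |
| `mean_snps_per_gene` | 22 | $\approx 3725$ tag SNPs over 167 genotyped genes |
| `frac_neurodev` | 0.03 | $\approx 115/3819$; the design does not state this fraction, so it is a free parameter |
| `n_gwas_studies` | 3 | the GAIN / nonGAIN / ISC triple used for meta-analysis |
| `effect_size`, `n_trios` | 1.3, 500 | modest planted odds ratio at a family-study scale |
| `gwas_n_genes`, `gwas_mean_snps` | 15000, 30 | genome-wide universe; negative-binomial SNP counts (size 0.8) give the long tail that makes SNP-count matching a real problem |

Planted association signal enters as a non-central 1-df chi-square:
a SNP in an associated gene gets the p-value of a
$\chi^2_1(\lambda)$ draw with
$\lambda = n_{trios}\,((OR-1)/(OR+1))^2$, the non-centrality a transmission
test would see with one heterozygous parent per trio on average. This keeps
generation fast at desk scale; full trio genotypes (`sim_trios()`, PED/MAP)
are simulated only for end-to-end smoke tests of the transmission stand-in
`tdt_standin()` — which is deliberately labelled non-equivalent to the
haplotype-aware pedigree disequilibrium test used on real pedigrees.

Evidence-strength parameters for associated genes — expression
$p \sim \mathrm{Beta}(0.3, 1)$, literature hit probability 0.4 vs. 0.05
null, probability 0.5 of a direct PPI edge to a seed — were chosen once as
"clearly enriched but not deterministic" levels and are exposed in the
config. All coordinates are 0-based half-open internally; BED is emitted
natively and 1-based positions appear only in PED/MAP and the GWAS tables
(column `pos_1based`). One seed in the config drives everything through
per-stage substreams, so identical configs give byte-identical outputs
while adding draws to one stage never perturbs another.

What the generator does **not** emulate: linkage disequilibrium between
SNPs, haplotype phase, and population stratification. A green test
therefore establishes that the pipeline's arithmetic, calibration and
recovery behave as specified on exchangeable-SNP worlds — not that the
pipeline is robust to LD-induced correlation between nearby tests.

## Numerical and display conventions

* Expected counts $n_{snps}\alpha$ are displayed rounded half away from
  zero to one decimal (3725 × 0.005 = 18.625 prints 18.6; 929 × 0.05 =
  46.45 prints 46.5); full precision is retained in the `exp_lt_*` columns.
* The genomic inflation factor divides the observed median 1-df chi-square
  statistic by `qchisq(0.5, 1)` (numerical quantile inversion, ≈ 0.4549).
* Bonferroni values are clipped at 1; BH q-values are computed by an
  explicit step-up that is oracle-tested against a double-loop
  implementation.
* SNPs inside overlapping genes count once per gene row but are
  deduplicated by snp id in union and "All" summary rows, keeping the
  per-category rows additive while avoiding double counting.

## Scales used by the test suite

The full replication scale for enrichment is 100,000 simulations; the test
suite and the acceptance script run at 2,000–10,000 so the whole suite
finishes in well under a minute on one CPU. Calibration tests use a
1,500-gene GWAS universe and the recovery test a 400-gene linkage universe
with a 500-SNP rank budget — sizes chosen for wall-clock budget only; the
planted-signal strengths (30% associated genes concentrated in the
neurodevelopment label, odds ratio 1.5, 500 trios) and all pass thresholds
are stated by the design, not tuned.

## Limitations

The literature domain consumes a precomputed hit matrix (no live queries);
tag-SNP selection, imputation, principal-component correction and the
haplotype-aware family test are out of scope and their outputs are inputs
here. Enrichment against real CATIE/GAIN universes — and therefore the
published empirical p-values — cannot be reproduced without the
access-controlled genotype data; the package reproduces the machinery and
validates it on synthetic universes instead.
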