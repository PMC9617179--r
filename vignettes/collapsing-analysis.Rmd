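---
title: "Rare-variant collapsing burden analysis with rvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rare-variant collapsing burden analysis with rvburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

## The problem

Severely affected patients — the motivating setting is critically ill
children whose exomes did not yield a diagnosis — may carry rare
loss-of-function (LOF) risk variants in genes not yet associated with any
disease. Single-gene association tests are underpowered at cohort sizes of a
few hundred cases, so the analysis *collapses* variants: every variant
passing a qualifying-variant (QV) model is treated as equivalent, an
individual "carries" a gene if it has at least one QV there, and carrier
proportions are compared between cases and controls over genes and gene
sets. rvburden implements this workflow end to end:

1. **QV models** (`qv_model()`): ultrarare LOF (absent from external
   reference datasets), flex LOF (external minor allele frequency < 0.1%),
   and an ultrarare synonymous model used as a negative control.
2. **Ancestry stratification** (`project_principal_components()`,
   `louvain_cluster()`): cases and controls are grouped into ancestry
   clusters, and every association test is stratified on those clusters.
3. **Exact stratified tests** (`cmh_exact_test()`, `fisher_exact_test()`,
   `mh_pooled_odds_ratio()`).
4. **An intolerance-threshold scan** (`loeuf_scan()`): nested gene sets
   defined by LOEUF thresholds, permutation empirical p-values, Bonferroni
   significance, and the optimal threshold.
5. **Gene-set burden batteries** (`run_burden_battery()`) under FDR control,
   and case-only candidate listing.
6. **Trio de novo enrichment** (`denovo_battery()`): one-sided Poisson tests
   of observed against expected de novo counts per consequence class.
7. **A synthetic cohort generator** (`sim_config()`, `simulate_cohort()`)
   that emulates the stratified case-control structure the methods assume,
   with ground truth for calibration and recovery studies.

## The statistical model

### Collapsing and stratified testing

For each ancestry cluster $k$ the data for a gene (or gene set) reduce to a
2×2 table: $a_k$ case carriers, $b_k$ case non-carriers, $c_k$ control
carriers, $d_k$ control non-carriers. The pooled effect is the
Mantel–Haenszel common odds ratio

$$\widehat{OR}_{MH} = \frac{\sum_k a_k d_k / n_k}{\sum_k b_k c_k / n_k},$$

with a 95% Wald interval on the log scale using the
Robins–Breslow–Greenland variance. The test of $OR = 1$ is exact and
conditional: given all margins, each $a_k$ follows a central hypergeometric
distribution, and the statistic $S = \sum_k a_k$ has the convolution of
those distributions as its null law. `cmh_exact_test()` builds that
convolution by dynamic programming, so the p-value is exact at any stratum
count, with no continuity corrections and no Monte-Carlo step. Strata with a
zero margin (no cases, no controls, no carriers, or all carriers) carry no
information about the odds ratio and are dropped from both estimation and
testing.

**Two-sided conventions.** Exact tests on discrete data admit several
two-sided conventions. The default doubles the smaller tail of $S$ and caps
at 1; `convention = "point"` instead sums the probabilities of all outcomes
no more likely than the observed one, which is what
`stats::mantelhaen.test(exact = TRUE)` and `stats::fisher.test()` compute.
Both are available because published analyses rarely state which was used;
the doubled-tail form is the default here and the test suite pins the exact
relationship between the two (they agree within a factor of two). The
single-table `fisher_exact_test()` follows the point-probability convention,
reports the sample odds ratio $ad/bc$ (zero cells flagged as 0/infinite),
and a Wald interval.

### The intolerance-threshold scan

Genes harbouring at least one QV are ordered by LOEUF (the LOF
observed/expected upper bound fraction; lower = less tolerant of LOF
variation), and one cumulative gene set is formed per unique score: the set
at threshold $t$ holds every QV-harbouring gene with LOEUF $\le t$. Each set
is collapsed and tested with the exact CMH test; significance across the
scan uses a Bonferroni correction over the number of unique thresholds.
Published LOEUF scores carry three decimals, which is why thousands of genes
share on the order of a couple thousand unique scores; the generator rounds
its simulated scores the same way.

Empirical p-values come from label permutations *within clusters*: each
permutation reassigns case labels inside every cluster, preserving each
cluster's case count, and the whole nominal p-vector is recomputed, so the
scan's dependence structure is preserved. The estimator is
$(r + 1)/(n + 1)$, where $r$ counts permutations at least as extreme;
`estimator = "plain"` gives $r/n$, which can reach zero when the observed
statistic is unbeaten — useful when the permutation count is small relative
to the Bonferroni cut, since $(r+1)/(n+1)$ is floored at $1/(n+1)$ and can
then never clear it.

**A key implementation fact.** Within-cluster permutation fixes every
margin: per-cluster case totals and per-cluster carrier counts at every
threshold. The exact null distribution of $S(t)$ is therefore
permutation-invariant, so it is computed once per threshold and the exact
p-value of each permutation is a table lookup; carrier status per threshold
is maintained incrementally (an individual flips to carrier at the first
threshold admitting a gene it carries). One permutation of a
2000-gene/3000-individual scan costs microseconds, and the "use an
asymptotic statistic inside the permutation loop" compromise found in some
pipelines is unnecessary — the exact test runs everywhere.

**The optimum and its ties.** The reported optimum minimises the empirical
p-value. A finite permutation count floors the empirical p, so a strong
signal ties a band of thresholds at the floor; ties are resolved by the
nominal exact p (which discriminates arbitrarily finely) and only then
toward the smaller, more intolerant threshold. Without this the optimum of
any strongly-signalled scan would degenerate to the left edge of the tied
band. A permutation scan that reports its minimum at exactly the empirical
floor — the typical published pattern — has necessarily made the same
choice.

### Negative control and inflation

The ultrarare synonymous model provides a negative control: synonymous
variants are assumed phenotypically neutral, so their per-gene association
p-values should be uniform if ancestry stratification is adequate. The
summary is the genomic inflation factor
$\lambda = \mathrm{median}(\chi^2_{obs}) / 0.4549$, computed from the
asymptotic (continuity-correction-free) CMH chi-square per gene: $\lambda$
compares the observed p-value distribution to the $\chi^2_1$ reference, and
the asymptotic statistic is the one with that reference distribution. Exact
p-values on sparse genes are heavily discrete and would deflate $\lambda$
artificially. The pipeline warns when $\lambda > 1.2$.

### De novo enrichment

For trios, the expected number of de novo variants of class $c$ in a gene
universe $G$ is $2 N_{trios} \sum_{g \in G} \mu_{g,c}$, where $\mu$ is the
per-gene per-chromosome per-generation mutation probability (set
`copies = 1` for rate tables already expressed per individual). Observed
counts are tested one-sided against the Poisson upper tail,
$p = P(X \ge \mathrm{obs})$, enrichment = observed/expected — the direction
of interest is excess, matching standard de novo enrichment tools.
Composite classes (missense+LOF, all) sum their component expectations and
counts.

## The synthetic cohort generator

`sim_config()` defaults describe the emulated study design; they are the
generator's definition of "realistic", chosen once:

| parameter | default | rationale |
|---|---|---|
| `n_cases` / `n_controls` | 231 / 5322 | post-QC scale of a realistic single-centre paediatric case cohort against biobank-style controls |
| `n_clusters`, mixtures | 3; cases (0.25, 0.35, 0.40), controls (0.45, 0.35, 0.20) | a few major ancestry clusters; deliberately *different* case and control mixtures so confounding by ancestry is present and stratification is load-bearing |
| `baseline_carrier_rate` | (4, 5, 6) ×10⁻⁴ | per-gene rare-LOF carrier probability of a few per ten thousand, distinct per cluster (different background variation rates); gives whole-intolerant-set carrier fractions of ~25% |
| `syn_carrier_multiplier` | 50 | rare synonymous variants are tens of times more abundant per gene than rare LOF variants; gives per-gene synonymous carrier rates of a few percent, enough for a meaningful $\lambda$ |
| `loeuf_range` | (0.03, 2.0), 3 dp | span of published LOEUF scores, rounded as published |
| `disease_flag_prob` | 0.25 | roughly a quarter of genes carry a known disease association |
| `enrichment_or` / `enrichment_loeuf_max` | 2.0 / 0.68 | case carrier odds doubled, confined to the intolerant tertile |
| `ultrarare_fraction` | 0.6 | the majority of rare QVs are absent from external references |
| `n_trios` / `mu_mean` | 114 / (7.4, 16, 2.2) ×10⁻⁶ | per-gene class mutation rates whose genome-scale sums reproduce expected de novo counts of the published order (e.g. ~7 LOF expected from 114 trios over ~13k genes) |

Carrier status is simulated directly at the gene level — a Bernoulli
indicator per gene per individual — because every downstream computation
consumes the 0/1 collapsed state. Enrichment acts on the odds scale, so the
configured value is directly comparable to estimated odds ratios. A
variant-level emitter (`cohort_to_variants()`, `write_cohort()`) produces
one synthetic site per carried gene (VCF plus annotation table) for I/O
round-trip testing. Common-variant dosages with Balding–Nichols-style
cluster divergence (`simulate_pca_dosage()`) feed the clustering stage.

**What the generator does not emulate:** linkage disequilibrium, realistic
site-frequency spectra, relatedness, sequencing error, variant-level QC.
Passing calibration and recovery tests therefore demonstrates the
statistical machinery is correct under the assumed sampling model, not that
real-exome artefacts are handled; on real data the synonymous control and
$\lambda$ are the intended guards.

## Clustering choices

The graph for Louvain community detection is a symmetric unweighted
k-nearest-neighbour graph (k = 20 by default) over the first 6 principal
components — standard practice when the clustering input is a PC embedding.
Louvain's vertex ordering is randomised, so a seed fixes the partition;
cluster labels are stable (numbered by decreasing size). The predefined
common-variant list a real study would use for PCA is, in simulations,
replaced by the generator's common-variant panel; real-data users supply
their own dosage matrix. Clusters failing per-cluster case/control minima
are dropped before testing (`filter_clusters()`), since a stratum without
both phenotypes carries no information.

## Numerical and design notes

- Frequency bounds are strict (`af < bound`), and "absent from external
  datasets" means the presence flag is false regardless of any recorded
  frequency; internal-frequency filters apply to the combined cohort before
  collapsing.
- The convolution of hypergeometric pmfs is renormalised after each FFT
  step; p-value comparisons in the permutation loop use a 1e-12 slack so
  ties are counted as ties.
- Degenerate strata in the scan contribute a constant to $S$ (e.g. a
  cluster where everyone carries); the constant is permutation-invariant
  and handled by shifting the lookup support.
- `bonferroni_alpha(alpha, m)` with the scan's unique-threshold count
  reproduces the usual published cutoffs (e.g. 0.05/1860 = 2.7×10⁻⁵ at two
  significant figures).
- All generator and analysis randomness flows from one integer seed through
  named substreams, so whole-pipeline runs are byte-reproducible
  (`run_pipeline()` writes the seed into every output header).

## Problem sizes used in the shipped studies

The package's own calibration and recovery studies (in `tests/testthat/`
and `scripts/acceptance.R`) run at deliberately desk-scale sizes, chosen as
the smallest designs at which the properties under test are identifiable:
threshold-recovery at 300 cases / 3000 controls / 2000 genes / 1000
permutations over 50 replicates; null calibration at 150/1500 with 400–600
genes, 500 permutations, 100 replicates; battery calibration at 150/1500
over 100 replicate batteries; and a full-enumeration equivalence proof of
the single-stratum exact CMH against doubled-tail Fisher over every 2×2
table with total ≤ 30. Real analyses would raise the permutation count (the
empirical-p floor is $1/(n+1)$, so resolving a Bonferroni cut near 3×10⁻⁵
needs on the order of 10⁵ permutations) and use the full gene panel.

## Known limitations

- The exact CMH conditions on margins; with very sparse strata its
  discreteness makes all reported p-values conservative (the calibration
  tests quantify this). Mid-p variants and conditional maximum-likelihood
  odds-ratio estimation are not implemented.
- Empirical p-values inherit the same conservatism: permutation ties are
  counted as hits, so under the null the empirical p is super-uniform
  rather than exactly uniform on discrete data.
- The scan's optimum is a point estimate whose localisation is limited by
  sample size and effect size; at the recovery-study scale the median
  |optimum − truth| is a few hundredths of a LOEUF unit, with occasional
  larger excursions. No confidence interval for the optimum is provided.
- Gene identity is by symbol; no alias resolution. Consequence annotation,
  variant QC, and de novo *calling* are out of scope — all are inputs.
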