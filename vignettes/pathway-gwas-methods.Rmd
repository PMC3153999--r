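---
title: "Pathway-based GWAS: model, permutation significance, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pathway-based GWAS: model, permutation significance, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathgwas)
```

## The question the method answers

Single-marker genome-wide association scans rank hundreds of thousands of
SNPs by their marginal association with a trait and then interpret the few
top hits. Many complex traits, however, are driven by modest effects spread
across functionally related genes, none of which clears a genome-wide
threshold on its own. Pathway-based GWAS asks a different question: are the
genes of a predefined set (a pathway) collectively over-represented near
the top of the genome-wide gene ranking? `pathgwas` implements this
analysis for quantitative traits end to end, together with a synthetic
cohort generator used to calibrate and power-test the chain.

## The statistic

**Gene statistics.** After SNP-level quality control, each SNP is tested
for additive association with the covariate-adjusted trait by simple OLS
(`t = beta/se`, the Wald statistic, `n - 2` df). Each SNP is mapped to the
gene it falls in (both genes when it falls in a shared region of
overlapping genes) or to its closest gene within 500 kb; each gene
$G_i$ with $x_i$ mapped SNPs is represented by
$r_i = \max_j |t_j|$, the strongest of its SNPs. The absolute value is
deliberate: for a two-sided test the sign of $t$ encodes which allele is
trait-increasing, not association strength.

**Enrichment score.** Genes are ranked $r_{(1)} \ge \dots \ge r_{(N)}$
(ties broken by gene id so ranking is deterministic). For a set $S$ with
$N_S$ genes, walking down the list the running sum gains
$r_{(i)}^p / N_R$ at members, with $N_R = \sum_{g \in S} r_g^p$, and loses
$1/(N - N_S)$ at non-members. The weight exponent $p$ defaults to 1,
emphasizing genes with extreme statistics ($p = 0$ recovers the classical
Kolmogorov–Smirnov statistic). Increments and decrements each total 1, so
the walk ends exactly at 0 and the enrichment score
$ES(S) = \max_i \text{(running sum)}$ — the maximum positive deviation —
lies in $[0, 1]$. The *leading edge* is the members ranked at or before
the peak: the genes that actually carry the signal. The positive maximum
(rather than the maximum absolute deviation) is used because the statistic
scans for over-representation at the *top* of the ranking; a signed
variant is easy to derive from the returned running-sum trace.

**Permutation null, NES, FDR, FWER.** Significance comes from
permutations in one of two modes:

* `phenotype` — adjusted trait residuals are shuffled across subjects and
  the entire chain (per-SNP scan, gene reduction, ranking, ES) is
  recomputed. This preserves the gene-size and LD structure of the data
  and is the default for unrelated-subject cohorts.
* `statistic` — the observed vector of gene statistics is reassigned to
  gene labels. This is the valid choice when phenotypes are not
  exchangeable, e.g. family cohorts whose per-SNP statistics come from a
  family-based test and are ingested via `load_external_stats()`.

Per set, the nominal p value is the fraction of permutations with null ES
strictly greater than the observed ES (reported as `< 1/n_perm` when no
permutation exceeds it). To compare sets of different sizes, each ES is
standardized by its own set's null mean and SD into a normalized
enrichment score (NES); permuted scores are standardized the same way,
giving a sets × permutations NES matrix. Then

* FDR q of a set = (fraction of all permuted NES values ≥ its NES) /
  (fraction of observed sets with NES ≥ it), clipped to $[0,1]$;
* FWER p of a set = fraction of permutations whose *maximum* NES across
  sets exceeds its NES;
* a set is called significant only when **both** q ≤ 0.05 and FWER p
  ≤ 0.05.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| call rate | ≥ 0.95 | per-SNP fraction of non-missing calls |
| HWE p | ≥ 0.001 | Pearson chi-square (1 df); mid-p exact test optional |
| MAF | ≥ 0.05 | minor allele frequency on non-missing calls |
| gene distance | ≤ 500,000 bp | strict: a SNP 500,001 bp from every gene is dropped |
| mapping window | 500,000 bp | same convention as the QC distance filter |
| covariate alpha | 0.05 | marginal retention threshold in the full model |
| weight exponent `p` | 1 | 0 = unweighted KS |
| `n_perm` | 1000 | 10,000 is advisable for `statistic` mode, whose per-permutation cost is tiny |
| `alpha_fdr`, `alpha_fwer` | 0.05 | joint significance criteria |

## Numerical and design choices

* **Distance convention.** Distances are base-pair offsets from the
  nearest gene *boundary*: 0 inside a gene, 1 immediately adjacent. The
  500-kb filter is strictly greater-than. Transcription start sites are
  not used; strand is ignored.
* **Sequential QC attribution.** Filters run in the order call rate →
  HWE → MAF → distance, and each SNP counts against the first filter it
  fails, which is how marker-attrition narratives are conventionally
  reported. `apply_qc()` is idempotent.
* **Tie SNPs outside genes.** A SNP exactly equidistant from two
  non-overlapping genes maps to both — a conservative extension of the
  overlapping-gene rule.
* **Covariate selection** is single-pass: one full model containing all
  candidates; terms with coefficient p ≤ α are kept, and a retained
  interaction pulls in its main effects. The adjustment model is then
  *refit* on the retained terms before residuals are taken. Stepwise
  procedures would change little here and are harder to reason about.
* **Normality check.** The Lilliefors test — Kolmogorov–Smirnov against
  the fitted normal with a null distribution calibrated for estimated
  parameters — so that its p values are uniform when the adjusted trait
  really is Gaussian. A plain `ks.test()` against the fitted normal is
  anticonservative about normality in this situation because estimating
  the mean and SD shrinks the statistic. `shapiro.test()` is available
  behind a flag. Non-normality is a warning, not an error.
* **Degenerate fits.** SNPs monomorphic in sample (centered dosage sum of
  squares below `1e-12`) or with fewer than 3 complete cases are flagged
  `NA` and excluded from gene reduction; numerically perfect fits are
  reported with a capped statistic and p = 0 rather than `Inf`.
* **Null SD convention.** Population SD (divide by the number of
  permutations). With ≥ 200 permutations the difference from the sample
  convention is far below Monte-Carlo noise, but the choice is pinned by
  tests.
* **Strictness of counts.** Nominal p and FWER use strict `>`; the two
  FDR fractions use `≥`. FDR q is clipped to $[0, 1]$ and *not*
  monotonized along the NES ranking.
* **FWER reading.** "Fraction of permutations whose greatest NES exceeds
  the observed" is computed as max-across-sets per permutation (the
  standard max-statistic null), not per-set-then-max.
* **Permutations are pooled jointly.** One shuffle per iteration is
  shared by every set, so overlap between sets propagates into the null
  NES matrix exactly as it does in the observed data — required for the
  FDR/FWER pooling to be coherent. In `statistic` mode the shuffle is
  implemented as one random gene→rank bijection per iteration, which is
  equivalent to permuting the statistic vector and re-ranking whenever the
  statistics are distinct (almost surely, for continuous statistics).
* **Covariate adjustment is not redone inside phenotype permutations**:
  residuals are exchangeable under the null of no genotype effect, and
  re-selecting covariates 1000 times would multiply cost for no change in
  the null distribution of ES.
* **Reproducibility.** Every stochastic function takes a `seed`;
  permutations consume one seeded stream in a fixed order, so results are
  bit-reproducible (the phenotype-mode permutation loop processes blocks
  of 128 shuffles per matrix product, but draws the shuffles in the same
  order regardless of block size).

## The synthetic cohort generator

`simulate_cohort()` produces the structure the analysis assumes, with a
known truth record for scoring:

* genotypes at each SNP are Binomial(2, MAF) draws — Hardy–Weinberg by
  construction — independent across SNPs (linkage equilibrium); an
  optional first-order LD knob copies the previous SNP's genotype with
  probability ρ and defaults off, since the method does not model LD;
* MAF is drawn from (0.10, 0.50) by default: the common-variant band that
  survives a 5% MAF filter, matching the published leading-edge SNP MAFs
  (0.08–0.39) in the bundled reference tables;
* genes are laid at fixed spacing (20 kb genes, 50 kb gaps, 250 genes per
  chromosome, 1-based inclusive coordinates), so all SNPs fall inside
  genes and mapping is unambiguous;
* the trait is a BMD-like quantity: intercept 0.5, linear age/sex/weight
  effects, per-gene additive genetic effects, and Gaussian noise with SD
  0.05 (units of g/cm²-scale traits); covariates are age ~ U(20, 80),
  sex ~ Bernoulli(0.5), and sex-shifted Gaussian height and weight;
* one SNP per causal gene carries the genetic effect, with its
  coefficient sized so the gene explains `per_gene_h2` of the
  covariate-adjusted trait variance (the gene reduction is best-SNP, so
  per-gene effects are the natural unit);
* gene sets are overlapping draws from the gene universe, sizes 10–50 on
  the default 1000-gene universe — the same fraction of the universe as
  the conventional 10–200 set-size band on a genome-scale list; the
  causal set is one of them, recorded in `truth`;
* missingness (default 2%, in line with array-era call rates) is applied
  after trait construction, as measurement loss, not biology.

What the generator does **not** emulate: linkage disequilibrium blocks
and their correlated gene statistics, population stratification, related
subjects, genotyping batch artifacts, non-Gaussian trait tails, and
MAF-dependent effect sizes. Passing calibration on synthetic cohorts
therefore demonstrates that the statistics are implemented correctly and
calibrated under the model's own assumptions — not that real cohorts are
free of confounding, which must be handled upstream (e.g. stratification
checks before the scan).

## Calibration and power settings used by the test suite

The package's own checks run at sizes chosen to make Monte-Carlo error
small while keeping a laptop-scale runtime: null calibration uses 100
complete-null cohorts of 300 subjects × 2000 SNPs (1000 genes × 2 SNPs),
50 pathways, 200 permutations each, requiring the any-set FWER rejection
rate to stay within binomial noise of its nominal level; power uses 50
cohorts of 1000 subjects with a planted causal pathway at
`per_gene_h2 = 0.01` — sized so causal best-SNP p values land in the
1e-3 to 1e-2 band of the bundled reference tables (expected
$t^2 \approx 1 + n h^2/(1 - h^2) \approx 11$ at $n = 1000$) — requiring
the causal set to top the NES ranking in at least 80% of replicates.
`scripts/acceptance.R` re-runs the same machinery from scratch at a
reduced replicate count and writes the resulting rates as JSON.

## Known limitations

* Only quantitative traits and additive coding; no binary traits, no
  covariates inside the per-SNP model (adjustment is a single upstream
  stage), no genomic-control correction.
* `statistic` mode treats gene statistics as exchangeable across genes;
  with strong LD between neighboring genes this understates dependence.
* FWER discreteness: with B permutations the smallest achievable p is
  1/B, and the rejection probability at threshold 0.05 is
  (⌊0.05B⌋+1)/(B+1), slightly above 0.05 at B = 200.
* The FDR q is a plug-in ratio estimator; it is not monotone in NES and
  can exceed a smaller set's q at a larger NES.
* With few sets the FDR denominator is coarse (steps of 1/n_sets).

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_subjects = 500, n_genes = 1000, n_pathways = 50,
                  causal_set_index = 7, per_gene_h2 = 0.015, seed = 1)
bundle <- run_pipeline(run_config(simulate = cfg, n_perm = 1000, seed = 1,
                                  outdir = "run1"))
report_top_table(bundle$results, 5)
bundle$cohort$truth$causal_set  # which set was planted
```
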