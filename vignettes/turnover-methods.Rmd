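---
title: "Methods: sex-bias turnover analysis on a fixed four-species phylogeny"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-bias turnover analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sbturnover)
```

## Scope and model

`sbturnover` analyses the evolution of sex-biased gonadal expression across
exactly four species on the rooted topology `(((Dmel,Dsim),Dyak),Dana)`,
with terminal-branch divergence ages of 5, 5, 13 and 44 My. The topology
and ages are a fixed analysis context (`phylo_context()`), not estimated:
every classification below is parsimony on this shape, and the package
deliberately rejects other species counts rather than generalising — the
statistics are only well defined with one outgroup and a three-species
ingroup.

The analysis proceeds in stages: per-species sex-bias calls, four-species
profile classification, standardized transition rates, fold-bias magnitude
across conservation tiers, and the two annotation-level contrasts
(expression breadth, branch dN/dS).

## Sex-bias calling

A gene is testis-biased in a species when its testis FPKM is at least
twice its ovary FPKM, the differential-expression p-value is below 0.05,
and the larger FPKM exceeds 1; symmetric for ovary bias; otherwise
unbiased. All three thresholds are arguments (`fold_cutoff`, `p_cutoff`,
`fpkm_floor`) with those defaults; a fold of exactly 2 counts as biased,
and genes expressed nowhere are unbiased. Status is driven by uncorrected
p-values; `bonferroni_sensitivity()` reports how many biased calls would
survive correction, as a sensitivity check rather than a mode of the main
analysis, and `classify_sex_bias(bonferroni = TRUE)` switches the rule
itself for users who want the stricter calls.

The test is a two-sided exact binomial on the raw testis count against the
gene's total gonadal count. The null proportion comes from median
normalization: each sample's median of positive counts is a depth proxy,
and the null expects reads to split in proportion to depth,
`p0 = m_t / (m_t + m_o)`. The two-sided p-value is the doubled smaller
tail, clamped at one; at equal depths this provably coincides with the
minimum-likelihood two-sided construction, and the tests verify both that
identity and agreement with exhaustive enumeration at small counts. The
reference median for the normalization factors themselves is the geometric
mean of the two sample medians — a symmetric choice; only the *ratio* of
depths enters the test, so the reference convention has no downstream
effect.

Two deliberate simplifications: one library per gonad per species is
assumed (replicates are pooled by summing, with a warning, because the
binomial test then ignores biological variance), and the two-fold rule is
applied to FPKM, not normalized counts, consistent with the FPKM floor
being an FPKM quantity. Sex-specific calls additionally require *exactly*
zero FPKM — i.e. zero mapped reads — in the opposite gonad;
`concordance_check()` scores such calls against any independent expression
table.

## Profile classes and the standardized transition rate

A gene's ordered status 4-vector falls into exactly one of four classes:
clade-wide (one status), LST (three equal, one deviant terminal branch —
the shared status is the ancestral state under parsimony), and two
multiple-transition classes (2+2 and three-state) where no ancestral state
is inferable and none is assigned. The 2+2 class records the species
bipartition, since paraphyletic and monophyletic arrangements are worth
distinguishing downstream. Deviation on the outgroup branch is exactly
equivalent to conservation across the three-species ingroup (TSI); these
outgroup LSTs are flagged with a caveat — the change may really be a
reversal on the short internal branch — but retained, because the status
is lineage-specific under either reading.

For branch $b$ and transition category $x \to y$:

$$\mathrm{S\text{-}LST}_{x\to y, b} =
  \frac{N_{x\to y, b}}{N_{\mathrm{cladewide}\,x} + N_{x\to y, b} +
        N_{x\to z, b}} \times 1000$$

where $z$ is the alternate derived state. The denominator approximates the
pool of genes that held the ancestral state when branch $b$ diverged,
making the six categories comparable; the factor 1000 is cosmetic. A zero
denominator yields a missing value, never zero. Category pairs are
contrasted within a branch by a 2×2 Pearson chi-squared test (no
continuity correction by default — the design has large counts; a
`correct` flag exists), and reported ratios are computed from unrounded
rates, then rounded to two decimals, because ratios of pre-rounded rates
do not reproduce consistently.

## Fold-bias across conservation tiers

Fold-bias is the ratio of the higher to the lower gonad FPKM; it is
infinite for sex-specific genes and is kept so — rank-based tests need
order, not magnitude, and placing sex-specific genes above all finite
folds is the only ordering consistent with their definition. Fold classes
use half-open bins $[2,5)$, $[5,10)$, $[10,\infty]$; the boundary
convention at 5 and 10 is genuinely ambiguous in common usage, so it is
documented here and configurable via `breaks`.

Conservation tiers order biased calls by the minimum time the status has
been held: `lst` (a gain in one terminal branch), `tsi` (ingroup-conserved,
13 My), `clade_wide` (44 My). Only *gains from the unbiased state* count as
the `lst` tier — a reversal's derived state has held for the same time but
is a different phenomenon, and mixing them would blur the age contrast.
Tests are Mann-Whitney for pairs and Kruskal-Wallis plus Dunn's post hoc
for the three-tier comparison; Dunn p-values are unadjusted by default
(with a Bonferroni flag), and "ranked ANOVA" throughout this package means
Kruskal-Wallis, which is what Dunn's test post-hocs.

## Breadth and divergence contrasts

Expression breadth is the percentage of 17 reference tissues/stages with
expression above a presence threshold, default 0 (any expression), with
FPKM ≥ 1 as the stricter sensitivity setting. Breadth is computed in the
reference species only and keyed by reference gene id — cross-species
breadth would conflate pleiotropy with ortholog annotation quality. The
identity of the 17 tissues is not material to the statistics; synthetic
data names them `T01..T17`.

Branch dN/dS values pass a saturation filter — dN < 1.5, dS < 1.5 and
dS > 0.001, all strict — applied per (gene, branch), so a gene can
legitimately enter one branch's contrast and not another's. The
single-ratio proxy `mean(dN)/mean(dS)` across passing branches mimics a
one-omega-per-tree model fit and is the quantity cross-checked against
gene-level ground truth in simulations. Likelihood-ratio tests of external
codon-model fits are consumed as log-likelihood pairs:
`2(lnL_alt - lnL_null)` against the upper chi-squared tail, with small
negative statistics (optimizer noise, tolerance 1e-6) clamped to zero.
Running the codon models themselves is out of scope; the package parses
free-ratio main-result text (`parse_freeratio_output()`) or a plain TSV.
The shipped example file is synthetic and labelled as such.

## The synthetic-data generator

The generator exists so that every downstream stage has data with known
truth. Its defaults are the study conditions the package targets:

* clade-wide status proportions 0.192 / 0.183 / 0.128 (testis / ovary /
  unbiased) at 10,740 genes;
* per-branch, per-category transition probabilities equal to the
  standardized rates of the four-species design divided by 1,000;
* a single deep library (45 million mapped reads) per gonad, with
  negative-binomial count noise at dispersion 0.1 around planted FPKM;
* breadth group means 96.02 / 70.72 / 65.71 / 43.1 percent for clade-wide
  ovary-biased / unbiased / testis-biased / testis-specific genes, and the
  six reference-branch LST category means spanning 61.3–98.7 percent;
* fold-bias medians rising with conservation tier — 3 / 6 / 12 for
  testis-biased genes and 2.5 / 5 / 10 for ovary-biased genes (lst / tsi /
  clade-wide). These medians are not published quantities; they were fixed
  once as values a fly transcriptomicist would call realistic for gonadal
  fold-bias distributions, with the testis medians above the ovary medians
  and a log-scale spread of 0.5;
* gene-level dN/dS centred per category (testis 0.25 > unbiased 0.15 >
  ovary 0.10; specificity tiers 0.25 < 0.32 < 0.45; a mild log-fold
  multiplier links magnitude to omega), likewise fixed once to mirror the
  qualitative ordering the analysis is meant to detect, not to match any
  printed number.

The sampling scheme makes the standardized rate an *unbiased* estimator of
the planted transition probability: each gene draws an ancestral state,
then transitions independently in each branch with the configured
probabilities. For any branch and category, the genes entering the
denominator are exactly those with no transition elsewhere, and within
that pool the transition fraction has the planted expectation — so
`E[S-LST]/1000` equals the configured rate with no correction factor. The
ancestral-state frequencies are derived by inverting the no-transition
product so expected clade-wide proportions hit their targets exactly;
residual probability mass becomes explicit multiple-transition profiles
drawn from a realistic subtype mix (unbiased/ovary and testis/unbiased 2+2
patterns common, testis/ovary rare, about a quarter three-state).

What the generator does *not* emulate: read-level data, sequence
evolution (rates are drawn, not simulated from codons), correlated
expression across genes, batch effects, or biological replicates.
Consequently, passing recovery tests demonstrates the estimators and the
pipeline plumbing are correct under the assumed noise model — they do not
validate the calling rule against real library preparation artefacts.

One measured property of the default noise level deserves emphasis: with
negative-binomial dispersion 0.1 on single libraries, a truly unbiased
gene has roughly a one-in-seven chance of showing a two-fold count ratio,
and the deep-count binomial test will then declare it significant. Status
recovery is therefore excellent for genes with planted fold ≥ 4 (≥ 95%,
verified in the tests) but near-threshold calls are intrinsically
unstable. For this reason the proportion- and rate-recovery checks (3
Monte-Carlo standard errors at 10,000 genes) run the classification
pipeline on the planted statuses — isolating the sampling error of the
generator and the estimator, which is what those tolerances describe —
while the count-level path is held to the fold ≥ 4 accuracy bound and the
fold-ordering detection rate, which are the properties it can and should
meet. This split is a property of threshold classification under
overdispersed counts, not of this implementation.

## Numerical choices and degenerate inputs

* TSV interchange with 6-significant-digit reals; gzip transparent.
* Sample clustering uses `1 - Spearman R` dissimilarity with average
  linkage; columns are sorted lexicographically first so tie-breaking is
  deterministic and gene order is irrelevant. Constant columns are an
  error naming the sample.
* Spearman p-values: exact permutation for n ≤ 10 without ties, t
  approximation otherwise.
* Zero total count in the DE test returns p = 1 (no evidence); an
  all-zero gonad library falls back to equal null depths, so a dead
  dataset classifies as all-unbiased rather than erroring.
* Chi-squared contrasts warn (but still report) when an expected cell is
  below 1.
* The S-LST of an empty ancestral pool is missing, not zero; ratios with
  a zero divisor are missing.
* Problem sizes in the tests — 10,000 genes for recovery checks, 4,000 ×
  100 seeds for the fold-ordering detection rate, 600 × 20 seeds for
  clustering structure — were chosen so each check's Monte-Carlo error is
  small relative to its tolerance while the full suite stays fast to run.

## Known limitations

* The binomial DE construction models technical (counting) noise only;
  with one library per gonad there is no estimate of biological variance,
  and the package intentionally does not offer a negative-binomial GLM
  path — use replicate-aware tools if replicates exist.
* Parsimony classification on four taxa cannot distinguish a change on
  the outgroup branch from a reversal on the internal branch; the caveat
  flag is the honest representation of that limit.
* Breadth as a pleiotropy proxy inherits the usual caveat that presence
  / absence at a threshold compresses expression structure.
* The fixed topology is an assumption, not an inference; applying the
  package to taxa where the tree is uncertain would require upstream work
  it does not provide.
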