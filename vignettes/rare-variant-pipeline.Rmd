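---
title: "Methods: rare-variant burden and trend testing in rvburden"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rare-variant burden and trend testing in rvburden}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvburden)
```

This vignette is the package's own account of the statistical methods
it implements, the conventions it freezes where the field leaves a
choice open, and what its synthetic-data tests do and do not establish
about real data.

## The setting

The intended input is a targeted case–control sequencing panel: a few
hundred candidate genes sequenced in cases with a rare disease and in
population controls, jointly genotyped and annotated upstream. All
analyses operate on a `cohort_dataset`: an aligned matrix of alt-allele
dosages (0/1/2, missing allowed), a sample table with case/control
phenotypes, variant records carrying site-level quality metrics, and a
per-variant annotation table (gene, consequence class, PolyPhen2/SIFT
calls, external MAF, ClinVar flag). Genotype phase is ignored
throughout because every downstream statistic is dosage- or
carrier-based. Multiallelic records are refused by the VCF reader
rather than silently dropped; splitting is an upstream responsibility.

## Quality control

**Hard filters.** Per-variant-type thresholds follow standard
short-variant practice: SNVs require QD > 2, SOR < 3, MQ > 40, FS < 60,
MQRankSum > −12.5 and ReadPosRankSum > −6; indels require QD > 2,
SOR < 10, FS < 200 and ReadPosRankSum > −10; all sites require
QUAL > 50, and genotypes with GQ ≤ 20 are set missing. A missing site
metric *passes* the corresponding rule (rank-sum metrics are undefined
at sites without heterozygotes); such sites are flagged in the report
rather than removed.

**Site filters** apply in a fixed, recorded order: autosomes only;
missingness ≤ 5%; Hardy–Weinberg exact p > 10⁻⁶ *in controls*; depth
≥ 10× in ≥ 95% of samples; site mean depth ≤ 2× the cohort mean. A
site is attributed to the first rule that removes it, so alternative
orderings can be compared from the per-rule attrition counts.

**HWE exact test.** `hwe_exact_p()` computes the exact conditional
distribution of the heterozygote count given the allele counts using
the stable mode-outward recurrence, and sums the probabilities of all
outcomes no more probable than the observed one (two-sided). Ties in
the probability comparison use a relative tolerance of 1 + 10⁻⁹; the
test agrees with direct log-factorial enumeration to below 10⁻¹² over
randomized tables with up to 200 alleles.

**Relatedness.** The unadjusted pairwise statistic
`A_jk = mean_i (x_ij − 2p_i)(x_ik − 2p_i) / (2 p_i (1 − p_i))` is ≈ 0
for unrelated pairs and ≈ 1 for duplicates; pairs above 0.3 are
flagged and the member with higher missingness (ties: lexicographically
larger id) is marked for removal. On a *rare-variant-only* panel the
per-site terms have enormous variance (a shared rare allele contributes
≈ 1/(2p)), so the estimator must be computed on the common sites:
`relatedness_ajk()` exposes a `maf_min` floor and the pipeline uses
0.01, skipping the stage with a logged note when fewer than 100
informative sites exist. This is a deliberate design choice: with ~2
thousand sites at MAF ≥ 0.01 the null standard deviation of A_jk is
≈ 0.02 and the 0.3 threshold is conservative; with a few dozen sites
the stage would flag noise.

**Ultra-rare balance.** For each allele-count class c ∈ {1, 2, 3} the
case-borne copies pooled across variants are tested against
Binomial(total copies, case chromosome fraction) with the exact
two-sided p (sum of outcomes no more probable than observed). A strong
control excess of singletons is the signature of technically
heterogeneous case/control call sets; the pipeline therefore removes
singletons — variants with combined-cohort allele count exactly 1 —
before any association testing. We read "appeared exactly once in
cases and controls" as *once in the union*; the per-group alternative
is available via `exclude_singletons(per_group = TRUE)`.

## Single-variant scan

Each variant with combined-cohort MAF strictly below 0.01 is tested
with a one-sided Fisher exact test (upper-tail hypergeometric, no
mid-p) on allele-count tables: each called individual contributes two
chromosomes, and the tested direction is enrichment in cases. Allele
counting (rather than carrier counting) is the convention for
single-variant rare scans; carrier-based testing remains available
through `cast_test()`. MAF for eligibility is computed on the combined
cohort — the conventional choice for variable-threshold and mask-based
rare-variant methods — with a `maf_group` switch for the controls-only
alternative.

**Genomic inflation** is λ = median(qχ²(1 − p, 1)) / qχ²(0.5, 1).
Two caveats frozen into the documentation: (i) one-sided Fisher
p-values on sparse tables are strongly discrete and conservative, so λ
well below 1 is the *expected* behaviour of a calibrated sparse scan —
λ is reported for the with/without-ClinVar contrast rather than as an
absolute calibration claim; (ii) excluding flagged strong signals
(e.g. ClinVar-pathogenic variants) must decrease λ when residual
inflation is driven by true signal, and the test suite reproduces that
contrast on spiked synthetic cohorts.

**Permutation FDR.** Because rare-variant p-values are discrete and
non-uniform, Benjamini–Hochberg on raw p is biased; the package uses an
empirical-null estimator. With observed p-values p(1..n) and B complete
re-tests under permuted labels, the adjusted value at p(i) is

> FDR(i) = [ (1/B) · #{null p ≤ p(i)} ] / #{observed p ≤ p(i)},

floored at the resolution 1/(B·n) and at p(i), capped at 1, then
monotonized step-up (running minimum from the largest p downward).
This formula is frozen here and verified against a literal double-loop
implementation; permutations shuffle phenotype labels over the whole
cohort, as no strata or covariates are modelled.

## Gene-level tests

**CMC collapsing** reduces a gene's qualifying variants to a
per-sample carrier indicator and dosage sum; missing genotypes impute
to 0 alt alleles — conservative for rare variants — with per-sample
missing counts logged.

**SKAT-O-style omnibus test.** Under an intercept-only binomial null
(fitted mean = case fraction), per-variant score statistics
S_v = g_v'(y − μ) are weighted by w_v = Beta-density(MAF_v; 1, 25).
For each ρ on the grid {0, 0.01, 0.04, 0.09, 0.16, 0.25, 0.5, 1},

> Q_ρ = (1 − ρ) Σ_v (w_v S_v)² + ρ (Σ_v w_v S_v)²

is referred to its null, a weighted mixture of 1-df chi-squares whose
weights are the eigenvalues of R_ρ·cov(WS). The score covariance uses
the finite-population factor n/(n−1), making it exact under label
permutation. The mixture tail is computed by four-moment matching to a
scaled noncentral chi-square; against 5·10⁵ Monte-Carlo draws of the
exact mixture the matched tail agrees to four significant digits, so
the approximation error of this step is negligible relative to the
asymptotic step discussed below.

*Combining across the grid.* The per-ρ p-values are combined with the
Cauchy combination test rather than a Bonferroni bound over the grid.
We measured both under the null (2,000 genes, n = 500): the Bonferroni
version attains P(p ≤ 0.05) ≈ 0.015 — badly conservative because the
per-ρ p-values are strongly correlated — while the Cauchy combination
attains ≈ 0.055, i.e. essentially nominal. Bonferroni remains
available (`grid_combine = "bonferroni"`), and at ρ-grid {1} the test
reduces exactly to the burden score test.

*Known limitation.* The analytic p targets the asymptotic
mixture-of-chi-squares distribution. At small n the label-permutation
distribution of Q deviates from that asymptotic law (the scores are
sums of few, skewed genotype contributions); at n = 60 the analytic
tail can differ from a 50,000-permutation estimate by a few times
10⁻³, most visibly at ρ = 0. Small-sample moment corrections are out
of scope by design; for small cohorts the permutation route (as used
in the test suite's oracles) is the reference.

Genes with fewer than 2 qualifying variants are reported *untested*
(a one-variant gene belongs in the single-variant scan), as are genes
with degenerate all-zero submatrices — never as p = 1. The gene scan
runs the nonsynonymous battery (missense, stop gained/lost, start
lost, splice donor/acceptor/region) and the synonymous battery
separately; multiple-testing adjustment is computed within battery so
the synonymous channel is an honest negative control.

**CAST** is a one-sided Fisher test on carrier counts between any
binary sample partition — e.g. mutation-carrier cases versus all other
cases — per gene, per gene set, or per single variant.

## RVTT and meta-analysis

The Rare Variant Trend Test asks whether per-sample counts of
qualifying variants in a gene set rise with case status. With
category scores s, case counts r_i, column totals n_i, R cases of N
samples:

> U = Σ s_i (r_i − n_i R/N),
> Var U = R(N−R)/N² · (N Σ s_i² n_i − (Σ s_i n_i)²)/(N−1),
> Z = U/√Var U,

the hypergeometric (permutation) variance convention with the N−1
denominator; positive Z means cases shifted toward higher counts; Z is
invariant to affine score transforms.

Conventions this implementation freezes (the original leaves them
open; each is configurable):

* threshold grid = all distinct cohort MAFs of mask-qualifying
  gene-set variants, truncated at `maf_max` (0.01); inclusion at a
  threshold is MAF ≤ t; MAF computed on the combined cohort;
* count categories are raw dosage sums capped at the 99th percentile
  of per-sample counts (never below 3), with the top bin aggregated —
  sparse high-count tails otherwise destabilize the variance; scores
  are the category values;
* the test statistic is the *signed* maximum T_max = max_t Z(t)
  (one-sided, case-ward trend); a two-sided |Z| variant is available;
* the permutation p is the add-one estimator
  (1 + #{T_max(b) ≥ T_max})/(B + 1), where every permutation re-runs
  the full threshold maximization (no frozen-threshold shortcut — the
  max statistic is only valid if the null maximizes too); with
  `exhaustive = TRUE` all C(N, R) label assignments are enumerated and
  the p-value is exact.

A gene set with no qualifying variant at any threshold, or no
threshold with a non-degenerate table, is *untestable* — distinct from
p = 1. At B = 1,000 and 2,000 null replicates the empirical type-I
error at α = 0.05 is within ±0.015 of nominal, and power rises
monotonically in the planted carrier odds ratio.

**Cauchy combination (CCT).** Per-cohort RVTT p-values are combined as
T = Σ ŵ_i tan((0.5 − p_i)π) with normalized weights, and
p = 0.5 − arctan(T)/π; terms with p_i < 10⁻¹⁵ use the tail-equivalent
ŵ_i/(p_i π). The combination is exact for a single input, valid under
arbitrary dependence, and agrees with a 50-digit reference evaluation
to 10⁻¹⁰. Permutation p-values enter CCT floored at 1/(B+1) by the
add-one estimator, so the (0,1) domain requirement is automatic;
untestable cohorts are dropped with weights renormalized.

## Enrichment

`hypergeom_overlap()` is the upper-tail hypergeometric overlap test
P(overlap ≥ observed) for two gene sets in a universe.
`sampling_enrichment()` tests a summed per-gene feature count (e.g.
significant eQTLs near each gene) against `n_perm` same-size random
gene draws without replacement; the p-value is one-sided (enrichment)
with the add-one estimator and the confidence interval is read off the
null percentiles. Feature tables are consumed pre-computed; QTL
calling and GWAS thresholding are out of scope.

## The synthetic-cohort generator

`simulate_cohort()` emulates the *statistical* structure the pipeline
assumes. Defaults mirror the targeted-panel study design: 496 cases,
2,516 controls, 430 genes, ~36 variants per gene (Poisson), a
frequency spectrum of 40% singletons / 50% Beta-shaped rare MAFs on
(0, 0.01) / 10% "common" (0.01–0.05, retained for QC exercises), a
consequence mix dominated by missense and synonymous classes with
PolyPhen2/SIFT damaging calls on half the missense variants, and
control singleton counts inflated 2× by adding control-private
singletons post hoc. Genotypes are drawn under HWE within each
phenotype group; in designated risk modules, qualifying (rare
nonsynonymous) variants have their *case carrier odds* multiplied by
the configured odds ratio (dominant-model parameterization — the
downstream tests are carrier/dosage based), converting back to an
allele frequency via q = 1 − √(1 − carrier probability), with an error
if the tilt is infeasible. Optional planted ClinVar-pathogenic
variants (rare missense in effect-carrying modules, default OR 8)
give the λ-contrast and the ClinVar-exclusion switch a positive
control. Site metrics, QUAL, DP and GQ are drawn from comfortably
filter-passing distributions so `plant_qc_violations()` can inject an
exactly-known removal manifest.

What the generator does **not** emulate — and hence what passing tests
do not establish about real data: linkage disequilibrium between
variants, population structure and ancestry admixture, batch- or
coverage-driven differential genotyping between cases and controls
(beyond the singleton inflation), annotation error, and non-dominant
effect architectures. Identical seeds give byte-identical VCF,
annotation and phenotype outputs.

## Problem sizes used by the test suite

The suite validates exactness by enumeration (hundreds of random
tables per exact test), RVTT validity both exhaustively (n = 8, all 70
label assignments) and at 2,000 null replicates of a 10-gene, n = 400
cohort at B = 1,000, RVTT power at 100 replicates per odds ratio, the
gene test against a 50,000-permutation reference at n = 60 and 2,000
null genes at n = 500, and the end-to-end emulation at the full
496/2,516/430 scale with 20 replicates at B = 1,000. These sizes are
the package's chosen trade-off between Monte-Carlo resolution and a
test suite that runs in minutes on one CPU; the statistical guarantees
they check are scale-free.

## Numerical conventions

* p-values never return exactly 0: exact tests floor at the smallest
  positive double, permutation tests at 1/(B+1).
* HWE and binomial two-sided sums classify probability ties with a
  relative tolerance (1 + 10⁻⁹ and the standard 1 + 10⁻⁷
  respectively).
* RVTT maximization ties across thresholds resolve to the smallest
  attaining threshold; permutation exceedance uses a 10⁻¹² slack so
  exhaustive enumeration reproduces ties exactly.
* Missing genotypes: excluded from allele counts and MAF denominators;
  imputed to 0 alt alleles inside burden/count statistics (logged).
* The SKAT-O eigen-spectrum drops eigenvalues below 10⁻¹² of the
  largest; weights use MAF floored at 10⁻⁸ to keep the Beta density
  finite.
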