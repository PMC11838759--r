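---
title: "Methods: fine-mapping, enrichment and ancestry contrasts in isdreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fine-mapping, enrichment and ancestry contrasts in isdreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`isdreg` packages the downstream statistical machinery of a multi-omic
GWAS follow-up study of inflammatory skin diseases: from per-disease
summary statistics to credible sets, regulatory-annotation enrichment,
ancestry allele-frequency contrasts, gene-set and expression analyses,
and two-locus LD arithmetic. This vignette records the models, the
parameters that matter, the design decisions taken where conventions
diverge, and what the synthetic-data generator does and does not emulate.

## Locus delineation and credible sets

Variants with p below the genome-wide threshold (default 5×10⁻⁸, strict)
are retained; variants in the MHC are removed first, because its
long-range LD makes distance-based locus logic meaningless there. The MHC
is fixed to chr6:25–34 Mb, a common operational convention; the bound is
a parameter (`mhc=`) and can be disabled. Remaining variants are merged
by single linkage per chromosome: a gap of at most 500,000 bp joins two
variants into one locus, so a gap of exactly 500 kb merges and 500,001 bp
splits. The locus lead is the smallest-p member, ties broken by smaller
position so results are order-invariant.

Credible sets use Wakefield's approximate Bayes factor with a normal
prior (variance `W`, default 0.04, i.e. sd 0.2 on the log-odds scale —
the field-standard default for binary-trait fine-mapping) under a
single-causal-variant approximation: per-variant posteriors are ABFs
normalised within the locus, accumulated in descending order until 95%
coverage, with boundary ties (posteriors equal to within 1e-12) all
included. Computation is done on log-ABFs with a log-sum-exp
normalisation, so z-scores in the hundreds do not overflow. The set is
minimal up to ties: dropping the last included entry drops coverage
below the target.

## Annotation overlap and observed/expected enrichment

Coordinates follow each format's native convention — BED intervals are
0-based half-open, variant positions 1-based — and the conversion happens
exactly once, inside the overlap query: a position `q` hits `[start, end)`
iff `start < q ≤ end`. Overlap is computed with GenomicRanges; the test
suite keeps an independent brute-force all-pairs scan as the oracle.

A credible-set locus counts as overlapping a track when **any** in-set
variant overlaps. The source analyses report locus proportions without
stating a membership rule; "any in-set variant" is the natural choice
under the single-causal model (the set is where the causal variant lives
with 95% probability). Variant-level indicators are exposed separately
for the GLM.

Expected overlap comes from a background catalogue of trait-associated
best-signal positions (points, not intervals), collapsed to one row per
trait-locus with the same 500 kb rule. The test is a one-sided upper-tail
exact binomial `P(X ≥ observed | n, rate)` — enrichment only, matching
how such overlaps are reported. Raw p-values are primary; a
Benjamini–Hochberg column is available but off by default, since the
source analyses report raw binomial p's. Whether the studied diseases'
own traits are removed from the background is configurable
(`exclude_traits`); the background p-value restriction before collapsing
is exposed and defaults to none, since the catalogue construction leaves
this unstated.

## Ancestry contrasts and the annotation GLM

Group risk-allele frequencies aggregate five constituent populations per
ancestry group by unweighted mean — the simplest defensible choice when
no aggregation is stated; a weighted option exists. Direction flags are
strict (`afr_higher` iff `raf_afr > raf_eur`; exact equality is a tie).
Locus-level direction is the majority vote of in-set variants, ties
flagged `tie`; the locus-level GLM built on it should be considered
experimental, as the variant-level model is the one with stated outcomes
(AfrA = 1, EurA = 0). Ties are excluded from the GLM outcome because the
coding has no tie category.

The GLM is an ordinary logistic regression (`stats::glm`, binomial) of
the higher-in-AfrA indicator on boolean annotation overlaps, jointly or
one predictor at a time; ORs are exponentiated coefficients with Wald
p-values. Constant predictors and (quasi-)complete separation raise
typed errors rather than returning absurd ORs; separation is flagged
when any |coefficient| exceeds 15 or a standard error is non-finite.
The test suite checks coefficients against a hand-written IRLS reference
to 1e-6.

Gene-set enrichment is the one-sided hypergeometric upper tail on the
2×2 hit table, with the sample odds ratio `(ad)/(bc)` and a
Haldane–Anscombe 0.5 correction only when a cell is zero. Gene sets with
≥ 500 members (after intersection with the universe) are rejected,
mirroring the usual term-size filter that drops uninformative broad
terms. Gene sets are flat inputs; ontology hierarchy is out of scope.

## Expression analyses

The module score follows the widely used binned-control scheme: genes are
binned (default 24 bins) by average expression, each module gene draws
100 controls from its bin (module genes excluded; with replacement if the
bin is small), and the per-column score is module mean minus control
mean. Both knobs are exposed. The control pool is sorted before sampling
so a fixed seed gives identical scores regardless of row order.

"Induced" genes in the stimulation contrast are defined by geometric-mean
fold change strictly above 1.5 and BH FDR ≤ 10% from a per-gene paired
t-test on log2 ratios (pseudocount 1). The paired t-test and BH are
deliberate, conventional choices — the source pipeline names its package
family but not the test. The diff-vs-avg Pearson correlation uses log2
fold changes by default (`log2fc = FALSE` switches to raw), since the
scale is not stated where the correlation is reported. Degenerate genes
with identical ratios in every donor get p = 0 (shifted) or p = 1 (flat)
rather than a t-test failure; with fewer than 3 induced genes the
correlation is reported as undefined.

## Two-locus LD arithmetic

`ld_stats` is definitional: `h_theory = p_a p_b`, `D = h_obs − h_theory`,
`D′ = D/D_max` with the usual positive/negative normalisers, and
`r² = D²/(p_a(1−p_a) p_b(1−p_b))`, with Fréchet-bound validation.
`solve_marginals` inverts a reported triple: writing `P = h_theory` and
`V = D²/r²`, the identity `(1−p_a)(1−p_b) = V/P` gives
`p_a + p_b = 1 + P − V/P`, so the marginals are roots of a quadratic.
The inversion cannot confirm the recovered pair matches the reference
panel the original lookup used — it only proves a consistent pair exists.
Association chi-square/p-values from genotype panels are not recomputed;
count-table input covers synthetic populations.

## The synthetic-data generator

The generator's defaults describe the emulated study: 7 diseases, 37
loci per disease (≈ 260 loci total), 25 candidate variants per locus,
10k/20k cases/controls, FST 0.1 between ancestry groups (a typical
African–European value), causal log-odds 0.25, and annotation coverage
0.6 for causal variants on enriched tracks versus 0.2 background.
Within each ancestry group, five populations are drawn hierarchically
(between-group FST as configured, within-group 0.02) and averaged,
mirroring the five-population group aggregation.

Summary statistics follow the standard marginal-statistics model for a
single-causal locus under LD: a proxy with correlation `r` to the causal
variant has expected z-score `r·z_causal` (equivalently
`β_j = r β_c · se_j/se_c`), and the noise on its z-score is correlated
`r` with the causal variant's noise. Both pieces matter: with
independent noise, or with effect attenuation applied on the β scale
while standard errors differ across allele frequencies, proxies overtake
the causal variant far too often and nominal 95% credible sets lose
~10–35% coverage. Under the correlated model, coverage of the planted
causal variant is ≈ 99–100% at the default settings, which the coverage
suite verifies on 1000 loci. Standard errors use the additive log-odds
approximation `se = 1/sqrt(2 n_eff p(1−p))`.

This is still an idealisation: there is no realistic LD map, no
haplotype structure (each locus has one causal variant by construction),
no imputation error, and annotation intervals are simple windows around
variants. Passing tests therefore demonstrate the statistical machinery
is correct under its stated model, not that the pipeline's conclusions
transfer to any particular real cohort.

## Problem sizes and numerical choices

The coverage study uses 1000 loci of 10 variants (≈ seconds); null
calibration of the enrichment test uses 500 simulated track draws over
30 single-variant loci and a 200-point background; GLM recovery uses 200
replicates at n = 5000; the end-to-end determinism check runs the full
default bundle twice and compares outputs byte for byte. Posterior
normalisation is asserted to 1e-12; oracle agreement (binomial and
hypergeometric tails, IRLS, BH) to 1e-12/1e-6 as stated above. Fréchet
validation uses a 1e-9 tolerance so frequencies arriving through floating
arithmetic are not spuriously rejected.

## Known limitations

Single-causal-variant fine-mapping only (no SuSiE/FINEMAP-style
multi-causal modelling, no LD-aware enrichment resampling); gene sets
are flat; no normalisation or differential-expression engine (normalised
inputs are assumed); no genotype-level haplotype phasing. The locus
counts the pipeline reports on synthetic data are its own; the source
study's printed locus/signal counts are not targeted, as they derive
from external cohort data.
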