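# isdreg

Regulatory and ancestry analysis of inflammatory skin disease (ISD) GWAS
signals.

GWAS of inflammatory skin diseases — acne, alopecia areata, atopic
dermatitis, psoriasis, lupus, systemic sclerosis, vitiligo — report
association signals whose causal variants and target cell types are mostly
unknown, and almost all of that evidence comes from European-ancestry
cohorts. `isdreg` implements, as a tested R pipeline over synthetic or
user-supplied tables, the analyses needed to ask two questions of such
signals: *do they fall in keratinocyte regulatory elements?* and *do their
risk alleles differ in frequency between African- and European-ancestry
populations, and is that difference linked to regulatory function?*

## What it computes

**Fine-mapping.** Loci are delineated from per-disease summary statistics
by keeping genome-wide-significant variants (p < 5×10⁻⁸), excluding the
MHC (chr6:25–34 Mb), and single-linkage merging variants within 500 kb.
Each locus gets a 95% Bayesian credible set under a single-causal-variant
approximation using Wakefield's approximate Bayes factor

    ABF = sqrt(se² / (se² + W)) · exp( β² W / (2 se² (se² + W)) ),

with prior variance `W = 0.04` by default; per-variant posteriors are the
ABFs normalised over the locus.

**Annotation enrichment.** For an annotation track (ATAC peaks, Bru-seq
eRNA intervals, promoter-capture Hi-C loop ends, eQTL status), the
proportion of credible-set loci overlapping the track is compared with the
overlap rate of a background catalogue of trait-associated loci:
`OE = (observed/n) / background rate`, with a one-sided exact binomial
p-value `P(X ≥ observed | n, rate)`. Cell-type specificity folds
(reference count / other cell type's count) are also provided.

**Ancestry contrasts.** Risk-allele frequencies aggregated over five
African-ancestry and five European-ancestry 1000 Genomes-style populations
are compared per variant (strict `raf_afr > raf_eur`); the binary
higher-in-AfrA outcome is modelled, jointly and marginally, against
annotation overlap indicators with a logistic GLM (reported as OR with
Wald p). eQTL target genes of direction-matched credible variants feed a
one-sided hypergeometric gene-set enrichment with a term-size (< 500)
filter.

**Expression.** Binned-control module scores (24 average-expression bins,
100 controls per module gene), lesional-vs-nonlesional fold changes
(pseudocounted means, Wilcoxon), and a paired stimulation contrast: genes
induced at FC > 1.5 and BH FDR ≤ 10% are tested for a Pearson correlation
between the between-group response difference and the average response.

**Two-locus LD.** `ld_stats()` derives D, D′, r² and the
linkage-equilibrium haplotype frequency from marginal and haplotype
frequencies; `solve_marginals()` inverts a reported
(theoretical, observed, r²) triple back to the marginals via a quadratic
feasibility argument; `beta_to_or()` converts log-odds effect sizes to
odds ratios.

**Synthetic data.** `sim_config()`/`simulate_bundle()` generate every
input with planted ground truth: one causal variant per locus with
LD-attenuated neighbour z-scores, Balding–Nichols ancestry frequencies at
a chosen FST, annotation tracks with separate causal/background coverage
probabilities, eQTL tables with a planted gene set, and paired stimulation
counts with group-specific fold changes.

## Worked example

```r
library(isdreg)

# reported LD triple for a disease variant pair: theoretical risk-risk
# haplotype frequency 0.114, observed 0.236, r2 0.3
sol <- solve_marginals(h_theory = 0.114, h_obs = 0.236, r2 = 0.3)
ld_stats(sol$p_a, sol$p_b, 0.236)
#> ld_pair: p_a=0.374 p_b=0.305 h_obs=0.236 h_theory=0.114 D=0.1220 D'=0.642 r2=0.300

beta_to_or(c(0.21, 0.46))
#> [1] 1.23 1.58
```

The recovered marginal risk-allele frequencies (0.374, 0.305) multiply
back to the theoretical haplotype frequency 0.114 — the variant pair is
observed together (0.236) twice as often as linkage equilibrium predicts
(r² = 0.30) — and the two log-odds effect sizes convert to odds ratios
1.23 and 1.58.

The full workflow is laid out as numbered drivers under `analysis/`
(simulate → finemap → enrichment → ancestry/GLM/gene sets → expression →
LD), each writing its tables under `results/`. On the default synthetic
bundle the fine-mapper recovers 258 of 259 planted loci with median
credible-set size 1, the planted ATAC/BRU tracks show OE ≈ 2.9–3.1 at
p < 10⁻³ while the unplanted Hi-C track does not, and the planted gene
set is the top enrichment (OR ≈ 200, p ≈ 10⁻¹²).

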