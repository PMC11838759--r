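#!/usr/bin/env Rscript
# Two-locus LD arithmetic for the pericarditis-linked variant pair, and
# the effect-size to odds-ratio conversions for the PheWAS associations.

suppressMessages(library(isdreg))

# The reported LD triple for the acne variant pair: theoretical risk-risk
# haplotype frequency 0.114, observed 0.236, r2 0.3. Recover the marginal
# risk-allele frequencies and verify the arithmetic closes.
sol <- solve_marginals(h_theory = 0.114, h_obs = 0.236, r2 = 0.3)
stopifnot(sol$feasible)
pair <- ld_stats(sol$p_a, sol$p_b, 0.236)
cat(sprintf("marginal RAFs: %.3f and %.3f\n", sol$p_a, sol$p_b))
cat(sprintf("theoretical T-T haplotype frequency: %.3f (observed %.3f)\n",
            pair$h_theory, pair$h_ab))
cat(sprintf("D=%.3f, D'=%.2f, r2=%.2f\n", pair$d, pair$d_prime, pair$r2))

# PheWAS effect sizes on the log-odds scale -> odds ratios
phewas <- data.frame(condition = c("pericarditis", "acute pericarditis"),
                     effect_size = c(0.21, 0.46))
phewas$or <- beta_to_or(phewas$effect_size)
cat("\nPheWAS effect-size to OR conversion:\n")
print(phewas, row.names = FALSE)

# the same arithmetic from a synthetic haplotype count table
counts <- round(c(pair$h_ab, pair$p_a - pair$h_ab,
                  pair$p_b - pair$h_ab,
                  1 - pair$p_a - pair$p_b + pair$h_ab) * 5008)
from_counts <- haplotype_counts_to_freqs(counts)
cat(sprintf("\nfrom a 2x2 count table of %d haplotypes: r2=%.2f\n",
            sum(counts), from_counts$r2))

dir.create("results", showWarnings = FALSE)
isdreg:::write_tsv_commented(
  data.frame(p_a = pair$p_a, p_b = pair$p_b, h_obs = pair$h_ab,
             h_theory = pair$h_theory, d = pair$d, d_prime = pair$d_prime,
             r2 = pair$r2),
  "results/ld_example.tsv")
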