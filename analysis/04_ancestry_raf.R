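#!/usr/bin/env Rscript
# Ancestry risk-allele-frequency contrasts: per-variant and per-locus
# direction proportions, the joint/marginal logistic GLM of the
# higher-in-AfrA flag on annotation overlaps, and gene-set enrichment of
# the eQTL targets of afr-higher credible variants.

suppressMessages(library(isdreg))

files <- list.files("results/simdata", pattern = "_sumstats\\.tsv$",
                    full.names = TRUE)
css <- lapply(files, function(f) {
  finemap_disease(read_summary_stats(f, sub("_sumstats\\.tsv$", "", basename(f))))
})
names(css) <- sub("_sumstats\\.tsv$", "", basename(files))
all_cs <- unlist(css, recursive = FALSE)

raf <- isdreg:::read_tsv_commented("results/simdata/ancestry_raf.tsv")
flags <- flag_raf_direction(raf)

props_v <- raf_proportions(flags, css, unit = "variant")
props_l <- raf_proportions(flags, css, unit = "locus")
props_v$unit <- "variant"; props_l$unit <- "locus"
isdreg:::write_tsv_commented(rbind(props_v, props_l),
                             "results/raf_proportions.tsv")
cat("share of credible variants with higher AfrA RAF, per disease:\n")
print(props_v[, c("disease", "afr_higher", "eur_higher", "tie")],
      row.names = FALSE)

beds <- list.files("results/simdata", pattern = "\\.bed$", full.names = TRUE)
tracks <- lapply(beds, function(b) read_bed(b, toupper(sub("\\.bed$", "", basename(b)))))
names(tracks) <- vapply(tracks, `[[`, character(1), "name")
eqtl <- read_eqtl_table("results/simdata/eqtl.tsv")

ind <- variant_overlap_indicators(all_cs, tracks, eqtl = eqtl)
glm_tab <- rbind(fit_raf_annotation_glm(flags, ind, mode = "joint"),
                 fit_raf_annotation_glm(flags, ind, mode = "marginal"))
isdreg:::write_tsv_commented(glm_tab, "results/glm.tsv")
cat("\njoint GLM of 1{afr_higher} on annotation overlaps",
    "(the generator plants no RAF-annotation link, so ORs should sit near 1):\n")
print(glm_tab[glm_tab$model == "joint" & glm_tab$term != "(Intercept)",
              c("term", "or_estimate", "p")], row.names = FALSE)

sets <- read_gmt("results/simdata/gene_sets.gmt")
targets <- collect_eqtl_targets(all_cs, eqtl, flags, "afr_higher")
gs <- geneset_enrichment_all(targets, sets, sort(unique(eqtl$gene)))
isdreg:::write_tsv_commented(gs, "results/geneset_enrichment.tsv")
cat(sprintf("\n%d afr-higher eQTL target genes; top gene set: %s (OR=%.1f, p=%.2g)\n",
            length(targets), gs$set_name[1], gs$or_estimate[1], gs$p[1]))
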