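#!/usr/bin/env Rscript
# Observed/expected overlap of credible-set loci with each annotation
# track, against the background trait-locus catalogue (exact one-sided
# binomial test), plus a cell-type specificity example.

suppressMessages(library(isdreg))

files <- list.files("results/simdata", pattern = "_sumstats\\.tsv$",
                    full.names = TRUE)
css <- lapply(files, function(f) {
  finemap_disease(read_summary_stats(f, sub("_sumstats\\.tsv$", "", basename(f))))
})
names(css) <- sub("_sumstats\\.tsv$", "", basename(files))

beds <- list.files("results/simdata", pattern = "\\.bed$", full.names = TRUE)
tracks <- lapply(beds, function(b) read_bed(b, toupper(sub("\\.bed$", "", basename(b)))))
names(tracks) <- vapply(tracks, `[[`, character(1), "name")
background <- read_background_loci("results/simdata/background_loci.tsv")

enr <- enrichment_table(css, tracks, background)
isdreg:::write_tsv_commented(enr, "results/enrichment.tsv")

cat("observed/expected enrichment (planted tracks: ATAC, BRU):\n")
agg <- aggregate(cbind(oe, p) ~ track, enr, function(x) round(mean(x), 3))
print(agg, row.names = FALSE)

# specificity of a reference cell type against others, on per-cell-type
# overlap counts of one track's intervals with the credible variants
counts <- c(NHEK = sum(enr$observed[enr$track == "ATAC"]),
            GM12878 = sum(enr$observed[enr$track == "HIC_LOOP_END"]),
            K562 = sum(enr$observed[enr$track == "BRU"]))
spec <- specificity_fold(counts, "NHEK")
cat(sprintf("specificity example: mean fold %s over other cell types\n",
            round(spec$mean_fold, 2)))
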