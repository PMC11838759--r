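Package: isdreg
Title: Regulatory and Ancestry Analysis of Inflammatory Skin Disease GWAS Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline relating inflammatory skin disease (ISD)
    GWAS signals to keratinocyte regulatory annotations and ancestry
    allele-frequency differences. Delineates distance-based disease loci
    from summary statistics, computes 95% Bayesian credible sets with
    Wakefield approximate Bayes factors, tests observed/expected overlap
    enrichment of credible-set loci with annotation tracks (ATAC, eRNA,
    Hi-C loop ends, eQTL) against a background trait-locus catalogue,
    compares risk-allele frequencies between African- and European-ancestry
    groups and jointly models the direction against annotations with a
    logistic GLM, runs hypergeometric gene-set enrichment of eQTL target
    genes, computes binned-control module scores and stimulation-response
    contrasts, and provides two-locus linkage-disequilibrium arithmetic.
    A seeded synthetic-data generator with planted ground truth emulates
    every input so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
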