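#' Build an ancestry risk-allele-frequency table
#'
#' Aggregates per-population risk-allele frequencies into one frequency per
#' ancestry group. The default aggregation is the unweighted mean across
#' the constituent populations; `weights` allows a sample-size-weighted
#' mean instead.
#'
#' @param variant_id Character vector.
#' @param afr,eur Matrices (variants x populations) of per-population RAFs.
#' @param weights_afr,weights_eur Optional per-population weights.
#' @return Data frame (`variant_id`, `raf_afr`, `raf_eur`, `n_pops_afr`,
#'   `n_pops_eur`).
#' @export
ancestry_freq_table <- function(variant_id, afr, eur,
                                weights_afr = NULL, weights_eur = NULL) {
  afr <- as.matrix(afr); eur <- as.matrix(eur)
  stopifnot(nrow(afr) == length(variant_id), nrow(eur) == length(variant_id))
  assert_prob(afr, "afr frequencies", open_left = FALSE, open_right = FALSE)
  assert_prob(eur, "eur frequencies", open_left = FALSE, open_right = FALSE)
  wmean <- function(m, w) {
    if (is.null(w)) rowMeans(m) else as.numeric(m %*% (w / sum(w)))
  }
  data.frame(variant_id = variant_id,
             raf_afr = wmean(afr, weights_afr),
             raf_eur = wmean(eur, weights_eur),
             n_pops_afr = ncol(afr), n_pops_eur = ncol(eur),
             stringsAsFactors = FALSE)
}

#' Flag risk-allele-frequency direction per variant
#'
#' Strict comparison of the aggregated African-ancestry versus
#' European-ancestry risk-allele frequency: `afr_higher` iff
#' `raf_afr > raf_eur`, `eur_higher` iff `<`, exact equality is a `tie`.
#'
#' @param freqs Ancestry frequency table (`variant_id`, `raf_afr`,
#'   `raf_eur`).
#' @param variants Optional character vector restricting (and ordering) the
#'   flags; every queried variant must be present in `freqs`.
#' @return Data frame (`variant_id`, `direction`).
#' @export
flag_raf_direction <- function(freqs, variants = NULL) {
  if (is.null(variants)) variants <- freqs$variant_id
  idx <- match(variants, freqs$variant_id)
  if (anyNA(idx)) {
    stop_typed("missing_variant_error",
               "variant(s) missing from frequency table: %s",
               paste(variants[is.na(idx)], collapse = ", "))
  }
  a <- freqs$raf_afr[idx]; e <- freqs$raf_eur[idx]
  data.frame(
    variant_id = variants,
    direction = ifelse(a > e, "afr_higher", ifelse(a < e, "eur_higher", "tie")),
    stringsAsFactors = FALSE)
}

#' Direction proportions per disease
#'
#' Proportions of `afr_higher` / `eur_higher` / `tie` flags, at the variant
#' level or collapsed to loci by majority vote of each locus's in-set
#' variants (a tied vote is a `tie`).
#'
#' @param flags Data frame (`variant_id`, `direction`) from
#'   [flag_raf_direction()].
#' @param unit `"variant"` or `"locus"`.
#' @param credible_sets_by_disease Named list (disease -> list of
#'   `credible_set`s); required. Variant-level proportions are over in-set
#'   variants.
#' @return Data frame (`disease`, `afr_higher`, `eur_higher`, `tie`, `n`);
#'   the three proportions sum to 1 per disease.
#' @export
raf_proportions <- function(flags, credible_sets_by_disease,
                            unit = c("variant", "locus")) {
  unit <- match.arg(unit)
  dirmap <- stats::setNames(flags$direction, flags$variant_id)
  rows <- lapply(names(credible_sets_by_disease), function(d) {
    css <- credible_sets_by_disease[[d]]
    dirs <- if (unit == "variant") {
      unlist(lapply(css, function(cs) {
        v <- credible_variants(cs)$variant_id
        unname(dirmap[v])
      }))
    } else {
      vapply(css, function(cs) {
        v <- credible_variants(cs)$variant_id
        majority_direction(unname(dirmap[v]))
      }, character(1))
    }
    if (anyNA(dirs)) {
      stop_typed("missing_variant_error",
                 "credible-set variant(s) without a RAF flag (disease %s)", d)
    }
    n <- length(dirs)
    data.frame(disease = d,
               afr_higher = mean(dirs == "afr_higher"),
               eur_higher = mean(dirs == "eur_higher"),
               tie = mean(dirs == "tie"),
               n = n, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Majority vote over per-variant directions; afr/eur tie -> "tie".
majority_direction <- function(dirs) {
  n_afr <- sum(dirs == "afr_higher"); n_eur <- sum(dirs == "eur_higher")
  if (n_afr > n_eur) "afr_higher" else if (n_eur > n_afr) "eur_higher" else "tie"
}

#' Logistic GLM of RAF direction on annotation overlaps
#'
#' Models the probability that a credible-set variant has a higher
#' African-ancestry risk-allele frequency (outcome 1 = `afr_higher`,
#' 0 = `eur_higher`; ties are excluded) as a function of boolean annotation
#' indicators (ATAC peak, eRNA/Bru interval, Hi-C loop end, skin-eQTL
#' status, ...). `joint` fits all predictors in one model; `marginal` fits
#' one single-predictor model per indicator.
#'
#' @param flags Data frame (`variant_id`, `direction`).
#' @param indicators Data frame with `variant_id` and one logical/0-1
#'   column per predictor (see [variant_overlap_indicators()]).
#' @param mode `"joint"` or `"marginal"`.
#' @param predictors Predictor columns to use (default: every non-id
#'   column of `indicators`).
#' @return Data frame (`term`, `estimate`, `or_estimate`, `p`, `model`);
#'   the intercept row is reported but carries no enrichment
#'   interpretation.
#' @export
fit_raf_annotation_glm <- function(flags, indicators,
                                   mode = c("joint", "marginal"),
                                   predictors = NULL) {
  mode <- match.arg(mode)
  if (is.null(predictors)) predictors <- setdiff(names(indicators), "variant_id")
  df <- merge(flags, indicators, by = "variant_id")
  df <- df[df$direction != "tie", , drop = FALSE]
  df$y <- as.integer(df$direction == "afr_higher")
  if (length(unique(df$y)) < 2) {
    stop_typed("domain_error", "need both outcome classes present after tie removal")
  }
  for (tm in predictors) {
    v <- df[[tm]]
    if (length(unique(v)) < 2) {
      stop_typed("constant_predictor_error", "predictor '%s' is constant", tm)
    }
  }
  fit_one <- function(terms, label) {
    f <- stats::as.formula(paste("y ~", paste(terms, collapse = " + ")))
    fit <- suppressWarnings(stats::glm(f, data = df, family = stats::binomial()))
    coefs <- summary(fit)$coefficients
    if (any(!is.finite(coefs[, "Std. Error"])) ||
        any(abs(coefs[, "Estimate"]) > 15)) {
      stop_typed("separation_error",
                 "(quasi-)complete separation fitting term(s): %s",
                 paste(terms, collapse = ", "))
    }
    data.frame(term = sub("TRUE$", "", rownames(coefs)),
               estimate = coefs[, "Estimate"],
               or_estimate = exp(coefs[, "Estimate"]),
               p = coefs[, "Pr(>|z|)"],
               model = label, stringsAsFactors = FALSE)
  }
  out <- if (mode == "joint") {
    fit_one(predictors, "joint")
  } else {
    do.call(rbind, lapply(predictors, function(tm) {
      res <- fit_one(tm, "marginal")
      res[res$term != "(Intercept)", , drop = FALSE]
    }))
  }
  rownames(out) <- NULL
  out
}

#' Hypergeometric gene-set enrichment
#'
#' One-sided Fisher/hypergeometric enrichment of a selected gene list in a
#' gene set, against a universe. The 2x2 table is
#' (hit, selected-not-set; set-not-selected, neither); the p-value is the
#' upper hypergeometric tail `P(X >= hits)` and the odds ratio is the
#' sample cross-product `(a d)/(b c)` with a Haldane-Anscombe 0.5
#' correction applied iff any cell is zero. Gene sets at or above
#' `max_set_size` genes (after intersection with the universe) are
#' rejected, mirroring the usual term-size filter for broad ontology terms.
#'
#' @param selected_genes Character vector (e.g. eQTL targets of
#'   `afr_higher` credible variants).
#' @param gene_set Character vector; the set under test.
#' @param universe Character vector; reference universe.
#' @param set_name Label for the result row.
#' @param max_set_size Strict upper bound on usable set size (default 500:
#'   sets of size >= 500 are rejected).
#' @return One-row data frame: `set_name`, `universe_size`, `set_size`,
#'   `selected_size`, `hits`, `or_estimate`, `p`.
#' @export
geneset_enrichment <- function(selected_genes, gene_set, universe,
                               set_name = NA_character_, max_set_size = 500L) {
  universe <- unique(universe)
  if (length(universe) == 0) stop_typed("domain_error", "empty universe")
  selected <- unique(intersect(selected_genes, universe))
  if (length(selected) == 0) stop_typed("domain_error", "empty selected gene list")
  gs <- unique(intersect(gene_set, universe))
  if (length(gs) == 0) stop_typed("domain_error", "gene set disjoint from universe")
  if (length(gs) >= max_set_size) {
    stop_typed("term_size_error",
               "gene set '%s' has %d genes (>= %d); rejected by term-size filter",
               set_name, length(gs), max_set_size)
  }
  N <- length(universe); K <- length(gs); n <- length(selected)
  a <- length(intersect(selected, gs))       # hits
  b <- n - a                                 # selected, not in set
  c_ <- K - a                                # in set, not selected
  d <- N - K - b                             # neither
  p <- stats::phyper(a - 1, K, N - K, n, lower.tail = FALSE)
  cells <- c(a, b, c_, d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells[1] * cells[4]) / (cells[2] * cells[3])
  data.frame(set_name = set_name, universe_size = N, set_size = K,
             selected_size = n, hits = a, or_estimate = or, p = p,
             stringsAsFactors = FALSE)
}

#' Enrichment over a GMT collection
#'
#' @param selected_genes Character vector.
#' @param sets Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector.
#' @param max_set_size Term-size filter; oversized sets are skipped with a
#'   message rather than aborting the batch.
#' @return Data frame, one row per tested set, sorted by p.
#' @export
geneset_enrichment_all <- function(selected_genes, sets, universe,
                                   max_set_size = 500L) {
  rows <- list()
  for (nm in names(sets)) {
    res <- tryCatch(
      geneset_enrichment(selected_genes, sets[[nm]], universe,
                         set_name = nm, max_set_size = max_set_size),
      term_size_error = function(e) { message(conditionMessage(e)); NULL })
    if (!is.null(res)) rows[[length(rows) + 1]] <- res
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' eQTL target genes of direction-matched credible variants
#'
#' Union of eQTL target genes over in-set credible variants whose
#' risk-allele-frequency flag matches `direction`.
#'
#' @param credible_sets List of `credible_set`s.
#' @param eqtl eQTL data frame (`variant_id`, `gene`).
#' @param flags Data frame (`variant_id`, `direction`).
#' @param direction `"afr_higher"`, `"eur_higher"` or `"tie"`.
#' @return Character vector of genes (possibly empty, with a warning).
#' @export
collect_eqtl_targets <- function(credible_sets, eqtl, flags,
                                 direction = "afr_higher") {
  v <- unique(unlist(lapply(credible_sets,
                            function(cs) credible_variants(cs)$variant_id)))
  matched <- flags$variant_id[flags$direction == direction]
  v <- intersect(v, matched)
  if (length(v) == 0) {
    warning("no credible-set variant matches direction '", direction, "'")
    return(character(0))
  }
  sort(unique(eqtl$gene[eqtl$variant_id %in% v]))
}
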