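#' Delineate disease loci from summary statistics
#'
#' Keeps genome-wide-significant variants (`p < p_threshold`, strict),
#' removes variants falling in the MHC region, then merges the survivors by
#' single linkage: on each chromosome, consecutive significant variants
#' separated by at most `merge_dist` bp belong to the same locus (a gap of
#' exactly 500,000 bp merges; 500,001 splits). The locus lead is the
#' smallest-p member, ties broken by smaller position.
#'
#' @param records Summary-stat data frame for a single disease
#'   (see [read_summary_stats()]).
#' @param p_threshold Genome-wide significance threshold (default 5e-8).
#' @param merge_dist Merge distance in bp (default 500,000).
#' @param mhc MHC region to exclude, as `list(chrom=, start=, end=)` with
#'   0-based half-open bounds (default chr6:25,000,000-34,000,000), or
#'   `NULL` to disable the exclusion.
#' @return A list of `locus` objects, each with `disease`, `chrom`, `span`,
#'   `lead` (one-row data frame) and `members` (data frame sorted by
#'   position). Empty list (with a warning) when nothing is significant.
#' @export
delineate_loci <- function(records, p_threshold = 5e-8,
                           merge_dist = 500000L,
                           mhc = list(chrom = "chr6", start = 25e6, end = 34e6)) {
  stopifnot(length(unique(records$disease)) <= 1)
  sig <- records[records$p < p_threshold, , drop = FALSE]
  if (!is.null(mhc)) {
    in_mhc <- norm_chrom(sig$chrom) == norm_chrom(mhc$chrom) &
      sig$pos > mhc$start & sig$pos <= mhc$end
    sig <- sig[!in_mhc, , drop = FALSE]
  }
  if (nrow(sig) == 0) {
    warning("no genome-wide-significant variants outside the MHC; no loci")
    return(list())
  }
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  loci <- list()
  for (chrom in unique(sig$chrom)) {
    sub <- sig[sig$chrom == chrom, , drop = FALSE]
    cl <- cluster_positions(sub$pos, merge_dist)
    for (members in split(sub, cl)) {
      rownames(members) <- NULL
      lead <- members[order(members$p, members$pos), , drop = FALSE][1, , drop = FALSE]
      loci[[length(loci) + 1]] <- structure(list(
        disease = members$disease[1] %||% NA_character_,
        chrom = chrom,
        span = c(min(members$pos), max(members$pos)),
        lead = lead,
        members = members
      ), class = "locus")
    }
  }
  # deterministic order: chrom then span start
  ord <- order(vapply(loci, function(l) l$chrom, character(1)),
               vapply(loci, function(l) l$span[1], numeric(1)))
  loci[ord]
}

#' @export
print.locus <- function(x, ...) {
  cat(sprintf("locus %s %s:%d-%d, %d variant(s), lead %s (p=%.3g)\n",
              x$disease, x$chrom, x$span[1], x$span[2], nrow(x$members),
              x$lead$variant_id, x$lead$p))
  invisible(x)
}

#' Wakefield approximate Bayes factor
#'
#' Single-variant Bayes factor for association versus the null from an
#' effect estimate and its standard error, under a normal prior on the
#' log-odds effect with variance `prior_w`:
#' `ABF = sqrt(se^2 / (se^2 + W)) * exp(beta^2 W / (2 se^2 (se^2 + W)))`.
#'
#' @param beta Effect estimate (log-odds per risk allele); vectorised.
#' @param se Standard error(s), > 0.
#' @param prior_w Prior variance W (default 0.04, i.e. sd 0.2 on the
#'   log-odds scale).
#' @param log If `TRUE` return the natural log of the ABF (numerically safe
#'   for large z).
#' @return Bayes factor(s), always > 0 (or their logs).
#' @export
wakefield_abf <- function(beta, se, prior_w = 0.04, log = FALSE) {
  if (any(se <= 0)) stop_typed("domain_error", "se must be > 0")
  if (prior_w <= 0) stop_typed("domain_error", "prior_w must be > 0")
  z2 <- (beta / se)^2
  labf <- 0.5 * base::log(se^2 / (se^2 + prior_w)) +
    z2 / 2 * prior_w / (se^2 + prior_w)
  if (log) labf else exp(labf)
}

#' 95% Bayesian credible set for a locus
#'
#' Under a single-causal-variant approximation, each member's posterior
#' probability of being causal is its Wakefield ABF normalised over the
#' locus. Members are ranked by posterior (descending) and accumulated
#' until the target coverage is reached; members tied (to within 1e-12)
#' with the last included posterior are also included.
#'
#' @param locus A `locus` from [delineate_loci()], or any data frame with
#'   `variant_id`, `chrom`, `pos`, `beta`, `se` columns.
#' @param coverage_target Posterior mass to cover (default 0.95).
#' @param prior_w Wakefield prior variance (default 0.04).
#' @return A `credible_set`: list with `locus`, `entries` (data frame
#'   sorted by posterior descending: `variant_id`, `chrom`, `pos`,
#'   `log_abf`, `abf`, `posterior`, `cumulative`, `in_set`) and `coverage`
#'   (sum of in-set posteriors, >= `coverage_target`).
#' @export
credible_set <- function(locus, coverage_target = 0.95, prior_w = 0.04) {
  members <- if (inherits(locus, "locus")) locus$members else locus
  if (nrow(members) < 1) stop_typed("domain_error", "locus has no members")
  labf <- wakefield_abf(members$beta, members$se, prior_w, log = TRUE)
  post <- exp(labf - max(labf))
  post <- post / sum(post)
  ord <- order(post, -members$pos, decreasing = TRUE)  # ties: smaller pos first
  entries <- data.frame(
    variant_id = members$variant_id[ord],
    chrom = members$chrom[ord],
    pos = members$pos[ord],
    log_abf = labf[ord],
    abf = exp(labf[ord]),
    posterior = post[ord],
    cumulative = cumsum(post[ord]),
    stringsAsFactors = FALSE
  )
  k <- which(entries$cumulative >= coverage_target - 1e-12)[1]
  if (is.na(k)) k <- nrow(entries)
  # include boundary ties
  while (k < nrow(entries) &&
         abs(entries$posterior[k + 1] - entries$posterior[k]) <= 1e-12) {
    k <- k + 1
  }
  entries$in_set <- seq_len(nrow(entries)) <= k
  structure(list(
    locus = if (inherits(locus, "locus")) locus else NULL,
    entries = entries,
    coverage = entries$cumulative[k],
    coverage_target = coverage_target,
    prior_w = prior_w
  ), class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("credible_set: %d of %d variant(s), coverage %.3f (target %.2f)\n",
              sum(x$entries$in_set), nrow(x$entries), x$coverage,
              x$coverage_target))
  invisible(x)
}

#' In-set variants of a credible set
#' @param cs A `credible_set`.
#' @return Data frame of the in-set entries.
#' @export
credible_variants <- function(cs) {
  stopifnot(inherits(cs, "credible_set"))
  cs$entries[cs$entries$in_set, , drop = FALSE]
}

#' Fine-map all loci of one disease
#'
#' Convenience wrapper: [delineate_loci()] then [credible_set()] per locus.
#'
#' @inheritParams delineate_loci
#' @inheritParams credible_set
#' @return List of `credible_set` objects.
#' @export
finemap_disease <- function(records, p_threshold = 5e-8, merge_dist = 500000L,
                            mhc = list(chrom = "chr6", start = 25e6, end = 34e6),
                            coverage_target = 0.95, prior_w = 0.04) {
  loci <- delineate_loci(records, p_threshold, merge_dist, mhc)
  lapply(loci, credible_set, coverage_target = coverage_target,
         prior_w = prior_w)
}

#' Flatten credible sets to one table
#'
#' @param credible_sets List of `credible_set` objects.
#' @return Data frame with `disease`, `locus_id` (chrom:span), and the
#'   per-variant entry columns.
#' @export
credible_set_table <- function(credible_sets) {
  rows <- lapply(seq_along(credible_sets), function(i) {
    cs <- credible_sets[[i]]
    loc <- cs$locus
    id <- if (!is.null(loc)) sprintf("%s:%d-%d", loc$chrom, loc$span[1], loc$span[2])
          else sprintf("locus%03d", i)
    cbind(data.frame(disease = if (!is.null(loc)) loc$disease else NA_character_,
                     locus_id = id, stringsAsFactors = FALSE),
          cs$entries)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
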