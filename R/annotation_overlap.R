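#' Does a variant position fall in an annotation track?
#'
#' Point-vs-interval query under the coordinate conventions used
#' throughout: summary-stat positions are 1-based points, BED intervals are
#' 0-based half-open, so a point `q` hits `[start, end)` iff
#' `start < q <= end`. Chromosome names are compared with the `chr` prefix
#' stripped.
#'
#' @param variant A one-row summary-stat data frame (needs `chrom`, `pos`).
#' @param track An `annotation_track`.
#' @return Logical scalar.
#' @export
variant_in_track <- function(variant, track) {
  points_in_track(variant$chrom, variant$pos, track)[1]
}

#' Vectorised point-in-track query
#'
#' @param chrom,pos Parallel vectors of positions (1-based).
#' @param track An `annotation_track`.
#' @return Logical vector, one per position.
#' @export
points_in_track <- function(chrom, pos, track) {
  stopifnot(inherits(track, "annotation_track"), length(chrom) == length(pos))
  if (length(pos) == 0) return(logical(0))
  subject <- track_granges(track)
  seqs <- union(unique(norm_chrom(chrom)), GenomeInfoDb::seqlevels(subject))
  query <- GenomicRanges::GRanges(
    seqnames = factor(norm_chrom(chrom), levels = seqs),
    ranges = IRanges::IRanges(start = pos, end = pos))
  GenomeInfoDb::seqlevels(subject) <- seqs
  IRanges::overlapsAny(query, subject)
}

#' Does a credible set overlap an annotation track?
#'
#' A locus counts as overlapping when at least one of its in-set credible
#' variants falls in the track.
#'
#' @param cs A `credible_set`.
#' @param track An `annotation_track`.
#' @return Logical scalar.
#' @export
locus_overlaps_track <- function(cs, track) {
  v <- credible_variants(cs)
  any(points_in_track(v$chrom, v$pos, track))
}

#' Background overlap rate
#'
#' Fraction of background trait-locus positions (points) falling in the
#' track; the expected per-locus overlap probability for the
#' observed/expected test.
#'
#' @param background Data frame of background loci (`chrom`, `pos`).
#' @param track An `annotation_track`.
#' @return Rate in \[0, 1\].
#' @export
background_rate <- function(background, track) {
  if (is.null(background) || nrow(background) == 0) {
    stop_typed("domain_error", "background catalogue is empty; rate undefined")
  }
  rate <- mean(points_in_track(background$chrom, background$pos, track))
  if (rate == 0) {
    warning("track '", track$name,
            "' overlaps no background locus; downstream test undefined")
  }
  rate
}

#' Observed/expected annotation enrichment
#'
#' Counts the credible-set loci overlapping a track, compares the observed
#' proportion with the background rate estimated from a trait-locus
#' catalogue, and tests for enrichment with a one-sided upper-tail exact
#' binomial test `P(X >= observed | n, rate)`.
#'
#' @param credible_sets List of `credible_set` objects for one disease.
#' @param track An `annotation_track`.
#' @param background Background-locus data frame (`chrom`, `pos`), or a
#'   pre-computed rate via `rate`.
#' @param rate Optional pre-computed background rate in (0,1).
#' @param disease Disease label for the result row.
#' @return One-row data frame: `disease`, `track`, `n_loci`, `observed`,
#'   `background_rate`, `oe`, `p`.
#' @export
oe_enrichment <- function(credible_sets, track, background = NULL,
                          rate = NULL, disease = NA_character_) {
  if (is.null(rate)) rate <- background_rate(background, track)
  if (rate <= 0 || rate >= 1) {
    stop_typed("domain_error",
               "degenerate background rate %.3f for track '%s'", rate, track$name)
  }
  n <- length(credible_sets)
  if (n == 0) stop_typed("domain_error", "no credible sets supplied")
  observed <- sum(vapply(credible_sets, locus_overlaps_track, logical(1),
                         track = track))
  p <- binom_upper_p(observed, n, rate)
  data.frame(disease = disease, track = track$name, n_loci = n,
             observed = observed, background_rate = rate,
             oe = (observed / n) / rate, p = p,
             stringsAsFactors = FALSE)
}

# Upper-tail exact binomial P(X >= observed | n, rate).
binom_upper_p <- function(observed, n, rate) {
  stats::pbinom(observed - 1, n, rate, lower.tail = FALSE)
}

#' Enrichment across diseases and tracks
#'
#' @param credible_sets_by_disease Named list (disease -> list of
#'   `credible_set`s).
#' @param tracks Named list of `annotation_track`s.
#' @param background Background-locus data frame.
#' @param exclude_traits Traits removed from the background before rate
#'   estimation (default none; pass the studied diseases' own traits to
#'   avoid self-overlap).
#' @param bh If `TRUE`, append a Benjamini-Hochberg adjusted `p_bh` column
#'   (off by default; raw binomial p-values are the primary output).
#' @return Data frame with one row per disease x track.
#' @export
enrichment_table <- function(credible_sets_by_disease, tracks, background,
                             exclude_traits = character(0), bh = FALSE) {
  bg <- background[!(background$trait %in% exclude_traits), , drop = FALSE]
  rows <- list()
  for (trk in tracks) {
    rate <- background_rate(bg, trk)
    for (d in names(credible_sets_by_disease)) {
      rows[[length(rows) + 1]] <- oe_enrichment(
        credible_sets_by_disease[[d]], trk, rate = rate, disease = d)
    }
  }
  out <- do.call(rbind, rows)
  if (bh) out$p_bh <- stats::p.adjust(out$p, method = "BH")
  rownames(out) <- NULL
  out
}

#' Per-variant overlap indicators
#'
#' Boolean overlap indicator per credible-set variant per track — the
#' predictor table for the ancestry GLM.
#'
#' @param credible_sets List of `credible_set`s.
#' @param tracks Named list of `annotation_track`s.
#' @param eqtl Optional eQTL data frame (`variant_id`); adds an `eqtl`
#'   indicator (variant has any retained eQTL target).
#' @return Data frame: `variant_id`, one logical column per track (lower
#'   case), optional `eqtl`.
#' @export
variant_overlap_indicators <- function(credible_sets, tracks, eqtl = NULL) {
  v <- do.call(rbind, lapply(credible_sets, credible_variants))
  v <- v[!duplicated(v$variant_id), , drop = FALSE]
  out <- data.frame(variant_id = v$variant_id, stringsAsFactors = FALSE)
  for (nm in names(tracks)) {
    out[[tolower(nm)]] <- points_in_track(v$chrom, v$pos, tracks[[nm]])
  }
  if (!is.null(eqtl)) out$eqtl <- v$variant_id %in% eqtl$variant_id
  rownames(out) <- NULL
  out
}

#' Cell-type specificity folds
#'
#' Compares a reference cell type's overlap count with every other cell
#' type's: fold = reference / other. Zero "other" counts give infinite
#' folds; these are reported in `excluded` and left out of the mean.
#'
#' @param counts_by_cell_type Named numeric vector of overlap counts.
#' @param reference Name of the reference cell type.
#' @return List: `reference_cell`, `fold` (named vector over other cell
#'   types), `mean_fold` (arithmetic mean of finite folds), `excluded`
#'   (cell types with zero counts).
#' @export
specificity_fold <- function(counts_by_cell_type, reference) {
  if (!(reference %in% names(counts_by_cell_type))) {
    stop_typed("domain_error", "reference cell type '%s' not present", reference)
  }
  if (any(counts_by_cell_type < 0)) {
    stop_typed("domain_error", "overlap counts must be >= 0")
  }
  others <- counts_by_cell_type[setdiff(names(counts_by_cell_type), reference)]
  fold <- counts_by_cell_type[[reference]] / others
  excluded <- names(others)[!is.finite(fold)]
  list(reference_cell = reference,
       fold = fold,
       mean_fold = mean(fold[is.finite(fold)]),
       excluded = excluded)
}
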