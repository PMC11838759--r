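#' Read GWAS summary statistics
#'
#' Parses a tab-separated summary-statistics table with a header naming at
#' least `chrom`, `pos`, `risk_allele`, `other_allele`, `beta`, `se`, `p`.
#' Every row is validated; malformed rows raise a line-numbered error rather
#' than being dropped. No significance filtering happens here — locus
#' delineation applies the genome-wide threshold downstream.
#'
#' @param path Path to the tab-separated file. Lines starting with `#` are
#'   treated as comments.
#' @param disease Disease label attached to every record.
#' @param build Genome build carried as metadata (default `"hg19"`).
#' @return A data frame of summary-stat records sorted by (chrom, pos) with
#'   columns `variant_id` (`chrom:pos:risk_allele`), `disease`, `chrom`,
#'   `pos`, `risk_allele`, `other_allele`, `beta`, `se`, `p` and a `build`
#'   attribute.
#' @export
read_summary_stats <- function(path, disease, build = "hg19") {
  if (!file.exists(path)) {
    stop_typed("io_error", "summary-statistics file not found: %s", path)
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("chrom", "pos", "risk_allele", "other_allele", "beta", "se", "p")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_typed("format_error", "summary-statistics file %s is missing column(s): %s",
               path, paste(missing, collapse = ", "))
  }
  validate_summary_stats(df, path)
  out <- data.frame(
    variant_id   = paste(df$chrom, df$pos, df$risk_allele, sep = ":"),
    disease      = disease,
    chrom        = df$chrom,
    pos          = as.integer(df$pos),
    risk_allele  = df$risk_allele,
    other_allele = df$other_allele,
    beta         = as.numeric(df$beta),
    se           = as.numeric(df$se),
    p            = as.numeric(df$p),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(out$variant_id)
  if (any(dup)) {
    stop_typed("format_error", "duplicate variant_id in %s: %s", path,
               paste(unique(out$variant_id[dup]), collapse = ", "))
  }
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "build") <- build
  out
}

# Row-level validation with 1-based data line numbers (header = line 0).
validate_summary_stats <- function(df, path) {
  num <- function(col) suppressWarnings(as.numeric(df[[col]]))
  for (col in c("beta", "se", "p")) {
    bad <- which(is.na(num(col)))
    if (length(bad) > 0) {
      stop_typed("row_error", "%s: non-numeric %s on data line %d",
                 path, col, bad[1])
    }
  }
  pos <- suppressWarnings(as.integer(df$pos))
  if (anyNA(pos)) {
    stop_typed("row_error", "%s: non-integer pos on data line %d",
               path, which(is.na(pos))[1])
  }
  se <- num("se"); p <- num("p")
  if (any(se <= 0)) {
    stop_typed("row_error", "%s: se must be > 0 (data line %d)",
               path, which(se <= 0)[1])
  }
  if (any(p <= 0 | p > 1)) {
    stop_typed("row_error", "%s: p must lie in (0,1] (data line %d)",
               path, which(p <= 0 | p > 1)[1])
  }
  alleles <- c("A", "C", "G", "T")
  bad_allele <- which(!(df$risk_allele %in% alleles) |
                        !(df$other_allele %in% alleles) |
                        df$risk_allele == df$other_allele)
  if (length(bad_allele) > 0) {
    stop_typed("row_error", "%s: invalid allele pair on data line %d",
               path, bad_allele[1])
  }
  invisible(TRUE)
}

#' Write GWAS summary statistics
#'
#' Inverse of [read_summary_stats()]; emits a commented provenance header
#' then the tab-separated table.
#'
#' @param records Data frame from [read_summary_stats()] or the simulator.
#' @param path Output path.
#' @export
write_summary_stats <- function(records, path) {
  cols <- c("chrom", "pos", "risk_allele", "other_allele", "beta", "se", "p")
  write_tsv_commented(records[, cols], path,
                      build = attr(records, "build") %||% "hg19")
}

#' Read a BED annotation track
#'
#' Reads a 3+ column BED file (0-based half-open intervals) into an
#' annotation track.
#'
#' @param path BED file path.
#' @param name Track name (e.g. `"ATAC"`, `"BRU"`, `"HIC_LOOP_END"`).
#' @param build Genome build metadata.
#' @return An `annotation_track` object: list with `name` and an `intervals`
#'   data frame (`chrom`, `start`, `end`, `name`) preserving file order.
#' @export
read_bed <- function(path, name, build = "hg19") {
  if (!file.exists(path)) stop_typed("io_error", "BED file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0) stop_typed("format_error", "BED file %s is empty", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- vapply(fields, length, integer(1))
  if (any(ncols < 3)) {
    stop_typed("format_error", "%s: fewer than 3 columns on line %d",
               path, which(ncols < 3)[1])
  }
  chrom <- vapply(fields, `[`, character(1), 1)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad) > 0) {
    stop_typed("row_error", "%s: non-integer coordinates on line %d", path, bad[1])
  }
  bad <- which(end <= start | start < 0)
  if (length(bad) > 0) {
    stop_typed("row_error",
               "%s: invalid interval on line %d (need 0 <= start < end)",
               path, bad[1])
  }
  iname <- ifelse(ncols >= 4, vapply(fields, function(f) f[4] %||% NA_character_,
                                     character(1)), NA_character_)
  annotation_track(name,
                   data.frame(chrom = chrom, start = start, end = end,
                              name = iname, stringsAsFactors = FALSE),
                   build = build)
}

#' Construct an annotation track
#'
#' @param name Track name.
#' @param intervals Data frame with `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `name`.
#' @param build Genome build metadata.
#' @export
annotation_track <- function(name, intervals, build = "hg19") {
  stopifnot(is.character(name), length(name) == 1L)
  if (!all(c("chrom", "start", "end") %in% names(intervals))) {
    stop_typed("format_error", "intervals need chrom, start, end columns")
  }
  if (nrow(intervals) == 0) {
    stop_typed("domain_error", "annotation track '%s' must be non-empty", name)
  }
  if (any(intervals$end <= intervals$start)) {
    stop_typed("domain_error", "track '%s' has empty/inverted interval(s)", name)
  }
  if (is.null(intervals$name)) intervals$name <- NA_character_
  structure(list(name = name,
                 intervals = intervals[, c("chrom", "start", "end", "name")],
                 build = build),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("annotation_track '%s': %d intervals on %d chromosome(s) [%s]\n",
              x$name, nrow(x$intervals),
              length(unique(x$intervals$chrom)), x$build))
  invisible(x)
}

# GRanges view of a track: BED half-open [start,end) -> 1-based closed
# [start+1, end], so a 1-based point q overlaps iff start < q <= end.
track_granges <- function(track) {
  GenomicRanges::GRanges(
    seqnames = norm_chrom(track$intervals$chrom),
    ranges = IRanges::IRanges(start = track$intervals$start + 1L,
                              end = track$intervals$end)
  )
}

#' Write an annotation track as BED
#'
#' @param track An `annotation_track`.
#' @param path Output path. BED has no header; coordinates are written back
#'   0-based half-open exactly as stored.
#' @export
write_bed <- function(track, path) {
  iv <- track$intervals
  has_name <- !all(is.na(iv$name))
  cols <- if (has_name) iv[, c("chrom", "start", "end", "name")]
          else iv[, c("chrom", "start", "end")]
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an eQTL variant-gene table
#'
#' Reads tab-separated (`variant_id`, `gene`, `p`) rows and applies the
#' nominal-significance filter: only rows with `p < p_max` are retained
#' (strict inequality).
#'
#' @param path File path.
#' @param p_max Retention threshold (default 0.05).
#' @return Data frame of retained records; the number dropped is reported
#'   via `message()`.
#' @export
read_eqtl_table <- function(path, p_max = 0.05) {
  if (!file.exists(path)) stop_typed("io_error", "eQTL file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    warning("eQTL table ", path, " is empty")
    return(data.frame(variant_id = character(), gene = character(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  required <- c("variant_id", "gene", "p")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_typed("format_error", "eQTL file %s is missing column(s): %s",
               path, paste(missing, collapse = ", "))
  }
  p <- suppressWarnings(as.numeric(df$p))
  if (anyNA(p)) {
    stop_typed("row_error", "%s: malformed p on data line %d",
               path, which(is.na(p))[1])
  }
  keep <- p < p_max
  message(sprintf("eQTL table %s: retained %d of %d rows at p < %g",
                  path, sum(keep), nrow(df), p_max))
  out <- df[keep, required, drop = FALSE]
  out$p <- p[keep]
  rownames(out) <- NULL
  out
}

#' Read a background trait-locus catalogue
#'
#' Tab-separated (`trait`, `chrom`, `pos`, `p`) table of trait-associated
#' best-signal positions (points, not intervals), as used for the
#' observed/expected enrichment background.
#'
#' @param path File path.
#' @param p_threshold Optional p-value restriction applied before collapsing
#'   (default `NULL`, no restriction).
#' @param collapse If `TRUE` (default), collapse to one best-signal row per
#'   trait-locus using distance-based merging (same 500 kb rule as disease
#'   loci).
#' @param merge_dist Merge distance in bp for collapsing.
#' @export
read_background_loci <- function(path, p_threshold = NULL, collapse = TRUE,
                                 merge_dist = 500000L) {
  if (!file.exists(path)) stop_typed("io_error", "background file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("trait", "chrom", "pos", "p")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_typed("format_error", "background file %s is missing column(s): %s",
               path, paste(missing, collapse = ", "))
  }
  df$pos <- as.integer(df$pos)
  df$p <- as.numeric(df$p)
  if (!is.null(p_threshold)) df <- df[df$p < p_threshold, , drop = FALSE]
  if (collapse) df <- collapse_background(df, merge_dist = merge_dist)
  rownames(df) <- NULL
  df
}

#' Collapse a trait catalogue to best-signal loci
#'
#' Within each trait and chromosome, variants within `merge_dist` of one
#' another (single linkage, gap `<= merge_dist` merges) are considered the
#' same locus and only the smallest-p row is kept.
#'
#' @param df Data frame with `trait`, `chrom`, `pos`, `p`.
#' @param merge_dist Merge distance in bp.
#' @export
collapse_background <- function(df, merge_dist = 500000L) {
  if (nrow(df) == 0) return(df)
  pieces <- split(df, list(df$trait, df$chrom), drop = TRUE)
  best <- lapply(pieces, function(g) {
    g <- g[order(g$pos), , drop = FALSE]
    cl <- cluster_positions(g$pos, merge_dist)
    do.call(rbind, lapply(split(g, cl), function(h) {
      h[order(h$p, h$pos), , drop = FALSE][1, , drop = FALSE]
    }))
  })
  out <- do.call(rbind, best)
  out <- out[order(out$trait, out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Single-linkage 1-d clustering: sorted positions; a gap > merge_dist opens
# a new cluster (gap exactly merge_dist merges).
cluster_positions <- function(pos, merge_dist) {
  stopifnot(!is.unsorted(pos))
  if (length(pos) == 0) return(integer(0))
  c(0L, cumsum(diff(pos) > merge_dist)) + 1L
}

#' Read gene sets in GMT format
#'
#' GMT dialect: one set per line — set name, description, then tab-separated
#' gene symbols.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of gene symbols.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop_typed("io_error", "GMT file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3)
  if (length(bad) > 0) {
    stop_typed("format_error", "%s: GMT line %d has fewer than 3 fields",
               path, bad[1])
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[`, character(1), 1)
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
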