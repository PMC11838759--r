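#' Binned-control module score
#'
#' Scores a gene module against expression-matched controls: genes are
#' binned into `n_bins` of equal size by their average expression across
#' all columns; for every module gene, `n_ctrl` control genes are sampled
#' from the same bin (module genes excluded; with replacement when the bin
#' holds fewer than `n_ctrl` candidates). The per-column score is the mean
#' expression of the module genes minus the mean expression of the pooled
#' control draw, so a module behaving like expression-matched background
#' scores ~0.
#'
#' @param mat Numeric matrix, genes x samples (or cells), non-negative,
#'   with unique rownames.
#' @param module_genes Character vector; at least one must be present in
#'   `mat` (absent genes are dropped with a warning).
#' @param n_bins Number of average-expression bins (default 24; reduced
#'   when there are fewer non-module genes than bins).
#' @param n_ctrl Control genes sampled per module gene (default 100).
#' @param seed Optional integer seed for the control draw.
#' @return Named numeric vector of per-column scores.
#' @export
module_score <- function(mat, module_genes, n_bins = 24L, n_ctrl = 100L,
                         seed = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (any(mat < 0)) stop_typed("domain_error", "expression values must be >= 0")
  if (anyDuplicated(rownames(mat))) {
    stop_typed("domain_error", "gene ids must be unique")
  }
  present <- intersect(module_genes, rownames(mat))
  if (length(present) == 0) {
    stop_typed("domain_error", "no module gene present in the matrix")
  }
  if (length(present) < length(module_genes)) {
    warning(length(module_genes) - length(present),
            " module gene(s) absent from the matrix; dropped")
  }
  if (!is.null(seed)) set.seed(seed)
  avg <- rowMeans(mat)
  n_bins <- max(1L, min(n_bins, nrow(mat)))
  # equal-size bins on the rank of average expression (ties broken stably)
  bin <- ceiling(rank(avg, ties.method = "first") / (nrow(mat) / n_bins))
  bin <- pmin(pmax(bin, 1L), n_bins)
  names(bin) <- rownames(mat)
  ctrl <- character(0)
  for (g in present) {
    pool <- sort(setdiff(names(bin)[bin == bin[[g]]], module_genes))
    if (length(pool) == 0) pool <- sort(names(bin)[bin == bin[[g]]])  # module-only bin
    ctrl <- c(ctrl, sample(pool, n_ctrl, replace = length(pool) < n_ctrl))
  }
  module_mean <- colMeans(mat[present, , drop = FALSE])
  ctrl_mean <- colMeans(mat[ctrl, , drop = FALSE])
  module_mean - ctrl_mean
}

#' Group fold change for one gene
#'
#' Ratio of pseudocounted group means with a two-sided Wilcoxon rank-sum
#' p-value across columns — e.g. lesional versus non-lesional expression
#' of one gene.
#'
#' @param mat Genes x samples matrix.
#' @param gene Gene id (rowname).
#' @param labels Per-column group labels.
#' @param label_a,label_b The two groups compared (fold = a over b).
#' @param pseudocount Added before the ratio (default 1).
#' @return List `fc`, `p`.
#' @export
group_fold_change <- function(mat, gene, labels, label_a, label_b,
                              pseudocount = 1) {
  if (!(gene %in% rownames(mat))) {
    stop_typed("domain_error", "gene '%s' absent from the matrix", gene)
  }
  stopifnot(length(labels) == ncol(mat))
  xa <- mat[gene, labels == label_a]
  xb <- mat[gene, labels == label_b]
  if (length(xa) == 0 || length(xb) == 0) {
    stop_typed("domain_error", "empty group ('%s' or '%s')", label_a, label_b)
  }
  fc <- (mean(xa) + pseudocount) / (mean(xb) + pseudocount)
  p <- suppressWarnings(stats::wilcox.test(xa, xb, exact = FALSE)$p.value)
  if (is.nan(p)) p <- 1  # all values tied: no evidence of a shift
  list(fc = fc, p = p)
}

#' Stimulation-response contrast between donor groups
#'
#' From a paired stimulated/unstimulated long table (one pair per donor),
#' computes per-gene per-donor log2 fold changes (pseudocounted), selects
#' the induced gene set — geometric-mean fold change strictly above
#' `fc_min` and Benjamini-Hochberg FDR at most `fdr_max` from a per-gene
#' paired t-test on log2 values — and correlates, over induced genes, the
#' group difference in mean response (`mu_A - mu_B`) with the average
#' response (`(mu_A + mu_B)/2`) by Pearson correlation.
#'
#' @param tbl Long data frame (`gene`, `donor`, `group`, `condition`,
#'   `count`) with conditions `"stim"` and `"unstim"`, groups `"A"`/`"B"`.
#' @param fc_min Induction threshold on the fold-change scale (strict >).
#' @param fdr_max BH FDR cut-off (inclusive <=).
#' @param pseudocount Added to counts before ratios.
#' @param log2fc If `TRUE` (default) correlate log2 fold changes; `FALSE`
#'   uses raw fold changes.
#' @return List: `responses` (per-gene data frame with `mean_fc`, `p`,
#'   `fdr`, `mu_a`, `mu_b`, `avg`, `diff`, `induced`), `induced` (gene
#'   ids), `pearson_r`, `pearson_p` (both `NA` with a warning when fewer
#'   than 3 induced genes).
#' @export
stimulation_contrast <- function(tbl, fc_min = 1.5, fdr_max = 0.10,
                                 pseudocount = 1, log2fc = TRUE) {
  needed <- c("gene", "donor", "group", "condition", "count")
  stopifnot(all(needed %in% names(tbl)))
  donors <- unique(tbl[, c("donor", "group")])
  if (min(table(donors$group)) < 2) {
    stop_typed("domain_error", "need >= 2 donors per group")
  }
  stim <- tbl[tbl$condition == "stim", ]
  unstim <- tbl[tbl$condition == "unstim", ]
  key <- function(d) paste(d$gene, d$donor, sep = "\r")
  idx <- match(key(stim), key(unstim))
  if (anyNA(idx)) {
    stop_typed("domain_error", "unpaired stimulated/unstimulated sample(s)")
  }
  lfc <- data.frame(
    gene = stim$gene, donor = stim$donor, group = stim$group,
    l2fc = log2((stim$count + pseudocount) / (unstim$count[idx] + pseudocount)),
    stringsAsFactors = FALSE)

  genes <- unique(lfc$gene)
  per_gene <- lapply(split(lfc, lfc$gene), function(g) {
    # paired test: one-sample t on per-donor log2FC; a zero-variance gene
    # (identical ratio in every donor) is degenerate — call it p = 0 when
    # shifted, p = 1 when flat
    tt <- tryCatch(stats::t.test(g$l2fc),
                   error = function(e) {
                     list(p.value = if (abs(mean(g$l2fc)) > 0) 0 else 1)
                   })
    mu_a <- mean(g$l2fc[g$group == "A"]); mu_b <- mean(g$l2fc[g$group == "B"])
    data.frame(gene = g$gene[1],
               mean_l2fc = mean(g$l2fc),
               mean_fc = 2^mean(g$l2fc),
               p = tt$p.value,
               mu_a = mu_a, mu_b = mu_b,
               avg = (mu_a + mu_b) / 2, diff = mu_a - mu_b,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, per_gene)
  res <- res[match(genes, res$gene), , drop = FALSE]
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$induced <- res$mean_fc > fc_min & res$fdr <= fdr_max
  rownames(res) <- NULL

  ind <- res[res$induced, , drop = FALSE]
  if (!log2fc) {
    ind$avg <- (2^ind$mu_a + 2^ind$mu_b) / 2
    ind$diff <- 2^ind$mu_a - 2^ind$mu_b
  }
  if (nrow(ind) < 3) {
    warning("fewer than 3 induced genes; correlation undefined")
    r <- NA_real_; pr <- NA_real_
  } else {
    ct <- stats::cor.test(ind$diff, ind$avg, method = "pearson")
    r <- unname(ct$estimate); pr <- ct$p.value
  }
  list(responses = res, induced = res$gene[res$induced],
       pearson_r = r, pearson_p = pr)
}

#' Read a genes x samples expression matrix
#'
#' Tab-separated, first column gene ids, remaining columns samples.
#'
#' @param path File path.
#' @return Numeric matrix with gene rownames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop_typed("io_error", "matrix file not found: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}
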