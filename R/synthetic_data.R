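#' Simulation configuration
#'
#' Validated parameter bundle for the synthetic study generator. The
#' defaults emulate the scale of the source study design: seven diseases,
#' distance-separated loci with a single causal variant each, case/control
#' GWAS with tens of thousands of samples, an African/European-ancestry
#' split with FST around 0.1, and annotation tracks whose causal-variant
#' coverage can be planted above the background rate.
#'
#' @param n_diseases Number of diseases simulated.
#' @param loci_per_disease Loci per disease.
#' @param variants_per_locus Candidate variants per locus.
#' @param n_cases,n_controls GWAS sample sizes.
#' @param fst Between-ancestry-group divergence in (0,1).
#' @param causal_beta Log-odds effect of the causal risk allele.
#' @param annotation_overlap_prob_null Coverage probability for non-causal
#'   variants and background loci.
#' @param annotation_overlap_prob_enriched Coverage probability for causal
#'   variants on enriched tracks.
#' @param seed Integer seed; fully determines all output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_diseases = 7L,
                       loci_per_disease = 37L,
                       variants_per_locus = 25L,
                       n_cases = 10000L,
                       n_controls = 20000L,
                       fst = 0.1,
                       causal_beta = 0.25,
                       annotation_overlap_prob_null = 0.2,
                       annotation_overlap_prob_enriched = 0.6,
                       seed = 1L) {
  stopifnot(n_diseases >= 1, loci_per_disease >= 1, variants_per_locus >= 1,
            n_cases >= 1, n_controls >= 1)
  assert_prob(fst, "fst")
  assert_prob(annotation_overlap_prob_null, "annotation_overlap_prob_null")
  assert_prob(annotation_overlap_prob_enriched, "annotation_overlap_prob_enriched")
  structure(list(
    n_diseases = as.integer(n_diseases),
    loci_per_disease = as.integer(loci_per_disease),
    variants_per_locus = as.integer(variants_per_locus),
    n_cases = as.integer(n_cases),
    n_controls = as.integer(n_controls),
    fst = fst,
    causal_beta = causal_beta,
    annotation_overlap_prob_null = annotation_overlap_prob_null,
    annotation_overlap_prob_enriched = annotation_overlap_prob_enriched,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Balding-Nichols population allele frequencies
#'
#' Draws per-population allele frequencies around an ancestral frequency
#' under the Balding-Nichols model: each population frequency is Beta with
#' mean `p_anc` and shapes `(p_anc (1-fst)/fst, (1-p_anc)(1-fst)/fst)`, so
#' the between-population variance is `fst * p_anc * (1 - p_anc)`. Values
#' are clipped to `[1/(2N), 1 - 1/(2N)]` with N = 5000 to keep frequencies
#' polymorphic.
#'
#' @param p_anc Ancestral frequency (vectorised), each in (0,1).
#' @param fst Divergence parameter in (0,1).
#' @param n_pops Populations to draw per ancestral frequency.
#' @return A matrix with `length(p_anc)` rows and `n_pops` columns.
#' @export
simulate_population_freqs <- function(p_anc, fst, n_pops = 2L) {
  assert_prob(p_anc, "p_anc")
  assert_prob(fst, "fst")
  k <- (1 - fst) / fst
  m <- matrix(stats::rbeta(length(p_anc) * n_pops,
                           shape1 = rep(p_anc * k, n_pops),
                           shape2 = rep((1 - p_anc) * k, n_pops)),
              nrow = length(p_anc), ncol = n_pops)
  eps <- 1 / (2 * 5000)
  pmin(pmax(m, eps), 1 - eps)
}

#' Simulate GWAS summary statistics with planted causal variants
#'
#' Generates, per disease, distance-separated loci each carrying one causal
#' variant with log-odds effect `causal_beta`. Non-causal variants are LD
#' proxies with correlation `r` drawn uniform on \[0.2, 0.95\]; their
#' expected marginal z-score is attenuated as `r * z_causal` (equivalently
#' `beta_j = r_j * beta_c * se_j / se_c`), and the noise on their z-scores
#' is correlated `r` with the causal variant's noise — the standard
#' marginal-statistics model for single-causal loci under LD. Standard
#' errors follow the additive log-odds approximation
#' `se = sqrt(1 / (2 n_eff p (1 - p)))` with
#' `n_eff = n_cases n_controls / (n_cases + n_controls)`; p-values are
#' two-sided Wald.
#'
#' Loci are placed 2 Mb apart (well beyond the 500 kb merge distance) on
#' autosomes other than chromosome 6, so the MHC exclusion never removes a
#' planted locus; within-locus variants span a 200 kb window.
#'
#' @param cfg A [sim_config()].
#' @return List with `stats` (summary-stat data frame across diseases, with
#'   `locus_id`), `truth` (list: `causal` data frame, `freqs` per-variant
#'   ancestral and group frequencies, `enriched_tracks`).
#' @export
simulate_summary_stats <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  neff <- as.numeric(cfg$n_cases) * as.numeric(cfg$n_controls) /
    (as.numeric(cfg$n_cases) + as.numeric(cfg$n_controls))
  chroms <- paste0("chr", setdiff(1:22, 6))
  m <- cfg$variants_per_locus
  rows <- list(); causal_rows <- list()
  alleles <- c("A", "C", "G", "T")
  for (d in seq_len(cfg$n_diseases)) {
    disease <- sprintf("disease%02d", d)
    for (l in seq_len(cfg$loci_per_disease)) {
      chrom <- chroms[((l - 1) %% length(chroms)) + 1]
      base <- 1e6 + ((l - 1) %/% length(chroms)) * 2e6 + (d - 1) * 5e5
      pos <- sort(sample(seq.int(base, base + 2e5), m))
      p_anc <- stats::runif(m, 0.05, 0.95)
      se <- sqrt(1 / (2 * neff * p_anc * (1 - p_anc)))
      ci <- sample.int(m, 1)
      r <- stats::runif(m, 0.2, 0.95); r[ci] <- 1
      true_beta <- r * cfg$causal_beta * se / se[ci]
      eps_c <- stats::rnorm(1); eps_i <- stats::rnorm(m)
      z_noise <- r * eps_c + sqrt(1 - r^2) * eps_i
      beta_obs <- true_beta + se * z_noise
      pval <- 2 * stats::pnorm(-abs(beta_obs / se))
      pval <- pmax(pval, .Machine$double.xmin)
      ra <- sample(alleles, m, replace = TRUE)
      oa <- vapply(ra, function(a) sample(setdiff(alleles, a), 1), character(1))
      locus_id <- sprintf("%s_L%03d", disease, l)
      df <- data.frame(
        variant_id = paste(chrom, pos, ra, sep = ":"),
        disease = disease, locus_id = locus_id,
        chrom = chrom, pos = pos,
        risk_allele = ra, other_allele = oa,
        beta = beta_obs, se = se, p = pval,
        p_anc = p_anc, ld_r = r,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1]] <- df
      causal_rows[[length(causal_rows) + 1]] <- data.frame(
        disease = disease, locus_id = locus_id,
        variant_id = df$variant_id[ci], stringsAsFactors = FALSE
      )
    }
  }
  stats <- do.call(rbind, rows)
  rownames(stats) <- NULL
  attr(stats, "build") <- "hg19"
  # Group-level frequencies: ancestry-group ancestral freq drawn at the
  # configured FST, then five constituent populations at low within-group
  # divergence, aggregated by unweighted mean (as downstream expects).
  pops <- simulate_population_freqs(stats$p_anc, cfg$fst, n_pops = 2L)
  within <- 0.02
  afr_pops <- simulate_population_freqs(pops[, 1], within, n_pops = 5L)
  eur_pops <- simulate_population_freqs(pops[, 2], within, n_pops = 5L)
  freqs <- data.frame(
    variant_id = stats$variant_id,
    p_anc = stats$p_anc,
    raf_afr = rowMeans(afr_pops),
    raf_eur = rowMeans(eur_pops),
    n_pops_afr = 5L, n_pops_eur = 5L,
    stringsAsFactors = FALSE
  )
  truth <- list(
    causal = do.call(rbind, causal_rows),
    freqs = freqs,
    enriched_tracks = c("ATAC", "BRU")
  )
  list(stats = stats, truth = truth)
}

#' Simulate annotation tracks with controllable overlap rates
#'
#' For tracks named in `truth$enriched_tracks`, each planted causal variant
#' is covered by an interval with probability
#' `annotation_overlap_prob_enriched`; every other variant and every
#' background-locus position is covered with probability
#' `annotation_overlap_prob_null`. Covering intervals are 200-1000 bp
#' windows containing the variant.
#'
#' @param stats Summary-stat data frame from [simulate_summary_stats()].
#' @param truth Matching ground-truth list.
#' @param cfg The [sim_config()] used.
#' @param background Optional background-locus data frame (`chrom`, `pos`)
#'   whose positions are covered at the null rate.
#' @param track_names Track names to generate.
#' @return Named list of `annotation_track` objects (a track with no drawn
#'   intervals is dropped with a warning).
#' @export
simulate_annotation_tracks <- function(stats, truth, cfg, background = NULL,
                                       track_names = c("ATAC", "BRU", "HIC_LOOP_END")) {
  if (nrow(stats) == 0) return(stats::setNames(list(), character(0)))
  is_causal <- stats$variant_id %in% truth$causal$variant_id
  pts <- data.frame(chrom = stats$chrom, pos = stats$pos, causal = is_causal,
                    stringsAsFactors = FALSE)
  if (!is.null(background) && nrow(background) > 0) {
    pts <- rbind(pts, data.frame(chrom = background$chrom, pos = background$pos,
                                 causal = FALSE, stringsAsFactors = FALSE))
  }
  tracks <- list()
  for (nm in track_names) {
    p_cov <- ifelse(pts$causal & nm %in% truth$enriched_tracks,
                    cfg$annotation_overlap_prob_enriched,
                    cfg$annotation_overlap_prob_null)
    covered <- stats::runif(nrow(pts)) < p_cov
    if (!any(covered)) {
      warning("track ", nm, ": no intervals drawn; track omitted")
      next
    }
    width <- sample(200:1000, sum(covered), replace = TRUE)
    offset <- vapply(width, function(w) sample.int(w, 1) - 1L, integer(1))
    start1 <- pts$pos[covered] - offset               # 1-based inclusive start
    iv <- data.frame(chrom = pts$chrom[covered],
                     start = pmax(start1 - 1L, 0L),   # 0-based half-open
                     end = pmax(start1 - 1L, 0L) + width,
                     name = NA_character_, stringsAsFactors = FALSE)
    tracks[[nm]] <- annotation_track(nm, iv)
  }
  tracks
}

#' Simulate a background trait-locus catalogue
#'
#' Best-signal point positions for `n_traits` pseudo-traits, spaced so that
#' loci within a trait never fall within the 500 kb merge distance.
#'
#' @param n_traits Number of traits.
#' @param loci_per_trait Loci per trait.
#' @return Data frame (`trait`, `chrom`, `pos`, `p`).
#' @export
simulate_background_loci <- function(n_traits = 50L, loci_per_trait = 8L) {
  chroms <- paste0("chr", setdiff(1:22, 6))
  rows <- lapply(seq_len(n_traits), function(t) {
    chrom <- sample(chroms, loci_per_trait, replace = TRUE)
    data.frame(trait = sprintf("trait%03d", t),
               chrom = chrom,
               pos = as.integer(stats::runif(loci_per_trait, 1e6, 5e7)),
               p = 10^stats::runif(loci_per_trait, -30, -8),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate an eQTL variant-gene table
#'
#' Each queried variant targets 0-3 genes; variants listed in
#' `planted_variants` draw their targets from `planted_genes`, everything
#' else from the remaining gene pool. All emitted p-values pass the nominal
#' p < 0.05 filter.
#'
#' @param variant_ids Character vector of variants to consider.
#' @param genes Gene universe to sample targets from.
#' @param prob_target Probability a variant has any eQTL target.
#' @param planted_variants,planted_genes Optional planted association.
#' @return Data frame (`variant_id`, `gene`, `p`).
#' @export
simulate_eqtl_table <- function(variant_ids, genes, prob_target = 0.3,
                                planted_variants = character(0),
                                planted_genes = character(0)) {
  rows <- list()
  other_genes <- setdiff(genes, planted_genes)
  for (v in variant_ids) {
    if (stats::runif(1) >= prob_target) next
    n_targets <- sample(1:3, 1)
    pool <- if (v %in% planted_variants && length(planted_genes) > 0)
      planted_genes else other_genes
    targets <- sample(pool, min(n_targets, length(pool)))
    rows[[length(rows) + 1]] <- data.frame(
      variant_id = v, gene = targets,
      p = stats::runif(length(targets), 1e-8, 0.049),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(variant_id = character(), gene = character(),
                      p = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a paired stimulation experiment
#'
#' Emulates a cytokine-stimulation design: per donor, an unstimulated and a
#' stimulated sample over `n_genes` genes with log-normal baseline counts.
#' Genes listed in `planted` are multiplied, in the stimulated condition,
#' by a group-specific fold change.
#'
#' @param n_genes Number of genes.
#' @param n_donors_per_group Donors in each of groups `"A"` and `"B"`.
#' @param planted Optional data frame (`gene` index or name, `fc_a`, `fc_b`).
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline parameters.
#' @param noise_sdlog Multiplicative measurement noise (sd on the log scale).
#' @return Long data frame (`gene`, `donor`, `group`, `condition`, `count`).
#' @export
simulate_stimulation_matrix <- function(n_genes, n_donors_per_group,
                                        planted = NULL,
                                        baseline_meanlog = log(100),
                                        baseline_sdlog = 1,
                                        noise_sdlog = 0.15) {
  if (n_donors_per_group < 1) {
    stop_typed("domain_error", "n_donors_per_group must be >= 1")
  }
  genes <- sprintf("gene%04d", seq_len(n_genes))
  fc <- matrix(1, nrow = n_genes, ncol = 2,
               dimnames = list(genes, c("A", "B")))
  if (!is.null(planted) && nrow(planted) > 0) {
    idx <- if (is.numeric(planted$gene)) planted$gene
           else match(planted$gene, genes)
    fc[idx, "A"] <- planted$fc_a
    fc[idx, "B"] <- planted$fc_b
  }
  base <- stats::rlnorm(n_genes, baseline_meanlog, baseline_sdlog)
  rows <- list()
  for (grp in c("A", "B")) {
    for (d in seq_len(n_donors_per_group)) {
      donor <- sprintf("%s%02d", grp, d)
      donor_eff <- stats::rlnorm(1, 0, 0.1)
      for (cond in c("unstim", "stim")) {
        mult <- if (cond == "stim") fc[, grp] else rep(1, n_genes)
        count <- base * donor_eff * mult *
          stats::rlnorm(n_genes, 0, noise_sdlog)
        rows[[length(rows) + 1]] <- data.frame(
          gene = genes, donor = donor, group = grp, condition = cond,
          count = count, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a complete synthetic input bundle
#'
#' Generates every input the pipeline consumes — per-disease summary
#' statistics, ancestry risk-allele-frequency table, annotation-track BEDs,
#' background trait catalogue, eQTL table, gene sets (GMT), a paired
#' stimulation table — plus `ground_truth.json`, into `dir`.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the ground-truth list.
#' @export
simulate_bundle <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_summary_stats(cfg)
  stats <- sim$stats; truth <- sim$truth

  for (d in unique(stats$disease)) {
    sub <- stats[stats$disease == d, ]
    write_summary_stats(sub, file.path(dir, paste0(d, "_sumstats.tsv")))
  }
  raf <- merge(truth$freqs,
               stats[, c("variant_id", "disease")], by = "variant_id")
  write_tsv_commented(
    raf[, c("variant_id", "raf_afr", "raf_eur", "n_pops_afr", "n_pops_eur")],
    file.path(dir, "ancestry_raf.tsv"))

  background <- simulate_background_loci()
  write_tsv_commented(background, file.path(dir, "background_loci.tsv"))

  tracks <- simulate_annotation_tracks(stats, truth, cfg, background = background)
  for (nm in names(tracks)) {
    write_bed(tracks[[nm]], file.path(dir, paste0(tolower(nm), ".bed")))
  }

  genes <- sprintf("GENE%03d", 1:200)
  planted_genes <- genes[1:15]
  causal_afr <- truth$causal$variant_id[
    truth$causal$variant_id %in%
      truth$freqs$variant_id[truth$freqs$raf_afr > truth$freqs$raf_eur]]
  eqtl <- simulate_eqtl_table(stats$variant_id, genes,
                              planted_variants = causal_afr,
                              planted_genes = planted_genes)
  write_tsv_commented(eqtl, file.path(dir, "eqtl.tsv"))

  sets <- list(planted_set = planted_genes,
               random_set_a = sample(genes, 20),
               random_set_b = sample(genes, 30))
  write_gmt(sets, file.path(dir, "gene_sets.gmt"))

  stim_planted <- data.frame(gene = 1:15,
                             fc_a = stats::runif(15, 2, 6),
                             fc_b = stats::runif(15, 1.5, 4))
  stim <- simulate_stimulation_matrix(200, 5, planted = stim_planted)
  write_tsv_commented(stim, file.path(dir, "stimulation.tsv"))

  jsonlite::write_json(
    list(causal = truth$causal,
         enriched_tracks = truth$enriched_tracks,
         planted_genes = planted_genes,
         seed = cfg$seed),
    file.path(dir, "ground_truth.json"),
    dataframe = "columns", auto_unbox = FALSE, digits = NA)
  invisible(truth)
}
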