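#' Pipeline configuration
#'
#' Bundles the input directory, output directory and every stage threshold
#' into one validated, serialisable list.
#'
#' @param input_dir Directory holding the inputs ([simulate_bundle()]
#'   layout: `*_sumstats.tsv`, `ancestry_raf.tsv`, `*.bed`,
#'   `background_loci.tsv`, `eqtl.tsv`, `gene_sets.gmt`,
#'   `stimulation.tsv`).
#' @param out_dir Run directory for stage tables, `summary.json` and the
#'   run log.
#' @param p_threshold Genome-wide significance threshold.
#' @param merge_dist Locus merge distance (bp).
#' @param prior_w Wakefield prior variance.
#' @param coverage Credible-set coverage target.
#' @param eqtl_p eQTL nominal-significance threshold.
#' @param fc_min,fdr_max Stimulation-contrast induction thresholds.
#' @param mhc MHC exclusion interval (`list(chrom, start, end)` or `NULL`).
#' @param seed Integer seed used for any stage randomness.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input_dir, out_dir,
                            p_threshold = 5e-8, merge_dist = 500000L,
                            prior_w = 0.04, coverage = 0.95,
                            eqtl_p = 0.05, fc_min = 1.5, fdr_max = 0.10,
                            mhc = list(chrom = "chr6", start = 25e6, end = 34e6),
                            seed = 1L) {
  stopifnot(p_threshold > 0, p_threshold < 1, merge_dist > 0, prior_w > 0)
  assert_prob(coverage, "coverage")
  assert_prob(eqtl_p, "eqtl_p")
  stopifnot(fc_min > 0)
  assert_prob(fdr_max, "fdr_max", open_right = FALSE)
  structure(list(input_dir = input_dir, out_dir = out_dir,
                 p_threshold = p_threshold, merge_dist = as.integer(merge_dist),
                 prior_w = prior_w, coverage = coverage, eqtl_p = eqtl_p,
                 fc_min = fc_min, fdr_max = fdr_max, mhc = mhc,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Polynomial rolling hash of the serialised config, for run-log provenance.
config_hash <- function(cfg) {
  json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(json))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop_typed("stage_error", "stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage over a self-contained input directory: fine-mapping
#' (locus delineation + credible sets) per disease, observed/expected
#' annotation enrichment against the background catalogue, ancestry
#' risk-allele-frequency flags and proportions, the joint and marginal
#' annotation GLMs, gene-set enrichment of eQTL targets, and the
#' stimulation contrast. Stage tables are written as commented TSVs under
#' `out_dir`, with a machine-readable `summary.json` and a `run.log`
#' recording the package version, seed and a config hash. The run is
#' deterministic given (inputs, config, seed).
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, the summary list.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  logf <- file.path(cfg$out_dir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat(sprintf("isdreg %s | seed %d | config %s\n",
              as.character(utils::packageVersion("isdreg")),
              cfg$seed, config_hash(cfg)), file = logf)

  need <- function(fname) {
    path <- file.path(cfg$input_dir, fname)
    if (!file.exists(path)) {
      stop_typed("stage_error", "stage 'inputs' failed: missing file %s", path)
    }
    path
  }

  ## inputs ----
  ss_files <- list.files(cfg$input_dir, pattern = "_sumstats\\.tsv$",
                         full.names = TRUE)
  if (length(ss_files) == 0) {
    stop_typed("stage_error", "stage 'inputs' failed: no *_sumstats.tsv in %s",
               cfg$input_dir)
  }
  diseases <- sub("_sumstats\\.tsv$", "", basename(ss_files))
  stats_by_disease <- run_stage("inputs", {
    stats::setNames(Map(read_summary_stats, ss_files, diseases), diseases)
  })
  raf <- run_stage("inputs", read_tsv_commented(need("ancestry_raf.tsv")))
  background <- run_stage("inputs",
                          read_background_loci(need("background_loci.tsv")))
  bed_files <- list.files(cfg$input_dir, pattern = "\\.bed$", full.names = TRUE)
  tracks <- run_stage("inputs", {
    nms <- toupper(sub("\\.bed$", "", basename(bed_files)))
    stats::setNames(Map(read_bed, bed_files, nms), nms)
  })
  eqtl <- run_stage("inputs", read_eqtl_table(need("eqtl.tsv"), cfg$eqtl_p))
  sets <- run_stage("inputs", read_gmt(need("gene_sets.gmt")))
  stim <- run_stage("inputs", read_tsv_commented(need("stimulation.tsv")))
  logline("inputs: %d disease(s), %d track(s), %d background loci, %d eQTL rows",
          length(diseases), length(tracks), nrow(background), nrow(eqtl))

  ## finemap ----
  cs_by_disease <- run_stage("finemap", {
    lapply(stats_by_disease, finemap_disease,
           p_threshold = cfg$p_threshold, merge_dist = cfg$merge_dist,
           mhc = cfg$mhc, coverage_target = cfg$coverage,
           prior_w = cfg$prior_w)
  })
  cs_tab <- do.call(rbind, lapply(cs_by_disease, credible_set_table))
  rownames(cs_tab) <- NULL
  write_tsv_commented(cs_tab, file.path(cfg$out_dir, "credible_sets.tsv"))
  counts <- data.frame(
    disease = names(cs_by_disease),
    n_loci = vapply(cs_by_disease, length, integer(1)),
    n_bci_variants = vapply(cs_by_disease, function(css) {
      sum(vapply(css, function(cs) sum(cs$entries$in_set), integer(1)))
    }, integer(1)),
    stringsAsFactors = FALSE)
  rownames(counts) <- NULL
  logline("finemap: %d loci, %d credible variants total",
          sum(counts$n_loci), sum(counts$n_bci_variants))

  ## enrichment ----
  enrich <- run_stage("enrichment",
                      enrichment_table(cs_by_disease, tracks, background))
  write_tsv_commented(enrich, file.path(cfg$out_dir, "enrichment.tsv"))

  ## ancestry ----
  flags <- run_stage("ancestry", flag_raf_direction(raf))
  props_v <- run_stage("ancestry",
                       raf_proportions(flags, cs_by_disease, unit = "variant"))
  props_l <- run_stage("ancestry",
                       raf_proportions(flags, cs_by_disease, unit = "locus"))
  props_v$unit <- "variant"; props_l$unit <- "locus"
  props <- rbind(props_v, props_l)
  write_tsv_commented(props, file.path(cfg$out_dir, "raf_proportions.tsv"))

  all_cs <- unlist(cs_by_disease, recursive = FALSE)
  indicators <- run_stage("glm",
                          variant_overlap_indicators(all_cs, tracks, eqtl = eqtl))
  glm_tab <- run_stage("glm", rbind(
    fit_raf_annotation_glm(flags, indicators, mode = "joint"),
    fit_raf_annotation_glm(flags, indicators, mode = "marginal")))
  write_tsv_commented(glm_tab, file.path(cfg$out_dir, "glm.tsv"))

  ## gene sets ----
  universe <- sort(unique(eqtl$gene))
  targets_afr <- run_stage("geneset",
                           collect_eqtl_targets(all_cs, eqtl, flags, "afr_higher"))
  gs_tab <- run_stage("geneset",
                      geneset_enrichment_all(targets_afr, sets, universe))
  if (!is.null(gs_tab)) {
    write_tsv_commented(gs_tab, file.path(cfg$out_dir, "geneset_enrichment.tsv"))
  }

  ## stimulation ----
  contrast <- run_stage("stimulation",
                        stimulation_contrast(stim, fc_min = cfg$fc_min,
                                             fdr_max = cfg$fdr_max))
  write_tsv_commented(contrast$responses,
                      file.path(cfg$out_dir, "stimulation_response.tsv"))

  summary <- list(
    counts = counts,
    enrichment = enrich,
    raf_proportions = props,
    glm = glm_tab,
    geneset = gs_tab,
    stimulation = list(n_induced = length(contrast$induced),
                       pearson_r = contrast$pearson_r,
                       pearson_p = contrast$pearson_p)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                       dataframe = "columns", auto_unbox = TRUE, digits = 10,
                       na = "null")
  logline("done")
  invisible(summary)
}
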