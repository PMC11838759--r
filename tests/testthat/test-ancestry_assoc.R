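test_that("RAF direction flags use strict comparison with exact ties", {
  freqs <- data.frame(
    variant_id = c("2:113627234:T", "5:96118852:G", "2:103060024:T"),
    raf_afr = c(0.63, 0.29, 0.10),
    raf_eur = c(0.34, 0.29, 0.22), stringsAsFactors = FALSE)
  flags <- flag_raf_direction(freqs)
  expect_equal(flags$direction, c("afr_higher", "tie", "eur_higher"))
  expect_error(flag_raf_direction(freqs, c("2:113627234:T", "1:1:A")),
               "1:1:A", class = "missing_variant_error")
  # permutation invariance of the flag map
  perm <- sample(nrow(freqs))
  flags2 <- flag_raf_direction(freqs[perm, ])
  expect_equal(flags2$direction[match(flags$variant_id, flags2$variant_id)],
               flags$direction)
})

test_that("ancestry group frequencies aggregate by unweighted mean", {
  afr <- rbind(c(0.1, 0.2, 0.3, 0.4, 0.5))
  eur <- rbind(c(0.2, 0.2, 0.2, 0.2, 0.3))
  tab <- ancestry_freq_table("v1", afr, eur)
  expect_equal(tab$raf_afr, 0.3)
  expect_equal(tab$raf_eur, 0.22)
  expect_equal(tab$n_pops_afr, 5)
  weighted <- ancestry_freq_table("v1", afr, eur, weights_afr = c(1, 0, 0, 0, 0))
  expect_equal(weighted$raf_afr, 0.1)
})

test_that("direction proportions sum to one and collapse to loci by majority", {
  members <- make_sumstats("chr1", c(100, 200, 300, 400), 0.3, 0.05, 1e-9)
  cs <- credible_set(members)  # all four in set
  flags <- data.frame(variant_id = members$variant_id,
                      direction = c("afr_higher", "afr_higher",
                                    "eur_higher", "tie"),
                      stringsAsFactors = FALSE)
  props <- raf_proportions(flags, list(dx = list(cs)), unit = "variant")
  expect_equal(unlist(props[, c("afr_higher", "eur_higher", "tie")],
                      use.names = FALSE), c(0.50, 0.25, 0.25))
  expect_equal(props$afr_higher + props$eur_higher + props$tie, 1)

  # locus majority: {afr, afr, eur} -> afr_higher
  maj <- credible_set(make_sumstats("chr2", c(100, 200, 300), 0.3, 0.05, 1e-9))
  maj_flags <- data.frame(variant_id = maj$entries$variant_id,
                          direction = c("afr_higher", "afr_higher", "eur_higher"),
                          stringsAsFactors = FALSE)
  lp <- raf_proportions(maj_flags, list(dx = list(maj)), unit = "locus")
  expect_equal(lp$afr_higher, 1)

  all_afr <- raf_proportions(
    data.frame(variant_id = members$variant_id, direction = "afr_higher"),
    list(dx = list(cs)), unit = "variant")
  expect_equal(unlist(all_afr[, c("afr_higher", "eur_higher", "tie")],
                      use.names = FALSE), c(1, 0, 0))
})

test_that("logistic GLM matches a hand-written IRLS reference", {
  set.seed(61)
  for (i in 1:20) {
    n <- sample(80:200, 1)
    x1 <- runif(n) < 0.4; x2 <- runif(n) < 0.3
    eta <- -0.3 + 0.8 * x1 - 0.5 * x2
    y <- runif(n) < plogis(eta)
    flags <- data.frame(variant_id = paste0("v", 1:n),
                        direction = ifelse(y, "afr_higher", "eur_higher"))
    ind <- data.frame(variant_id = paste0("v", 1:n), atac = x1, eqtl = x2)
    fit <- tryCatch(fit_raf_annotation_glm(flags, ind, mode = "joint"),
                    constant_predictor_error = function(e) NULL,
                    separation_error = function(e) NULL)
    if (is.null(fit)) next
    ref <- irls_logistic(cbind(1, x1, x2), as.numeric(y))
    expect_equal(fit$estimate, ref, tolerance = 1e-6)
  }
})

test_that("GLM is calibrated under the null and recovers a planted OR of 1.4", {
  set.seed(62)
  null_or <- numeric(200); null_p <- numeric(200)
  for (i in 1:200) {
    n <- 2000
    y <- runif(n) < 0.5
    x <- runif(n) < 0.3  # independent of outcome
    fit <- fit_raf_annotation_glm(
      data.frame(variant_id = paste0("v", 1:n),
                 direction = ifelse(y, "afr_higher", "eur_higher")),
      data.frame(variant_id = paste0("v", 1:n), eqtl = x), mode = "marginal")
    null_or[i] <- fit$or_estimate
    null_p[i] <- fit$p
  }
  expect_gte(mean(null_or), 0.85)
  expect_lte(mean(null_or), 1.18)
  expect_lte(mean(null_p < 0.05), 0.07)

  est <- numeric(200)
  for (i in 1:200) {
    n <- 5000
    x <- runif(n) < 0.3
    y <- runif(n) < plogis(-0.1 + 0.34 * x)  # true OR exp(0.34) ~ 1.40
    fit <- fit_raf_annotation_glm(
      data.frame(variant_id = paste0("v", 1:n),
                 direction = ifelse(y, "afr_higher", "eur_higher")),
      data.frame(variant_id = paste0("v", 1:n), eqtl = x), mode = "marginal")
    est[i] <- fit$or_estimate
  }
  expect_gte(mean(est), 1.3)
  expect_lte(mean(est), 1.5)
})

test_that("degenerate GLM inputs raise typed errors", {
  n <- 50
  flags <- data.frame(variant_id = paste0("v", 1:n),
                      direction = rep(c("afr_higher", "eur_higher"), n / 2))
  const <- data.frame(variant_id = paste0("v", 1:n), atac = rep(TRUE, n))
  expect_error(fit_raf_annotation_glm(flags, const), "atac",
               class = "constant_predictor_error")
  # perfectly separating predictor
  sep <- data.frame(variant_id = paste0("v", 1:n),
                    atac = flags$direction == "afr_higher")
  expect_error(fit_raf_annotation_glm(flags, sep),
               class = "separation_error")
  one_class <- data.frame(variant_id = paste0("v", 1:n),
                          direction = "afr_higher")
  expect_error(fit_raf_annotation_glm(one_class, sep), class = "domain_error")
})

test_that("gene-set enrichment matches the hypergeometric summation oracle", {
  universe <- paste0("g", 1:100)
  gene_set <- paste0("g", 1:10)
  selected <- paste0("g", c(1:5, 50:52))  # 8 selected, 5 hits
  res <- geneset_enrichment(selected, gene_set, universe, set_name = "s")
  expect_equal(c(res$hits, res$selected_size - res$hits,
                 res$set_size - res$hits,
                 res$universe_size - res$set_size - res$selected_size + res$hits),
               c(5, 3, 5, 87))
  expect_equal(res$or_estimate, 29.0)
  # frozen exact tail sum_{k>=5} C(10,k) C(90,8-k) / C(100,8)
  expect_equal(res$p, 1.6366919038214944e-4, tolerance = 1e-12)

  # no hits: all-zero-hit table takes the Haldane-Anscombe correction
  none <- geneset_enrichment(paste0("g", 50:57), gene_set, universe)
  expect_lt(none$or_estimate, 1)
  expect_gt(none$p, 0.9)

  expect_error(geneset_enrichment(selected, paste0("g", 1:100),
                                  paste0("g", 1:600), max_set_size = 100),
               class = "term_size_error")
  expect_error(geneset_enrichment(character(0), gene_set, universe),
               class = "domain_error")
})

test_that("enrichment p equals brute-force tail summation for small tables", {
  set.seed(63)
  for (i in 1:60) {
    N <- sample(10:60, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    universe <- paste0("g", 1:N)
    gene_set <- sample(universe, K)
    selected <- sample(universe, n)
    a <- length(intersect(gene_set, selected))
    res <- tryCatch(
      geneset_enrichment(selected, gene_set, universe, max_set_size = N + 1),
      domain_error = function(e) NULL)
    if (is.null(res)) next
    oracle <- sum(dhyper(a:min(K, n), K, N - K, n))
    expect_equal(res$p, oracle, tolerance = 1e-12)
  }
})

test_that("eQTL target collection follows the direction filter", {
  cs <- credible_set(make_sumstats("chr2", c(100, 200, 300), 0.3, 0.05, 1e-9))
  v <- cs$entries$variant_id
  eqtl <- data.frame(variant_id = c(v[1], v[1], v[2], v[2], v[3]),
                     gene = c("IL1A", "IL1B", "IL1A", "IL37", "KRT1"),
                     stringsAsFactors = FALSE)
  flags <- data.frame(variant_id = v,
                      direction = c("afr_higher", "afr_higher", "eur_higher"))
  afr <- collect_eqtl_targets(list(cs), eqtl, flags, "afr_higher")
  expect_equal(afr, c("IL1A", "IL1B", "IL37"))
  eur <- collect_eqtl_targets(list(cs), eqtl, flags, "eur_higher")
  expect_equal(eur, "KRT1")
  expect_length(intersect(afr, eur), 0)
  expect_warning(none <- collect_eqtl_targets(list(cs), eqtl, flags, "tie"))
  expect_length(none, 0)
})
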