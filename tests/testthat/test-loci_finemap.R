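test_that("locus merging is inclusive at exactly 500 kb", {
  two_close <- make_sumstats("chr1", c(1000000, 1400000), 0.3, 0.05, 1e-9)
  loci <- delineate_loci(two_close)
  expect_length(loci, 1)
  expect_equal(nrow(loci[[1]]$members), 2)

  boundary <- make_sumstats("chr1", c(1000000, 1500000), 0.3, 0.05, 1e-9)
  expect_length(delineate_loci(boundary), 1)  # gap exactly 500,000 merges

  split <- make_sumstats("chr1", c(1000000, 1500001), 0.3, 0.05, 1e-9)
  expect_length(delineate_loci(split), 2)     # gap 500,001 splits
})

test_that("MHC variants are excluded before merging", {
  rec <- rbind(make_sumstats("chr6", 30000000, 0.3, 0.05, 1e-9),
               make_sumstats("chr1", 1000000, 0.3, 0.05, 1e-9))
  loci <- delineate_loci(rec)
  expect_length(loci, 1)
  expect_equal(loci[[1]]$chrom, "chr1")
  # disabling the exclusion restores the chr6 locus
  expect_length(delineate_loci(rec, mhc = NULL), 2)
  # nothing significant outside the MHC -> empty result with a warning
  only_mhc <- make_sumstats("chr6", 30000000, 0.3, 0.05, 1e-9)
  expect_warning(out <- delineate_loci(only_mhc), "no genome-wide")
  expect_length(out, 0)
})

test_that("lead variant is the smallest p, ties broken by position", {
  rec <- make_sumstats("chr1", c(1000000, 1100000, 1200000), 0.3, 0.05,
                       p = c(1e-9, 1e-10, 1e-10))
  locus <- delineate_loci(rec)[[1]]
  expect_equal(locus$lead$pos, 1100000L)
  expect_equal(locus$span, c(1000000, 1200000))
})

test_that("delineation is idempotent and order-invariant", {
  set.seed(21)
  for (i in 1:10) {
    pos <- sort(sample(1:6e6, 12))
    rec <- make_sumstats("chr2", pos, 0.3, 0.05,
                         p = 10^runif(12, -12, -6))
    loci1 <- delineate_loci(rec, mhc = NULL)
    shuffled <- rec[sample(nrow(rec)), ]
    loci2 <- delineate_loci(shuffled, mhc = NULL)
    expect_equal(loci1, loci2)
    refed <- do.call(rbind, lapply(loci1, `[[`, "members"))
    loci3 <- delineate_loci(refed, mhc = NULL)
    expect_equal(lapply(loci3, `[[`, "span"), lapply(loci1, `[[`, "span"))
  }
})

test_that("Wakefield ABF matches the closed form and its limits", {
  # frozen from exact arithmetic (mpmath, 30 digits):
  # sqrt(se^2/(se^2+W)) * exp(beta^2 W / (2 se^2 (se^2+W)))
  expect_equal(wakefield_abf(0.2, 0.05, 0.04), 451.6037304130713,
               tolerance = 1e-12)
  # null effect: BF below 1 for any se
  for (se in c(0.01, 0.1, 1)) {
    expect_equal(wakefield_abf(0, se), sqrt(se^2 / (se^2 + 0.04)))
    expect_lt(wakefield_abf(0, se), 1)
  }
  # vanishing prior mass: BF -> 1
  expect_equal(wakefield_abf(0.7, 0.2, prior_w = 1e-12), 1, tolerance = 1e-6)
  expect_error(wakefield_abf(0.1, 0), class = "domain_error")
  # log form is consistent and safe at huge z
  expect_equal(log(wakefield_abf(0.2, 0.05)),
               wakefield_abf(0.2, 0.05, log = TRUE), tolerance = 1e-12)
  expect_true(is.finite(wakefield_abf(2, 0.01, log = TRUE)))
})

test_that("credible sets accumulate posterior mass to the target", {
  single <- credible_set(make_sumstats("chr1", 100, 0.3, 0.05, 1e-9))
  expect_equal(single$entries$posterior, 1)
  expect_equal(single$coverage, 1)

  sym <- credible_set(make_sumstats("chr1", c(100, 200, 300), 0.3, 0.05, 1e-9))
  expect_equal(sym$entries$posterior, rep(1 / 3, 3))
  expect_true(all(sym$entries$in_set))  # boundary ties are all included

  # constructed ABFs giving posteriors (0.90, 0.06, 0.03, 0.01):
  # with se = 1, W = 1, log ABF = 0.5 log(1/2) + beta^2/4, so beta =
  # sqrt(4 (target - 0.5 log 0.5)) hits any target log ABF exactly
  target <- log(c(0.90, 0.06, 0.03, 0.01))
  beta <- sqrt(4 * (target + 5 - 0.5 * log(0.5)))
  cs <- credible_set(data.frame(variant_id = paste0("v", 1:4), chrom = "chr1",
                                pos = 1:4 * 100L, beta = beta, se = 1,
                                stringsAsFactors = FALSE),
                     prior_w = 1)
  expect_equal(cs$entries$posterior, c(0.90, 0.06, 0.03, 0.01),
               tolerance = 1e-9)
  expect_equal(sum(cs$entries$in_set), 2)
  expect_equal(cs$coverage, 0.96, tolerance = 1e-9)
})

test_that("posteriors normalise and respond monotonically to effect size", {
  set.seed(31)
  for (i in 1:20) {
    m <- sample(2:12, 1)
    df <- make_sumstats("chr3", sort(sample(1:1e5, m)),
                        beta = rnorm(m, 0, 0.3), se = runif(m, 0.02, 0.2),
                        p = runif(m))
    cs <- credible_set(df)
    expect_equal(sum(cs$entries$posterior), 1, tolerance = 1e-12)
    expect_true(!is.unsorted(rev(cs$entries$posterior)))
    expect_gte(cs$coverage, 0.95)
    # minimality up to ties: dropping the last in-set entry breaks coverage
    k <- sum(cs$entries$in_set)
    if (k > 1) expect_lt(cs$entries$cumulative[k - 1], 0.95)
    # raising one member's |beta| at fixed se never lowers its posterior
    j <- sample(m, 1)
    df2 <- df
    df2$beta[j] <- df2$beta[j] + sign(df2$beta[j] + 1e-12) * 0.1
    cs2 <- credible_set(df2)
    p1 <- cs$entries$posterior[cs$entries$variant_id == df$variant_id[j]]
    p2 <- cs2$entries$posterior[cs2$entries$variant_id == df$variant_id[j]]
    expect_gte(p2, p1 - 1e-12)
  }
})

test_that("the planted causal variant is recovered in simulated credible sets", {
  # small-scale version of the coverage study (the full 1000-locus run is
  # the acceptance check)
  cfg <- sim_config(n_diseases = 1, loci_per_disease = 200,
                    variants_per_locus = 10, causal_beta = 0.25,
                    n_cases = 20000, n_controls = 20000, seed = 42)
  sim <- simulate_summary_stats(cfg)
  hit <- vapply(split(sim$stats, sim$stats$locus_id), function(members) {
    cs <- credible_set(members, prior_w = cfg$causal_beta^2)
    causal <- sim$truth$causal$variant_id[
      sim$truth$causal$locus_id == members$locus_id[1]]
    causal %in% credible_variants(cs)$variant_id
  }, logical(1))
  expect_gte(mean(hit), 0.95)
})
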