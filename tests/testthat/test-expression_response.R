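test_that("module score vanishes when controls match the module exactly", {
  mat <- matrix(5, nrow = 200, ncol = 12,
                dimnames = list(sprintf("g%03d", 1:200), paste0("c", 1:12)))
  score <- module_score(mat, c("g001", "g002", "g003"), seed = 1)
  expect_true(all(abs(score) < 1e-9))
})

test_that("module score recovers a planted shift in one column group", {
  set.seed(71)
  n_genes <- 300; n_cols <- 40
  mat <- matrix(rlnorm(n_genes * n_cols, log(10), 0.4), nrow = n_genes,
                dimnames = list(sprintf("g%03d", 1:n_genes), paste0("c", 1:n_cols)))
  module <- sprintf("g%03d", 1:10)
  shift <- 3
  mat[module, 1:20] <- mat[module, 1:20] + shift
  score <- module_score(mat, module, seed = 2)
  expect_lt(abs(mean(score[1:20]) - mean(score[21:40]) - shift), 1)
  expect_gt(mean(score[1:20]), mean(score[21:40]))
})

test_that("module score handles degenerate sizes and stays invariant to layout", {
  mat <- matrix(seq_len(30 * 4), nrow = 30,
                dimnames = list(sprintf("g%02d", 1:30), paste0("c", 1:4)))
  one <- module_score(mat, "g05", n_bins = 2, n_ctrl = 10, seed = 3)
  expect_length(one, 4)
  expect_error(module_score(mat, "absent"), class = "domain_error")

  # column permutation permutes the scores; row permutation leaves them
  # unchanged under the same seed
  big <- matrix(rlnorm(100 * 6), nrow = 100,
                dimnames = list(sprintf("g%03d", 1:100), paste0("c", 1:6)))
  module <- c("g001", "g050")
  base <- module_score(big, module, seed = 4)
  perm <- sample(ncol(big))
  expect_equal(module_score(big[, perm], module, seed = 4), base[perm])
  rperm <- sample(nrow(big))
  expect_equal(module_score(big[rperm, ], module, seed = 4), base)
})

test_that("group fold change uses pseudocounted means and Wilcoxon", {
  mat <- rbind(IL1A = c(rep(2, 10), rep(2, 10)),
               IL1R2 = c(rep(9, 30), rep(4, 30))[1:20])
  labels <- rep(c("lesional", "nonlesional"), each = 10)
  same <- group_fold_change(mat, "IL1A", labels, "lesional", "nonlesional")
  expect_equal(same$fc, 1)
  expect_gt(same$p, 0.99)

  set.seed(72)
  n <- 200
  big <- rbind(GENE = c(rnorm(n, 20, 0.5), rnorm(n, 9.5, 0.5)))
  lab <- rep(c("a", "b"), each = n)
  doubled <- group_fold_change(big, "GENE", lab, "a", "b")
  expect_lt(abs(doubled$fc - 2), 0.1)  # (20+1)/(9.5+1) = 2, pseudocount-attenuated
  expect_lt(doubled$p, 1e-6)

  expect_error(group_fold_change(mat, "missing", labels, "a", "b"),
               class = "domain_error")
})

test_that("stimulation contrast applies strict FC and inclusive FDR boundaries", {
  donors <- c("A01", "A02", "B01", "B02")
  groups <- c("A", "A", "B", "B")
  mk <- function(gene, unstim, stim) {
    rbind(data.frame(gene = gene, donor = donors, group = groups,
                     condition = "unstim", count = unstim),
          data.frame(gene = gene, donor = donors, group = groups,
                     condition = "stim", count = stim))
  }
  tbl <- rbind(mk("gene1", 99, c(203, 201, 201, 201)),
               mk("gene2", 99, 199),
               mk("gene3", 99, c(99, 100, 98, 99)),
               mk("gene4", 50, c(155, 153, 154, 153)),
               mk("gene5", 10, c(34, 33, 32, 33)))
  # fc_min = 2 keeps the boundary exactly representable: gene2's per-donor
  # ratio is (199+1)/(99+1) = 2 in every donor, so mean FC is exactly 2
  res <- suppressWarnings(stimulation_contrast(tbl, fc_min = 2))
  r <- res$responses
  expect_true(r$induced[r$gene == "gene1"])
  expect_false(r$induced[r$gene == "gene2"])  # mean FC exactly at fc_min -> excluded
  expect_false(r$induced[r$gene == "gene3"])
  expect_equal(sort(res$induced), c("gene1", "gene4", "gene5"))

  expect_error(stimulation_contrast(tbl[tbl$group == "A" & tbl$donor == "A01", ]),
               class = "domain_error")
})

test_that("stimulation contrast recovers a planted diff-vs-avg correlation", {
  set.seed(73)
  avg_fc <- runif(15, 1, 3)                 # planted log2 responses
  diff_fc <- 0.5 * avg_fc + rnorm(15, 0, 0.1)
  planted <- data.frame(gene = 1:15,
                        fc_a = 2^(avg_fc + diff_fc / 2),
                        fc_b = 2^(avg_fc - diff_fc / 2))
  tbl <- simulate_stimulation_matrix(120, 6, planted = planted,
                                     noise_sdlog = 0.05)
  res <- stimulation_contrast(tbl, fc_min = 1.2)
  expect_gte(length(res$induced), 10)
  expect_gt(res$pearson_r, 0.7)

  # null: with no planted genes the induced set is tiny and r undefined
  null_tbl <- simulate_stimulation_matrix(100, 4)
  expect_warning(null_res <- stimulation_contrast(null_tbl), "fewer than 3")
  expect_true(is.na(null_res$pearson_r))
})

test_that("diff-avg correlation is weak when response differences are null", {
  set.seed(74)
  r_vals <- replicate(200, {
    avg <- runif(15, 0.8, 2.5)
    diff <- rnorm(15, 0, 0.3)          # independent of avg
    suppressWarnings(cor(diff, avg))
  })
  expect_gte(mean(abs(r_vals) < 0.5), 0.90)
})

test_that("Benjamini-Hochberg and Pearson internals match closed forms", {
  set.seed(75)
  for (i in 1:10) {
    p <- runif(sample(5:50, 1))
    expect_equal(p.adjust(p, "BH"), bh_stepup(p), tolerance = 1e-12)
  }
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  y <- c(0.8, 2.9, 2.5, 4.0, 4.1)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(cor.test(x, y)$estimate), r_closed, tolerance = 1e-12)
})
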