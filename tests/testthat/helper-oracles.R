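# Independent oracles and small fixture builders used across the suite.

# Brute-force all-pairs point-in-interval scan (1-based point vs 0-based
# half-open interval: hit iff start < q <= end), independent of the
# GRanges-backed implementation.
brute_points_in_track <- function(chrom, pos, track) {
  iv <- track$intervals
  ivc <- sub("^chr", "", iv$chrom)
  qc <- sub("^chr", "", chrom)
  vapply(seq_along(pos), function(i) {
    any(ivc == qc[i] & iv$start < pos[i] & pos[i] <= iv$end)
  }, logical(1))
}

# Hand-written iteratively-reweighted least squares for logistic
# regression; the reference the GLM implementation is checked against.
irls_logistic <- function(X, y, tol = 1e-12, max_iter = 100) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < tol) return(as.numeric(beta_new))
    beta <- as.numeric(beta_new)
  }
  as.numeric(beta)
}

# Benjamini-Hochberg step-up by its textbook definition.
bh_stepup <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 1
  for (i in n:1) {
    running <- min(running, p[o[i]] * n / i)
    adj[o[i]] <- running
  }
  adj
}

# Small summary-stat data frame builder (one disease).
make_sumstats <- function(chrom, pos, beta, se, p,
                          disease = "dx", risk = "A", other = "G") {
  n <- length(pos)
  data.frame(
    variant_id = paste(chrom, pos, rep_len(risk, n), sep = ":"),
    disease = disease,
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    risk_allele = rep_len(risk, n), other_allele = rep_len(other, n),
    beta = rep_len(beta, n), se = rep_len(se, n), p = rep_len(p, n),
    stringsAsFactors = FALSE)
}

make_track <- function(chrom, start, end, name = "T") {
  annotation_track(name, data.frame(chrom = chrom, start = start, end = end,
                                    stringsAsFactors = FALSE))
}

# One-variant-per-locus credible sets from point positions.
point_credible_sets <- function(chrom, pos) {
  chrom <- rep_len(chrom, length(pos))
  lapply(seq_along(pos), function(i) {
    credible_set(data.frame(
      variant_id = paste0("v", i), chrom = chrom[i], pos = pos[i],
      beta = 0.3, se = 0.05, stringsAsFactors = FALSE))
  })
}

write_lines_tmp <- function(lines, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
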