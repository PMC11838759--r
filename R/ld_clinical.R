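#' Two-locus linkage-disequilibrium statistics
#'
#' From the two risk-allele marginal frequencies and the observed
#' risk-risk haplotype frequency, derives the standard two-locus LD
#' quantities: the linkage-equilibrium ("theoretical") haplotype frequency
#' `h_theory = p_a * p_b`, the covariance `D = h_ab - h_theory`, its
#' normalised form `D'` (`D / D_max`, with
#' `D_max = min(p_a (1-p_b), (1-p_a) p_b)` for `D > 0` and
#' `min(p_a p_b, (1-p_a)(1-p_b))` for `D < 0`; `D = 0` gives `D' = 0`),
#' and the squared allelic correlation
#' `r2 = D^2 / (p_a (1-p_a) p_b (1-p_b))`.
#'
#' @param p_a,p_b Risk-allele frequencies at the two loci, each in (0,1).
#' @param h_ab Observed risk-risk haplotype frequency; must satisfy the
#'   Frechet bounds `max(0, p_a + p_b - 1) <= h_ab <= min(p_a, p_b)`.
#' @return An `ld_pair` list: `p_a`, `p_b`, `h_ab`, `h_theory`, `d`,
#'   `d_prime`, `r2`.
#' @export
ld_stats <- function(p_a, p_b, h_ab) {
  assert_prob(p_a, "p_a"); assert_prob(p_b, "p_b")
  tol <- 1e-9
  lo <- max(0, p_a + p_b - 1); hi <- min(p_a, p_b)
  if (h_ab < lo - tol || h_ab > hi + tol) {
    stop_typed("frechet_error",
               "h_ab=%.6g violates Frechet bounds [%.6g, %.6g] for p_a=%.6g, p_b=%.6g",
               h_ab, lo, hi, p_a, p_b)
  }
  h_theory <- p_a * p_b
  d <- h_ab - h_theory
  d_max <- if (d > 0) min(p_a * (1 - p_b), (1 - p_a) * p_b)
           else min(p_a * p_b, (1 - p_a) * (1 - p_b))
  d_prime <- if (d == 0) 0 else d / d_max
  r2 <- d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
  structure(list(p_a = p_a, p_b = p_b, h_ab = h_ab, h_theory = h_theory,
                 d = d, d_prime = d_prime, r2 = r2),
            class = "ld_pair")
}

#' @export
print.ld_pair <- function(x, ...) {
  cat(sprintf("ld_pair: p_a=%.3f p_b=%.3f h_obs=%.3f h_theory=%.3f D=%.4f D'=%.3f r2=%.3f\n",
              x$p_a, x$p_b, x$h_ab, x$h_theory, x$d, x$d_prime, x$r2))
  invisible(x)
}

#' Recover marginal frequencies from an LD summary triple
#'
#' Feasibility solver: given a reported linkage-equilibrium haplotype
#' frequency `h_theory`, observed haplotype frequency `h_obs` and `r2`,
#' finds marginal frequencies `(p_a, p_b)` consistent with all three.
#' Writing `P = p_a p_b = h_theory`, `D = h_obs - h_theory` and
#' `V = D^2 / r2 = p_a (1-p_a) p_b (1-p_b)`, expanding
#' `(1-p_a)(1-p_b) = V / P` gives the sum `S = p_a + p_b = 1 + P - V/P`,
#' so the marginals are the roots of `t^2 - S t + P = 0`. The pair is
#' infeasible when `r2` and `D` contradict (`D = 0` with `r2 > 0`), the
#' discriminant is negative, a root leaves (0,1), or the implied
#' haplotype frequency violates the Frechet bounds.
#'
#' @param h_theory Linkage-equilibrium haplotype frequency in (0,1).
#' @param h_obs Observed haplotype frequency in (0,1).
#' @param r2 Squared allelic correlation in \[0,1\].
#' @return List with `feasible` (logical); when feasible also `p_a`,
#'   `p_b` (larger root first) and the verifying `ld_pair`; when not, a
#'   `reason` string.
#' @export
solve_marginals <- function(h_theory, h_obs, r2) {
  assert_prob(h_theory, "h_theory"); assert_prob(h_obs, "h_obs")
  if (r2 < 0 || r2 > 1) stop_typed("domain_error", "r2 must lie in [0,1]")
  infeasible <- function(reason) list(feasible = FALSE, reason = reason)
  d <- h_obs - h_theory
  if (d == 0) {
    return(infeasible(if (r2 > 0) "D = 0 contradicts r2 > 0"
                      else "D = 0 and r2 = 0: marginals under-determined"))
  }
  if (r2 == 0) return(infeasible("r2 = 0 contradicts h_obs != h_theory"))
  P <- h_theory
  V <- d^2 / r2
  S <- 1 + P - V / P
  disc <- S^2 - 4 * P
  if (disc < 0) return(infeasible("negative discriminant: no real marginals"))
  roots <- sort((S + c(1, -1) * sqrt(disc)) / 2, decreasing = TRUE)
  if (any(roots <= 0 | roots >= 1)) {
    return(infeasible("root outside (0,1)"))
  }
  pair <- tryCatch(ld_stats(roots[1], roots[2], h_obs),
                   frechet_error = function(e) NULL)
  if (is.null(pair)) return(infeasible("implied h_obs violates Frechet bounds"))
  list(feasible = TRUE, p_a = roots[1], p_b = roots[2], ld = pair)
}

#' Convert a log-odds effect size to an odds ratio
#'
#' `OR = exp(beta)`; the PheWAS-reporting conversion between an effect
#' size on the log-odds scale and the printed odds ratio.
#'
#' @param beta Log-odds effect size (vectorised).
#' @param digits Rounding applied to the returned OR (default 2, matching
#'   the usual reporting precision; use `NULL` for full precision).
#' @return Odds ratio(s).
#' @export
beta_to_or <- function(beta, digits = 2) {
  or <- exp(beta)
  if (!is.null(digits)) or <- round(or, digits)
  or
}

#' LD statistics from a 2x2 haplotype count table
#'
#' @param counts Numeric vector or 2x2 matrix of haplotype counts in the
#'   order AB, Ab, aB, ab (A/B = risk alleles). Frequencies are
#'   `counts/sum(counts)`; the result delegates to [ld_stats()].
#' @return An `ld_pair`.
#' @export
haplotype_counts_to_freqs <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) != 4 || any(counts < 0)) {
    stop_typed("domain_error", "need 4 non-negative haplotype counts (AB, Ab, aB, ab)")
  }
  total <- sum(counts)
  if (total <= 0) stop_typed("domain_error", "total haplotype count must be > 0")
  f <- counts / total
  p_a <- f[1] + f[2]
  p_b <- f[1] + f[3]
  ld_stats(p_a, p_b, f[1])
}
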