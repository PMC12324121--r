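#' Oracle summary statistics from the simulator's own effects
#'
#' Packages the cohort's true per-SNP effect sizes as a summary-statistics
#' table (p-values set to the numerical floor so every variant passes any
#' threshold). This is the default scoring input for validation work: the
#' polygenic index then equals the true genetic value, so estimator checks
#' are about the estimator, not about discovery-GWAS noise. Use
#' [simulate_gwas()] for realistic estimated weights.
#'
#' @param cohort a `trio_cohort`.
#' @return a `sumstats` object.
#' @export
sumstats_from_truth <- function(cohort) {
  s <- cohort$snps
  as_sumstats(data.frame(SNP = s$id, A1 = s$effect_allele, A2 = s$other_allele,
                         BETA = s$beta, P = 1e-300, stringsAsFactors = FALSE))
}

#' Simulate an independent discovery GWAS
#'
#' Draws an independent discovery sample at the cohort's allele frequencies,
#' generates the adult phenotype from the same additive model, and runs
#' per-SNP univariate regressions, returning estimated effects and Wald
#' p-values. SNPs are processed in blocks to bound memory.
#'
#' @param cohort a `trio_cohort` (supplies SNP frequencies, true effects and
#'   the phenotype variance model).
#' @param n_discovery discovery sample size.
#' @param block number of SNPs simulated per block.
#' @return a `sumstats` object with estimated `BETA` and `P`.
#' @export
simulate_gwas <- function(cohort, n_discovery = 1e5, block = 200L) {
  cfg <- cohort$config
  s <- cohort$snps
  p <- nrow(s)
  n <- as.integer(n_discovery)
  sigma_E <- cfg$bmi_parent_sd * sqrt(1 - cfg$h2_bmi)
  beta_hat <- se_hat <- numeric(p)
  # per-SNP residual environment is shared across blocks via one noise draw
  e <- stats::rnorm(n, 0, sigma_E)
  gsum <- numeric(n)  # running genetic value
  blocks <- split(seq_len(p), ceiling(seq_len(p) / block))
  G_list <- vector("list", length(blocks))
  for (bi in seq_along(blocks)) {
    j <- blocks[[bi]]
    G <- matrix(stats::rbinom(n * length(j), 2L, rep(s$maf[j], each = n)),
                n, length(j))
    gsum <- gsum + drop(G %*% s$beta[j])
    G_list[[bi]] <- G
  }
  y <- gsum + e
  vy <- stats::var(y)
  for (bi in seq_along(blocks)) {
    j <- blocks[[bi]]
    G <- G_list[[bi]]
    gm <- colMeans(G)
    gv <- colMeans(G^2) - gm^2          # population-variance form
    sxy <- drop(crossprod(G, y)) / n - gm * mean(y)
    b <- sxy / gv
    # residual variance of the univariate fit
    s2 <- (vy * (n - 1) / n - b * sxy) * n / (n - 2)
    beta_hat[j] <- b
    se_hat[j] <- sqrt(s2 / (n * gv))
    G_list[bi] <- list(NULL)
  }
  z <- beta_hat / se_hat
  pval <- pmax(2 * stats::pnorm(-abs(z)), 1e-300)
  as_sumstats(data.frame(SNP = s$id, A1 = s$effect_allele, A2 = s$other_allele,
                         BETA = beta_hat, P = pval, stringsAsFactors = FALSE))
}
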