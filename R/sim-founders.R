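#' Draw founder genotypes and genetic values
#'
#' Draws per-SNP allele frequencies uniformly on `config$maf_range`, per-SNP
#' effect sizes from a normal distribution rescaled so that the additive
#' genetic value has variance `h2_bmi * bmi_parent_sd^2`, and one generation
#' of founder genotypes at Hardy-Weinberg proportions (SNPs independent).
#' Uses the current RNG state; [simulate_trio_cohort()] seeds it once.
#'
#' @param config a [sim_config()] object.
#' @param n number of founders to draw (default `config$n_families`).
#' @param snps optionally reuse the SNP frame (id, maf, beta, alleles) of a
#'   previous call so that mothers and fathers share frequencies and effects.
#' @return list with `genotypes` (n x n_snps dosage matrix, SNP ids as column
#'   names), `gv` (genetic values, kg/m^2), and `snps` (data frame: id,
#'   effect_allele, other_allele, maf, beta).
#' @export
draw_founders <- function(config, n = config$n_families, snps = NULL) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config", call. = FALSE)
  p <- config$n_snps
  if (is.null(snps)) {
    maf <- stats::runif(p, config$maf_range[1], config$maf_range[2])
    beta_raw <- stats::rnorm(p)
    target <- config$h2_bmi * config$bmi_parent_sd^2
    denom <- sum(beta_raw^2 * 2 * maf * (1 - maf))
    beta <- if (target == 0) rep(0, p) else beta_raw * sqrt(target / denom)
    # unambiguous allele pairs only (strand-symmetric A/T, C/G never emitted)
    pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "C"), c("T", "G"),
                   c("G", "A"), c("C", "A"), c("C", "T"), c("G", "T"))
    pick <- sample.int(nrow(pairs), p, replace = TRUE)
    snps <- data.frame(id = sprintf("snp%04d", seq_len(p)),
                       effect_allele = pairs[pick, 1],
                       other_allele = pairs[pick, 2],
                       maf = maf, beta = beta,
                       stringsAsFactors = FALSE)
  }
  G <- matrix(stats::rbinom(n * p, 2L, rep(snps$maf, each = n)), n, p,
              dimnames = list(NULL, snps$id))
  list(genotypes = G, gv = drop(G %*% snps$beta), snps = snps)
}

#' Pair mothers and fathers by phenotypic assortative mating
#'
#' Ranks each sex on phenotype plus independent Gaussian noise and matches by
#' rank. For jointly Gaussian phenotypes, rank-matching the noisy scores makes
#' them comonotone, so the realized spousal correlation is
#' `1 / (1 + tau^2 / var(x))` per side; solving gives noise SD
#' `tau = sd(x) * sqrt(1/|rho_am| - 1)`, the closed form used here. With
#' `rho_am = 0` the pairing is a uniform random permutation; negative
#' `rho_am` matches ranks in opposite order.
#'
#' @param mother_phenotype,father_phenotype equal-length numeric vectors.
#' @param rho_am target spousal phenotypic correlation, `|rho_am| < 1`.
#' @return integer permutation `perm`: mother `i` is paired with father
#'   `perm[i]`.
#' @export
pair_mates <- function(mother_phenotype, father_phenotype, rho_am) {
  n <- length(mother_phenotype)
  if (length(father_phenotype) != n)
    stop("phenotype vectors must have equal length", call. = FALSE)
  check_scalar(rho_am, "rho_am", lo = -1, hi = 1, open = TRUE)
  if (rho_am == 0) return(sample.int(n))
  a <- abs(rho_am)
  tau_m <- stats::sd(mother_phenotype) * sqrt(1 / a - 1)
  tau_f <- stats::sd(father_phenotype) * sqrt(1 / a - 1)
  om <- order(mother_phenotype + stats::rnorm(n, 0, tau_m))
  of <- order(father_phenotype + stats::rnorm(n, 0, tau_f),
              decreasing = rho_am < 0)
  perm <- integer(n)
  perm[om] <- of
  perm
}

#' Transmit alleles from parents to children
#'
#' Per SNP, the child receives exactly one allele from each parent: a
#' heterozygous parent transmits the effect allele with probability 1/2,
#' homozygous parents transmit deterministically. Output dosages are
#' therefore always Mendelian-consistent with the parental pair.
#'
#' @param mother_dosages,father_dosages dosage matrices (families x SNPs)
#'   with entries in `{0, 1, 2}`.
#' @return child dosage matrix of the same shape.
#' @export
transmit <- function(mother_dosages, father_dosages) {
  if (!identical(dim(mother_dosages), dim(father_dosages)))
    stop("parental dosage matrices must have identical dimensions", call. = FALSE)
  if (!all(mother_dosages %in% 0:2) || !all(father_dosages %in% 0:2))
    stop("dosages must be in {0, 1, 2}", call. = FALSE)
  m <- length(mother_dosages)
  am <- stats::rbinom(m, 1L, mother_dosages / 2)
  af <- stats::rbinom(m, 1L, father_dosages / 2)
  child <- mother_dosages # reuse dim/dimnames
  child[] <- am + af
  child
}
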