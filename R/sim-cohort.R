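#' Simulate a complete synthetic trio cohort
#'
#' Orchestrates one cohort draw: founder genotypes and genetic values for
#' mothers and fathers (shared SNP frequencies and effects), parental true
#' BMI, phenotypic assortative pairing, Mendelian transmission to children,
#' all phenotypes and covariates, survey design fields, and BMI-dependent
#' participation flags. All randomness flows from `config$seed`, so cohorts
#' are bit-reproducible given the configuration.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `trio_cohort`: list with `config`, `snps`
#'   (per-SNP frame), `geno` (mother/father/child dosage matrices), `gv`
#'   (genetic values), `pheno` (one row per family, wide across sweeps) and
#'   `truth` (the generative parameters plus realized per-SNP effects and the
#'   realized first-stage coefficient).
#' @export
simulate_trio_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("'config' must be a sim_config", call. = FALSE)
  set.seed(config$seed)
  n <- config$n_families
  fm <- draw_founders(config, n)
  ff <- draw_founders(config, n, snps = fm$snps)
  sigma_E <- config$bmi_parent_sd * sqrt(1 - config$h2_bmi)
  bmi_m_true <- config$bmi_parent_mean + fm$gv + stats::rnorm(n, 0, sigma_E)
  bmi_f_true <- config$bmi_parent_mean + ff$gv + stats::rnorm(n, 0, sigma_E)
  perm <- pair_mates(bmi_m_true, bmi_f_true, config$rho_am)
  G_f <- ff$genotypes[perm, , drop = FALSE]
  gv_f <- ff$gv[perm]
  bmi_f_true <- bmi_f_true[perm]
  G_c <- transmit(fm$genotypes, G_f)
  gv_c <- drop(G_c %*% fm$snps$beta)

  cohort <- structure(list(
    config = config,
    snps = fm$snps,
    geno = list(mother = fm$genotypes, father = G_f, child = G_c),
    gv = list(mother = fm$gv, father = gv_f, child = gv_c),
    pheno = data.frame(family_id = sprintf("fam%05d", seq_len(n)),
                       mother_bmi_true = bmi_m_true,
                       father_bmi_true = bmi_f_true,
                       stringsAsFactors = FALSE),
    paired = TRUE,
    truth = NULL), class = "trio_cohort")

  cohort <- assign_design(cohort)
  cohort <- simulate_phenotypes(cohort, config)
  cohort <- simulate_attrition(cohort, config)
  cohort$truth <- sim_truth(cohort)
  cohort
}

# survey design fields: SRS (unit weights) or a two-stratum clustered design
# with stratum 2 oversampled, giving unequal recruitment weights
assign_design <- function(cohort) {
  cfg <- cohort$config
  n <- cfg$n_families
  ph <- cohort$pheno
  if (cfg$design == "srs") {
    ph$stratum <- 1L
    ph$cluster <- seq_len(n)
    ph$recruit_weight <- 1
  } else {
    K <- cfg$n_clusters
    ph$cluster <- sample.int(K, n, replace = TRUE)
    ph$stratum <- ifelse(ph$cluster <= K %/% 2, 1L, 2L)
    w <- ifelse(ph$stratum == 2L, 1 / cfg$oversample, 1)
    ph$recruit_weight <- w / mean(w)
  }
  cohort$pheno <- ph
  cohort
}

#' Fill phenotypes and covariates of a paired trio cohort
#'
#' Generates, per family: self-reported parental BMI (classical error, plus
#' an optional mean bias), child sex, maternal age/education, social class,
#' two generic principal-component covariates, ages at each sweep, child BMI
#' per sweep from the structural model (direct genetic effect on the child's
#' standardized genetic value + maternal/paternal nurture on parental *true*
#' BMI + covariate effects + persistent child environment + sweep noise),
#' birthweight from maternal true BMI, and ordinal diet items from a latent
#' diet-healthiness factor thresholded at fixed quartile cutpoints (sweeps at
#' or above `config$diet_min_age` only).
#'
#' @param cohort a partially built `trio_cohort` with genotypes, pairing,
#'   design fields and parental true BMI present.
#' @param config the [sim_config()] used to build it.
#' @return the cohort with `pheno` completed.
#' @export
simulate_phenotypes <- function(cohort, config) {
  if (!isTRUE(cohort$paired))
    stop("phenotypes requested before pairing: run pair_mates()/simulate_trio_cohort() first",
         call. = FALSE)
  n <- config$n_families
  ph <- cohort$pheno
  cm <- ph$mother_bmi_true - config$bmi_parent_mean
  cp <- ph$father_bmi_true - config$bmi_parent_mean

  ph$mother_bmi_rep <- ph$mother_bmi_true + config$report_bias +
    stats::rnorm(n, 0, config$sigma_report)
  ph$father_bmi_rep <- ph$father_bmi_true + config$report_bias +
    stats::rnorm(n, 0, config$sigma_report)

  ph$sex <- stats::rbinom(n, 1L, 0.5)
  ph$maternal_educ <- 12 - 0.15 * cm + stats::rnorm(n, 0, 2) -
    1 * (ph$stratum == 2L)
  ph$maternal_age <- 28 + 0.3 * (ph$maternal_educ - 12) + stats::rnorm(n, 0, 4)
  class_latent <- 0.5 * scale(ph$maternal_educ)[, 1] + stats::rnorm(n)
  ph$social_class <- as.integer(cut(class_latent,
    breaks = stats::quantile(class_latent, probs = seq(0, 1, 0.2)),
    include.lowest = TRUE, labels = FALSE))
  ph$pc1 <- stats::rnorm(n)
  ph$pc2 <- stats::rnorm(n)

  ph$birthweight <- 3400 + config$beta_bw * cm + stats::rnorm(n, 0, 450)

  sd_gv <- stats::sd(cohort$gv$child)
  a_std <- if (sd_gv > 0) (cohort$gv$child - mean(cohort$gv$child)) / sd_gv else rep(0, n)
  u <- stats::rnorm(n, 0, config$sigma_child_env)
  clus_eff <- if (config$cluster_sd > 0) {
    ce <- stats::rnorm(max(ph$cluster), 0, config$cluster_sd)
    ce[ph$cluster]
  } else rep(0, n)

  var_d <- (config$diet_bmi_m * config$bmi_parent_sd)^2 +
           (config$diet_bmi_p * config$bmi_parent_sd)^2 + 1
  for (t in seq_along(config$sweep_ages)) {
    age <- config$sweep_ages[t]
    ph[[paste0("age_", age)]] <- age + stats::runif(n, -0.25, 0.25)
    ph[[paste0("bmi_", age)]] <- config$alpha_t[t] +
      config$delta_t[t] * a_std +
      config$gamma_m_t[t] * cm + config$gamma_p_t[t] * cp +
      config$sex_effect * ph$sex +
      config$educ_effect * (ph$maternal_educ - 12) +
      u + clus_eff + stats::rnorm(n, 0, config$sigma_e_t[t])
    if (age >= config$diet_min_age) {
      d_lat <- -config$diet_bmi_m * cm - config$diet_bmi_p * cp + stats::rnorm(n)
      for (item in names(config$diet_loadings)) {
        lo <- config$diet_loadings[[item]]
        lat <- lo * d_lat + stats::rnorm(n)
        sd_lat <- sqrt(lo^2 * var_d + 1)
        cuts <- stats::qnorm(c(0.25, 0.5, 0.75)) * sd_lat
        ph[[paste0("diet_", item, "_", age)]] <-
          1L + findInterval(lat, cuts)  # 1..4, higher = healthier
      }
    }
  }
  cohort$pheno <- ph
  cohort
}

#' Simulate BMI-dependent participation (attrition)
#'
#' Participation at the first sweep is Bernoulli(`p_base`); at each later
#' sweep it is Bernoulli of `p_base + attrition_slope * z`, where `z` is the
#' child's BMI z-score (cohort-standardized) at the immediately preceding
#' sweep, clipped to `[0.01, 0.99]`. Flags are independent across sweeps
#' given the prior-sweep z (a Markov attrition mechanism).
#'
#' @param cohort a `trio_cohort` with child BMI columns present.
#' @param config the [sim_config()] used to build it.
#' @return the cohort with logical `part_<age>` columns added.
#' @export
simulate_attrition <- function(cohort, config) {
  ph <- cohort$pheno
  ages <- config$sweep_ages
  if (is.null(ph[[paste0("bmi_", ages[1])]]))
    stop("child BMI must be simulated before attrition", call. = FALSE)
  if (!is.finite(config$attrition_slope) ||
      config$p_base + config$attrition_slope * 0 < 0 ||
      config$p_base > 1)
    stop("'attrition_slope'/'p_base' produce invalid participation probabilities",
         call. = FALSE)
  n <- nrow(ph)
  for (t in seq_along(ages)) {
    if (t == 1L || config$attrition_slope == 0) {
      p <- rep(config$p_base, n)
    } else {
      z_prev <- scale(ph[[paste0("bmi_", ages[t - 1L])]])[, 1]
      p <- clip(config$p_base + config$attrition_slope * z_prev, 0.01, 0.99)
    }
    ph[[paste0("part_", ages[t])]] <- stats::rbinom(n, 1L, p) == 1L
  }
  cohort$pheno <- ph
  cohort
}

# generative parameter set + realized quantities, serialized beside cohorts
sim_truth <- function(cohort) {
  cfg <- cohort$config
  gv_par <- c(cohort$gv$mother, cohort$gv$father)
  gv_all <- c(gv_par, cohort$gv$child)
  s <- stats::sd(gv_all)
  lambda <- if (s > 0) {
    g_std <- (gv_par - mean(gv_all)) / s
    bmi <- c(cohort$pheno$mother_bmi_true, cohort$pheno$father_bmi_true)
    stats::cov(bmi, g_std) / stats::var(g_std)
  } else 0
  truth <- unclass(cfg)
  truth$beta_snp <- cohort$snps$beta
  truth$lambda_first_stage <- lambda  # kg/m^2 per pooled-SD of genetic value
  truth
}

#' @export
print.trio_cohort <- function(x, ...) {
  cat(sprintf("Synthetic trio cohort: %d families, %d SNPs, %d sweeps (%s y)\n",
              x$config$n_families, x$config$n_snps,
              length(x$config$sweep_ages),
              paste(x$config$sweep_ages, collapse = ",")))
  cat(sprintf("  design: %s   spousal true-BMI r = %.3f\n", x$config$design,
              stats::cor(x$pheno$mother_bmi_true, x$pheno$father_bmi_true)))
  invisible(x)
}
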