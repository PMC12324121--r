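#' Simulation configuration for a synthetic trio cohort
#'
#' Defines the generative model of the synthetic mother-father-child cohort:
#' independent biallelic SNPs at Hardy-Weinberg proportions, an additive
#' genetic value explaining `h2_bmi` of parental BMI variance, phenotypic
#' assortative mating with target spousal correlation `rho_am`, child BMI per
#' assessment sweep driven by a direct genetic effect (`delta_t`, kg/m^2 per
#' SD of the child's genetic value) plus maternal/paternal nurture effects
#' (`gamma_m_t`, `gamma_p_t`, kg/m^2 of offspring BMI per kg/m^2 of the
#' parent's *true* BMI), classical self-report error on parental BMI,
#' birthweight driven by maternal BMI, ordinal diet items generated from a
#' latent diet-healthiness factor, and BMI-dependent attrition.
#'
#' Defaults emulate a UK birth-cohort trio sample: ~2,600 genotyped trios,
#' spousal BMI correlation 0.21, attrition slope -0.034 participation
#' probability per +1 SD of prior-sweep BMI z-score, and age profiles in
#' which both direct and nurture effects strengthen from age 3 to 17.
#'
#' @param n_families number of trios.
#' @param n_snps number of independent causal SNPs.
#' @param maf_range range of the uniform minor-allele-frequency draw, within (0,1).
#' @param h2_bmi proportion of parental BMI variance explained by the genetic
#'   value, in `[0,1]`.
#' @param rho_am target spousal phenotypic (true BMI) correlation, `|rho_am| < 1`.
#' @param delta_t direct genetic effect per sweep (kg/m^2 per SD of child
#'   genetic value); defaults to a linear 0.3 to 1.0 profile across sweeps.
#' @param gamma_m_t,gamma_p_t maternal/paternal nurture effect per sweep
#'   (kg/m^2 offspring BMI per kg/m^2 parental true BMI); maternal default is
#'   a linear 0.15 to 0.32 profile, paternal default 0.
#' @param beta_bw birthweight effect (grams per kg/m^2 maternal true BMI).
#' @param sigma_report SD of classical parental self-report error (kg/m^2).
#' @param report_bias mean self-report bias (kg/m^2, usually negative or 0).
#' @param diet_loadings named per-item loadings of the latent diet factor.
#' @param diet_bmi_m,diet_bmi_p effect of centred parental true BMI on the
#'   latent diet-healthiness factor (negative of the loading enters, so
#'   positive values mean higher parental BMI, less healthy diet).
#' @param attrition_slope change in participation probability per +1 SD of
#'   the prior sweep's BMI z-score.
#' @param p_base baseline per-sweep participation probability, in (0,1].
#' @param sweep_ages strictly increasing assessment ages in years.
#' @param bmi_parent_mean,bmi_parent_sd mean and SD of parental true BMI.
#' @param sigma_child_env SD of the persistent child-level environment shared
#'   across sweeps (controls BMI tracking between sweeps).
#' @param design `"srs"` (unit weights, one cluster per family) or
#'   `"clustered"` (two strata of clusters, the second oversampled so that
#'   recruitment weights are unequal).
#' @param n_clusters total number of clusters under the clustered design.
#' @param oversample relative sampling rate of stratum 2 clusters.
#' @param cluster_sd SD of a cluster-level random intercept on child BMI.
#' @param seed RNG seed; all randomness of a cohort flows from it.
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_trio_cohort()]
#' @export
sim_config <- function(n_families = 2600,
                       n_snps = 500,
                       maf_range = c(0.05, 0.5),
                       h2_bmi = 0.08,
                       rho_am = 0.21,
                       delta_t = NULL,
                       gamma_m_t = NULL,
                       gamma_p_t = NULL,
                       beta_bw = 15,
                       sigma_report = 1,
                       report_bias = 0,
                       diet_loadings = c(fruit = 0.8, veg = 0.8, fastfood = 0.6,
                                         sugary = 0.7, sweetened = 0.5),
                       diet_bmi_m = 0.05,
                       diet_bmi_p = 0,
                       attrition_slope = -0.034,
                       p_base = 0.85,
                       sweep_ages = c(3, 5, 7, 11, 14, 17),
                       bmi_parent_mean = 25,
                       bmi_parent_sd = 4,
                       sigma_child_env = 1.6,
                       design = c("srs", "clustered"),
                       n_clusters = 40,
                       oversample = 2,
                       cluster_sd = 0,
                       seed = 1L) {
  design <- match.arg(design)
  n_sweeps <- length(sweep_ages)
  if (n_sweeps < 1L || any(diff(sweep_ages) <= 0))
    stop("'sweep_ages' must be non-empty and strictly increasing", call. = FALSE)
  if (is.null(delta_t))   delta_t   <- seq(0.3, 1.0, length.out = n_sweeps)
  if (is.null(gamma_m_t)) gamma_m_t <- seq(0.15, 0.32, length.out = n_sweeps)
  if (is.null(gamma_p_t)) gamma_p_t <- rep(0, n_sweeps)
  delta_t   <- rep_len(delta_t, n_sweeps)
  gamma_m_t <- rep_len(gamma_m_t, n_sweeps)
  gamma_p_t <- rep_len(gamma_p_t, n_sweeps)

  check_scalar(n_families, "n_families", lo = 1)
  check_scalar(n_snps, "n_snps", lo = 1)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range >= 1) ||
      maf_range[1] > maf_range[2])
    stop("'maf_range' must be an ordered pair within (0, 1)", call. = FALSE)
  check_scalar(h2_bmi, "h2_bmi", lo = 0, hi = 1)
  check_scalar(rho_am, "rho_am", lo = -1, hi = 1, open = TRUE)
  check_scalar(sigma_report, "sigma_report", lo = 0)
  check_scalar(p_base, "p_base", lo = 0, hi = 1)
  if (p_base <= 0) stop("'p_base' must be positive", call. = FALSE)
  check_scalar(bmi_parent_sd, "bmi_parent_sd", lo = 0)
  check_scalar(sigma_child_env, "sigma_child_env", lo = 0)
  check_scalar(cluster_sd, "cluster_sd", lo = 0)
  check_scalar(oversample, "oversample", lo = 1e-8)
  if (design == "clustered") check_scalar(n_clusters, "n_clusters", lo = 4)
  if (is.null(names(diet_loadings)))
    names(diet_loadings) <- paste0("item", seq_along(diet_loadings))

  cfg <- list(n_families = as.integer(n_families), n_snps = as.integer(n_snps),
              maf_range = maf_range, h2_bmi = h2_bmi, rho_am = rho_am,
              delta_t = delta_t, gamma_m_t = gamma_m_t, gamma_p_t = gamma_p_t,
              beta_bw = beta_bw, sigma_report = sigma_report,
              report_bias = report_bias, diet_loadings = diet_loadings,
              diet_bmi_m = diet_bmi_m, diet_bmi_p = diet_bmi_p,
              attrition_slope = attrition_slope, p_base = p_base,
              sweep_ages = sweep_ages, bmi_parent_mean = bmi_parent_mean,
              bmi_parent_sd = bmi_parent_sd, sigma_child_env = sigma_child_env,
              design = design, n_clusters = as.integer(n_clusters),
              oversample = oversample, cluster_sd = cluster_sd,
              seed = as.integer(seed),
              # fixed secondary coefficients of the generative model
              alpha_t = NULL,            # filled below from sweep ages
              sigma_e_t = NULL,
              sex_effect = 0.2,          # kg/m^2, males
              educ_effect = -0.04,       # kg/m^2 per year of maternal education
              diet_min_age = 11)         # diet items collected from this age
  cfg$alpha_t <- 15.8 - 0.4 * sweep_ages + 0.045 * sweep_ages^2
  cfg$sigma_e_t <- seq(0.8, 1.5, length.out = n_sweeps)
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic trio-cohort configuration\n")
  cat(sprintf("  families: %d   SNPs: %d   h2_bmi: %.3f   rho_am: %.2f   design: %s\n",
              x$n_families, x$n_snps, x$h2_bmi, x$rho_am, x$design))
  cat(sprintf("  sweeps (y): %s\n", paste(x$sweep_ages, collapse = ", ")))
  cat(sprintf("  delta_t:   %s\n", paste(sprintf("%.2f", x$delta_t), collapse = ", ")))
  cat(sprintf("  gamma_m_t: %s\n", paste(sprintf("%.2f", x$gamma_m_t), collapse = ", ")))
  cat(sprintf("  gamma_p_t: %s\n", paste(sprintf("%.2f", x$gamma_p_t), collapse = ", ")))
  cat(sprintf("  attrition slope: %.3f / SD   p_base: %.2f   seed: %d\n",
              x$attrition_slope, x$p_base, x$seed))
  invisible(x)
}
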