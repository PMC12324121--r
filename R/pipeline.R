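#' Run the full per-sweep analysis of a trio cohort
#'
#' Per sweep: trims child BMI outliers (single-pass k-SD rule), computes LMS
#' BMI z-scores, extracts the MCA diet factor where the sweep has at least
#' two diet items (skipped with a logged reason otherwise), constructs
#' combined non-response x recruitment weights from a logistic response
#' model, and fits the requested model families for each outcome. Results
#' are returned as a tidy table, one row per (model, outcome, sweep, term),
#' and reruns with the same cohort and seed are identical.
#'
#' @param cohort a `trio_cohort`.
#' @param sweeps sweep ages to analyse (default: all in the cohort).
#' @param outcomes any of `"bmi"`, `"bmi_z"`, `"diet"`, `"birthweight"`.
#' @param models any of `"phenotypic"`, `"mr"`, `"mr_duo"`, `"pgi"`, `"lpm"`.
#' @param sumstats summary statistics for PGI construction (default: the
#'   simulator's own effects).
#' @param p_threshold,weighted_pgi PGI options, see [build_pgi()].
#' @param trim_k SD multiple for outlier deletion (default 3).
#' @param lms_ref LMS reference for z-scores.
#' @param diet_cutpoint category boundary for the linear probability models.
#' @param use_nonresponse_weights estimate and apply non-response weights
#'   (default TRUE); otherwise recruitment weights are used as-is.
#' @param out_dir optional directory: writes `results.csv` and `run_log.txt`.
#' @param seed seed recorded in the log (model fitting itself is
#'   deterministic given the cohort).
#' @return data frame of class `results_table` with columns model, outcome,
#'   sweep, term, estimate, se, ci_low, ci_high, n, F_mother, F_father;
#'   attribute `log` carries skipped-stage messages.
#' @export
run_full_analysis <- function(cohort,
                              sweeps = cohort$config$sweep_ages,
                              outcomes = c("bmi"),
                              models = c("phenotypic", "mr"),
                              sumstats = sumstats_from_truth(cohort),
                              p_threshold = 5e-8, weighted_pgi = TRUE,
                              trim_k = 3, lms_ref = synthetic_lms_reference(),
                              diet_cutpoint = 3L,
                              use_nonresponse_weights = TRUE,
                              out_dir = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "trio_cohort"))
  bad <- setdiff(outcomes, c("bmi", "bmi_z", "diet", "birthweight"))
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  needs_pgi <- any(models %in% c("mr", "mr_duo", "pgi")) ||
    ("lpm" %in% models)
  pgi <- if (needs_pgi)
    build_pgi(cohort, sumstats, p_threshold, weighted_pgi) else NULL
  cluster <- if (cohort$config$design == "clustered") cohort$pheno$cluster else NULL

  rows <- list()
  add <- function(fit, outcome, sweep) {
    fs <- fit$first_stage_F
    rows[[length(rows) + 1L]] <<- data.frame(
      model = fit$model, outcome = outcome,
      sweep = if (is.null(sweep)) NA_real_ else sweep,
      term = names(fit$coef), estimate = unname(fit$coef), se = unname(fit$se),
      ci_low = unname(fit$ci_low), ci_high = unname(fit$ci_high), n = fit$n,
      F_mother = unname(fs["mother_bmi"] %||% NA_real_),
      F_father = unname(fs["father_bmi"] %||% NA_real_),
      stringsAsFactors = FALSE)
  }

  for (sweep in sweeps) {
    ph <- cohort$pheno
    bmi_col <- paste0("bmi_", sweep)
    if (is.null(ph[[bmi_col]]))
      stop("sweep ", sweep, " not present in the cohort", call. = FALSE)
    keep <- trim_outliers(ph[[bmi_col]], k = trim_k)
    n_trim <- sum(!keep, na.rm = TRUE)
    if (n_trim) note("sweep %s: trimmed %d BMI outlier(s) beyond %g SD",
                     sweep, n_trim, trim_k)
    ph[[bmi_col]][!is.na(keep) & !keep] <- NA

    zcol <- paste0("bmiz_", sweep)
    ok <- !is.na(ph[[bmi_col]])
    ph[[zcol]] <- NA_real_
    ph[[zcol]][ok] <- lms_zscore(ph[[bmi_col]][ok],
                                 ifelse(ph$sex[ok] == 1, "male", "female"),
                                 ph[[paste0("age_", sweep)]][ok], lms_ref)

    dietcol <- paste0("diet_factor_", sweep)
    has_diet <- FALSE
    n_items <- length(grep(paste0("^diet_.*_", sweep, "$"), names(ph)))
    if ("diet" %in% outcomes || "lpm" %in% models) {
      if (n_items >= 2L) {
        dfac <- diet_factor_sweep(cohort, sweep)
        ph[[dietcol]] <- dfac$diet_factor
        has_diet <- TRUE
      } else {
        note("sweep %s: MCA skipped (%d diet item(s) available, need >= 2)",
             sweep, n_items)
      }
    }

    cohort_s <- cohort
    cohort_s$pheno <- ph

    w <- ph$recruit_weight
    if (use_nonresponse_weights) {
      part <- ph[[paste0("part_", sweep)]]
      if (!is.null(part) && !all(part)) {
        base_cov <- ph[c("maternal_educ", "maternal_age", "social_class",
                         "mother_bmi_rep", "father_bmi_rep")]
        ws <- estimate_response_weights(base_cov, part, ph$recruit_weight)
        w <- ws$table$combined_weight
      }
    }

    for (outcome in outcomes) {
      oc <- switch(outcome, bmi = "bmi", bmi_z = zcol,
                   diet = if (has_diet) dietcol else NA, birthweight = "birthweight")
      if (is.na(oc)) next
      if (outcome == "birthweight" && sweep != sweeps[1]) next  # assessed once
      sw_arg <- if (outcome == "birthweight") NULL else sweep
      for (mdl in models) {
        fit <- switch(mdl,
          phenotypic = fit_phenotypic_model(cohort_s, oc, sw_arg, w, cluster),
          mr = fit_trio_mr(cohort_s, oc, sw_arg, pgi, w, cluster),
          mr_duo = fit_trio_mr(cohort_s, oc, sw_arg, pgi, w, cluster,
                               drop_father = TRUE),
          pgi = fit_pgi_model(cohort_s, oc, sw_arg, pgi, w, cluster),
          lpm = NULL)
        if (!is.null(fit)) add(fit, outcome, sweep)
      }
      if ("lpm" %in% models && outcome == "diet" && has_diet) {
        for (item in names(cohort$config$diet_loadings)) {
          for (mode in c("phenotypic", "mr")) {
            fit <- fit_lpm(cohort_s, item, sweep, diet_cutpoint, mode,
                           pgi = pgi, weights = w, cluster = cluster)
            add(fit, paste0("diet:", item), sweep)
          }
        }
      }
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(model = character(), outcome = character(), sweep = numeric(),
               term = character(), estimate = numeric(), se = numeric(),
               ci_low = numeric(), ci_high = numeric(), n = integer(),
               F_mother = numeric(), F_father = numeric())
  rownames(res) <- NULL
  attr(res, "log") <- log_lines
  attr(res, "seed") <- seed
  attr(res, "config_hash") <- config_hash(cohort$config)
  class(res) <- c("results_table", "data.frame")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(res, file.path(out_dir, "results.csv"), row.names = FALSE)
    writeLines(c(sprintf("trionurture %s", as.character(utils::packageVersion("trionurture"))),
                 sprintf("seed: %d", seed),
                 sprintf("config_hash: %s", config_hash(cohort$config)),
                 log_lines),
               file.path(out_dir, "run_log.txt"))
  }
  res
}

#' Parameter-recovery experiment for the trio MR design
#'
#' Simulates `n_reps` replicate cohorts from `config`, fits the trio MR
#' model (and optionally the birthweight MR model) at one sweep, and reports
#' bias, empirical SD, mean robust SE and 95% CI coverage for the maternal
#' and paternal nurture effects against the generative truth.
#'
#' @param config a [sim_config()]; its seed anchors replicate seeds.
#' @param n_reps number of replicate cohorts.
#' @param sweep sweep age analysed (default: last).
#' @param include_birthweight also fit the birthweight MR model.
#' @param use_weights analyse with recruitment weights (default TRUE).
#' @return list: `summary` (per-estimand data frame with truth, mean
#'   estimate, bias, empirical SD, mean SE, coverage) and `estimates`
#'   (replicate-level draws).
#' @export
run_recovery_experiment <- function(config, n_reps = 200L,
                                    sweep = utils::tail(config$sweep_ages, 1),
                                    include_birthweight = FALSE,
                                    use_weights = TRUE) {
  t_idx <- match(sweep, config$sweep_ages)
  if (is.na(t_idx)) stop("sweep not in config$sweep_ages", call. = FALSE)
  cols <- c("gamma_m", "gamma_p", if (include_birthweight) "beta_bw")
  est <- se <- matrix(NA_real_, n_reps, length(cols),
                      dimnames = list(NULL, cols))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    co <- simulate_trio_cohort(cfg)
    pgi <- build_pgi(co)
    w <- if (use_weights) NULL else rep(1, cfg$n_families)
    fit <- fit_trio_mr(co, "bmi", sweep, pgi, weights = w)
    est[r, "gamma_m"] <- fit$coef["mother_bmi"]
    se[r, "gamma_m"] <- fit$se["mother_bmi"]
    est[r, "gamma_p"] <- fit$coef["father_bmi"]
    se[r, "gamma_p"] <- fit$se["father_bmi"]
    if (include_birthweight) {
      fbw <- fit_trio_mr(co, "birthweight", NULL, pgi, weights = w)
      est[r, "beta_bw"] <- fbw$coef["mother_bmi"]
      se[r, "beta_bw"] <- fbw$se["mother_bmi"]
    }
  }
  truth <- c(gamma_m = config$gamma_m_t[t_idx], gamma_p = config$gamma_p_t[t_idx],
             if (include_birthweight) c(beta_bw = config$beta_bw))
  cover <- vapply(cols, function(cn)
    mean(truth[cn] >= est[, cn] - 1.96 * se[, cn] &
         truth[cn] <= est[, cn] + 1.96 * se[, cn]), numeric(1))
  summary <- data.frame(estimand = cols, truth = truth[cols],
                        mean_estimate = colMeans(est),
                        bias = colMeans(est) - truth[cols],
                        empirical_sd = apply(est, 2, stats::sd),
                        mean_se = colMeans(se), coverage = cover,
                        row.names = NULL)
  list(summary = summary, estimates = est, se = se, n_reps = n_reps,
       sweep = sweep)
}

#' Collider/assortment bias demonstration for the duo model
#'
#' Fits the trio MR model and the mother-offspring duo model (father's PGI
#' and BMI omitted) on one large cohort, then repeats with the paternal
#' nurture effect set to zero, and (optionally) with assortment switched off,
#' quantifying the mother-coefficient bias of each configuration against the
#' generative truth in Monte Carlo SE units.
#'
#' @param config a [sim_config()] with `rho_am > 0` and some positive
#'   `gamma_p_t` (the configuration in which the duo model is biased).
#' @param sweep sweep age analysed (default: last).
#' @param include_no_assortment also run the `rho_am = 0` variant, isolating
#'   the collider path from the assortment path.
#' @return data frame: scenario, model, estimate, se, truth, bias, bias_z.
#' @export
run_bias_demo <- function(config, sweep = utils::tail(config$sweep_ages, 1),
                          include_no_assortment = FALSE) {
  t_idx <- match(sweep, config$sweep_ages)
  if (config$rho_am <= 0 || config$gamma_p_t[t_idx] <= 0)
    stop("bias demo requires rho_am > 0 and gamma_p_t > 0 at the analysed sweep",
         call. = FALSE)
  scenarios <- list(nurture_father = config)
  cfg0 <- config
  cfg0$gamma_p_t <- rep(0, length(config$gamma_p_t))
  cfg0$seed <- config$seed + 1L
  scenarios$null_father <- cfg0
  if (include_no_assortment) {
    cfg1 <- config
    cfg1$rho_am <- 0
    cfg1$seed <- config$seed + 2L
    scenarios$no_assortment <- cfg1
  }
  out <- list()
  for (nm in names(scenarios)) {
    cfg <- scenarios[[nm]]
    co <- simulate_trio_cohort(cfg)
    pgi <- build_pgi(co)
    truth <- cfg$gamma_m_t[t_idx]
    for (mdl in c("trio", "duo")) {
      fit <- fit_trio_mr(co, "bmi", sweep, pgi, drop_father = mdl == "duo")
      b <- unname(fit$coef["mother_bmi"]); s <- unname(fit$se["mother_bmi"])
      out[[length(out) + 1L]] <- data.frame(
        scenario = nm, model = mdl, estimate = b, se = s, truth = truth,
        bias = b - truth, bias_z = (b - truth) / s, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Type-I error calibration under a global null configuration
#'
#' Simulates replicate cohorts, fits the phenotypic and trio MR models at
#' one sweep, and reports the rejection rate of the nominal two-sided 5%
#' test for the maternal and paternal coefficients. Intended for a
#' configuration with all effect parameters zero, where every rejection is a
#' type-I error.
#'
#' @param config a [sim_config()] (typically with `delta_t`, `gamma_m_t`,
#'   `gamma_p_t` all zero and `rho_am = 0`).
#' @param n_reps number of replicate cohorts.
#' @param sweep sweep age analysed (default: last).
#' @param alpha nominal level.
#' @return data frame: model, term, rejection_rate, n_reps.
#' @export
run_null_calibration <- function(config, n_reps = 500L,
                                 sweep = utils::tail(config$sweep_ages, 1),
                                 alpha = 0.05) {
  zcrit <- stats::qnorm(1 - alpha / 2)
  terms <- c("mother_bmi", "father_bmi")
  rej <- array(0, c(2, 2), dimnames = list(c("phenotypic", "mr"), terms))
  for (r in seq_len(n_reps)) {
    cfg <- config
    cfg$seed <- config$seed + r
    co <- simulate_trio_cohort(cfg)
    pgi <- build_pgi(co)
    fits <- list(phenotypic = fit_phenotypic_model(co, "bmi", sweep),
                 mr = fit_trio_mr(co, "bmi", sweep, pgi))
    for (m in names(fits))
      for (tm in terms)
        rej[m, tm] <- rej[m, tm] +
          (abs(fits[[m]]$coef[tm] / fits[[m]]$se[tm]) > zcrit)
  }
  data.frame(model = rep(rownames(rej), each = 2),
             term = rep(terms, 2),
             rejection_rate = as.vector(t(rej)) / n_reps,
             n_reps = n_reps, stringsAsFactors = FALSE)
}
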