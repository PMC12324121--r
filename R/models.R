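# design construction shared by the model families

# covariate matrix (with intercept) for one sweep; sweep = NULL omits the
# age spline (used for birthweight, assessed once)
design_covariates <- function(ph, sweep = NULL) {
  parts <- list("(Intercept)" = rep(1, nrow(ph)), sex = ph$sex)
  if (!is.null(sweep)) {
    age <- ph[[paste0("age_", sweep)]]
    ns_b <- natural_spline_basis(age, df = 2)
    parts$age_ns1 <- ns_b[, 1]
    parts$age_ns2 <- ns_b[, 2]
  }
  parts$maternal_age <- ph$maternal_age
  parts$maternal_educ <- ph$maternal_educ
  cls <- factor(ph$social_class)
  if (nlevels(cls) > 1L) {
    dm <- stats::model.matrix(~ cls)[, -1, drop = FALSE]
    colnames(dm) <- paste0("class", levels(cls)[-1])
    for (nm in colnames(dm)) parts[[nm]] <- dm[, nm]
  }
  parts$pc1 <- ph$pc1
  parts$pc2 <- ph$pc2
  X <- do.call(cbind, parts)
  colnames(X) <- names(parts)
  X
}

# outcome vector: "bmi" -> bmi_<sweep>; "birthweight"; otherwise a literal
# pheno column name (e.g. "bmiz_17", "diet_factor_14")
outcome_vector <- function(ph, outcome, sweep = NULL) {
  col <- switch(outcome,
                bmi = paste0("bmi_", sweep),
                birthweight = "birthweight",
                outcome)
  if (is.null(ph[[col]]))
    stop("outcome column '", col, "' not found in cohort phenotypes",
         call. = FALSE)
  ph[[col]]
}

# assemble complete-case pieces for one model; regression-specific complete
# cases: rows must be complete on everything the model uses, and (for
# sweep-specific outcomes) participating at that sweep
model_frame <- function(cohort, outcome, sweep, pgi = NULL, weights = NULL,
                        need_pgi = c("none", "child", "all"),
                        require_participation = !is.null(sweep)) {
  need_pgi <- match.arg(need_pgi)
  ph <- cohort$pheno
  y <- outcome_vector(ph, outcome, sweep)
  Xc <- design_covariates(ph, sweep)
  endog <- cbind(mother_bmi = ph$mother_bmi_rep, father_bmi = ph$father_bmi_rep)
  w <- if (is.null(weights)) ph$recruit_weight else weights
  P <- NULL
  if (need_pgi != "none") {
    if (is.null(pgi)) stop("this model requires PGIs; supply 'pgi' (see build_pgi)",
                           call. = FALSE)
    stopifnot(identical(pgi$family_id, ph$family_id))
    P <- cbind(pgi_mother = pgi$pgi_mother, pgi_father = pgi$pgi_father,
               pgi_child = pgi$pgi_child)
  }
  ok <- !is.na(y) & stats::complete.cases(Xc) & stats::complete.cases(endog) &
    !is.na(w)
  if (!is.null(P)) ok <- ok & stats::complete.cases(P)
  if (require_participation && !is.null(sweep)) {
    part <- ph[[paste0("part_", sweep)]]
    if (!is.null(part)) ok <- ok & part
  }
  if (!any(ok)) stop("no complete cases for outcome '", outcome, "'",
                     if (!is.null(sweep)) paste0(" at sweep ", sweep), call. = FALSE)
  list(y = y[ok], Xc = Xc[ok, , drop = FALSE], endog = endog[ok, , drop = FALSE],
       pgi = if (!is.null(P)) P[ok, , drop = FALSE] else NULL,
       weights = w[ok], cluster = ph$cluster[ok], n = sum(ok))
}

#' Phenotypic multivariable regression of an offspring outcome
#'
#' Weighted least squares of the outcome on mother's and father's
#' self-reported BMI plus covariates (child sex, age-at-assessment natural
#' spline, maternal age, maternal education, social-class indicators,
#' principal components). The offspring PGI is *not* included, following
#' standard practice for phenotypic models.
#'
#' @param cohort a `trio_cohort`.
#' @param outcome `"bmi"`, `"birthweight"`, or a phenotype column name.
#' @param sweep sweep age in years (NULL for birthweight).
#' @param weights combined analysis weights (default: recruitment weights).
#' @param cluster optional cluster ids for cluster-robust variance (use
#'   `cohort$pheno$cluster` under the clustered design).
#' @return a `trio_model` tagged `"phenotypic"`.
#' @export
fit_phenotypic_model <- function(cohort, outcome = "bmi", sweep = NULL,
                                 weights = NULL, cluster = NULL) {
  mf <- model_frame(cohort, outcome, sweep, weights = weights, need_pgi = "none")
  cl <- if (!is.null(cluster)) mf$cluster else NULL
  fit_wls(mf$y, cbind(mf$endog, mf$Xc), mf$weights, cluster = cl,
          model = "phenotypic")
}

#' Trio Mendelian-randomization model (IV-2SLS)
#'
#' Instruments mother's and father's self-reported BMI with their
#' standardized polygenic indices, conditioning on the child's PGI and the
#' full covariate set. With `drop_father = TRUE` the father's BMI and PGI are
#' omitted (the mother-offspring "duo" sensitivity model, which is biased
#' when the father's PGI has an indirect effect, via the collider opened by
#' conditioning on the child's PGI and via assortative mating).
#'
#' @inheritParams fit_phenotypic_model
#' @param pgi output of [build_pgi()].
#' @param drop_father fit the duo model (mother only).
#' @return a `trio_model` tagged `"mr"` (or `"mr_duo"`), with per-endogenous
#'   first-stage partial F statistics.
#' @export
fit_trio_mr <- function(cohort, outcome = "bmi", sweep = NULL,
                        pgi = build_pgi(cohort), weights = NULL,
                        cluster = NULL, drop_father = FALSE) {
  mf <- model_frame(cohort, outcome, sweep, pgi = pgi, weights = weights,
                    need_pgi = "all")
  cl <- if (!is.null(cluster)) mf$cluster else NULL
  if (drop_father) {
    endog <- mf$endog[, "mother_bmi", drop = FALSE]
    instr <- mf$pgi[, "pgi_mother", drop = FALSE]
  } else {
    endog <- mf$endog
    instr <- mf$pgi[, c("pgi_mother", "pgi_father"), drop = FALSE]
  }
  exog <- cbind(pgi_child = mf$pgi[, "pgi_child"], mf$Xc)
  fit_iv2sls(mf$y, endog, instr, exog, mf$weights, cluster = cl,
             model = if (drop_father) "mr_duo" else "mr")
}

#' Three-PGI direct/indirect genetic-effect decomposition
#'
#' Weighted regression of the outcome on mother's, father's and child's
#' standardized PGIs plus covariates. The child coefficient captures the
#' direct genetic effect; the parental coefficients capture indirect
#' (nurture) effects. Also reports the mother/child coefficient ratio with a
#' delta-method standard error; the ratio is reported as `NA` when the child
#' coefficient is indistinguishable from zero (|estimate| < 2 SE).
#'
#' @inheritParams fit_trio_mr
#' @return a `trio_model` tagged `"pgi"` with an extra `ratio` field
#'   (`estimate`, `se`).
#' @export
fit_pgi_model <- function(cohort, outcome = "bmi", sweep = NULL,
                          pgi = build_pgi(cohort), weights = NULL,
                          cluster = NULL) {
  mf <- model_frame(cohort, outcome, sweep, pgi = pgi, weights = weights,
                    need_pgi = "all")
  cl <- if (!is.null(cluster)) mf$cluster else NULL
  fit <- fit_wls(mf$y, cbind(mf$pgi, mf$Xc), mf$weights, cluster = cl,
                 model = "pgi")
  bm <- fit$coef["pgi_mother"]; bc <- fit$coef["pgi_child"]
  if (is.finite(bc) && abs(bc) >= 2 * fit$se["pgi_child"]) {
    g <- c(1 / bc, -bm / bc^2)
    Vb <- fit$vcov[c("pgi_mother", "pgi_child"), c("pgi_mother", "pgi_child")]
    fit$ratio <- list(estimate = unname(bm / bc),
                      se = sqrt(drop(t(g) %*% Vb %*% g)))
  } else {
    fit$ratio <- list(estimate = NA_real_, se = NA_real_)
  }
  fit
}

#' Linear probability model for a dichotomized diet item
#'
#' Dichotomizes an ordinal, healthy-coded diet item at a category boundary
#' and fits the phenotypic or MR machinery with the 0/1 outcome, so
#' coefficients are probability differences per kg/m^2 of parental BMI.
#'
#' @inheritParams fit_trio_mr
#' @param item diet item name (e.g. `"fruit"`).
#' @param cutpoint first category counted as healthy (see [dichotomize()]).
#' @param mode `"phenotypic"` or `"mr"`.
#' @return a `trio_model` tagged `"lpm_phenotypic"` or `"lpm_mr"`.
#' @export
fit_lpm <- function(cohort, item, sweep, cutpoint = 3L,
                    mode = c("phenotypic", "mr"), pgi = NULL, weights = NULL,
                    cluster = NULL) {
  mode <- match.arg(mode)
  col <- paste0("diet_", item, "_", sweep)
  if (is.null(cohort$pheno[[col]]))
    stop("diet item column '", col, "' not found", call. = FALSE)
  tmp <- cohort
  bin_col <- paste0("bin_", item, "_", sweep)
  tmp$pheno[[bin_col]] <- dichotomize(cohort$pheno[[col]], cutpoint)
  fit <- if (mode == "phenotypic") {
    fit_phenotypic_model(tmp, bin_col, sweep, weights, cluster)
  } else {
    if (is.null(pgi)) pgi <- build_pgi(cohort)
    fit_trio_mr(tmp, bin_col, sweep, pgi, weights, cluster)
  }
  fit$model <- paste0("lpm_", mode)
  fit
}
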