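test_that("phenotypic model recovers the nurture effect absent genetic confounding", {
  cfg <- sim_config(n_families = 20000, n_snps = 60, delta_t = 0,
                    gamma_m_t = 0.26, gamma_p_t = 0, rho_am = 0,
                    sigma_report = 0, seed = 61)
  co <- cached_fixture("pheno_cohort", function() simulate_trio_cohort(cfg))
  fit <- fit_phenotypic_model(co, "bmi", 17)
  mc_se <- fit$se["mother_bmi"]
  expect_lt(abs(fit$coef["mother_bmi"] - 0.26), 2 * mc_se)
  expect_lt(abs(fit$coef["father_bmi"]), 2 * fit$se["father_bmi"])
})

test_that("trio MR recovers maternal and paternal effects on the default calibration", {
  co <- default_cohort()
  pgi <- default_pgi()
  fit <- fit_trio_mr(co, "bmi", 17, pgi)
  gm <- co$config$gamma_m_t[6]
  expect_lt(abs(fit$coef["mother_bmi"] - gm), 3 * fit$se["mother_bmi"])
  expect_lt(abs(fit$coef["father_bmi"]), 3 * fit$se["father_bmi"])
  expect_true(all(fit$first_stage_F > 10))
  # MR on the z-score outcome runs end to end
  expect_error(fit_trio_mr(co, "bmi_z_missing", 17, pgi), "not found")
})

test_that("the duo model is unbiased when the father has no indirect effect", {
  co <- default_cohort()  # gamma_p = 0 by default
  pgi <- default_pgi()
  duo <- fit_trio_mr(co, "bmi", 17, pgi, drop_father = TRUE)
  gm <- co$config$gamma_m_t[6]
  expect_lt(abs(duo$coef["mother_bmi"] - gm), 3 * duo$se["mother_bmi"])
  expect_identical(duo$model, "mr_duo")
  expect_false("father_bmi" %in% names(duo$coef))
})

test_that("the three-PGI model separates direct and indirect effects", {
  co <- default_cohort()
  pgi <- default_pgi()
  fit <- fit_pgi_model(co, "bmi", 17, pgi)
  lambda <- co$truth$lambda_first_stage
  gm <- co$config$gamma_m_t[6]
  # structural values: mother coef ~ gamma_m * lambda, child coef ~ delta
  # (plus the transmitted-nurture share); directions and rough magnitudes
  expect_lt(abs(fit$coef["pgi_mother"] - gm * lambda), 4 * fit$se["pgi_mother"])
  expect_gt(fit$coef["pgi_child"] / fit$se["pgi_child"], 5)
  expect_lt(abs(fit$coef["pgi_father"]), 3 * fit$se["pgi_father"])
  expect_false(is.na(fit$ratio$estimate))
  expect_gt(fit$ratio$estimate, 0)
})

test_that("mother/child PGI coefficient ratio falls in the calibration band", {
  co <- cached_fixture("ratio_cohort", function()
    simulate_trio_cohort(sim_config(n_families = 8000, n_snps = 120, seed = 62)))
  fit <- fit_pgi_model(co, "bmi", 17, build_pgi(co))
  expect_gt(fit$ratio$estimate, 0.25)
  expect_lt(fit$ratio$estimate, 0.50)
})

test_that("null parental PGI effects leave the ratio undefined or near zero", {
  cfg <- sim_config(n_families = 3000, n_snps = 60, gamma_m_t = 0,
                    gamma_p_t = 0, rho_am = 0, seed = 63)
  co <- simulate_trio_cohort(cfg)
  fit <- fit_pgi_model(co, "bmi", 17, build_pgi(co))
  expect_lt(abs(fit$coef["pgi_mother"]), 3 * fit$se["pgi_mother"])
  expect_gt(fit$coef["pgi_child"], 0)
})

test_that("linear probability models match the bivariate-normal closed form", {
  set.seed(64)
  n <- 20000
  x <- rnorm(n, 0, 4)            # centred maternal BMI
  b <- -0.05 * 0.6               # latent loading x BMI effect
  lat <- b * x + rnorm(n, 0, sqrt(0.6^2 + 1))
  cutp <- 0.3
  yb <- as.integer(lat >= cutp)
  fit <- fit_wls(yb, cbind(int = 1, x = x))
  sigma_lat <- sqrt(b^2 * 16 + 0.6^2 + 1)
  slope_true <- dnorm(cutp / sigma_lat) * (b * 16 / sigma_lat) / 16
  expect_lt(abs(fit$coef["x"] - slope_true), 2 * fit$se["x"])
})

test_that("fit_lpm dichotomizes and propagates through both modes", {
  co <- default_cohort()
  pgi <- default_pgi()
  ph_fit <- fit_lpm(co, "fruit", 14, cutpoint = 3, mode = "phenotypic")
  expect_identical(ph_fit$model, "lpm_phenotypic")
  expect_true(all(abs(ph_fit$coef[c("mother_bmi", "father_bmi")]) < 0.05))
  mr_fit <- fit_lpm(co, "fruit", 14, cutpoint = 3, mode = "mr", pgi = pgi)
  expect_identical(mr_fit$model, "lpm_mr")
  # constant outcome: slopes zero, intercept equals the constant
  co2 <- co
  co2$pheno$diet_const_14 <- 3L
  cfit <- fit_lpm(co2, "const", 14, cutpoint = 3, mode = "phenotypic")
  expect_lt(max(abs(cfit$coef[names(cfit$coef) != "(Intercept)"])), 1e-10)
  expect_equal(unname(cfit$coef["(Intercept)"]), 1)
})

test_that("models error with no complete cases", {
  co <- tiny_cohort()
  co$pheno$bmi_17 <- NA_real_
  expect_error(fit_phenotypic_model(co, "bmi", 17), "complete cases")
})
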