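test_that("founder genotypes follow Hardy-Weinberg proportions", {
  set.seed(1)
  cfg <- sim_config(n_families = 10000, n_snps = 1, maf_range = c(0.5, 0.5))
  f <- draw_founders(cfg)
  freq <- table(factor(f$genotypes[, 1], levels = 0:2)) / 10000
  # (0.25, 0.5, 0.25) within 4 binomial SEs at n = 10,000
  expect_lt(abs(freq[[1]] - 0.25), 4 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(freq[[2]] - 0.50), 4 * sqrt(0.50 * 0.50 / 10000))
  expect_lt(abs(freq[[3]] - 0.25), 4 * sqrt(0.25 * 0.75 / 10000))
})

test_that("h2_bmi = 0 gives identically zero genetic values", {
  set.seed(2)
  f <- draw_founders(sim_config(n_families = 50, n_snps = 20, h2_bmi = 0))
  expect_identical(unique(f$snps$beta), 0)
  expect_identical(unique(f$gv), 0)
})

test_that("genetic value explains the configured share of parental BMI variance", {
  cfg <- sim_config(n_families = 20000, n_snps = 150, h2_bmi = 0.25, seed = 3)
  co <- simulate_trio_cohort(cfg)
  ratio <- var(co$gv$mother) / var(co$pheno$mother_bmi_true)
  expect_lt(abs(ratio - 0.25), 0.02)
})

test_that("invalid configurations are rejected with the parameter name", {
  expect_error(sim_config(h2_bmi = 1.5), "h2_bmi")
  expect_error(sim_config(rho_am = 1), "rho_am")
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(sweep_ages = c(5, 3)), "sweep_ages")
  expect_error(sim_config(sigma_report = -1), "sigma_report")
})

test_that("random mating gives near-zero spousal correlation", {
  set.seed(4)
  x <- rnorm(2000, 25, 4); y <- rnorm(2000, 25, 4)
  p <- pair_mates(x, y, 0)
  expect_true(all(sort(p) == 1:2000))
  expect_lt(abs(cor(x, y[p])), 0.05)
})

test_that("rank-matched pairing hits the target spousal correlation", {
  set.seed(5)
  x <- rnorm(10000, 25, 4); y <- rnorm(10000, 25, 4)
  p <- pair_mates(x, y, 0.21)
  expect_lt(abs(cor(x, y[p]) - 0.21), 0.03)
  p2 <- pair_mates(x, y, -0.4)
  expect_lt(abs(cor(x, y[p2]) + 0.4), 0.03)
  expect_error(pair_mates(x, y, 1), "rho_am")
  expect_error(pair_mates(x, y[1:10], 0.2), "equal length")
})

test_that("phenotypic assortment induces only weak parental PGI correlation", {
  cfg <- sim_config(n_families = 10000, n_snps = 150, h2_bmi = 0.05,
                    rho_am = 0.21, seed = 6)
  co <- simulate_trio_cohort(cfg)
  pgi <- build_pgi(co)
  r <- cor(pgi$pgi_mother, pgi$pgi_father)
  expect_lt(abs(r), 0.05)
  # bounded by h2 * rho_am + 3 MC SEs
  expect_lt(r, 0.05 * 0.21 + 3 / sqrt(10000))
})

test_that("transmission obeys Mendel's laws", {
  set.seed(7)
  zero <- matrix(0L, 1000, 1)
  expect_true(all(transmit(zero, zero) == 0))
  het <- matrix(1L, 10000, 1)
  child <- transmit(het, het)
  freq <- table(factor(child, levels = 0:2)) / 10000
  expect_lt(abs(freq[[1]] - 0.25), 4 * sqrt(0.25 * 0.75 / 10000))
  expect_lt(abs(freq[[2]] - 0.50), 4 * sqrt(0.25 / 10000))
  # heterozygous parent transmits the effect allele with probability 1/2:
  # one het parent x homozygous-ref parent
  child2 <- transmit(het, matrix(0L, 10000, 1))
  p_hat <- mean(child2)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 10000))
  expect_error(transmit(matrix(3L, 2, 2), matrix(0L, 2, 2)), "dosages")
  expect_error(transmit(matrix(0L, 2, 2), matrix(0L, 3, 2)), "dimensions")
})

test_that("child allele frequencies conserve founder frequencies", {
  co <- tiny_cohort()
  big <- cached_fixture("freq_cohort", function()
    simulate_trio_cohort(sim_config(n_families = 5000, n_snps = 80, seed = 8)))
  n <- big$config$n_families
  f_par <- (colMeans(big$geno$mother) + colMeans(big$geno$father)) / 4
  f_child <- colMeans(big$geno$child) / 2
  se <- sqrt(pmax(f_par * (1 - f_par), 1e-12) / (2 * n))
  expect_true(all(abs(f_child - f_par) <= 3 * se))
})

test_that("cohorts are bit-reproducible given config and seed", {
  cfg <- sim_config(n_families = 50, n_snps = 10, seed = 123)
  a <- simulate_trio_cohort(cfg)
  b <- simulate_trio_cohort(cfg)
  expect_identical(a$geno, b$geno)
  expect_identical(a$pheno, b$pheno)
})
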