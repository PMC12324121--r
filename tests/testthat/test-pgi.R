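write_ss <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

test_that("ambiguous-allele rows are dropped and counted", {
  path <- write_ss(data.frame(SNP = c("s1", "s2", "s3", "s4"),
                              A1 = c("A", "A", "C", "G"),
                              A2 = c("T", "G", "G", "C"),
                              BETA = c(0.1, 0.2, 0.3, 0.4),
                              P = c(1e-9, 1e-9, 1e-9, 1e-9)))
  ss <- read_sumstats(path)
  expect_identical(ss$SNP, "s2")
  expect_identical(attr(ss, "n_ambiguous_dropped"), 3L)
})

test_that("malformed sumstats files produce named errors", {
  path <- write_ss(data.frame(SNP = "s1", A1 = "A", A2 = "G", BETA = 0.1))
  expect_error(read_sumstats(path), "P")
  path2 <- write_ss(data.frame(SNP = c("s1", "s1"), A1 = "A", A2 = "G",
                               BETA = 0.1, P = 0.5))
  expect_error(read_sumstats(path2), "s1")
  path3 <- write_ss(data.frame(SNP = character(), A1 = character(),
                               A2 = character(), BETA = numeric(), P = numeric()))
  ss <- read_sumstats(path3)
  expect_identical(nrow(ss), 0L)
  expect_error(pgi_score(matrix(0, 2, 2), ss), "empty")
})

test_that("p-value thresholding is strict and clumping is flagged off", {
  ss <- as_sumstats(data.frame(SNP = c("a", "b"), A1 = "A", A2 = "G",
                               BETA = 1, P = c(1e-9, 1e-7)))
  kept <- select_snps(ss, 5e-8)
  expect_identical(kept$SNP, "a")
  expect_false(attr(kept, "clumped"))
  expect_identical(nrow(select_snps(ss, 1)), 2L)
})

test_that("simulated-GWAS thresholding matches a brute-force recount", {
  co <- cached_fixture("gwas_cohort", function()
    simulate_trio_cohort(sim_config(n_families = 200, n_snps = 300,
                                    h2_bmi = 0.05, seed = 21)))
  set.seed(22)
  ss <- simulate_gwas(co, n_discovery = 30000)
  kept <- select_snps(ss, 5e-8)
  expect_identical(nrow(kept), sum(ss$P < 5e-8))
  expect_gt(nrow(kept), 0L)
  # estimated effects track the generative ones
  expect_gt(cor(ss$BETA, co$snps$beta), 0.5)
})

test_that("scoring matches closed forms and a brute-force double loop", {
  ss1 <- as_sumstats(data.frame(SNP = "s1", A1 = "A", A2 = "G", BETA = 0.5, P = 0.5))
  g <- matrix(2, 1, 1, dimnames = list(NULL, "s1"))
  expect_equal(as.numeric(pgi_score(g, ss1, weighted = TRUE)), 1.0)
  expect_equal(as.numeric(pgi_score(g, ss1, weighted = FALSE)), 2.0)
  expect_equal(as.numeric(pgi_score(0 * g, ss1)), 0)

  set.seed(23)
  G <- matrix(sample(0:2, 50, TRUE), 10, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  ss <- as_sumstats(data.frame(SNP = paste0("v", 1:5), A1 = "A", A2 = "G",
                               BETA = rnorm(5), P = 0.5))
  brute <- numeric(10)
  for (i in 1:10) for (j in 1:5) brute[i] <- brute[i] + ss$BETA[j] * G[i, j]
  expect_equal(as.numeric(pgi_score(G, ss)), brute, tolerance = 1e-12)
  expect_error(pgi_score(G[, 1:3], ss), "v4")
})

test_that("allele flips shift weighted scores by a constant only", {
  set.seed(24)
  G <- matrix(sample(0:2, 60, TRUE), 20, 3,
              dimnames = list(NULL, paste0("v", 1:3)))
  ss <- as_sumstats(data.frame(SNP = paste0("v", 1:3), A1 = c("A", "C", "G"),
                               A2 = c("G", "T", "T"), BETA = c(0.5, -0.2, 0.3),
                               P = 0.5))
  ss_flip <- ss
  ss_flip$A1 <- ss$A2; ss_flip$A2 <- ss$A1; ss_flip$BETA <- -ss$BETA
  ea <- stats::setNames(ss$A1, ss$SNP)  # dosages count the original A1
  s0 <- pgi_score(G, ss, effect_alleles = ea)
  s1 <- pgi_score(G, ss_flip, effect_alleles = ea)
  expect_identical(attr(s1, "n_flipped"), 3L)
  shift <- s1 - s0
  expect_equal(max(shift) - min(shift), 0, tolerance = 1e-12)
  expect_equal(unique(round(shift, 10)), -2 * sum(ss$BETA))
  expect_equal(standardize_pgi(s1), standardize_pgi(s0), ignore_attr = TRUE)
})

test_that("standardization uses reference moments only", {
  set.seed(25)
  raw <- rnorm(100)
  z_all <- standardize_pgi(raw)
  expect_lt(abs(mean(z_all)), 1e-10)
  expect_lt(abs(sd(z_all) - 1), 1e-10)
  half <- 1:50
  z_half <- standardize_pgi(raw, half)
  expect_lt(abs(mean(z_half[half])), 1e-10)
  expect_lt(abs(sd(z_half[half]) - 1), 1e-10)
  expect_gt(abs(mean(z_half[-half])), 1e-6)
  expect_error(standardize_pgi(rep(1, 10)), "zero")
})

test_that("Mendelian errors are detected per the impossibility rules", {
  m <- matrix(c(0L, 0L, 2L), 1, 3)
  f <- matrix(c(0L, 2L, 2L), 1, 3)
  c_ <- matrix(c(1L, 1L, 1L), 1, 3)
  res <- mendelian_error_rate(m, f, c_)
  # SNP1: parents 0/0 child 1 -> error; SNP2: 0/2 child 1 -> fine;
  # SNP3: 2/2 child 1 -> error
  expect_equal(res$per_family, 100 * 2 / 3)
  expect_error(mendelian_error_rate(m, f, NULL), "three")
})

test_that("simulated cohorts have exactly zero Mendelian errors", {
  res <- mendelian_error_rate(default_cohort())
  expect_identical(res$mean, 0)
  expect_identical(res$max, 0)
})

test_that("child PGI regressed on mid-parent PGI has slope near 1 under random mating", {
  co <- cached_fixture("rm_cohort", function()
    simulate_trio_cohort(sim_config(n_families = 5000, n_snps = 120,
                                    rho_am = 0, seed = 26)))
  pgi <- build_pgi(co)
  mid <- (pgi$pgi_mother + pgi$pgi_father) / 2
  slope <- coef(lm(pgi$pgi_child ~ mid))[2]
  expect_lt(abs(slope - 1), 0.05)
})

test_that("trio PGIs are standardized in the pooled trio reference", {
  pgi <- default_pgi()
  pooled <- c(pgi$pgi_mother, pgi$pgi_father, pgi$pgi_child)
  expect_lt(abs(mean(pooled)), 1e-10)
  expect_lt(abs(sd(pooled) - 1), 1e-10)
  expect_identical(attr(pgi, "n_snps_used"), 120L)
})
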