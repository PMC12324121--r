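# shared fixtures, built once per test run and cached

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(name, maker) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- maker()
  .fixture_cache[[name]]
}

# mid-size cohort under the default (paper-like) generative calibration
default_cohort <- function() {
  cached_fixture("default", function()
    simulate_trio_cohort(sim_config(n_families = 4000, n_snps = 120, seed = 424)))
}

default_pgi <- function() {
  cached_fixture("default_pgi", function() build_pgi(default_cohort()))
}

# tiny cohort for I/O and structural checks
tiny_cohort <- function() {
  cached_fixture("tiny", function()
    simulate_trio_cohort(sim_config(n_families = 60, n_snps = 12, seed = 99)))
}

# Burt-matrix eigendecomposition route: independent oracle for the principal
# inertias of indicator-matrix correspondence analysis
burt_inertias <- function(Z, J) {
  n <- nrow(Z)
  B <- crossprod(Z)
  cm <- colSums(Z) / (n * J)
  SB <- (B / (n * J^2) - tcrossprod(cm)) / sqrt(tcrossprod(cm))
  ev <- eigen(SB, symmetric = TRUE)$values
  ev[ev > 1e-12]
}

# closed-form design-based variance of a survey-weighted mean under a
# stratified, with-replacement cluster design (linearization)
stratified_mean_var <- function(y, w, stratum, cluster) {
  mu <- sum(w * y) / sum(w)
  z <- w * (y - mu) / sum(w)
  v <- 0
  for (h in unique(stratum)) {
    idx <- stratum == h
    zc <- tapply(z[idx], cluster[idx], sum)
    n_h <- length(zc)
    v <- v + n_h / (n_h - 1) * sum((zc - mean(zc))^2)
  }
  v
}
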