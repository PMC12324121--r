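#' Non-response weights from a logistic response model
#'
#' Fits a logistic regression of the response flag on baseline covariates,
#' floors the estimated response probabilities at `p_floor`, and combines
#' them with the design weights as `design / p_hat`, renormalized to mean 1
#' among responders. When everyone responds the combined weights equal the
#' design weights (up to the mean-1 normalization).
#'
#' @param covariates data frame or matrix of baseline covariates (complete).
#' @param response logical (or 0/1) response flag.
#' @param design_weights recruitment/design weights (default 1).
#' @param p_floor minimum allowed response probability (default 0.02).
#' @return list of class `weight_set`: `table` (response, p_hat,
#'   design_weight, combined_weight per unit), `model` coefficients (NULL in
#'   the all-respond case) and `normalization`.
#' @export
estimate_response_weights <- function(covariates, response,
                                      design_weights = NULL, p_floor = 0.02) {
  response <- as.logical(response)
  n <- length(response)
  if (anyNA(response)) stop("response flag must be non-missing", call. = FALSE)
  X <- as.data.frame(covariates)
  if (nrow(X) != n) stop("covariates and response differ in length", call. = FALSE)
  if (anyNA(X)) stop("baseline covariates must be complete", call. = FALSE)
  if (is.null(design_weights)) design_weights <- rep(1, n)
  if (any(design_weights <= 0)) stop("design weights must be > 0", call. = FALSE)
  if (!any(response)) stop("no responders; cannot construct weights", call. = FALSE)

  if (all(response)) {
    p_hat <- rep(1, n)
    coefs <- NULL
  } else {
    dat <- cbind(.resp = as.integer(response), X)
    separated <- FALSE
    fit <- withCallingHandlers(
      stats::glm(.resp ~ ., data = dat, family = stats::binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          separated <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (separated || !fit$converged)
      stop("response model shows (quasi-)separation; reduce the covariate set",
           call. = FALSE)
    p_hat <- pmax(stats::fitted(fit), p_floor)
    coefs <- stats::coef(fit)
  }
  combined <- design_weights / p_hat
  norm <- mean(combined[response])
  combined <- combined / norm
  structure(list(
    table = data.frame(response = response, p_hat = p_hat,
                       design_weight = design_weights,
                       combined_weight = combined),
    model = coefs, normalization = norm), class = "weight_set")
}

#' Rao-Wu rescaling bootstrap for a survey-weighted contrast
#'
#' Per replicate and stratum with `n_h` clusters, resamples `n_h - 1`
#' clusters with replacement and rescales each unit's weight by
#' `n_h / (n_h - 1)` times the cluster's resampling multiplicity, so weights
#' are unbiased in expectation. `contrast_fn(weights)` is evaluated on each
#' replicate weight vector; the 95% CI is percentile-based (order statistics
#' of the replicates).
#'
#' @param weights base analysis weights (one per unit).
#' @param stratum,cluster design identifiers per unit; every stratum must
#'   contain at least 2 clusters.
#' @param contrast_fn function of a weight vector returning a scalar (e.g.
#'   the MR-minus-phenotypic mother coefficient).
#' @param B number of bootstrap replicates (default 500).
#' @param seed RNG seed for the replicate draws.
#' @return list of class `bootstrap_result`: `replicates`, `estimate`
#'   (contrast at the original weights), `se`, `ci` (percentile 2.5/97.5%),
#'   `B`, `seed`.
#' @export
rao_wu_bootstrap <- function(weights, stratum, cluster, contrast_fn,
                             B = 500L, seed = 1L) {
  n <- length(weights)
  stopifnot(length(stratum) == n, length(cluster) == n)
  strata <- unique(stratum)
  # per-stratum cluster bookkeeping
  info <- lapply(strata, function(h) {
    idx <- which(stratum == h)
    cl <- factor(cluster[idx])
    if (nlevels(cl) < 2L)
      stop("stratum '", h, "' has a single cluster; Rao-Wu bootstrap needs >= 2",
           call. = FALSE)
    list(idx = idx, cl_int = as.integer(cl), n_h = nlevels(cl))
  })
  set.seed(seed)
  reps <- numeric(B)
  for (b in seq_len(B)) {
    w <- weights
    for (s in info) {
      n_h <- s$n_h
      m <- tabulate(sample.int(n_h, n_h - 1L, replace = TRUE), nbins = n_h)
      w[s$idx] <- weights[s$idx] * (n_h / (n_h - 1L)) * m[s$cl_int]
    }
    reps[b] <- contrast_fn(w)
  }
  est <- contrast_fn(weights)
  srt <- sort(reps)
  ci <- unname(stats::quantile(srt, c(0.025, 0.975), type = 1))
  structure(list(replicates = reps, estimate = est, se = stats::sd(reps),
                 ci = ci, B = B, seed = seed), class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("Rao-Wu bootstrap (B = %d): estimate %.4f, SE %.4f, 95%% CI [%.4f, %.4f]\n",
              x$B, x$estimate, x$se, x$ci[1], x$ci[2]))
  invisible(x)
}

#' Z-test for the difference of two coefficients
#'
#' `z = (est1 - est2) / sqrt(se1^2 + se2^2 - 2 cov)`. Supply the covariance
#' of the two estimates (e.g. from joint bootstrap replicates) when they come
#' from the same sample; with `cov = 0` (the default) the test ignores their
#' correlation, which is conservative for positively correlated estimates,
#' and a message notes the caveat.
#'
#' @param est1,se1,est2,se2 estimates and standard errors (SEs > 0).
#' @param cov covariance between the two estimates (default 0).
#' @param quiet suppress the zero-covariance caveat.
#' @return list: `z`, `p` (two-sided normal), `diff`, `se_diff`.
#' @export
diff_z_test <- function(est1, se1, est2, se2, cov = 0, quiet = FALSE) {
  if (se1 <= 0 || se2 <= 0) stop("standard errors must be > 0", call. = FALSE)
  v <- se1^2 + se2^2 - 2 * cov
  if (v <= 0) stop("variance of the difference is non-positive", call. = FALSE)
  if (cov == 0 && !quiet)
    message("diff_z_test: covariance taken as 0; same-sample estimates are correlated")
  z <- (est1 - est2) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)), diff = est1 - est2,
       se_diff = sqrt(v))
}
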