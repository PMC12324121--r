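#' Natural cubic spline basis for age at assessment
#'
#' Two-column natural cubic spline basis with boundary knots at the observed
#' age range and one interior knot at the median (the `df = 2` construction
#' of [splines::ns()]); the basis is linear beyond the boundary knots. Knots
#' are stored so the basis is reproducible on new data.
#'
#' @param x numeric values (ages in years).
#' @param df basis dimension (default 2).
#' @param knots,boundary optional explicit interior/boundary knots.
#' @return matrix with `df` columns and attributes `knots`, `boundary`.
#' @export
natural_spline_basis <- function(x, df = 2, knots = NULL, boundary = NULL) {
  if ((is.null(knots) || is.null(boundary)) && length(unique(x)) < 3L)
    stop("need at least 3 distinct values for a natural spline basis", call. = FALSE)
  if (is.null(boundary)) boundary <- range(x)
  if (is.null(knots))
    knots <- stats::quantile(x, probs = seq_len(df - 1) / df, names = FALSE)
  b <- splines::ns(x, knots = knots, Boundary.knots = boundary)
  out <- unclass(b)[, , drop = FALSE]
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  attr(out, "knots") <- knots
  attr(out, "boundary") <- boundary
  out
}

# construct a trio_model result object
new_trio_model <- function(coef, vcov, n, model, first_stage_F = NULL,
                           dropped = character(0), extra = list()) {
  se <- sqrt(diag(vcov))
  out <- c(list(coef = coef, vcov = vcov, se = se,
                ci_low = coef - 1.96 * se, ci_high = coef + 1.96 * se,
                n = n, model = model, first_stage_F = first_stage_F,
                dropped = dropped), extra)
  class(out) <- "trio_model"
  out
}

#' @export
print.trio_model <- function(x, ...) {
  cat(sprintf("trio_model [%s], n = %d\n", x$model, x$n))
  tab <- data.frame(estimate = x$coef, se = x$se,
                    ci_low = x$ci_low, ci_high = x$ci_high)
  print(round(tab, 4))
  if (!is.null(x$first_stage_F))
    cat("first-stage partial F:",
        paste(sprintf("%s = %.1f", names(x$first_stage_F), x$first_stage_F),
              collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.trio_model <- function(object, ...) object$coef

#' @export
vcov.trio_model <- function(object, ...) object$vcov

# drop collinear columns by pivoted QR; returns kept index, warns with names
drop_collinear <- function(Xt, names_x) {
  qrx <- qr(Xt)
  if (qrx$rank == ncol(Xt)) return(seq_len(ncol(Xt)))
  keep <- sort(qrx$pivot[seq_len(qrx$rank)])
  warning("dropping collinear column(s): ",
          paste(names_x[-keep], collapse = ", "), call. = FALSE)
  keep
}

# sandwich covariance given bread (k x k), per-row scores (n x k), cluster
robust_vcov <- function(bread, scores, n, k, cluster = NULL) {
  if (is.null(cluster)) {
    meat <- crossprod(scores)
    adj <- n / (n - k)
  } else {
    sg <- rowsum(scores, group = cluster)
    meat <- crossprod(sg)
    g <- nrow(sg)
    adj <- g / (g - 1) * (n - 1) / (n - k)
  }
  adj * bread %*% meat %*% bread
}

#' Weighted least squares with robust (sandwich) variance
#'
#' Minimizes `sum w_i (y_i - x_i' beta)^2`. Variance is the HC1-style
#' heteroskedasticity-consistent sandwich with small-sample factor
#' `n/(n-k)`, or the cluster-robust sandwich (scores summed within cluster,
#' CR1 adjustment) when `cluster` is given. Collinear columns are dropped
#' with a warning naming them.
#'
#' @param y response vector.
#' @param X design matrix (include the intercept column yourself).
#' @param weights positive case weights (default 1).
#' @param cluster optional cluster ids for cluster-robust variance.
#' @param model tag stored on the result.
#' @return a `trio_model`.
#' @export
fit_wls <- function(y, X, weights = NULL, cluster = NULL, model = "wls") {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (nrow(X) != n) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0) || any(!is.finite(weights)))
    stop("weights must be non-negative and finite", call. = FALSE)
  if (any(weights == 0)) {  # zero replicate weights: unit contributes nothing
    pos <- weights > 0
    return(fit_wls(y[pos], X[pos, , drop = FALSE], weights[pos],
                   cluster[pos], model))
  }
  sw <- sqrt(weights)
  keep <- drop_collinear(X * sw, colnames(X))
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  X <- X[, keep, drop = FALSE]
  Xt <- X * sw
  k <- ncol(X)
  if (qr(Xt)$rank < k)
    stop("design remains rank deficient after dropping: ",
         paste(colnames(X), collapse = ", "), call. = FALSE)
  XtWX <- crossprod(Xt)
  bread <- chol2inv(chol(XtWX))
  beta <- drop(bread %*% crossprod(Xt, y * sw))
  names(beta) <- colnames(X)
  e <- y - drop(X %*% beta)
  scores <- X * (weights * e)
  V <- robust_vcov(bread, scores, n, k, cluster)
  dimnames(V) <- list(colnames(X), colnames(X))
  new_trio_model(beta, V, n, model, dropped = dropped,
                 extra = list(residuals = e, weights = weights))
}

#' First-stage partial F statistic for excluded instruments
#'
#' Weighted regression of one endogenous regressor on included exogenous
#' covariates plus the excluded instruments, against the covariates-only
#' restricted fit: `F = ((RSS_r - RSS_f)/q) / (RSS_f/(n - k_full))` with
#' weighted residual sums of squares.
#'
#' @param endog one endogenous regressor (vector).
#' @param instruments matrix of excluded instruments (q >= 1 columns).
#' @param exog matrix of included exogenous covariates (with intercept).
#' @param weights positive case weights.
#' @return the F statistic, with attributes `df1`, `df2`.
#' @export
first_stage_partial_F <- function(endog, instruments, exog, weights = NULL) {
  instruments <- as.matrix(instruments)
  exog <- as.matrix(exog)
  q <- ncol(instruments)
  if (q == 0L) stop("no excluded instruments supplied", call. = FALSE)
  n <- length(endog)
  if (is.null(weights)) weights <- rep(1, n)
  sw <- sqrt(weights)
  rss <- function(M) {
    f <- qr.resid(qr(M * sw), endog * sw)
    sum(f^2)
  }
  full <- cbind(exog, instruments)
  rss_f <- rss(full)
  rss_r <- rss(exog)
  k_full <- qr(full * sw)$rank
  f <- ((rss_r - rss_f) / q) / (rss_f / (n - k_full))
  structure(f, df1 = q, df2 = n - k_full)
}

#' Weighted two-stage least squares (IV) with robust variance
#'
#' With instruments `Z = [instruments, exog]` and regressors
#' `X = [endog, exog]`, computes the weighted 2SLS estimator: the weighted
#' projection of `X` onto `Z` replaces the endogenous columns, and the
#' second-stage normal equations give `beta`. The robust/cluster sandwich
#' uses second-stage structural residuals `y - X beta` (not fitted-X
#' residuals) with the projected regressors as scores. Per-endogenous
#' first-stage partial F statistics are attached.
#'
#' @param y response.
#' @param endog matrix of endogenous regressors (m columns).
#' @param instruments matrix of excluded instruments (>= m columns).
#' @param exog matrix of included exogenous covariates (with intercept).
#' @param weights positive case weights.
#' @param cluster optional cluster ids.
#' @param model tag stored on the result.
#' @return a `trio_model`; `first_stage_F` holds one partial F per
#'   endogenous regressor.
#' @export
fit_iv2sls <- function(y, endog, instruments, exog, weights = NULL,
                       cluster = NULL, model = "mr") {
  endog <- as.matrix(endog); instruments <- as.matrix(instruments)
  exog <- as.matrix(exog)
  if (is.null(colnames(endog))) colnames(endog) <- paste0("endog", seq_len(ncol(endog)))
  if (is.null(colnames(exog))) colnames(exog) <- paste0("exog", seq_len(ncol(exog)))
  if (ncol(instruments) < ncol(endog))
    stop("under-identified: fewer instruments than endogenous regressors",
         call. = FALSE)
  n <- length(y)
  if (is.null(weights)) weights <- rep(1, n)
  if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
  if (any(weights == 0)) {
    pos <- weights > 0
    return(fit_iv2sls(y[pos], endog[pos, , drop = FALSE], instruments[pos, , drop = FALSE],
                      exog[pos, , drop = FALSE], weights[pos], cluster[pos], model))
  }
  sw <- sqrt(weights)

  fs <- vapply(seq_len(ncol(endog)), function(j)
    as.numeric(first_stage_partial_F(endog[, j], instruments, exog, weights)),
    numeric(1))
  names(fs) <- colnames(endog)
  if (any(fs < 1e-6))
    stop("near-singular first stage (partial F < 1e-6) for: ",
         paste(names(fs)[fs < 1e-6], collapse = ", "), call. = FALSE)

  X <- cbind(endog, exog)
  Z <- cbind(instruments, exog)
  Zt <- Z * sw
  qz <- qr(Zt)
  if (qz$rank < ncol(Zt))
    stop("instrument/covariate matrix is rank deficient", call. = FALSE)
  Xhat_t <- qr.fitted(qz, X * sw)   # exog columns reproduced exactly
  colnames(Xhat_t) <- colnames(X)
  keep <- drop_collinear(Xhat_t, colnames(X))
  dropped <- setdiff(colnames(X), colnames(X)[keep])
  X <- X[, keep, drop = FALSE]
  Xhat_t <- Xhat_t[, keep, drop = FALSE]
  k <- ncol(X)
  A <- crossprod(Xhat_t)            # Xhat' W Xhat
  bread <- chol2inv(chol(A))
  beta <- drop(bread %*% crossprod(Xhat_t, y * sw))
  names(beta) <- colnames(X)
  u <- y - drop(X %*% beta)         # structural residuals
  Xhat <- Xhat_t / sw
  scores <- Xhat * (weights * u)
  V <- robust_vcov(bread, scores, n, k, cluster)
  dimnames(V) <- list(colnames(X), colnames(X))
  new_trio_model(beta, V, n, model, first_stage_F = fs, dropped = dropped,
                 extra = list(residuals = u, weights = weights))
}
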