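test_that("natural spline basis is natural and reproduces splines exactly", {
  set.seed(51)
  x <- runif(200, 0, 10)
  b <- natural_spline_basis(x, df = 2)
  expect_identical(ncol(b), 2L)
  # second derivative zero at/beyond the boundary knots (numerical)
  bb <- function(v) natural_spline_basis(v, knots = attr(b, "knots"),
                                         boundary = attr(b, "boundary"))
  h <- 1e-3
  # outward second difference at the boundary knot: the basis is linear there
  g0 <- attr(b, "boundary")[2]
  expect_lt(max(abs((bb(g0 + 2 * h) - 2 * bb(g0 + h) + bb(g0)) / h^2)), 1e-6)
  for (g in c(g0 + 1, 12, 15)) {
    d2 <- (bb(g + h) - 2 * bb(g) + bb(g - h)) / h^2
    expect_lt(max(abs(d2)), 1e-6)
  }
  # a natural cubic spline on the same knots is reproduced exactly
  f <- stats::splinefun(c(0, 5, 10), c(1, -2, 4), method = "natural")
  xs <- seq(-1, 11, by = 0.1)
  X <- cbind(1, natural_spline_basis(xs, knots = 5, boundary = c(0, 10)))
  res <- qr.resid(qr(X), f(xs))
  expect_lt(max(abs(res)), 1e-8)
  expect_error(natural_spline_basis(c(1, 1, 2)), "3 distinct")
})

test_that("weighted least squares matches closed forms", {
  set.seed(52)
  y <- rnorm(40)
  res <- fit_wls(y, matrix(1, 40, 1, dimnames = list(NULL, "int")))
  expect_equal(unname(res$coef), mean(y))
  expect_equal(unname(res$se), sd(y) / sqrt(40))

  n <- 50
  X <- cbind(1, rnorm(n), rnorm(n))
  w <- runif(n, 0.5, 2)
  yy <- rnorm(n)
  fit <- fit_wls(yy, X, w)
  oracle <- solve(t(X) %*% diag(w) %*% X, t(X) %*% diag(w) %*% yy)
  expect_equal(unname(fit$coef), drop(oracle), tolerance = 1e-10)
  expect_equal(unname(fit$coef), unname(coef(lm(yy ~ X - 1, weights = w))),
               tolerance = 1e-10)
})

test_that("duplicating rows with halved weights leaves estimates unchanged", {
  set.seed(53)
  n <- 30
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  w <- runif(n, 0.5, 2)
  f1 <- fit_wls(y, X, w)
  f2 <- fit_wls(c(y, y), rbind(X, X), c(w, w) / 2)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
})

test_that("collinear columns are dropped with a warning naming them", {
  set.seed(54)
  x1 <- rnorm(30)
  X <- cbind(int = 1, a = x1, b = 2 * x1)
  expect_warning(fit <- fit_wls(rnorm(30), X), "b")
  expect_identical(fit$dropped, "b")
})

test_that("IV with the endogenous regressor as its own instrument equals WLS", {
  set.seed(55)
  n <- 60
  x <- rnorm(n)
  ex <- matrix(1, n, 1, dimnames = list(NULL, "int"))
  y <- 1 + 2 * x + rnorm(n)
  w <- runif(n, 0.5, 2)
  iv <- fit_iv2sls(y, cbind(x = x), cbind(x), ex, w)
  wls <- fit_wls(y, cbind(x = x, int = 1), w)
  expect_equal(unname(iv$coef["x"]), unname(wls$coef["x"]), tolerance = 1e-12)
})

test_that("just-identified IV matches the ratio-of-covariances closed form", {
  z <- c(0, 1, 0, 1)
  x <- c(1, 2, 3, 6)
  y <- c(2, 3, 5, 9)
  fit <- fit_iv2sls(y, cbind(x = x), cbind(z = z),
                    matrix(1, 4, 1, dimnames = list(NULL, "int")))
  expect_equal(unname(fit$coef["x"]), cov(z, y) / cov(z, x), tolerance = 1e-10)
  expect_equal(unname(fit$coef["x"]), 1.25, tolerance = 1e-10)
})

test_that("projection-form 2SLS equals the explicit two-stage route", {
  set.seed(56)
  n <- 200
  z1 <- rnorm(n); z2 <- rnorm(n); c1 <- rnorm(n)
  x1 <- z1 + 0.3 * z2 + 0.5 * c1 + rnorm(n)
  x2 <- 0.4 * z1 + z2 - 0.2 * c1 + rnorm(n)
  y <- 1 + 0.7 * x1 - 0.4 * x2 + 0.2 * c1 + rnorm(n)
  w <- runif(n, 0.5, 2)
  ex <- cbind(int = 1, c1 = c1)
  iv <- fit_iv2sls(y, cbind(x1 = x1, x2 = x2), cbind(z1, z2), ex, w)
  h1 <- fitted(lm(x1 ~ z1 + z2 + c1, weights = w))
  h2 <- fitted(lm(x2 ~ z1 + z2 + c1, weights = w))
  manual <- coef(lm(y ~ h1 + h2 + c1, weights = w))
  expect_equal(unname(iv$coef[c("x1", "x2")]), unname(manual[c("h1", "h2")]),
               tolerance = 1e-10)
})

test_that("just-identified IV is invariant to instrument reparameterization", {
  set.seed(57)
  n <- 150
  Z <- cbind(rnorm(n), rnorm(n))
  x1 <- Z[, 1] + rnorm(n); x2 <- Z[, 2] + rnorm(n)
  y <- 0.5 * x1 - 0.2 * x2 + rnorm(n)
  ex <- matrix(1, n, 1, dimnames = list(NULL, "int"))
  A <- matrix(c(2, 1, -1, 3), 2, 2)
  f1 <- fit_iv2sls(y, cbind(x1 = x1, x2 = x2), Z, ex)
  f2 <- fit_iv2sls(y, cbind(x1 = x1, x2 = x2), Z %*% A, ex)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-8)
})

test_that("identification failures raise errors", {
  n <- 20
  x1 <- rnorm(n); x2 <- rnorm(n); z <- rnorm(n)
  ex <- matrix(1, n, 1)
  expect_error(fit_iv2sls(rnorm(n), cbind(x1, x2), cbind(z), ex),
               "under-identified")
  expect_error(fit_iv2sls(rnorm(n), cbind(x1), cbind(z * 0), ex),
               "first stage")
})

test_that("partial F equals the squared first-stage t for one instrument", {
  set.seed(58)
  n <- 100
  z <- rnorm(n); c1 <- rnorm(n)
  x <- 0.5 * z + 0.3 * c1 + rnorm(n)
  f <- first_stage_partial_F(x, cbind(z), cbind(1, c1))
  t_stat <- summary(lm(x ~ z + c1))$coefficients["z", "t value"]
  expect_equal(as.numeric(f), t_stat^2, tolerance = 1e-10)
})

test_that("irrelevant instruments give mean partial F near 1", {
  set.seed(59)
  fs <- replicate(500, {
    n <- 60
    z <- rnorm(n); c1 <- rnorm(n)
    x <- 0.3 * c1 + rnorm(n)
    as.numeric(first_stage_partial_F(x, cbind(z), cbind(1, c1)))
  })
  expect_lt(abs(mean(fs) - 1), 0.2)
})

test_that("zero-weight units are excluded without affecting the fit", {
  set.seed(60)
  n <- 40
  X <- cbind(1, rnorm(n))
  y <- rnorm(n)
  w <- runif(n, 0.5, 2)
  w0 <- c(w, 0, 0)
  f1 <- fit_wls(y, X, w)
  f2 <- fit_wls(c(y, 100, -50), rbind(X, c(1, 5), c(1, -5)), w0)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  expect_identical(f2$n, length(y))
})
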