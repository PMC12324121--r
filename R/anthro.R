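#' Synthetic LMS growth reference
#'
#' A synthetic LMS (Box-Cox power L, median M, coefficient of variation S)
#' BMI reference table spanning ages 2-18 years for both sexes, with smooth
#' monotone-in-late-childhood median curves and mildly age-varying L and S.
#' It is *not* a licensed national reference; it exists so that z-scoring is
#' fully exercisable offline. Any user table in the same layout (columns
#' sex, age, L, M, S) can be used via [read_lms_reference()].
#'
#' @param ages age grid in years.
#' @return `lms_reference` data frame with columns sex ("male"/"female"),
#'   age, L, M, S.
#' @export
synthetic_lms_reference <- function(ages = seq(2, 18, by = 0.5)) {
  build <- function(sex, m_shift, s_shift) {
    data.frame(sex = sex, age = ages,
               L = -1.5 + 0.02 * ages,
               M = 15.8 - 0.4 * ages + 0.045 * ages^2 + m_shift,
               S = 0.08 + 0.003 * ages + s_shift,
               stringsAsFactors = FALSE)
  }
  ref <- rbind(build("male", 0.2, 0), build("female", 0, 0.005))
  structure(ref, class = c("lms_reference", "data.frame"))
}

#' Read an LMS reference table
#'
#' @param path CSV with columns sex, age, L, M, S.
#' @return an `lms_reference` data frame.
#' @export
read_lms_reference <- function(path) {
  ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "L", "M", "S")
  miss <- setdiff(need, names(ref))
  if (length(miss))
    stop("LMS table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(ref$M <= 0) || any(ref$S <= 0))
    stop("LMS table requires M > 0 and S > 0", call. = FALSE)
  for (sx in unique(ref$sex)) {
    a <- ref$age[ref$sex == sx]
    if (any(diff(a) <= 0))
      stop("LMS age grid must be strictly increasing within sex '", sx, "'",
           call. = FALSE)
  }
  structure(ref[need], class = c("lms_reference", "data.frame"))
}

# interpolate L, M, S at given (sex, age); errors outside the grid
lms_interp <- function(sex, age, ref) {
  sex <- as.character(sex)
  n <- max(length(sex), length(age))
  sex <- rep_len(sex, n); age <- rep_len(age, n)
  L <- M <- S <- numeric(n)
  for (sx in unique(sex)) {
    sub <- ref[ref$sex == sx, ]
    if (!nrow(sub)) stop("sex '", sx, "' not present in LMS reference", call. = FALSE)
    idx <- sex == sx
    a <- age[idx]
    if (any(a < min(sub$age) | a > max(sub$age)))
      stop("age outside the LMS reference grid [", min(sub$age), ", ",
           max(sub$age), "]; no extrapolation", call. = FALSE)
    L[idx] <- stats::approx(sub$age, sub$L, a)$y
    M[idx] <- stats::approx(sub$age, sub$M, a)$y
    S[idx] <- stats::approx(sub$age, sub$S, a)$y
  }
  list(L = L, M = M, S = S)
}

#' BMI to age/sex-adjusted z-score via the LMS method
#'
#' `z = ((x/M)^L - 1) / (L * S)` with L, M, S linearly interpolated in age
#' within sex; the log branch `z = log(x/M)/S` is used when `|L| < 1e-8`.
#'
#' @param x BMI in kg/m^2, positive.
#' @param sex "male"/"female" (recycled).
#' @param age age in years, within the reference grid (no extrapolation).
#' @param ref an `lms_reference` table.
#' @return numeric z-scores.
#' @export
lms_zscore <- function(x, sex, age, ref = synthetic_lms_reference()) {
  if (any(!is.finite(x)) || any(x <= 0))
    stop("BMI values must be positive and finite", call. = FALSE)
  p <- lms_interp(sex, age, ref)
  ifelse(abs(p$L) > 1e-8,
         ((x / p$M)^p$L - 1) / (p$L * p$S),
         log(x / p$M) / p$S)
}

#' Invert an LMS z-score back to BMI
#'
#' Exact inverse of [lms_zscore()]: `x = M * (1 + L*S*z)^(1/L)` (log branch
#' `M * exp(S*z)` when `|L| < 1e-8`).
#'
#' @inheritParams lms_zscore
#' @param z z-scores.
#' @return BMI in kg/m^2.
#' @export
invert_zscore <- function(z, sex, age, ref = synthetic_lms_reference()) {
  p <- lms_interp(sex, age, ref)
  base <- 1 + p$L * p$S * z
  if (any(base <= 0 & abs(p$L) > 1e-8))
    stop("z-score outside the invertible range of the Box-Cox transform",
         call. = FALSE)
  ifelse(abs(p$L) > 1e-8, p$M * base^(1 / p$L), p$M * exp(p$S * z))
}

#' Single-pass outlier trimming mask
#'
#' Flags values at least `k` standard deviations from the sample mean, with
#' mean and SD computed once on the full input (not iterated). Intended per
#' sweep, matching a one-shot three-SD deletion rule.
#'
#' @param values numeric, may contain NA.
#' @param k SD multiple (default 3).
#' @return logical mask, TRUE = retained; NA where the input is NA.
#' @export
trim_outliers <- function(values, k = 3) {
  obs <- values[!is.na(values)]
  if (length(obs) < 2L)
    stop("need at least 2 non-missing values to trim", call. = FALSE)
  m <- mean(obs); s <- stats::sd(obs)
  if (s == 0) return(ifelse(is.na(values), NA, TRUE))
  ifelse(is.na(values), NA, abs(values - m) < k * s)
}

#' Dichotomize an ordered diet item
#'
#' Items are healthy-coded (higher category = healthier). The indicator is 1
#' iff the category is at or above `cutpoint` (the first category counted as
#' "healthy").
#'
#' @param item integer-coded ordered categories `1..K`.
#' @param cutpoint integer category boundary in `1..K`.
#' @return 0/1 integer vector (NA preserved).
#' @export
dichotomize <- function(item, cutpoint) {
  k_max <- max(item, na.rm = TRUE)
  if (length(cutpoint) != 1L || !is.finite(cutpoint) ||
      cutpoint != round(cutpoint) || cutpoint < 1 || cutpoint > k_max)
    stop("'cutpoint' must name a category boundary in 1..", k_max, call. = FALSE)
  as.integer(item >= cutpoint)
}
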