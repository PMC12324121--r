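#' Indicator (disjunctive) matrix for multiple correspondence analysis
#'
#' Builds the 0/1 indicator matrix of a table of categorical items: one
#' column per observed category, each row summing to the number of items.
#' Row masses are uniform `1/n`; column masses are category frequencies over
#' `n * J`. Categories observed zero times are dropped with a warning.
#' Incomplete rows are rejected: the MCA operates on listwise-complete data.
#'
#' @param table data frame of categorical items (factors or integer codes).
#' @return list: `Z` (indicator matrix), `row_mass`, `col_mass`, `item`
#'   (item index of each column), `category` (category label of each column).
#' @export
indicator_matrix <- function(table) {
  table <- as.data.frame(table)
  if (ncol(table) < 1L) stop("no items supplied", call. = FALSE)
  if (anyNA(table))
    stop("indicator_matrix() requires listwise-complete rows", call. = FALSE)
  n <- nrow(table)
  J <- ncol(table)
  blocks <- lapply(seq_len(J), function(j) {
    f <- if (is.factor(table[[j]])) table[[j]] else factor(table[[j]])
    if (length(unique(as.integer(f))) < 2L)
      stop("item '", names(table)[j], "' has fewer than 2 observed categories",
           call. = FALSE)
    Zj <- stats::model.matrix(~ f - 1)
    colnames(Zj) <- paste(names(table)[j], levels(f), sep = ":")
    Zj
  })
  Z <- do.call(cbind, blocks)
  item <- rep(seq_len(J), vapply(blocks, ncol, 1L))
  zero <- colSums(Z) == 0
  if (any(zero)) {
    warning("dropping zero-frequency categor(ies): ",
            paste(colnames(Z)[zero], collapse = ", "))
    Z <- Z[, !zero, drop = FALSE]
    item <- item[!zero]
  }
  list(Z = Z, row_mass = rep(1 / n, n), col_mass = colSums(Z) / (n * J),
       item = item,
       category = sub("^[^:]*:", "", colnames(Z)))
}

#' First MCA dimension of an indicator matrix
#'
#' Correspondence analysis of the indicator matrix: with `P = Z / sum(Z)`,
#' row masses `r` and column masses `c`, the standardized residual matrix
#' `S = D_r^{-1/2} (P - r c') D_c^{-1/2}` is decomposed by SVD and row
#' principal coordinates on dimension 1 (`D_r^{-1/2} u_1 d_1`) are returned,
#' together with column principal coordinates and the share of total inertia
#' carried by dimension 1.
#'
#' @param indicator output of [indicator_matrix()] (or a raw 0/1 matrix).
#' @return list of class `diet_factor`: `scores` (row principal coordinates,
#'   unoriented), `col_coords`, `inertia` (all principal inertias),
#'   `inertia_share` (dimension 1), `sv` (singular values).
#' @export
mca_first_factor <- function(indicator) {
  if (is.matrix(indicator))
    indicator <- list(Z = indicator,
                      row_mass = rep(1 / nrow(indicator), nrow(indicator)),
                      col_mass = colSums(indicator) / sum(indicator))
  Z <- indicator$Z
  if (nrow(Z) <= ncol(Z))
    stop("need more rows than total categories for a stable MCA", call. = FALSE)
  P <- Z / sum(Z)
  r <- rowSums(P); cm <- colSums(P)
  S <- (P - tcrossprod(r, cm)) / sqrt(tcrossprod(r, cm))
  dec <- svd(S)
  if (dec$d[1] < 1e-12)
    stop("degenerate table: no non-trivial MCA dimension (all rows identical?)",
         call. = FALSE)
  scores <- unname(dec$u[, 1] * dec$d[1] / sqrt(r))
  col_coords <- dec$v[, 1] * dec$d[1] / sqrt(cm)
  names(col_coords) <- colnames(Z)
  inertia <- dec$d^2
  structure(list(scores = scores, col_coords = col_coords,
                 inertia = inertia, inertia_share = inertia[1] / sum(inertia),
                 sv = dec$d),
            class = "diet_factor")
}

#' Orient and standardize a diet factor
#'
#' Flips the factor's sign, if needed, so that it correlates positively with
#' a healthy-coded anchor item (diet variables are coded so that higher
#' values mean a healthier diet), then standardizes to mean 0, SD 1.
#'
#' @param factor a `diet_factor` from [mca_first_factor()].
#' @param anchor numeric healthy-coded values of the anchor item, one per row.
#' @return the `diet_factor` with standardized, oriented `scores` and fields
#'   `flipped`, `anchor_cor`.
#' @export
orient_standardize <- function(factor, anchor) {
  if (length(anchor) != length(factor$scores))
    stop("anchor must have one value per scored row", call. = FALSE)
  r <- suppressWarnings(stats::cor(factor$scores, as.numeric(anchor)))
  if (!is.finite(r) || abs(r) < 1e-10)
    stop("factor is uncorrelated with the anchor item; choose another anchor",
         call. = FALSE)
  s <- if (r < 0) -factor$scores else factor$scores
  factor$flipped <- r < 0
  factor$anchor_cor <- abs(r)
  if (factor$flipped) factor$col_coords <- -factor$col_coords
  factor$scores <- (s - mean(s)) / stats::sd(s)
  factor
}

#' Latent diet factor for one sweep of a cohort
#'
#' Convenience wrapper: listwise-complete rows of the sweep's diet items are
#' scored on the first MCA dimension, oriented on the anchor item and
#' standardized. Requires at least `min_items` items at that sweep (a single
#' item cannot support an MCA).
#'
#' @param cohort a `trio_cohort`.
#' @param sweep sweep age (years).
#' @param anchor_item item name used to orient the factor (default "fruit",
#'   or the first available item).
#' @param min_items minimum number of items (default 2).
#' @return data frame `family_id`, `diet_factor` (NA for incomplete rows),
#'   with the fitted `diet_factor` object as attribute `fit`.
#' @export
diet_factor_sweep <- function(cohort, sweep, anchor_item = NULL, min_items = 2L) {
  ph <- cohort$pheno
  cols <- grep(paste0("^diet_.*_", sweep, "$"), names(ph), value = TRUE)
  if (length(cols) < min_items)
    stop("sweep ", sweep, " has ", length(cols),
         " diet item(s); MCA needs at least ", min_items, call. = FALSE)
  items <- ph[cols]
  names(items) <- sub(paste0("_", sweep, "$"), "", sub("^diet_", "", cols))
  if (is.null(anchor_item))
    anchor_item <- if ("fruit" %in% names(items)) "fruit" else names(items)[1]
  if (!anchor_item %in% names(items))
    stop("anchor item '", anchor_item, "' not measured at sweep ", sweep,
         call. = FALSE)
  complete <- stats::complete.cases(items)
  fit <- mca_first_factor(indicator_matrix(items[complete, , drop = FALSE]))
  fit <- orient_standardize(fit, as.numeric(items[[anchor_item]][complete]))
  out <- data.frame(family_id = ph$family_id, diet_factor = NA_real_,
                    stringsAsFactors = FALSE)
  out$diet_factor[complete] <- fit$scores
  structure(out, fit = fit)
}
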