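#' Read GWAS summary statistics
#'
#' Reads a whitespace- or tab-delimited file with header columns `SNP`, `A1`
#' (effect allele), `A2` (other allele), `BETA`, `P` (extra columns are
#' ignored). Rows with strand-ambiguous allele pairs (A/T or C/G) are dropped
#' and counted, since their orientation cannot be resolved without strand
#' information.
#'
#' @param path file path.
#' @return a `sumstats` data frame (columns SNP, A1, A2, BETA, P) with
#'   attributes `n_ambiguous_dropped` and `clumped = FALSE`.
#' @export
read_sumstats <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  need <- c("SNP", "A1", "A2", "BETA", "P")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("summary-statistics file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df <- df[need]
  as_sumstats(df)
}

#' Construct a sumstats object from a data frame
#'
#' Validates alleles, p-values and variant-id uniqueness and drops
#' strand-ambiguous (A/T, C/G) rows, recording the count.
#'
#' @param df data frame with columns SNP, A1, A2, BETA, P.
#' @return a `sumstats` data frame.
#' @export
as_sumstats <- function(df) {
  df$A1 <- toupper(df$A1); df$A2 <- toupper(df$A2)
  if (nrow(df)) {
    if (!all(df$A1 %in% c("A", "C", "G", "T")) ||
        !all(df$A2 %in% c("A", "C", "G", "T")))
      stop("alleles must be one of A, C, G, T", call. = FALSE)
    if (any(df$P <= 0 | df$P > 1))
      stop("p-values must lie in (0, 1]", call. = FALSE)
    dup <- unique(df$SNP[duplicated(df$SNP)])
    if (length(dup))
      stop("duplicate variant id(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  ambiguous <- (df$A1 == "A" & df$A2 == "T") | (df$A1 == "T" & df$A2 == "A") |
               (df$A1 == "C" & df$A2 == "G") | (df$A1 == "G" & df$A2 == "C")
  out <- df[!ambiguous, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_ambiguous_dropped = sum(ambiguous), clumped = FALSE,
            class = c("sumstats", "data.frame"))
}

#' Threshold summary statistics on p-value
#'
#' Retains variants with `P < p_threshold` (strict). No linkage-disequilibrium
#' clumping is performed — simulated SNPs are independent — and the result
#' carries `clumped = FALSE` so users scoring real data know the gap.
#'
#' @param sumstats a `sumstats` object.
#' @param p_threshold inclusion threshold in (0, 1].
#' @return the retained `sumstats` subset.
#' @export
select_snps <- function(sumstats, p_threshold = 5e-8) {
  check_scalar(p_threshold, "p_threshold", lo = 0, hi = 1, open = FALSE)
  if (p_threshold <= 0) stop("'p_threshold' must be positive", call. = FALSE)
  out <- sumstats[sumstats$P < p_threshold, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, n_ambiguous_dropped = attr(sumstats, "n_ambiguous_dropped"),
            clumped = FALSE, class = c("sumstats", "data.frame"))
}

#' Score genotypes against summary statistics
#'
#' Weighted score: `sum_j BETA_j * g_ij`; unweighted: `sum_j sign(BETA_j) *
#' g_ij` (effect-allele-aligned allele count). Dosages are assumed to count
#' the effect allele; if `effect_alleles` (a named vector giving the allele
#' counted by each genotype column) is supplied and disagrees with the
#' sumstats orientation for a variant, its dosage is flipped to `2 - g` and
#' the flip is recorded in the `n_flipped` attribute.
#'
#' @param genotypes dosage matrix with variant ids as column names.
#' @param sumstats a `sumstats` object; every variant must be present in
#'   `genotypes`.
#' @param weighted use GWAS effect sizes (`TRUE`) or allele counts signed by
#'   the effect direction (`FALSE`).
#' @param effect_alleles optional named character vector: allele counted by
#'   each dosage column.
#' @return numeric vector of raw scores, attribute `n_flipped`.
#' @export
pgi_score <- function(genotypes, sumstats, weighted = TRUE, effect_alleles = NULL) {
  if (nrow(sumstats) == 0L)
    stop("cannot score against empty summary statistics", call. = FALSE)
  missing_ids <- setdiff(sumstats$SNP, colnames(genotypes))
  if (length(missing_ids))
    stop("variant(s) absent from genotypes: ",
         paste(utils::head(missing_ids, 10), collapse = ", "),
         if (length(missing_ids) > 10) ", ..." else "", call. = FALSE)
  G <- genotypes[, sumstats$SNP, drop = FALSE]
  n_flipped <- 0L
  if (!is.null(effect_alleles)) {
    ea <- effect_alleles[sumstats$SNP]
    flip <- ea == sumstats$A2
    bad <- !flip & ea != sumstats$A1
    if (any(bad, na.rm = TRUE) || anyNA(ea))
      stop("dosage orientation unknown for variant(s): ",
           paste(sumstats$SNP[which(bad | is.na(ea))], collapse = ", "),
           call. = FALSE)
    if (any(flip)) {
      G[, flip] <- 2 - G[, flip]
      n_flipped <- sum(flip)
    }
  }
  w <- if (weighted) sumstats$BETA else sign(sumstats$BETA)
  structure(drop(G %*% w), n_flipped = n_flipped)
}

#' Standardize polygenic scores in a reference subsample
#'
#' Scales raw scores to mean 0, SD 1 using the unweighted moments of the
#' reference subsample (the complete-trio sample in the intended analysis);
#' the same reference moments are applied to all persons.
#'
#' @param raw numeric vector of raw scores.
#' @param reference logical or integer index of reference persons (default:
#'   everyone).
#' @return numeric vector of standardized scores with attributes `mean_ref`,
#'   `sd_ref`.
#' @export
standardize_pgi <- function(raw, reference = seq_along(raw)) {
  ref <- raw[reference]
  if (length(ref) < 2L) stop("reference subsample too small", call. = FALSE)
  m <- mean(ref); s <- stats::sd(ref)
  if (!is.finite(s) || s <= 0)
    stop("reference subsample has zero score variance; cannot standardize",
         call. = FALSE)
  structure((raw - m) / s, mean_ref = m, sd_ref = s)
}

#' Build standardized trio polygenic indices for a cohort
#'
#' Scores mother, father and child genotypes against (thresholded) summary
#' statistics and standardizes all scores with the pooled complete-trio
#' moments, the scaling used for instrument variables downstream.
#'
#' @param cohort a `trio_cohort`.
#' @param sumstats a `sumstats` object (default: the simulator's own per-SNP
#'   effects via [sumstats_from_truth()]).
#' @param p_threshold p-value inclusion threshold passed to [select_snps()].
#' @param weighted weighted or unweighted score, see [pgi_score()].
#' @return data frame: family_id, `pgi_mother`, `pgi_father`, `pgi_child`
#'   (standardized) and the corresponding `raw_*` columns; attributes
#'   `n_snps_used`, `weighted`, `p_threshold`.
#' @export
build_pgi <- function(cohort, sumstats = sumstats_from_truth(cohort),
                      p_threshold = 5e-8, weighted = TRUE) {
  ss <- select_snps(sumstats, p_threshold)
  if (nrow(ss) == 0L)
    stop("no variants pass p < ", format(p_threshold), call. = FALSE)
  raw <- lapply(cohort$geno, pgi_score, sumstats = ss, weighted = weighted)
  pooled <- unlist(raw, use.names = FALSE)
  m <- mean(pooled); s <- stats::sd(pooled)
  if (s <= 0) stop("polygenic scores have zero variance", call. = FALSE)
  out <- data.frame(family_id = cohort$pheno$family_id,
                    pgi_mother = (raw$mother - m) / s,
                    pgi_father = (raw$father - m) / s,
                    pgi_child  = (raw$child - m) / s,
                    raw_mother = as.numeric(raw$mother),
                    raw_father = as.numeric(raw$father),
                    raw_child  = as.numeric(raw$child),
                    stringsAsFactors = FALSE)
  structure(out, n_snps_used = nrow(ss), weighted = weighted,
            p_threshold = p_threshold, mean_ref = m, sd_ref = s)
}

#' Per-family Mendelian-error rate
#'
#' A SNP counts as a Mendelian error for a family iff the child dosage is
#' impossible under biparental transmission: the child must receive between
#' `(mother==2) + (father==2)` and `(mother>=1) + (father>=1)` effect
#' alleles. Returns the percentage of SNPs in error per family plus cohort
#' summaries — the genotyping-quality audit used on real trio data (simulated
#' cohorts are error-free by construction).
#'
#' @param mother,father,child dosage matrices (families x SNPs) in `{0,1,2}`,
#'   or a `trio_cohort` as the single first argument.
#' @return list: `per_family` (percent), `mean`, `median`, `max` (percent).
#' @export
mendelian_error_rate <- function(mother, father = NULL, child = NULL) {
  if (inherits(mother, "trio_cohort")) {
    g <- mother$geno
    mother <- g$mother; father <- g$father; child <- g$child
  }
  if (is.null(father) || is.null(child))
    stop("all three trio members are required", call. = FALSE)
  if (!identical(dim(mother), dim(father)) || !identical(dim(mother), dim(child)))
    stop("trio dosage matrices must share dimensions", call. = FALSE)
  if (!all(c(mother, father, child) %in% 0:2))
    stop("dosages must be in {0, 1, 2}", call. = FALSE)
  cmin <- (mother == 2) + (father == 2)
  cmax <- (mother >= 1) + (father >= 1)
  err <- child < cmin | child > cmax
  per_family <- 100 * rowMeans(err)
  list(per_family = per_family, mean = mean(per_family),
       median = stats::median(per_family), max = max(per_family))
}
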