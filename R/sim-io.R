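#' Write a trio cohort to plain-text files
#'
#' Emits, under `dir`: `genotypes.csv` (one row per person keyed by
#' family_id + role, one column per SNP id), `pheno.csv` (one row per
#' family, wide across sweeps), `snps.csv`, `truth.json` (configuration and
#' generative truth, full numeric precision), `dictionary.yaml` (column
#' dictionary with stored column classes used to make the round trip exact),
#' and optionally a minimal VCF 4.2 with GT-only genotype fields.
#'
#' @param cohort a `trio_cohort`.
#' @param dir output directory (created if needed).
#' @param vcf also write `genotypes.vcf`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, vcf = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  roles <- c("mother", "father", "child")
  gen <- do.call(rbind, lapply(roles, function(r) {
    g <- cohort$geno[[r]]
    df <- as.data.frame(g)
    cbind(data.frame(family_id = cohort$pheno$family_id,
                     role = rep(r, nrow(g)), stringsAsFactors = FALSE), df)
  }))
  write_csv_exact(gen, file.path(dir, "genotypes.csv"))
  write_csv_exact(cohort$pheno, file.path(dir, "pheno.csv"))
  write_csv_exact(cohort$snps, file.path(dir, "snps.csv"))
  jsonlite::write_json(list(config = unclass(cohort$config), truth = cohort$truth),
                       file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE,
                       null = "null")
  dict <- list(
    pheno = lapply(stats::setNames(names(cohort$pheno), names(cohort$pheno)),
                   function(cn) list(class = class(cohort$pheno[[cn]])[1],
                                     description = pheno_column_doc(cn))),
    genotypes = list(layout = "one row per person (family_id + role), dosage of the effect allele per SNP column"))
  yaml::write_yaml(dict, file.path(dir, "dictionary.yaml"))
  if (vcf) write_trio_vcf(cohort, file.path(dir, "genotypes.vcf"))
  invisible(dir)
}

# terse column descriptions for the shipped dictionary
pheno_column_doc <- function(cn) {
  if (grepl("^bmi_", cn)) return("child BMI (kg/m^2) at the sweep age suffix")
  if (grepl("^age_", cn)) return("child age (years) at assessment")
  if (grepl("^part_", cn)) return("participation flag at the sweep")
  if (grepl("^diet_", cn)) return("ordinal diet item, higher = healthier")
  switch(cn,
    family_id = "family identifier",
    mother_bmi_true = "mother true BMI (kg/m^2)",
    father_bmi_true = "father true BMI (kg/m^2)",
    mother_bmi_rep = "mother self-reported BMI (kg/m^2)",
    father_bmi_rep = "father self-reported BMI (kg/m^2)",
    sex = "child sex (1 = male)",
    maternal_age = "maternal age at birth (years)",
    maternal_educ = "maternal education (years)",
    social_class = "social class, 5 ordered categories",
    pc1 = "generic principal-component covariate",
    pc2 = "generic principal-component covariate",
    birthweight = "birthweight (grams)",
    recruit_weight = "recruitment (design) weight",
    stratum = "design stratum id",
    cluster = "design cluster id",
    "simulated field")
}

#' Read a trio cohort written by [write_cohort()]
#'
#' @param dir directory containing the cohort files.
#' @return a `trio_cohort`.
#' @export
read_cohort <- function(dir) {
  need <- c("genotypes.csv", "pheno.csv", "snps.csv", "truth.json",
            "dictionary.yaml")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop("cohort directory is missing '", f, "'", call. = FALSE)
  dict <- yaml::read_yaml(file.path(dir, "dictionary.yaml"))
  classes <- vapply(dict$pheno, function(d) d$class, character(1))
  ph <- utils::read.csv(file.path(dir, "pheno.csv"), stringsAsFactors = FALSE,
                        colClasses = classes)
  gen <- utils::read.csv(file.path(dir, "genotypes.csv"),
                         stringsAsFactors = FALSE, check.names = FALSE)
  snps <- utils::read.csv(file.path(dir, "snps.csv"), stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  cfg <- meta$config
  class(cfg) <- "sim_config"
  geno <- lapply(c(mother = "mother", father = "father", child = "child"),
                 function(r) {
    sub <- gen[gen$role == r, , drop = FALSE]
    if (nrow(sub) && !identical(sub$family_id, ph$family_id))
      stop("genotype rows out of order for role '", r, "'", call. = FALSE)
    m <- as.matrix(sub[, snps$id, drop = FALSE])
    storage.mode(m) <- "integer"
    rownames(m) <- NULL
    m
  })
  beta <- snps$beta
  structure(list(config = cfg, snps = snps, geno = geno,
                 gv = lapply(geno, function(g) drop(g %*% beta)),
                 pheno = ph, paired = TRUE, truth = meta$truth),
            class = "trio_cohort")
}

#' Minimal VCF 4.2 export of trio genotypes
#'
#' GT-only, unphased, one sample column per person (`<family>_<role>`), the
#' effect allele written as ALT so dosage d maps to GT 0/0, 0/1, 1/1.
#'
#' @param cohort a `trio_cohort`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trio_vcf <- function(cohort, path) {
  roles <- c("mother", "father", "child")
  samples <- as.vector(t(outer(cohort$pheno$family_id, roles, paste, sep = "_")))
  gt_map <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", samples), collapse = "\t")), con)
  n <- nrow(cohort$pheno)
  for (j in seq_len(nrow(cohort$snps))) {
    dos <- as.vector(t(cbind(cohort$geno$mother[, j], cohort$geno$father[, j],
                             cohort$geno$child[, j])))
    writeLines(paste(c("1", j, cohort$snps$id[j], cohort$snps$other_allele[j],
                       cohort$snps$effect_allele[j], ".", "PASS", ".", "GT",
                       gt_map[dos + 1L]), collapse = "\t"), con)
  }
  invisible(path)
}
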