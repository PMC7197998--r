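#' Case-control genotype dataset
#'
#' The container consumed by every analysis stage: a genotype matrix coded as
#' minor-allele counts, a binary phenotype, optional covariates, and optional
#' per-SNP metadata.
#'
#' @param genotypes integer matrix, individuals in rows and SNPs in columns;
#'   entries 0, 1, 2 (count of the minor allele) or `NA` for a missing call.
#'   Column names are SNP identifiers.
#' @param phenotype per-individual disease status: either a numeric 0/1 vector
#'   (1 = case) or a character/factor vector with levels `"case"` /
#'   `"control"`.
#' @param covariates optional `data.frame` of per-individual covariates
#'   (e.g. `age`, `sex`, `bmi`, admixture proportions). `sex` may be coded
#'   `"male"`/`"female"`.
#' @param snp_meta optional `data.frame` of SNP metadata aligned to the
#'   genotype columns; see [osteo_snp_panel()] for the expected columns
#'   (`snp_id`, `gene`, `chrom_pos`, `ref_allele`, `minor_allele`, `maf`).
#' @param individuals optional character vector of individual identifiers;
#'   defaults to the genotype row names or `ind1..indN`.
#'
#' @return An object of class `mdr_dataset`: a list with elements
#'   `genotypes`, `phenotype` (integer 0/1), `covariates`, `snp_meta`,
#'   `individuals`.
#' @export
mdr_dataset <- function(genotypes, phenotype, covariates = NULL,
                        snp_meta = NULL, individuals = NULL) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- paste0("snp", seq_len(ncol(genotypes)))
  }
  phenotype <- encode_phenotype(phenotype)
  n <- nrow(genotypes)
  if (length(phenotype) != n) {
    stop_mdr("phenotype length (", length(phenotype),
             ") does not match the number of individuals (", n, ")")
  }
  bad <- !is.na(genotypes) & !(genotypes %in% 0:2)
  if (any(bad)) {
    stop_mdr("invalid genotype code(s): ",
             paste(unique(genotypes[bad]), collapse = ", "),
             "; expected 0, 1, 2 or NA")
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != n) {
      stop_mdr("covariate row count does not match the number of individuals")
    }
  }
  if (!is.null(snp_meta)) {
    snp_meta <- validate_snp_meta(snp_meta)
    if (nrow(snp_meta) != ncol(genotypes)) {
      stop_mdr("snp_meta rows must align with genotype columns")
    }
    colnames(genotypes) <- snp_meta$snp_id
  }
  individuals <- individuals %||% rownames(genotypes) %||%
    sprintf("ind%03d", seq_len(n))
  rownames(genotypes) <- individuals
  structure(
    list(genotypes = genotypes, phenotype = phenotype,
         covariates = covariates, snp_meta = snp_meta,
         individuals = individuals),
    class = "mdr_dataset"
  )
}

encode_phenotype <- function(phenotype) {
  if (is.factor(phenotype)) phenotype <- as.character(phenotype)
  if (is.character(phenotype)) {
    ok <- phenotype %in% c("case", "control")
    if (!all(ok)) {
      stop_mdr("phenotype labels must be 'case'/'control'; got: ",
               paste(unique(phenotype[!ok]), collapse = ", "))
    }
    return(as.integer(phenotype == "case"))
  }
  phenotype <- as.integer(phenotype)
  if (!all(phenotype %in% 0:1)) {
    stop_mdr("numeric phenotype must be coded 0 (control) / 1 (case)")
  }
  phenotype
}

validate_snp_meta <- function(snp_meta) {
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  needed <- c("snp_id", "maf")
  miss <- setdiff(needed, names(snp_meta))
  if (length(miss)) stop_mdr("snp_meta lacks column(s): ",
                             paste(miss, collapse = ", "))
  if (any(snp_meta$maf < 0 | snp_meta$maf > 0.5)) {
    stop_mdr("snp_meta$maf must lie in [0, 0.5] after minor-allele orientation")
  }
  if (all(c("ref_allele", "minor_allele") %in% names(snp_meta)) &&
      any(snp_meta$ref_allele == snp_meta$minor_allele)) {
    stop_mdr("ref_allele and minor_allele must differ")
  }
  snp_meta
}

#' @export
print.mdr_dataset <- function(x, ...) {
  cat(sprintf("<mdr_dataset> %d individuals (%d cases / %d controls), %d SNPs\n",
              length(x$phenotype), sum(x$phenotype == 1L),
              sum(x$phenotype == 0L), ncol(x$genotypes)))
  if (!is.null(x$covariates)) {
    cat("covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  }
  n_miss <- sum(is.na(x$genotypes))
  if (n_miss) cat("missing genotype calls:", n_miss, "\n")
  invisible(x)
}

#' @export
dim.mdr_dataset <- function(x) dim(x$genotypes)

#' Number of individuals in a dataset
#' @param dataset an [mdr_dataset()].
#' @return integer count.
#' @export
n_individuals <- function(dataset) nrow(dataset$genotypes)

#' SNP identifiers of a dataset
#' @inheritParams n_individuals
#' @return character vector of SNP ids (genotype column names).
#' @export
snp_ids <- function(dataset) colnames(dataset$genotypes)

# Row-subset a dataset, keeping all components aligned.
dataset_subset <- function(dataset, idx) {
  mdr_dataset(
    genotypes  = dataset$genotypes[idx, , drop = FALSE],
    phenotype  = dataset$phenotype[idx],
    covariates = if (is.null(dataset$covariates)) NULL else
      dataset$covariates[idx, , drop = FALSE],
    snp_meta   = dataset$snp_meta,
    individuals = dataset$individuals[idx]
  )
}

#' Split a dataset into strata
#'
#' Partitions the individuals by sex or by an age cutoff (the convention for
#' early/late disease onset uses 50 years). Strata are disjoint and their
#' union is the original dataset; empty strata are dropped.
#'
#' @inheritParams n_individuals
#' @param by `"sex"` or `"age"`.
#' @param cutoff age cutoff in years when `by = "age"`; individuals with
#'   age <= cutoff form the first stratum.
#' @return named list of `mdr_dataset` strata.
#' @export
stratify <- function(dataset, by = c("sex", "age"), cutoff = 50) {
  by <- match.arg(by)
  cov <- dataset$covariates
  if (is.null(cov) || !(by %in% names(cov))) {
    stop_mdr("covariate '", by, "' is required for stratification but absent")
  }
  if (by == "sex") {
    key <- as.character(cov$sex)
    groups <- split(seq_along(key), key)
  } else {
    age <- cov$age
    if (any(is.na(age))) stop_mdr("age contains missing values")
    key <- ifelse(age <= cutoff, sprintf("age<=%g", cutoff),
                  sprintf("age>%g", cutoff))
    groups <- split(seq_along(key), key)
  }
  lapply(groups, function(idx) dataset_subset(dataset, idx))
}

#' Expand printed genotype counts into an individual-level dataset
#'
#' Reconstructs a single-SNP (or multi-SNP, independent columns) dataset from
#' per-group genotype counts, as printed in a frequency table. Useful for
#' re-analysing published count tables at the individual level.
#'
#' @param snp_id SNP identifier.
#' @param case_counts,control_counts length-3 integer vectors
#'   `(n0, n1, n2)` of genotype code counts in cases and controls.
#' @return an [mdr_dataset()] with one SNP.
#' @export
dataset_from_counts <- function(snp_id, case_counts, control_counts) {
  stopifnot(length(case_counts) == 3L, length(control_counts) == 3L)
  g <- c(rep(0:2, times = case_counts), rep(0:2, times = control_counts))
  y <- c(rep(1L, sum(case_counts)), rep(0L, sum(control_counts)))
  m <- matrix(as.integer(g), ncol = 1, dimnames = list(NULL, snp_id))
  mdr_dataset(m, y)
}
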