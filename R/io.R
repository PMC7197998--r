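#' Read a tabular case-control genotype file
#'
#' Three dialects are supported:
#' \describe{
#'   \item{`csv-coded`}{comma-separated; genotypes already coded 0/1/2
#'     (minor-allele count), missing as `NA`.}
#'   \item{`allele-pairs`}{comma-separated; genotypes as two-letter allele
#'     pairs (`"CT"`, order-insensitive), missing as `NA` or `--`. Codes are
#'     oriented so that they count the minor allele estimated in the control
#'     group, unless `snp_meta` fixes the minor allele.}
#'   \item{`mdr-flatfile`}{the tab-delimited attribute file used by MDR-style
#'     software: SNP columns coded 0/1/2, a final `Class` column (1 = case,
#'     0 = control), missing as `-9`.}
#' }
#'
#' @param path file to read.
#' @param dialect one of `"csv-coded"`, `"allele-pairs"`, `"mdr-flatfile"`.
#' @param class_column name of the phenotype column (`"Class"` by default).
#' @param missing missing-genotype sentinel token(s); defaults per dialect
#'   (`NA`/empty for the csv dialects, `-9` for the flat file).
#' @param snp_meta optional SNP metadata (see [mdr_dataset()]); if it carries
#'   `ref_allele`/`minor_allele`, allele-pair orientation uses it instead of
#'   the control-group estimate.
#' @param covariate_columns character vector of column names to treat as
#'   covariates rather than SNPs.
#' @return an [mdr_dataset()].
#' @export
read_genotype_table <- function(path,
                                dialect = c("csv-coded", "allele-pairs",
                                            "mdr-flatfile"),
                                class_column = "Class",
                                missing = NULL,
                                snp_meta = NULL,
                                covariate_columns = character()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop_mdr("file not found: ", path)
  sep <- if (dialect == "mdr-flatfile") "\t" else ","
  missing <- missing %||% switch(dialect,
                                 "mdr-flatfile" = "-9",
                                 c("NA", "", "--"))
  nf <- utils::count.fields(path, sep = sep, comment.char = "")
  if (length(unique(nf)) > 1L) {
    bad <- which(nf != nf[1])[1]
    stop_mdr("malformed row at line ", bad, " of ", path, ": expected ",
             nf[1], " fields, found ", nf[bad])
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          comment.char = "", stringsAsFactors = FALSE)
  if (!(class_column %in% names(df))) {
    stop_mdr("phenotype column '", class_column, "' not found in ", path)
  }
  pheno_raw <- df[[class_column]]
  if (all(pheno_raw %in% c("0", "1"))) {
    phenotype <- as.integer(pheno_raw)
  } else if (all(pheno_raw %in% c("case", "control"))) {
    phenotype <- as.integer(pheno_raw == "case")
  } else {
    stop_mdr("phenotype column '", class_column, "' is not binary ",
             "(expected 0/1 or case/control)")
  }
  cov <- NULL
  if (length(covariate_columns)) {
    miss_cov <- setdiff(covariate_columns, names(df))
    if (length(miss_cov)) stop_mdr("covariate column(s) not found: ",
                                   paste(miss_cov, collapse = ", "))
    cov <- df[covariate_columns]
    for (nm in names(cov)) {
      num <- suppressWarnings(as.numeric(cov[[nm]]))
      if (!anyNA(num[!is.na(cov[[nm]])])) cov[[nm]] <- num
    }
  }
  snp_cols <- setdiff(names(df), c(class_column, covariate_columns))
  if (!length(snp_cols)) stop_mdr("no SNP columns found in ", path)
  raw <- as.matrix(df[snp_cols])
  raw[raw %in% missing] <- NA_character_

  if (dialect == "allele-pairs") {
    geno <- decode_allele_pairs(raw, phenotype, snp_meta, path)
  } else {
    ok <- is.na(raw) | raw %in% c("0", "1", "2")
    if (!all(ok)) {
      stop_mdr("unknown genotype symbol(s) in ", path, ": ",
               paste(utils::head(unique(raw[!ok]), 5), collapse = ", "))
    }
    geno <- matrix(as.integer(raw), nrow = nrow(raw),
                   dimnames = dimnames(raw))
  }
  mdr_dataset(geno, phenotype, covariates = cov, snp_meta = snp_meta)
}

# Convert two-letter allele pairs to minor-allele counts. Orientation: the
# minor allele is the less frequent allele among controls (tie broken
# alphabetically), unless snp_meta$minor_allele fixes it.
decode_allele_pairs <- function(raw, phenotype, snp_meta, path) {
  ok <- is.na(raw) | grepl("^[ACGT]{2}$", raw)
  if (!all(ok)) {
    stop_mdr("unknown genotype symbol(s) in ", path, ": ",
             paste(utils::head(unique(raw[!ok]), 5), collapse = ", "))
  }
  geno <- matrix(NA_integer_, nrow(raw), ncol(raw), dimnames = dimnames(raw))
  for (j in seq_len(ncol(raw))) {
    pairs <- raw[, j]
    a1 <- substr(pairs, 1, 1)
    a2 <- substr(pairs, 2, 2)
    alleles <- sort(unique(stats::na.omit(c(a1, a2))))
    if (length(alleles) > 2L) {
      stop_mdr("SNP ", colnames(raw)[j], " has more than two alleles: ",
               paste(alleles, collapse = ", "))
    }
    minor <- NULL
    if (!is.null(snp_meta) && "minor_allele" %in% names(snp_meta)) {
      hit <- match(colnames(raw)[j], snp_meta$snp_id)
      if (!is.na(hit)) minor <- snp_meta$minor_allele[hit]
    }
    if (is.null(minor)) {
      ctrl <- phenotype == 0L
      pool <- c(a1[ctrl], a2[ctrl])
      pool <- pool[!is.na(pool)]
      if (!length(pool)) pool <- stats::na.omit(c(a1, a2))
      tab <- table(factor(pool, levels = alleles))
      # less frequent allele is minor; exact tie -> alphabetically first
      minor <- names(tab)[order(tab, names(tab))][1]
    }
    geno[, j] <- (a1 == minor) + (a2 == minor)
  }
  geno
}

#' Write a dataset to a genotype file
#'
#' Inverse of [read_genotype_table()] for each dialect; a written file read
#' back with the same dialect reproduces the dataset exactly.
#'
#' @inheritParams read_genotype_table
#' @param dataset an [mdr_dataset()].
#' @param missing_sentinel token used for missing genotypes; defaults to
#'   `"NA"` for the csv dialects and `"-9"` for the MDR flat file.
#' @return invisibly, `path`.
#' @export
write_genotype_table <- function(dataset, path,
                                 dialect = c("csv-coded", "allele-pairs",
                                             "mdr-flatfile"),
                                 class_column = "Class",
                                 missing_sentinel = NULL) {
  dialect <- match.arg(dialect)
  missing_sentinel <- missing_sentinel %||%
    if (dialect == "mdr-flatfile") "-9" else "NA"
  geno <- dataset$genotypes
  if (dialect == "allele-pairs") {
    sm <- dataset$snp_meta
    if (is.null(sm) || !all(c("ref_allele", "minor_allele") %in% names(sm))) {
      stop_mdr("allele-pairs output requires snp_meta with ref_allele ",
               "and minor_allele")
    }
    out <- matrix(NA_character_, nrow(geno), ncol(geno),
                  dimnames = dimnames(geno))
    for (j in seq_len(ncol(geno))) {
      ref <- sm$ref_allele[match(colnames(geno)[j], sm$snp_id)]
      minor <- sm$minor_allele[match(colnames(geno)[j], sm$snp_id)]
      out[, j] <- c(paste0(ref, ref), paste0(ref, minor),
                    paste0(minor, minor))[geno[, j] + 1L]
    }
    chr <- out
  } else {
    chr <- matrix(as.character(geno), nrow(geno), dimnames = dimnames(geno))
  }
  chr[is.na(chr)] <- missing_sentinel
  df <- as.data.frame(chr, stringsAsFactors = FALSE)
  df[[class_column]] <- dataset$phenotype
  sep <- if (dialect == "mdr-flatfile") "\t" else ","
  ok <- try(utils::write.table(df, path, sep = sep, quote = FALSE,
                               row.names = FALSE, col.names = TRUE),
            silent = TRUE)
  if (inherits(ok, "try-error")) stop_mdr("cannot write to ", path)
  invisible(path)
}

#' Write the MDR flat-file dialect
#'
#' Tab-delimited attribute file (SNP columns coded 0/1/2, final `Class`
#' column), the interchange format of MDR-style software.
#'
#' @inheritParams write_genotype_table
#' @export
write_mdr_flatfile <- function(dataset, path, missing_sentinel = "-9") {
  if (anyNA(dataset$phenotype)) stop_mdr("phenotype must not be missing")
  write_genotype_table(dataset, path, dialect = "mdr-flatfile",
                       missing_sentinel = missing_sentinel)
}

#' Export SNP metadata as JSON
#'
#' @param snp_meta a SNP metadata `data.frame` (see [osteo_snp_panel()]).
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_snp_meta_json <- function(snp_meta, path) {
  jsonlite::write_json(validate_snp_meta(snp_meta), path, digits = NA)
  invisible(path)
}

#' Path to a bundled example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a character vector of file names).
#' @export
mdr_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "mdrkit")))
  }
  p <- system.file("extdata", file, package = "mdrkit")
  if (p == "") stop_mdr("no bundled file named '", file, "'")
  p
}
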