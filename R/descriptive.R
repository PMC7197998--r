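#' Genotype counts for one SNP in one group
#'
#' Counts of the genotype codes 0/1/2 (minor-allele count) among cases or
#' controls, over non-missing calls only.
#'
#' @inheritParams n_individuals
#' @param snp_id SNP identifier (a genotype column name).
#' @param group `"case"` or `"control"`.
#' @return a `genotype_counts` object: list with `snp_id`, `group`,
#'   `n0`, `n1`, `n2`, `n_typed`.
#' @export
genotype_counts <- function(dataset, snp_id, group = c("case", "control")) {
  group <- match.arg(group)
  if (!(snp_id %in% snp_ids(dataset))) {
    stop_mdr("unknown SNP: ", snp_id)
  }
  g <- dataset$genotypes[dataset$phenotype == (group == "case"), snp_id]
  n <- tabulate(g + 1L, 3L)
  new_genotype_counts(snp_id, group, n[1], n[2], n[3])
}

new_genotype_counts <- function(snp_id, group, n0, n1, n2) {
  stopifnot(n0 >= 0, n1 >= 0, n2 >= 0)
  structure(list(snp_id = snp_id, group = group,
                 n0 = as.integer(n0), n1 = as.integer(n1),
                 n2 = as.integer(n2),
                 n_typed = as.integer(n0 + n1 + n2)),
            class = "genotype_counts")
}

#' @export
print.genotype_counts <- function(x, ...) {
  cat(sprintf("<genotype_counts> %s [%s]: 0/1/2 = %d/%d/%d (n = %d)\n",
              x$snp_id, x$group, x$n0, x$n1, x$n2, x$n_typed))
  invisible(x)
}

#' Allele counts derived from genotype counts
#'
#' The minor-allele count is `n1 + 2*n2` out of `2*n_typed` alleles; the
#' frequency is kept at full precision (round only for presentation).
#'
#' @param gc a `genotype_counts` object (or a length-3 numeric
#'   `(n0, n1, n2)`).
#' @return list with `snp_id`, `group`, `minor_count`, `total_alleles`,
#'   `minor_freq` (`NaN` when no individual is typed).
#' @export
allele_counts <- function(gc) {
  if (is.numeric(gc) && length(gc) == 3L) {
    gc <- new_genotype_counts(NA_character_, NA_character_,
                              gc[1], gc[2], gc[3])
  }
  stopifnot(inherits(gc, "genotype_counts"))
  minor <- gc$n1 + 2L * gc$n2
  total <- 2L * gc$n_typed
  structure(list(snp_id = gc$snp_id, group = gc$group,
                 minor_count = minor, total_alleles = total,
                 minor_freq = if (total > 0) minor / total else NaN),
            class = "allele_counts")
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("<allele_counts> %s [%s]: minor %d / %d (%.1f%%)\n",
              x$snp_id, x$group, x$minor_count, x$total_alleles,
              100 * x$minor_freq))
  invisible(x)
}

#' Hardy-Weinberg equilibrium chi-square test
#'
#' Pearson goodness-of-fit of the observed genotype counts against the
#' expected proportions p^2, 2pq, q^2 implied by the sample allele frequency;
#' 1 degree of freedom (one allele frequency estimated from the data), no
#' continuity correction. The test is conventionally applied to the control
#' group of a case-control study.
#'
#' @inheritParams allele_counts
#' @return an `hwe_result`: list with `snp_id`, `chi2`, `df` (= 1), `p`.
#'   A monomorphic SNP (q = 0 or 1) is in trivial equilibrium:
#'   `chi2 = 0`, `p = 1`.
#' @export
hwe_chisq <- function(gc) {
  if (is.numeric(gc) && length(gc) == 3L) {
    gc <- new_genotype_counts(NA_character_, NA_character_,
                              gc[1], gc[2], gc[3])
  }
  stopifnot(inherits(gc, "genotype_counts"))
  n <- gc$n_typed
  if (n == 0L) stop_mdr("no typed individuals: HWE test undefined")
  q <- (gc$n1 + 2 * gc$n2) / (2 * n)
  p <- 1 - q
  if (q == 0 || q == 1) {
    chi2 <- 0
  } else {
    expected <- c(p^2, 2 * p * q, q^2) * n
    chi2 <- sum((c(gc$n0, gc$n1, gc$n2) - expected)^2 / expected)
  }
  structure(list(snp_id = gc$snp_id, chi2 = chi2, df = 1L,
                 p = stats::pchisq(chi2, df = 1, lower.tail = FALSE)),
            class = "hwe_result")
}

#' @export
print.hwe_result <- function(x, ...) {
  cat(sprintf("<hwe_result> %s: chi2 = %.4f (df = 1), p = %.4g\n",
              x$snp_id %||% "?", x$chi2, x$p))
  invisible(x)
}

#' Descriptive genotype/allele frequency table
#'
#' A frequency table in the layout customary for candidate-gene case-control
#' reports: per SNP, genotype counts with percentages in cases and controls,
#' a derived minor-allele row, and (optionally) the HWE chi-square p-value in
#' controls.
#'
#' @inheritParams n_individuals
#' @param hwe add the control-group HWE p-value column.
#' @param hwe_group group on which HWE is tested (`"control"` by default).
#' @return a `data.frame` with columns `snp_id`, `row` (genotype code or
#'   `"minor_allele"`), `case_n`, `case_pct`, `control_n`, `control_pct`,
#'   and `hwe_p` (on the first row of each SNP) when `hwe = TRUE`.
#' @export
describe_dataset <- function(dataset, hwe = TRUE,
                             hwe_group = c("control", "case")) {
  hwe_group <- match.arg(hwe_group)
  out <- lapply(snp_ids(dataset), function(s) {
    gca <- genotype_counts(dataset, s, "case")
    gco <- genotype_counts(dataset, s, "control")
    aca <- allele_counts(gca)
    aco <- allele_counts(gco)
    d <- data.frame(
      snp_id = s,
      row = c("0", "1", "2", "minor_allele"),
      case_n = c(gca$n0, gca$n1, gca$n2, aca$minor_count),
      case_pct = c(100 * c(gca$n0, gca$n1, gca$n2) / max(gca$n_typed, 1L),
                   100 * aca$minor_freq),
      control_n = c(gco$n0, gco$n1, gco$n2, aco$minor_count),
      control_pct = c(100 * c(gco$n0, gco$n1, gco$n2) /
                        max(gco$n_typed, 1L), 100 * aco$minor_freq),
      stringsAsFactors = FALSE
    )
    if (hwe) {
      d$hwe_p <- NA_real_
      d$hwe_p[1] <- hwe_chisq(if (hwe_group == "control") gco else gca)$p
    }
    d
  })
  do.call(rbind, out)
}
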