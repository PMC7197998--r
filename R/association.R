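#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the probability-mass criterion: the sum of
#' hypergeometric probabilities of all tables with the observed margins whose
#' probability does not exceed that of the observed table. The reported odds
#' ratio is the sample (cross-product) estimate `ad/bc` by default; the
#' conditional maximum-likelihood estimate (as in [stats::fisher.test()]) is
#' available via `or = "cmle"`.
#'
#' @param x 2x2 matrix of non-negative integer counts.
#' @param or odds-ratio estimator: `"sample"` (default) or `"cmle"`.
#' @return list with `or`, `p`. A zero margin gives `p = 1` and a
#'   non-estimable (`NA`) odds ratio.
#' @export
fisher_exact_2x2 <- function(x, or = c("sample", "cmle")) {
  or <- match.arg(or)
  x <- as.matrix(x)
  if (!all(dim(x) == c(2L, 2L))) stop_mdr("x must be a 2x2 table")
  if (any(x < 0) || any(x != round(x))) stop_mdr("counts must be non-negative integers")
  m <- sum(x[1, ])          # row 1 margin
  n <- sum(x[2, ])          # row 2 margin
  k <- sum(x[, 1])          # column 1 margin
  if (m == 0 || n == 0 || k == 0 || k == sum(x)) {
    return(list(or = NA_real_, p = 1))
  }
  support <- max(0L, k - n):min(k, m)
  dens <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x[1, 1], m, n, k)
  p <- sum(dens[dens <= p_obs * (1 + 1e-7)])
  est <- if (or == "sample") {
    unname((x[1, 1] * x[2, 2]) / (x[1, 2] * x[2, 1]))
  } else {
    unname(stats::fisher.test(x)$estimate)
  }
  list(or = est, p = min(p, 1))
}

#' Fisher-Freeman-Halton exact test for an r x c table
#'
#' Exact p-value by complete enumeration of all contingency tables with the
#' observed margins, summing the probabilities of tables no more probable
#' than the observed one. Enumeration is guarded by `max_tables`; beyond it,
#' either an error is raised or (with `monte_carlo = TRUE`) the p-value is
#' estimated by sampling tables from the null distribution via
#' [stats::r2dtable()].
#'
#' @param x matrix of non-negative integer counts, at least 2x2.
#' @param max_tables abort enumeration beyond this many candidate tables.
#' @param monte_carlo fall back to Monte-Carlo estimation instead of erroring
#'   when the enumeration guard trips.
#' @param B number of Monte-Carlo tables.
#' @param seed RNG seed for the Monte-Carlo path.
#' @return list with `p` and `method` (`"enumeration"` or `"monte-carlo"`).
#' @export
fisher_exact_rxc <- function(x, max_tables = 2e6, monte_carlo = FALSE,
                             B = 1e5, seed = NULL) {
  x <- as.matrix(x)
  if (nrow(x) < 2L || ncol(x) < 2L) stop_mdr("x must be at least 2x2")
  if (any(x < 0) || any(x != round(x))) stop_mdr("counts must be non-negative integers")
  rs <- rowSums(x)
  cs <- colSums(x)
  if (any(rs == 0) || any(cs == 0)) {
    keep_r <- rs > 0; keep_c <- cs > 0
    x <- x[keep_r, keep_c, drop = FALSE]
    if (nrow(x) < 2L || ncol(x) < 2L) return(list(p = 1, method = "degenerate"))
    rs <- rowSums(x); cs <- colSums(x)
  }
  N <- sum(x)
  # log multivariate hypergeometric probability of a table with these margins
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(N + 1)
  table_logp <- function(tab) log_const - sum(lgamma(tab + 1))
  logp_obs <- table_logp(x)

  count <- 0L
  total <- 0
  overflow <- FALSE
  nr <- nrow(x); nc <- ncol(x)
  tab <- matrix(0L, nr, nc)
  # enumerate cell by cell in row-major order; last row/column forced
  recurse <- function(i, j, row_left, col_left) {
    if (overflow) return()
    if (i == nr) {
      # last row forced by column margins
      if (any(col_left < 0)) return()
      tab[nr, ] <<- col_left
      count <<- count + 1L
      if (count > max_tables) { overflow <<- TRUE; return() }
      lp <- table_logp(tab)
      if (lp <= logp_obs + 1e-7) total <<- total + exp(lp)
      return()
    }
    if (j == nc) {
      v <- row_left
      if (v < 0 || v > col_left[nc]) return()
      tab[i, nc] <<- v
      cl <- col_left; cl[nc] <- cl[nc] - v
      recurse(i + 1L, 1L, rs[i + 1L], cl)
      return()
    }
    for (v in 0:min(row_left, col_left[j])) {
      tab[i, j] <<- v
      cl <- col_left; cl[j] <- cl[j] - v
      recurse(i, j + 1L, row_left - v, cl)
      if (overflow) return()
    }
  }
  recurse(1L, 1L, rs[1L], cs)
  if (overflow) {
    if (!monte_carlo) {
      stop_mdr("table too large for complete enumeration (> ", max_tables,
               " tables); rerun with monte_carlo = TRUE")
    }
    p <- with_seed(seed, {
      sim <- stats::r2dtable(B, rs, cs)
      hits <- vapply(sim, function(t) table_logp(t) <= logp_obs + 1e-7,
                     logical(1))
      (sum(hits) + 1) / (B + 1)
    })
    return(list(p = p, method = "monte-carlo"))
  }
  list(p = min(total, 1), method = "enumeration")
}

#' Bonferroni significance threshold
#'
#' `alpha / m` for `m` tests. Candidate-gene reports customarily display the
#' threshold truncated to three decimals (e.g. 0.05/9 shown as 0.005);
#' pass `digits` to apply that presentation truncation.
#'
#' @param alpha family-wise error rate, in (0, 1).
#' @param m_tests number of tests, >= 1.
#' @param digits if non-`NULL`, truncate (not round) to this many decimals.
#' @return the per-test threshold.
#' @export
bonferroni_threshold <- function(alpha, m_tests, digits = NULL) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop_mdr("alpha must lie in (0, 1)")
  }
  if (!is.numeric(m_tests) || m_tests < 1) stop_mdr("m_tests must be >= 1")
  th <- alpha / m_tests
  if (!is.null(digits)) th <- trunc(th * 10^digits) / 10^digits
  th
}

#' Pooled two-sample t-test from summary statistics
#'
#' Student's t with pooled variance, computed from group means, standard
#' deviations and sizes (as tabulated in a demographics table).
#'
#' @param mean1,sd1,n1 first group summary.
#' @param mean2,sd2,n2 second group summary.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
two_sample_summary_test <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop_mdr("each group needs n >= 2")
  if (sd1 <= 0 || sd2 <= 0) stop_mdr("standard deviations must be positive")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  t <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Covariate-adjusted codominant logistic regression for one SNP
#'
#' Fits `phenotype ~ het + hom + covariates` by maximum likelihood
#' ([stats::glm()] with binomial family), the SNP entered as two indicator
#' terms — heterozygote and minor-allele homozygote — against the
#' major-allele homozygote reference. Reports Wald odds ratios, 95%
#' confidence intervals and p-values per term. Complete separation (a
#' genotype class with zero cases or zero controls) is detected and the term
#' is reported as non-estimable rather than rescued.
#'
#' @inheritParams genotype_counts
#' @param covariates character vector of covariate column names to adjust
#'   for (e.g. `c("age", "sex", "bmi", "anc1", "anc2")`).
#' @return list with
#'   `results` (a `data.frame`: `term`, `or`, `ci_low`, `ci_high`, `p`,
#'   `estimable`), `fit` (coefficients, standard errors, convergence flag,
#'   `n_used`), and `reference` (the reference genotype code).
#' @export
logistic_codominant <- function(dataset, snp_id, covariates = character()) {
  if (!(snp_id %in% snp_ids(dataset))) stop_mdr("unknown SNP: ", snp_id)
  g <- dataset$genotypes[, snp_id]
  df <- data.frame(y = dataset$phenotype,
                   het = as.integer(g == 1L),
                   hom = as.integer(g == 2L))
  df <- add_covariates(df, dataset, covariates)
  df <- df[stats::complete.cases(df) & !is.na(g), , drop = FALSE]
  if (length(unique(df$y)) < 2L) {
    stop_mdr("need at least one case and one control after dropping missing")
  }
  # separation diagnostic: genotype class empty of cases or of controls
  cls <- factor(ifelse(df$hom == 1L, 2L, df$het), levels = 0:2)
  tab <- table(df$y, cls)
  sep <- colnames(tab)[tab["0", ] == 0 | tab["1", ] == 0]
  inestimable <- c(het = "1" %in% sep, hom = "2" %in% sep)

  fit <- stats::glm(y ~ ., family = stats::binomial(), data = df)
  res <- wald_results(fit, terms = c("het", "hom"),
                      inestimable = inestimable)
  list(results = res,
       fit = list(coefficients = stats::coef(fit),
                  se = summary(fit)$coefficients[, "Std. Error"],
                  converged = fit$converged,
                  n_used = nrow(df)),
       reference = "0 (major-allele homozygote)")
}

add_covariates <- function(df, dataset, covariates) {
  if (!length(covariates)) return(df)
  cov <- dataset$covariates
  miss <- setdiff(covariates, names(cov %||% data.frame()))
  if (length(miss)) stop_mdr("covariate(s) not found: ",
                             paste(miss, collapse = ", "))
  for (nm in covariates) {
    v <- cov[[nm]]
    if (is.character(v)) v <- factor(v)
    df[[nm]] <- v
  }
  df
}

wald_results <- function(fit, terms, inestimable = NULL) {
  sm <- summary(fit)$coefficients
  out <- lapply(terms, function(tm) {
    bad <- isTRUE(inestimable[[tm]]) || !(tm %in% rownames(sm)) ||
      is.na(sm[tm, "Estimate"])
    if (bad) {
      data.frame(term = tm, or = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, p = NA_real_, estimable = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      b <- sm[tm, "Estimate"]; se <- sm[tm, "Std. Error"]
      data.frame(term = tm, or = exp(b),
                 ci_low = exp(b - 1.959963984540054 * se),
                 ci_high = exp(b + 1.959963984540054 * se),
                 p = sm[tm, "Pr(>|z|)"], estimable = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

#' Logistic-regression corroboration of a multi-SNP interaction
#'
#' Fits a logistic model with the SNPs' minor-allele-count codes as main
#' effects plus their product term(s) (and optional covariates), and returns
#' the Wald test of the highest-order product term — the standard
#' parametric check of an interaction proposed by a model-free search.
#'
#' @inheritParams logistic_codominant
#' @param snp_idv character vector of 2 or 3 SNP ids.
#' @param coding per-SNP main-effect code entering the model:
#'   `"additive"` (minor-allele count 0/1/2, default) or `"dominant"`
#'   (minor-allele carrier indicator).
#' @return list with `p` (highest-order interaction Wald p, `NA` if
#'   non-estimable), `term`, `results` (per-term Wald table), `fit`, and
#'   `diagnostic` (`NULL`, or a message on separation/collinearity).
#' @export
logistic_interaction_check <- function(dataset, snp_idv,
                                       covariates = character(),
                                       coding = c("additive", "dominant")) {
  coding <- match.arg(coding)
  if (length(snp_idv) < 2L || length(snp_idv) > 3L) {
    stop_mdr("interaction check takes 2 or 3 SNPs")
  }
  bad <- setdiff(snp_idv, snp_ids(dataset))
  if (length(bad)) stop_mdr("unknown SNP(s): ", paste(bad, collapse = ", "))
  g <- dataset$genotypes[, snp_idv, drop = FALSE]
  vars <- paste0("g", seq_along(snp_idv))
  df <- data.frame(y = dataset$phenotype)
  for (i in seq_along(vars)) {
    df[[vars[i]]] <- if (coding == "dominant") as.numeric(g[, i] >= 1L)
                     else as.numeric(g[, i])
  }
  df <- add_covariates(df, dataset, covariates)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  form <- stats::as.formula(paste(
    "y ~", paste(c(paste(vars, collapse = " * "), covariates),
                 collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = df)
  top <- paste(vars, collapse = ":")
  co <- stats::coef(fit)
  diagnostic <- NULL
  if (anyNA(co)) {
    diagnostic <- paste("collinear/aliased term(s):",
                        paste(names(co)[is.na(co)], collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  if (!(top %in% rownames(sm)) || is.na(co[[top]])) {
    return(list(p = NA_real_, term = top, results = NULL, fit = fit,
                diagnostic = diagnostic %||% "interaction term not estimable"))
  }
  se <- sm[top, "Std. Error"]
  if (se > 50) {
    diagnostic <- diagnostic %||%
      "quasi-separation: interaction standard error diverged"
  }
  all_terms <- setdiff(rownames(sm), "(Intercept)")
  list(p = sm[top, "Pr(>|z|)"], term = top,
       results = wald_results(fit, all_terms), fit = fit,
       diagnostic = diagnostic)
}

#' Unadjusted allele-level association for one SNP
#'
#' Collapses genotypes to a 2x2 allele-by-group table (each individual
#' contributes two alleles) and applies [fisher_exact_2x2()]; the odds ratio
#' is the sample allele OR with a Woolf (log-OR normal) confidence interval.
#'
#' @inheritParams genotype_counts
#' @return a `data.frame` row: `term = "minor_allele"`, `or`, `ci_low`,
#'   `ci_high`, `p`, `estimable`.
#' @export
allele_association <- function(dataset, snp_id) {
  aca <- allele_counts(genotype_counts(dataset, snp_id, "case"))
  aco <- allele_counts(genotype_counts(dataset, snp_id, "control"))
  tab <- matrix(c(aca$minor_count, aca$total_alleles - aca$minor_count,
                  aco$minor_count, aco$total_alleles - aco$minor_count),
                nrow = 2, byrow = TRUE)
  ft <- fisher_exact_2x2(tab)
  estimable <- is.finite(ft$or) && !is.na(ft$or) && ft$or > 0
  if (estimable) {
    se <- sqrt(sum(1 / tab))
    ci <- exp(log(ft$or) + c(-1, 1) * 1.959963984540054 * se)
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  data.frame(term = "minor_allele", or = ft$or, ci_low = ci[1],
             ci_high = ci[2], p = ft$p, estimable = estimable,
             stringsAsFactors = FALSE)
}
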