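#' The nine-SNP articular-cartilage ECM panel
#'
#' Metadata for nine biallelic variants in eight genes of the articular
#' cartilage extracellular-matrix pathway (VEGFA, HIF1AN, COL3A1, EGF, MMP3,
#' MMP13, NOS2, NOS3), with minor-allele frequencies reported for the
#' Mexican population. This panel is the default for the simulator, so
#' validation studies run at realistic candidate-gene allele frequencies.
#'
#' @return a `data.frame` with columns `snp_id`, `gene`, `chrom_pos`
#'   (1-based `"chr:pos"`, no coordinate arithmetic intended), `ref_allele`,
#'   `minor_allele`, `maf`.
#' @export
osteo_snp_panel <- function() {
  data.frame(
    snp_id = c("rs699947", "rs3025039", "rs11292", "rs1800255", "rs4444903",
               "rs679620", "rs2252070", "rs2297518", "rs2070744"),
    gene = c("VEGFA", "VEGFA", "HIF1AN", "COL3A1", "EGF",
             "MMP3", "MMP13", "NOS2", "NOS3"),
    chrom_pos = c("6:43736389", "6:43752536", "10:102313607", "2:189864080",
                  "4:110834110", "11:102713620", "11:102826539",
                  "17:26096597", "7:150690079"),
    ref_allele = c("C", "C", "A", "G", "G", "C", "T", "G", "T"),
    minor_allele = c("A", "T", "G", "A", "A", "T", "C", "A", "C"),
    maf = c(0.42, 0.30, 0.13, 0.23, 0.38, 0.31, 0.29, 0.13, 0.27),
    stringsAsFactors = FALSE
  )
}

#' Simulate genotypes under Hardy-Weinberg equilibrium
#'
#' Independent biallelic loci (linkage equilibrium) with genotype
#' probabilities `(1-q)^2, 2q(1-q), q^2` at minor-allele frequency `q`.
#'
#' @param mafs vector of minor-allele frequencies, each in (0, 0.5].
#' @param n number of individuals.
#' @param seed RNG seed.
#' @param snp_idv optional column names.
#' @return integer matrix `n x length(mafs)` with entries 0/1/2.
#' @export
simulate_genotypes <- function(mafs, n, seed = NULL, snp_idv = NULL) {
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop_mdr("minor-allele frequencies must lie in (0, 0.5]")
  }
  with_seed(seed, {
    g <- vapply(mafs, function(q) {
      sample.int(3L, n, replace = TRUE,
                 prob = c((1 - q)^2, 2 * q * (1 - q), q^2)) - 1L
    }, integer(n))
    g <- matrix(as.integer(g), nrow = n)
    colnames(g) <- snp_idv %||% paste0("snp", seq_along(mafs))
    g
  })
}

#' Construct a penetrance model
#'
#' A map from multilocus genotype tuples to disease probability, driving the
#' case-control simulator.
#'
#' @param loci character vector of SNP ids (length k).
#' @param table numeric vector of length `3^k` of disease probabilities,
#'   ordered with the first locus varying fastest (the cell order of
#'   [build_cell_table()]).
#' @return a `penetrance_model`: list with `loci`, `table` (named by
#'   genotype tuple `"g1/g2/..."`).
#' @export
penetrance_model <- function(loci, table) {
  k <- length(loci)
  if (length(table) != 3^k) stop_mdr("table must have 3^k = ", 3^k, " entries")
  if (any(table < 0 | table > 1)) stop_mdr("penetrances must lie in [0, 1]")
  labels <- apply(as.matrix(expand.grid(rep(list(0:2), k))), 1L,
                  paste, collapse = "/")
  structure(list(loci = loci, table = stats::setNames(as.numeric(table),
                                                      labels)),
            class = "penetrance_model")
}

#' @export
print.penetrance_model <- function(x, ...) {
  cat(sprintf("<penetrance_model> loci: %s\n", paste(x$loci, collapse = ", ")))
  print(x$table)
  invisible(x)
}

#' Purely epistatic XOR penetrance for two loci
#'
#' Disease probability is `baseline + effect` when exactly one of the two
#' loci is heterozygous, `baseline` otherwise — a checkerboard pattern with
#' no main effects when the heterozygote probability is 1/2 at both loci
#' (i.e. MAF 0.5), and only weak marginal signal at nearby frequencies. The
#' canonical planted interaction for validating an epistasis search.
#'
#' @param loci two SNP ids.
#' @param baseline background disease probability.
#' @param effect added probability in the discordant-heterozygosity cells;
#'   `baseline + effect` must not exceed 1.
#' @return a [penetrance_model()].
#' @export
xor_penetrance <- function(loci, baseline = 0.05, effect = 0.4) {
  if (length(loci) != 2L) stop_mdr("XOR penetrance takes exactly 2 loci")
  if (baseline < 0 || effect < 0 || baseline + effect > 1) {
    stop_mdr("need baseline, effect >= 0 and baseline + effect <= 1")
  }
  grid <- expand.grid(g1 = 0:2, g2 = 0:2)
  hit <- xor(grid$g1 == 1L, grid$g2 == 1L)
  penetrance_model(loci, ifelse(hit, baseline + effect, baseline))
}

#' Additive single-locus penetrance
#'
#' Disease probability `baseline + genotype * effect_per_allele`: a marginal
#' (non-epistatic) risk locus for testing single-SNP association stages.
#'
#' @param locus one SNP id.
#' @param baseline background disease probability.
#' @param effect_per_allele added probability per minor allele.
#' @return a [penetrance_model()].
#' @export
additive_penetrance <- function(locus, baseline = 0.1,
                                effect_per_allele = 0.1) {
  if (baseline < 0 || baseline + 2 * effect_per_allele > 1) {
    stop_mdr("penetrances must stay within [0, 1]")
  }
  penetrance_model(locus, baseline + (0:2) * effect_per_allele)
}

# Default covariate model: group-specific age and BMI normals, sex Bernoulli
# and a shared 3-component admixture Dirichlet, at values typical of a
# Mexican knee-osteoarthritis case-control cohort.
default_covariate_model <- function() {
  list(age = list(case = c(mean = 47.2, sd = 12.4),
                  control = c(mean = 40.9, sd = 12.0)),
       bmi = list(case = c(mean = 29.0, sd = 4.19),
                  control = c(mean = 24.8, sd = 4.38)),
       female_prob = c(case = 0.87, control = 0.714),
       admixture_alpha = c(amerindian = 11, european = 8, african = 1))
}

#' Simulate a case-control genotype dataset
#'
#' Individuals are drawn from a Hardy-Weinberg population at the panel's
#' minor-allele frequencies; disease status is assigned by the penetrance
#' model and individuals are accumulated by rejection sampling until exactly
#' `n_cases` cases and `n_controls` controls are collected (mirroring
#' case-control ascertainment). With `penetrance = NULL` the phenotype is
#' independent of every genotype, and labels are assigned directly — the
#' null generator. Covariates are drawn from group-specific distributions
#' (age and BMI normal, sex Bernoulli, admixture Dirichlet) independent of
#' genotype; missing genotype calls are masked completely at random.
#'
#' @param n_cases,n_controls target group sizes.
#' @param snp_meta SNP metadata with `snp_id` and `maf` columns; defaults to
#'   the nine-SNP panel of [osteo_snp_panel()].
#' @param penetrance a [penetrance_model()] over a subset of the panel's
#'   SNPs, or `NULL` for the null model.
#' @param covariate_model covariate parameters (see
#'   the default in the source); `NULL` suppresses covariates.
#' @param admixture include three admixture-proportion columns
#'   (`anc1..anc3`, summing to 1).
#' @param missing_rate per-call probability of masking a genotype.
#' @param seed RNG seed; the full dataset is a pure function of the
#'   configuration and this seed.
#' @param max_draws rejection-sampling cap on total individuals drawn.
#' @return an [mdr_dataset()] with attribute `"sim_config"` recording the
#'   generating configuration.
#' @export
simulate_case_control <- function(n_cases = 92L, n_controls = 147L,
                                  snp_meta = osteo_snp_panel(),
                                  penetrance = NULL,
                                  covariate_model = default_covariate_model(),
                                  admixture = TRUE,
                                  missing_rate = 0, seed = NULL,
                                  max_draws = 1e7) {
  if (n_cases < 1L || n_controls < 1L) stop_mdr("need n_cases, n_controls > 0")
  if (missing_rate < 0 || missing_rate >= 1) {
    stop_mdr("missing_rate must lie in [0, 1)")
  }
  snp_meta <- validate_snp_meta(snp_meta)
  if (!is.null(penetrance)) {
    stopifnot(inherits(penetrance, "penetrance_model"))
    bad <- setdiff(penetrance$loci, snp_meta$snp_id)
    if (length(bad)) stop_mdr("penetrance loci not in panel: ",
                              paste(bad, collapse = ", "))
  }
  with_seed(seed, {
    geno <- draw_ascertained_genotypes(n_cases, n_controls, snp_meta,
                                       penetrance, max_draws)
    phenotype <- c(rep(1L, n_cases), rep(0L, n_controls))
    cov <- NULL
    if (!is.null(covariate_model)) {
      cov <- draw_covariates(phenotype, covariate_model, admixture)
    }
    if (missing_rate > 0) {
      mask <- stats::runif(length(geno)) < missing_rate
      geno[mask] <- NA_integer_
    }
    ds <- mdr_dataset(geno, phenotype, covariates = cov, snp_meta = snp_meta)
    attr(ds, "sim_config") <- list(
      n_cases = n_cases, n_controls = n_controls,
      penetrance = penetrance, missing_rate = missing_rate, seed = seed)
    ds
  })
}

draw_ascertained_genotypes <- function(n_cases, n_controls, snp_meta,
                                       penetrance, max_draws) {
  m <- nrow(snp_meta)
  if (is.null(penetrance)) {
    # phenotype independent of genotype: direct assignment is
    # distributionally identical to constant-penetrance rejection sampling
    return(simulate_genotypes(snp_meta$maf, n_cases + n_controls,
                              snp_idv = snp_meta$snp_id))
  }
  loci_idx <- match(penetrance$loci, snp_meta$snp_id)
  cases <- matrix(NA_integer_, 0L, m)
  controls <- matrix(NA_integer_, 0L, m)
  drawn <- 0
  batch <- max(1000L, 2L * (n_cases + n_controls))
  while ((nrow(cases) < n_cases || nrow(controls) < n_controls)) {
    if (drawn >= max_draws) {
      stop_mdr("could not accumulate ", n_cases, "/", n_controls,
               " cases/controls within ", max_draws,
               " draws; penetrance model leaves a group unreachable")
    }
    g <- simulate_genotypes(snp_meta$maf, batch, snp_idv = snp_meta$snp_id)
    drawn <- drawn + batch
    idx <- cell_index(g[, loci_idx, drop = FALSE])
    pen <- unname(penetrance$table[idx])
    disease <- stats::runif(batch) < pen
    if (nrow(cases) < n_cases) {
      cases <- rbind(cases, g[disease, , drop = FALSE])
    }
    if (nrow(controls) < n_controls) {
      controls <- rbind(controls, g[!disease, , drop = FALSE])
    }
  }
  out <- rbind(cases[seq_len(n_cases), , drop = FALSE],
               controls[seq_len(n_controls), , drop = FALSE])
  colnames(out) <- snp_meta$snp_id
  out
}

draw_covariates <- function(phenotype, cm, admixture) {
  n <- length(phenotype)
  grp <- ifelse(phenotype == 1L, "case", "control")
  age <- bmi <- numeric(n)
  sex <- character(n)
  for (g in c("case", "control")) {
    i <- grp == g
    age[i] <- stats::rnorm(sum(i), cm$age[[g]]["mean"], cm$age[[g]]["sd"])
    bmi[i] <- stats::rnorm(sum(i), cm$bmi[[g]]["mean"], cm$bmi[[g]]["sd"])
    sex[i] <- ifelse(stats::runif(sum(i)) < cm$female_prob[[g]],
                     "female", "male")
  }
  cov <- data.frame(age = age, sex = sex, bmi = bmi,
                    stringsAsFactors = FALSE)
  if (admixture) {
    alpha <- cm$admixture_alpha
    draws <- vapply(alpha, function(a) stats::rgamma(n, shape = a),
                    numeric(n))
    props <- draws / rowSums(draws)
    cov$anc1 <- props[, 1]; cov$anc2 <- props[, 2]; cov$anc3 <- props[, 3]
  }
  cov
}
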