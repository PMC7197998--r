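# Independent reference implementations used as oracles. Deliberately naive
# (per-individual loops, string-keyed cell maps) so they share no code path
# with the package internals they check.

# Expand a per-SNP printed count table (columns snp_id, group, n0, n1, n2)
# into an individual-level dataset; untyped individuals get NA so per-SNP
# totals can differ, as in real genotyping reports.
dataset_from_count_table <- function(counts, n_cases, n_controls) {
  snps <- unique(counts$snp_id)
  geno <- matrix(NA_integer_, n_cases + n_controls, length(snps),
                 dimnames = list(NULL, snps))
  for (s in snps) {
    for (grp in c("case", "control")) {
      row <- counts[counts$snp_id == s & counts$group == grp, ]
      g <- rep(0:2, times = c(row$n0, row$n1, row$n2))
      offset <- if (grp == "case") 0L else n_cases
      geno[offset + seq_along(g), s] <- g
    }
  }
  mdr_dataset(geno, c(rep(1L, n_cases), rep(0L, n_controls)))
}

# Naive per-fold MDR evaluation of one combo: loops over individuals,
# cells keyed by genotype strings.
naive_combo_cv <- function(geno, pheno, combo, fold_id,
                           threshold = 1, unknown = "low") {
  g <- geno[, combo, drop = FALSE]
  typed <- apply(g, 1L, function(r) !any(is.na(r)))
  key <- apply(g, 1L, paste, collapse = "/")
  nfold <- max(fold_id)
  train_ba <- test_ba <- rep(NA_real_, nfold)
  for (f in seq_len(nfold)) {
    tr <- which(typed & fold_id != f)
    te <- which(typed & fold_id == f)
    n_case <- sum(pheno[tr] == 1)
    n_ctrl <- sum(pheno[tr] == 0)
    if (n_case == 0 || n_ctrl == 0) next
    cells <- list()
    for (i in tr) {
      k <- key[i]
      cur <- cells[[k]]
      if (is.null(cur)) cur <- c(0, 0)
      cur[if (pheno[i] == 1) 1 else 2] <- cur[if (pheno[i] == 1) 1 else 2] + 1
      cells[[k]] <- cur
    }
    risk <- lapply(cells, function(cc) {
      if ((cc[1] / n_case) >= threshold * (cc[2] / n_ctrl)) "high" else "low"
    })
    predict1 <- function(i) {
      r <- risk[[key[i]]]
      if (is.null(r)) if (unknown == "high") "high" else
        if (unknown == "exclude") NA_character_ else "low"
      else r
    }
    ba <- function(idx) {
      pred <- vapply(idx, predict1, character(1))
      keep <- !is.na(pred)
      y <- pheno[idx][keep]
      p <- pred[keep]
      if (sum(y == 1) == 0 || sum(y == 0) == 0) return(NA_real_)
      (sum(p == "high" & y == 1) / sum(y == 1) +
          sum(p == "low" & y == 0) / sum(y == 0)) / 2
    }
    train_ba[f] <- ba(tr)
    test_ba[f] <- ba(te)
  }
  list(train_ba = train_ba, test_ba = test_ba)
}

# Naive cell table: loop + string keys; returns named list cell -> c(case, ctrl)
naive_cell_table <- function(geno, pheno, combo) {
  g <- geno[, combo, drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(g))) {
    if (any(is.na(g[i, ]))) next
    k <- paste(g[i, ], collapse = "/")
    cur <- out[[k]]
    if (is.null(cur)) cur <- c(case = 0, control = 0)
    slot <- if (pheno[i] == 1) "case" else "control"
    cur[slot] <- cur[slot] + 1
    out[[k]] <- cur
  }
  out
}

# Definition-level mutual information: double sum over the joint table.
naive_mutual_information <- function(x, c) {
  n <- length(x)
  jt <- table(x, c) / n
  px <- rowSums(jt)
  pc <- colSums(jt)
  s <- 0
  for (i in seq_along(px)) for (j in seq_along(pc)) {
    if (jt[i, j] > 0) s <- s + jt[i, j] * log2(jt[i, j] / (px[i] * pc[j]))
  }
  unname(s)
}

# Random small dataset for property tests.
random_dataset <- function(n, m, maf = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(sample(0:2, n * m, replace = TRUE,
                     prob = c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)),
              n, m, dimnames = list(NULL, sprintf("rs%03d", seq_len(m))))
  y <- c(rep(1L, ceiling(n / 2)), rep(0L, floor(n / 2)))
  mdr_dataset(g, y)
}

printed_hwe_controls <- c(
  rs3025039 = 0.061, rs699947 = 0.063, rs11292 = 0.011, rs1800255 = 0.102,
  rs4444903 = 0.890, rs679620 = 0.073, rs2252070 = 0.602, rs2297518 = 0.887,
  rs2070744 = 0.092)

read_count_fixture <- function() {
  read.delim(mdr_example("oa_genotype_counts.tsv"),
             stringsAsFactors = FALSE)
}
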