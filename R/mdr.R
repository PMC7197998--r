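#' Multilocus genotype cell table
#'
#' Cross-tabulates case and control counts over the `3^k` genotype cells of a
#' k-locus SNP combination — the dimensionality-reduction table at the core
#' of MDR. Individuals missing a genotype at any combination SNP are
#' excluded (per-combination deletion, which maximises data use).
#'
#' @inheritParams n_individuals
#' @param combo character vector of 1 to 5 distinct SNP ids.
#' @return an `mdr_cell_table`: list with `combo`, `genotype` (character
#'   labels `"g1/g2/..."` for all `3^k` cells), `case_count`, `control_count`
#'   (integer vectors over cells), `n_cases`, `n_controls`.
#' @export
build_cell_table <- function(dataset, combo) {
  k <- length(combo)
  if (k < 1L || k > 5L) stop_mdr("combination size must be 1..5")
  if (anyDuplicated(combo)) stop_mdr("duplicate SNP in combination")
  bad <- setdiff(combo, snp_ids(dataset))
  if (length(bad)) stop_mdr("unknown SNP(s): ", paste(bad, collapse = ", "))
  g <- dataset$genotypes[, combo, drop = FALSE]
  cc <- !rowSums(is.na(g))
  idx <- cell_index(g[cc, , drop = FALSE])
  is_case <- dataset$phenotype[cc] == 1L
  ncell <- 3L^k
  case_count <- tabulate(idx[is_case], ncell)
  control_count <- tabulate(idx[!is_case], ncell)
  labels <- apply(as.matrix(expand.grid(rep(list(0:2), k))), 1L,
                  paste, collapse = "/")
  structure(list(combo = combo, genotype = labels,
                 case_count = case_count, control_count = control_count,
                 n_cases = sum(case_count),
                 n_controls = sum(control_count)),
            class = "mdr_cell_table")
}

# 1-based cell index of each row of a complete 0/1/2 genotype matrix:
# first column varies fastest (matches expand.grid ordering).
cell_index <- function(g) {
  idx <- rep(1L, nrow(g))
  mult <- 1L
  for (j in seq_len(ncol(g))) {
    idx <- idx + g[, j] * mult
    mult <- mult * 3L
  }
  idx
}

#' @export
print.mdr_cell_table <- function(x, ...) {
  cat(sprintf("<mdr_cell_table> %s: %d cases / %d controls\n",
              paste(x$combo, collapse = " x "), x$n_cases, x$n_controls))
  nz <- x$case_count + x$control_count > 0
  print(data.frame(genotype = x$genotype[nz], cases = x$case_count[nz],
                   controls = x$control_count[nz]))
  invisible(x)
}

#' High/low-risk labelling of genotype cells
#'
#' A cell is labelled high-risk when the ratio of its within-cases percentage
#' to its within-controls percentage meets or exceeds the threshold (default
#' 1.0); cells with cases but no controls are high-risk; empty cells are
#' `"unknown"`. With equal case and control totals the rule reduces to the
#' raw case:control ratio.
#'
#' @param ct an `mdr_cell_table`.
#' @param threshold_ratio positive risk-ratio threshold; ties at the
#'   threshold are labelled high ("met or exceeded").
#' @return an `mdr_risk_labeling`: list with `combo`, `genotype`, `label`
#'   (character vector over cells: `"high"`, `"low"`, `"unknown"`),
#'   `threshold_ratio`.
#' @export
label_cells <- function(ct, threshold_ratio = 1.0) {
  stopifnot(inherits(ct, "mdr_cell_table"), threshold_ratio > 0)
  if (ct$n_cases == 0L || ct$n_controls == 0L) {
    stop_mdr("need at least one case and one control to label cells")
  }
  lhs <- ct$case_count * ct$n_controls
  rhs <- threshold_ratio * ct$control_count * ct$n_cases
  empty <- ct$case_count + ct$control_count == 0L
  label <- ifelse(empty, "unknown", ifelse(lhs >= rhs, "high", "low"))
  structure(list(combo = ct$combo, genotype = ct$genotype, label = label,
                 threshold_ratio = threshold_ratio),
            class = "mdr_risk_labeling")
}

#' Balanced accuracy of a high/low risk classification
#'
#' `(sensitivity + specificity) / 2`, where a high-risk prediction calls a
#' case; the appropriate accuracy when cases and controls are unequal in
#' number.
#'
#' @param truth case/control labels (`"case"`/`"control"`, 0/1, or logical
#'   is-case).
#' @param predicted_risk `"high"`/`"low"` labels (or logical is-high) of the
#'   same length.
#' @return balanced accuracy in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, predicted_risk) {
  if (is.character(truth) || is.factor(truth)) {
    truth <- as.character(truth) == "case"
  } else truth <- as.logical(as.integer(truth))
  if (is.character(predicted_risk) || is.factor(predicted_risk)) {
    predicted_risk <- as.character(predicted_risk) == "high"
  } else predicted_risk <- as.logical(predicted_risk)
  if (length(truth) != length(predicted_risk)) stop_mdr("length mismatch")
  if (!any(truth) || all(truth)) {
    stop_mdr("need at least one case and one control")
  }
  sens <- sum(predicted_risk & truth) / sum(truth)
  spec <- sum(!predicted_risk & !truth) / sum(!truth)
  (sens + spec) / 2
}

#' Stratified cross-validation fold assignment
#'
#' Assigns each individual to one of `folds` folds by a seeded shuffle
#' within cases and within controls separately, so every fold preserves the
#' case:control ratio as closely as possible.
#'
#' @param phenotype 0/1 phenotype vector.
#' @param folds number of folds (default 10).
#' @param seed RNG seed for the shuffle.
#' @return integer fold id per individual.
#' @export
assign_folds <- function(phenotype, folds = 10L, seed = NULL) {
  phenotype <- encode_phenotype(phenotype)
  if (sum(phenotype == 1L) < folds || sum(phenotype == 0L) < folds) {
    stop_mdr("too few cases or controls for ", folds, " stratified folds")
  }
  fold_id <- integer(length(phenotype))
  with_seed(seed, {
    for (cls in c(0L, 1L)) {
      idx <- which(phenotype == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold_id
}

# Vectorised CV engine for one SNP combination. Inputs are restricted to the
# combination's complete cases. Counts per (cell, fold) are formed in one
# tabulate() pass; training counts are totals minus the held-out fold.
# Returns per-fold training and testing balanced accuracies (NA when a fold
# lacks typed cases or controls).
eval_combo_cv <- function(cell_idx, is_case, fold_id, ncell, nfold,
                          threshold_ratio = 1.0, unknown = "low") {
  key <- cell_idx + ncell * (fold_id - 1L)
  case_cf <- matrix(tabulate(key[is_case], ncell * nfold), ncell, nfold)
  ctrl_cf <- matrix(tabulate(key[!is_case], ncell * nfold), ncell, nfold)
  tr_case <- rowSums(case_cf) - case_cf
  tr_ctrl <- rowSums(ctrl_cf) - ctrl_cf
  n_case_tr <- colSums(tr_case)
  n_ctrl_tr <- colSums(tr_ctrl)
  nonempty <- (tr_case + tr_ctrl) > 0
  high <- (tr_case * rep(n_ctrl_tr, each = ncell) >=
             threshold_ratio * tr_ctrl * rep(n_case_tr, each = ncell)) &
    nonempty
  train_ba <- (colSums(tr_case * high) / n_case_tr +
                 colSums(tr_ctrl * !high) / n_ctrl_tr) / 2
  pred <- if (unknown == "high") high | !nonempty else high
  if (unknown == "exclude") {
    n_case_te <- colSums(case_cf * nonempty)
    n_ctrl_te <- colSums(ctrl_cf * nonempty)
    sens <- colSums(case_cf * (pred & nonempty)) / n_case_te
    spec <- colSums(ctrl_cf * (!pred & nonempty)) / n_ctrl_te
  } else {
    n_case_te <- colSums(case_cf)
    n_ctrl_te <- colSums(ctrl_cf)
    sens <- colSums(case_cf * pred) / n_case_te
    spec <- colSums(ctrl_cf * !pred) / n_ctrl_te
  }
  test_ba <- (sens + spec) / 2
  train_ba[!is.finite(train_ba)] <- NA_real_
  test_ba[!is.finite(test_ba)] <- NA_real_
  list(train_ba = train_ba, test_ba = test_ba)
}

# Complete-case projection of one combination: cell index, case flag and
# fold id restricted to individuals typed at every combination SNP.
combo_projection <- function(dataset, combo, fold_id) {
  g <- dataset$genotypes[, combo, drop = FALSE]
  cc <- rowSums(is.na(g)) == 0L
  list(cell_idx = cell_index(g[cc, , drop = FALSE]),
       is_case = dataset$phenotype[cc] == 1L,
       fold_id = fold_id[cc],
       ncell = 3L^length(combo))
}

#' Cross-validate one SNP combination
#'
#' For each fold, the high/low-risk labelling is learned on the training 90%
#' and balanced accuracy is evaluated on both the training and the held-out
#' partition. Test individuals that fall in a cell unseen in training
#' ("unknown" cells) are predicted per `unknown`: low-risk (default,
#' conservative), high-risk, or excluded from that fold's test accuracy.
#'
#' @inheritParams build_cell_table
#' @inheritParams label_cells
#' @param folds number of cross-validation folds (default 10).
#' @param seed RNG seed governing the fold shuffle.
#' @param unknown prediction rule for unknown cells: `"low"`, `"high"` or
#'   `"exclude"`.
#' @param fold_id optional precomputed fold assignment (overrides
#'   `folds`/`seed`), so several calls can share identical folds.
#' @return list with `fold_train_ba` and `fold_test_ba` (length `folds`).
#' @export
cross_validate <- function(dataset, combo, folds = 10L, seed = NULL,
                           threshold_ratio = 1.0,
                           unknown = c("low", "high", "exclude"),
                           fold_id = NULL) {
  unknown <- match.arg(unknown)
  fold_id <- fold_id %||% assign_folds(dataset$phenotype, folds, seed)
  nfold <- max(fold_id)
  pr <- combo_projection(dataset, combo, fold_id)
  r <- eval_combo_cv(pr$cell_idx, pr$is_case, pr$fold_id, pr$ncell, nfold,
                     threshold_ratio, unknown)
  list(fold_train_ba = r$train_ba, fold_test_ba = r$test_ba)
}

#' Exhaustive MDR combination search
#'
#' Evaluates every k-locus SNP combination for each size `k_min..k_max`
#' under one shared stratified fold assignment. For each size, the best
#' combination maximises the mean training balanced accuracy; the
#' cross-validation consistency (CVC) is the number of folds in which that
#' combination is also the fold's best (by fold training accuracy).
#' Combinations are enumerated in lexicographic SNP-id order and ties take
#' the first maximum, so tie-breaking is reproducible.
#'
#' @inheritParams cross_validate
#' @param k_min,k_max combination sizes to search.
#' @param snps SNP ids to search over (default: all).
#' @return an `mdr_search_result`: list with `models` (one `mdr_model` per
#'   size: `combo`, `k`, `fold_train_ba`, `fold_test_ba`, `train_ba`,
#'   `test_ba`, `cvc`, `folds`), `fold_id`, and the call configuration.
#' @export
mdr_search <- function(dataset, k_min = 1L, k_max = 3L, folds = 10L,
                       seed = NULL, threshold_ratio = 1.0,
                       unknown = c("low", "high", "exclude"),
                       snps = NULL, fold_id = NULL) {
  unknown <- match.arg(unknown)
  snps <- sort(snps %||% snp_ids(dataset))
  if (k_max > length(snps)) stop_mdr("k_max exceeds the number of SNPs")
  if (k_min < 1L || k_min > k_max) stop_mdr("need 1 <= k_min <= k_max")
  fold_id <- fold_id %||% assign_folds(dataset$phenotype, folds, seed)
  nfold <- max(fold_id)
  models <- lapply(k_min:k_max, function(k) {
    combos <- utils::combn(snps, k, simplify = FALSE)
    train <- matrix(NA_real_, length(combos), nfold)
    test <- matrix(NA_real_, length(combos), nfold)
    for (i in seq_along(combos)) {
      pr <- combo_projection(dataset, combos[[i]], fold_id)
      r <- eval_combo_cv(pr$cell_idx, pr$is_case, pr$fold_id, pr$ncell,
                         nfold, threshold_ratio, unknown)
      train[i, ] <- r$train_ba
      test[i, ] <- r$test_ba
    }
    mean_train <- rowMeans(train, na.rm = TRUE)
    best <- which.max(mean_train)
    fold_best <- apply(train, 2L, function(col) {
      if (all(is.na(col))) NA_integer_ else which.max(col)
    })
    structure(list(combo = combos[[best]], k = k,
                   fold_train_ba = train[best, ],
                   fold_test_ba = test[best, ],
                   train_ba = mean_train[best],
                   test_ba = mean(test[best, ], na.rm = TRUE),
                   cvc = sum(fold_best == best, na.rm = TRUE),
                   folds = nfold),
              class = "mdr_model")
  })
  names(models) <- paste0("k", k_min:k_max)
  structure(list(models = models, fold_id = fold_id,
                 config = list(k_min = k_min, k_max = k_max, folds = nfold,
                               seed = seed, threshold_ratio = threshold_ratio,
                               unknown = unknown, snps = snps)),
            class = "mdr_search_result")
}

#' @export
print.mdr_model <- function(x, ...) {
  cat(sprintf("<mdr_model> k=%d [%s]: train BA %.4f, test BA %.4f, CVC %d/%d%s\n",
              x$k, paste(x$combo, collapse = ", "), x$train_ba, x$test_ba,
              x$cvc, x$folds,
              if (!is.null(x$perm_p)) sprintf(", perm p %.4g", x$perm_p) else ""))
  invisible(x)
}

#' @export
print.mdr_search_result <- function(x, ...) {
  cat("<mdr_search_result>\n")
  for (m in x$models) print(m)
  invisible(x)
}

#' Select the final MDR model across sizes
#'
#' Statistical-parsimony rule: maximise testing balanced accuracy; break
#' ties by cross-validation consistency, then by the smaller model size.
#'
#' @param models list of `mdr_model` objects (or an `mdr_search_result`).
#' @param tol numeric tolerance for declaring ties.
#' @return the selected `mdr_model`.
#' @export
select_final_model <- function(models, tol = 1e-9) {
  if (inherits(models, "mdr_search_result")) models <- models$models
  if (!length(models)) stop_mdr("empty model list")
  best <- models[[1L]]
  for (m in models[-1L]) {
    if (m$test_ba > best$test_ba + tol) best <- m
    else if (abs(m$test_ba - best$test_ba) <= tol) {
      if (m$cvc > best$cvc) best <- m
      else if (m$cvc == best$cvc && m$k < best$k) best <- m
    }
  }
  best
}

#' Permutation test of the best k-locus model
#'
#' The phenotype labels are permuted `n_perm` times (covariates and
#' genotypes stay attached to their individuals); each permutation reruns
#' the size-k search — with freshly assigned stratified folds — and records
#' the best model's testing balanced accuracy. The p-value is
#' `(1 + #{permuted >= observed}) / (n_perm + 1)`.
#'
#' @inheritParams mdr_search
#' @param k model size under test.
#' @param n_perm number of permutations (>= 19 for alpha = 0.05 resolution).
#' @param seed RNG seed governing folds and permutations.
#' @return list with `perm_p`, `observed_test_ba`, `perm_test_ba`
#'   (length `n_perm`), and `observed_model`.
#' @export
permutation_test <- function(dataset, k, n_perm = 99L, folds = 10L,
                             seed = NULL, threshold_ratio = 1.0,
                             unknown = c("low", "high", "exclude"),
                             snps = NULL) {
  unknown <- match.arg(unknown)
  if (n_perm < 19L) stop_mdr("n_perm must be >= 19")
  snps <- sort(snps %||% snp_ids(dataset))
  combos <- utils::combn(snps, k, simplify = FALSE)
  # genotype cell indices never change under phenotype permutation
  g_cc <- lapply(combos, function(cb) {
    g <- dataset$genotypes[, cb, drop = FALSE]
    cc <- which(rowSums(is.na(g)) == 0L)
    list(cc = cc, idx = cell_index(g[cc, , drop = FALSE]),
         ncell = 3L^k)
  })
  search_once <- function(pheno, fold_id) {
    best_train <- -Inf
    best_test <- NA_real_
    best_i <- NA_integer_
    for (i in seq_along(combos)) {
      pr <- g_cc[[i]]
      r <- eval_combo_cv(pr$idx, pheno[pr$cc] == 1L, fold_id[pr$cc],
                         pr$ncell, folds, threshold_ratio, unknown)
      mt <- mean(r$train_ba, na.rm = TRUE)
      if (mt > best_train) {
        best_train <- mt
        best_test <- mean(r$test_ba, na.rm = TRUE)
        best_i <- i
      }
    }
    list(test_ba = best_test, combo = combos[[best_i]])
  }
  with_seed(seed, {
    fold_id <- assign_folds(dataset$phenotype, folds, seed = NULL)
    obs <- search_once(dataset$phenotype, fold_id)
    perm_ba <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      pheno_b <- dataset$phenotype[sample.int(length(dataset$phenotype))]
      fold_b <- assign_folds(pheno_b, folds, seed = NULL)
      perm_ba[b] <- search_once(pheno_b, fold_b)$test_ba
    }
    list(perm_p = (1 + sum(perm_ba >= obs$test_ba - 1e-12)) / (n_perm + 1),
         observed_test_ba = obs$test_ba,
         perm_test_ba = perm_ba,
         observed_model = obs$combo)
  })
}
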