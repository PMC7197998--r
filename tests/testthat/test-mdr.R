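test_that("one-locus cell tables equal the published count rows", {
  cnt <- read_count_fixture()
  ds <- dataset_from_count_table(cnt, 92, 147)
  ct <- build_cell_table(ds, "rs679620")
  expect_equal(ct$case_count, c(39, 30, 11))
  expect_equal(ct$control_count, c(41, 27, 11))
  expect_equal(ct$n_cases, 80)
  expect_equal(ct$n_controls, 79)
})

test_that("cell tables conserve counts and match a naive counting oracle", {
  set.seed(30)
  for (r in 1:10) {
    ds <- random_dataset(30, 3)
    ds$genotypes[sample(90, 8)] <- NA  # per-combination deletion
    combo <- sample(snp_ids(ds), 2)
    ct <- build_cell_table(ds, combo)
    expect_equal(sum(ct$case_count) + sum(ct$control_count),
                 sum(!apply(is.na(ds$genotypes[, combo]), 1, any)))
    ref <- naive_cell_table(ds$genotypes, ds$phenotype, combo)
    for (k in names(ref)) {
      i <- match(k, ct$genotype)
      expect_equal(unname(ct$case_count[i]), unname(ref[[k]]["case"]))
      expect_equal(unname(ct$control_count[i]), unname(ref[[k]]["control"]))
    }
  }
  expect_error(build_cell_table(random_dataset(10, 2), c("rs001", "rs001")),
               "duplicate")
})

test_that("risk labelling follows the percentage-ratio threshold rule", {
  ds <- dataset_from_counts("s", c(3, 22, 25), c(1, 49, 50))
  ct <- build_cell_table(ds, "s")
  lb <- label_cells(ct)
  # cell 0: (3/50)/(1/100) = 6 >= 1 -> high
  expect_equal(lb$label[1], "high")
  ds2 <- dataset_from_counts("s", c(1, 24, 25), c(2, 24, 24))
  lb2 <- label_cells(build_cell_table(ds2, "s"))
  expect_equal(lb2$label[1], "low")  # ratio 0.5
  # empty cell -> unknown
  ds3 <- dataset_from_counts("s", c(5, 5, 0), c(5, 5, 0))
  lb3 <- label_cells(build_cell_table(ds3, "s"))
  expect_equal(lb3$label[3], "unknown")
  # ties at the threshold are high ("met or exceeded")
  expect_equal(lb3$label[1], "high")
})

test_that("labelling is invariant to duplicating every individual", {
  set.seed(14)
  ds <- random_dataset(40, 2)
  dup <- mdr_dataset(ds$genotypes[rep(1:40, 2), ],
                     ds$phenotype[rep(1:40, 2)])
  l1 <- label_cells(build_cell_table(ds, snp_ids(ds)))
  l2 <- label_cells(build_cell_table(dup, snp_ids(dup)))
  expect_identical(l1$label, l2$label)
})

test_that("balanced accuracy follows its closed form", {
  truth <- c("case", "case", "case", "control", "control")
  expect_equal(balanced_accuracy(truth, c("high", "high", "high",
                                          "low", "low")), 1)
  expect_equal(balanced_accuracy(truth, rep("high", 5)), 0.5)
  expect_equal(balanced_accuracy(truth, c("high", "high", "low",
                                          "low", "low")),
               (2 / 3 + 1) / 2)
  expect_error(balanced_accuracy(rep("case", 3), rep("high", 3)),
               "at least one")
})

test_that("fold assignment is stratified, seeded and reproducible", {
  y <- c(rep(1L, 45), rep(0L, 63))
  f1 <- assign_folds(y, 10, seed = 9)
  f2 <- assign_folds(y, 10, seed = 9)
  expect_identical(f1, f2)
  expect_false(identical(f1, assign_folds(y, 10, seed = 10)))
  per_fold_cases <- table(f1[y == 1])
  expect_lte(diff(range(per_fold_cases)), 1)
  expect_error(assign_folds(c(1L, rep(0L, 30)), 10), "too few")
})

test_that("cross-validation is deterministic and perfect signal scores 1", {
  set.seed(2)
  ds <- random_dataset(60, 2)
  r1 <- cross_validate(ds, snp_ids(ds), seed = 5)
  r2 <- cross_validate(ds, snp_ids(ds), seed = 5)
  expect_identical(r1, r2)
  # fully penetrant locus: genotype 2 <=> case
  g <- c(rep(2L, 30), rep(0L, 15), rep(1L, 15))
  ds2 <- mdr_dataset(matrix(g, ncol = 1, dimnames = list(NULL, "s")),
                     c(rep(1L, 30), rep(0L, 30)))
  r <- cross_validate(ds2, "s", seed = 1)
  expect_equal(r$fold_train_ba, rep(1, 10))
  expect_equal(r$fold_test_ba, rep(1, 10))
})

test_that("training accuracy dominates any constant classifier", {
  set.seed(44)
  for (r in 1:10) {
    ds <- random_dataset(50, 2)
    ct <- build_cell_table(ds, snp_ids(ds))
    lb <- label_cells(ct)
    key <- apply(ds$genotypes, 1, paste, collapse = "/")
    pred <- lb$label[match(key, ct$genotype)]
    truth <- ifelse(ds$phenotype == 1, "case", "control")
    ba <- balanced_accuracy(truth, pred)
    expect_gte(ba, 0.5)  # constant high or low both score exactly 0.5
  }
})

test_that("label-shuffled data cross-validates to chance", {
  set.seed(55)
  ba <- replicate(60, {
    g <- matrix(sample(0:2, 400, replace = TRUE), ncol = 1,
                dimnames = list(NULL, "s"))
    y <- sample(c(rep(1L, 200), rep(0L, 200)))
    mean(cross_validate(mdr_dataset(g, y), "s", seed = 1)$fold_test_ba,
         na.rm = TRUE)
  })
  expect_lt(abs(mean(ba) - 0.5), 0.05)
})

test_that("the search reproduces a naive re-evaluation on small instances", {
  set.seed(70)
  for (r in 1:10) {
    n <- sample(30:40, 1)
    ds <- random_dataset(n, 4)
    fold_id <- assign_folds(ds$phenotype, 5, seed = r)
    combos <- utils::combn(sort(snp_ids(ds)), 2, simplify = FALSE)
    naive_train <- sapply(combos, function(cb) {
      mean(naive_combo_cv(ds$genotypes, ds$phenotype, cb,
                          fold_id)$train_ba, na.rm = TRUE)
    })
    res <- mdr_search(ds, 2, 2, fold_id = fold_id)
    best <- which.max(naive_train)
    expect_identical(res$models$k2$combo, combos[[best]])
    expect_equal(res$models$k2$train_ba, naive_train[best],
                 tolerance = 1e-12)
    ref <- naive_combo_cv(ds$genotypes, ds$phenotype, combos[[best]],
                          fold_id)
    expect_equal(res$models$k2$fold_train_ba, ref$train_ba,
                 tolerance = 1e-12)
    expect_equal(res$models$k2$fold_test_ba, ref$test_ba,
                 tolerance = 1e-12)
  }
})

test_that("unknown-cell handling supports low, high and exclude rules", {
  set.seed(91)
  ds <- random_dataset(36, 3)
  fold_id <- assign_folds(ds$phenotype, 4, seed = 2)
  for (rule in c("low", "high", "exclude")) {
    mine <- cross_validate(ds, snp_ids(ds)[1:2], fold_id = fold_id,
                           unknown = rule)
    ref <- naive_combo_cv(ds$genotypes, ds$phenotype, snp_ids(ds)[1:2],
                          fold_id, unknown = rule)
    expect_equal(mine$fold_test_ba, ref$test_ba, tolerance = 1e-12,
                 info = rule)
  }
})

test_that("final-model selection applies the parsimony tie-breaks", {
  m <- function(k, test_ba, cvc) {
    structure(list(combo = paste0("s", 1:k), k = k, test_ba = test_ba,
                   cvc = cvc, folds = 10), class = "mdr_model")
  }
  expect_equal(select_final_model(list(m(2, 0.6, 5)))$k, 2)
  picked <- select_final_model(list(m(1, 0.60, 7), m(2, 0.60, 10)))
  expect_equal(picked$cvc, 10)
  picked2 <- select_final_model(list(m(1, 0.55, 8), m(2, 0.55, 8),
                                     m(3, 0.55, 8)))
  expect_equal(picked2$k, 1)
  picked3 <- select_final_model(list(m(1, 0.52, 10), m(3, 0.64, 4)))
  expect_equal(picked3$k, 3)
  expect_error(select_final_model(list()), "empty")
})

test_that("permutation p-values stay in range and detect planted signal", {
  set.seed(33)
  ds <- simulate_case_control(
    100, 100, snp_meta = osteo_snp_panel()[1:4, ],
    penetrance = xor_penetrance(c("rs699947", "rs3025039"),
                                baseline = 0.05, effect = 0.5),
    covariate_model = NULL, seed = 8)
  pt <- permutation_test(ds, 2, n_perm = 19, seed = 3)
  expect_gte(pt$perm_p, 1 / 20)
  expect_lte(pt$perm_p, 1)
  expect_equal(pt$perm_p, 1 / 20)  # strong planted signal beats every perm
  expect_error(permutation_test(ds, 2, n_perm = 5), "n_perm")
})

test_that("the full pipeline is a pure function of data, config and seed", {
  ds <- simulate_case_control(50, 60, snp_meta = osteo_snp_panel()[1:5, ],
                              covariate_model = NULL, seed = 21)
  r1 <- mdr_search(ds, 1, 2, seed = 4)
  r2 <- mdr_search(ds, 1, 2, seed = 4)
  expect_identical(r1$models, r2$models)
  p1 <- permutation_test(ds, 1, n_perm = 19, seed = 6)
  p2 <- permutation_test(ds, 1, n_perm = 19, seed = 6)
  expect_identical(p1, p2)
})
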