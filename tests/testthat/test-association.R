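test_that("2x2 Fisher test agrees with the independent reference and is symmetric", {
  r <- fisher_exact_2x2(matrix(1, 2, 2))
  expect_equal(r$or, 1)
  expect_equal(r$p, 1)
  set.seed(21)
  for (i in 1:30) {
    tab <- matrix(rpois(4, sample(3:20, 1)), 2, 2)
    mine <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine$p, ref, tolerance = 1e-6)
    # invariance under row and column permutation
    expect_equal(mine$p, fisher_exact_2x2(tab[2:1, ])$p, tolerance = 1e-12)
    expect_equal(mine$p, fisher_exact_2x2(tab[, 2:1])$p, tolerance = 1e-12)
  }
  zero <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(zero$p, 1)
  expect_true(is.na(zero$or))
})

test_that("r x c exact test enumerates the Freeman-Halton p", {
  # observed table at its margins' expectation is modal -> p = 1
  expect_equal(fisher_exact_rxc(matrix(1, 2, 3))$p, 1)
  # zero column reduces to the 2x2 test
  t23 <- matrix(c(4, 0, 2, 3, 0, 5), 2, 3, byrow = TRUE)
  expect_equal(fisher_exact_rxc(t23)$p,
               fisher_exact_2x2(t23[, c(1, 3)])$p, tolerance = 1e-12)
  set.seed(8)
  for (i in 1:20) {
    tab <- matrix(rpois(6, 5) + 1, 2, 3)
    expect_equal(fisher_exact_rxc(tab)$p, stats::fisher.test(tab)$p.value,
                 tolerance = 1e-9)
  }
  tab33 <- matrix(rpois(9, 4) + 1, 3, 3)
  expect_equal(fisher_exact_rxc(tab33)$p, stats::fisher.test(tab33)$p.value,
               tolerance = 1e-9)
})

test_that("enumeration guard trips to an error or a Monte-Carlo estimate", {
  tab <- matrix(c(9, 7, 8, 6, 7, 9), 2, 3)
  expect_error(fisher_exact_rxc(tab, max_tables = 10),
               "monte_carlo")
  mc <- fisher_exact_rxc(tab, max_tables = 10, monte_carlo = TRUE,
                         B = 20000, seed = 4)
  exact <- fisher_exact_rxc(tab)$p
  expect_equal(mc$method, "monte-carlo")
  expect_lt(abs(mc$p - exact), 0.02)
})

test_that("codominant logistic fit reduces to the 2x2 closed form", {
  # SNP with only genotypes 0 and 2: hom term is a single binary predictor
  a <- 20; b <- 30; c_ <- 35; d <- 15  # cases-exposed etc.
  g <- c(rep(2L, a), rep(0L, b), rep(2L, c_), rep(0L, d))
  y <- c(rep(1L, a + b), rep(0L, c_ + d))
  ds <- mdr_dataset(matrix(g, ncol = 1, dimnames = list(NULL, "s")), y)
  fit <- logistic_codominant(ds, "s")
  hom <- fit$results[fit$results$term == "hom", ]
  expect_equal(hom$or, (a * d) / (b * c_), tolerance = 1e-6)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  expect_equal(log(hom$ci_high / hom$or) / 1.959963984540054, se,
               tolerance = 1e-5)
  # het never observed -> non-estimable, not a crash
  het <- fit$results[fit$results$term == "het", ]
  expect_false(het$estimable)
})

test_that("a genotype class with zero cases is reported non-estimable", {
  # mirrors a heterozygote row observed only among controls
  g <- c(rep(0L, 60), rep(2L, 14), rep(0L, 50), rep(1L, 25), rep(2L, 11))
  y <- c(rep(1L, 74), rep(0L, 86))
  ds <- mdr_dataset(matrix(g, ncol = 1, dimnames = list(NULL, "rs11292")), y)
  fit <- logistic_codominant(ds, "rs11292")
  het <- fit$results[fit$results$term == "het", ]
  expect_false(het$estimable)
  expect_true(is.na(het$or))
  hom <- fit$results[fit$results$term == "hom", ]
  expect_true(hom$estimable)
})

test_that("logistic estimates recover a known log-odds ratio", {
  set.seed(77)
  n <- 5000
  g <- sample(0:2, n, replace = TRUE, prob = c(0.49, 0.42, 0.09))
  eta <- -0.4 + 0.7 * (g == 1) + 1.4 * (g == 2)
  y <- as.integer(runif(n) < plogis(eta))
  ds <- mdr_dataset(matrix(as.integer(g), ncol = 1,
                           dimnames = list(NULL, "s")), y)
  fit <- logistic_codominant(ds, "s")
  expect_lt(abs(log(fit$results$or[fit$results$term == "het"]) - 0.7), 0.1)
  # intercept of the null-SNP-free pathway equals the raw log odds
  g0 <- mdr_dataset(matrix(0L, 200, 1, dimnames = list(NULL, "s")),
                    c(rep(1L, 80), rep(0L, 120)))
  f0 <- logistic_codominant(g0, "s")
  expect_equal(unname(f0$fit$coefficients["(Intercept)"]), log(80 / 120),
               tolerance = 1e-6)
})

test_that("covariate adjustment consumes dataset covariates", {
  set.seed(42)
  ds <- simulate_case_control(120, 150, seed = 10)
  fit <- logistic_codominant(ds, "rs679620",
                             covariates = c("age", "sex", "bmi",
                                            "anc1", "anc2"))
  expect_true(all(c("age", "sexmale", "bmi", "anc1", "anc2") %in%
                    names(fit$fit$coefficients)))
  expect_error(logistic_codominant(ds, "rs679620", covariates = "height"),
               "not found")
})

test_that("the interaction check flags XOR epistasis that main effects miss", {
  set.seed(13)
  n <- 1200
  # carrier probability 1/2 per locus (MAF 1 - sqrt(0.5)) so dominance
  # codes are balanced: XOR of the codes has null main effects
  q <- 1 - sqrt(0.5)
  g1 <- sample(0:2, n, replace = TRUE, prob = c((1-q)^2, 2*q*(1-q), q^2))
  g2 <- sample(0:2, n, replace = TRUE, prob = c((1-q)^2, 2*q*(1-q), q^2))
  risk <- xor(g1 >= 1, g2 >= 1)
  y <- as.integer(runif(n) < ifelse(risk, 0.7, 0.3))
  ds <- mdr_dataset(cbind(a = as.integer(g1), b = as.integer(g2)), y)
  res <- logistic_interaction_check(ds, c("a", "b"), coding = "dominant")
  expect_lt(res$p, 1e-10)
  # a main-effects-only model sees nothing: the signal is purely epistatic
  d1 <- as.numeric(g1 >= 1); d2 <- as.numeric(g2 >= 1)
  mains_only <- summary(stats::glm(y ~ d1 + d2,
                                   family = stats::binomial()))$coefficients
  expect_true(all(mains_only[c("d1", "d2"), "Pr(>|z|)"] > 0.001))
  # the default additive coding detects the same epistasis
  expect_lt(logistic_interaction_check(ds, c("a", "b"))$p, 0.05)
  # duplicate SNP entered twice -> aliased, diagnosed not crashed
  ds2 <- mdr_dataset(cbind(a = as.integer(g1), b = as.integer(g1)), y)
  res2 <- logistic_interaction_check(ds2, c("a", "b"))
  expect_false(is.null(res2$diagnostic))
})

test_that("Bonferroni threshold scales as alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 9, digits = 3), 0.005)
  expect_equal(bonferroni_threshold(0.05, 9), 0.05 / 9)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  for (m in c(2, 7, 20)) {
    expect_equal(bonferroni_threshold(0.04, m) * m, 0.04)
  }
  expect_error(bonferroni_threshold(0.05, 0), "m_tests")
  expect_error(bonferroni_threshold(1.5, 3), "alpha")
})

test_that("summary-statistics t-test matches a raw-data pooled t", {
  expect_equal(two_sample_summary_test(10, 2, 30, 10, 2, 30)$p, 1)
  set.seed(6)
  x <- rnorm(40); y <- rnorm(55)
  # rescale to exact moments so the summary path sees the same inputs
  x <- (x - mean(x)) / sd(x) * 1.3 + 5.2
  y <- (y - mean(y)) / sd(y) * 1.1 + 4.6
  ref <- t.test(x, y, var.equal = TRUE)
  mine <- two_sample_summary_test(5.2, 1.3, 40, 4.6, 1.1, 55)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
  expect_error(two_sample_summary_test(1, 0, 10, 2, 1, 10), "positive")
  expect_error(two_sample_summary_test(1, 1, 1, 2, 1, 10), "n >= 2")
})

test_that("unadjusted allele odds ratios derive from the 2x2 allele table", {
  cnt <- read_count_fixture()
  ds <- dataset_from_count_table(cnt, 92, 147)
  r <- allele_association(ds, "rs1800255")
  # minor 56/168 in cases vs 49/148 in controls
  expect_equal(r$or, (56 * 99) / (112 * 49), tolerance = 1e-12)
  expect_true(r$ci_low < r$or && r$or < r$ci_high)
})
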