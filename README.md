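# mdrkit

Case-control SNP analysis with gene–gene interaction (epistasis) detection by
**multifactor dimensionality reduction (MDR)**, for candidate-gene association
studies — the setting where a few dozen to a few hundred cases and controls
are genotyped at a small panel of biallelic variants and the question is
whether *combinations* of genotypes, rather than any single locus, carry
disease risk.

The package covers the complete analysis such a study reports:

* **Descriptive genetics** — genotype and allele frequency tables, with the
  Hardy–Weinberg equilibrium (HWE) chi-square test in controls.
* **Single-SNP inference** — Fisher exact tests (2×2 and exact r×c by
  Freeman–Halton enumeration), covariate-adjusted codominant logistic
  regression with Wald odds ratios and confidence intervals, Bonferroni
  correction, and pooled t-tests from summary statistics.
* **The MDR engine** — exhaustive k-locus combination search with stratified
  10-fold cross-validation, balanced accuracy, cross-validation consistency,
  parsimony-based model selection, and permutation significance.
* **Entropy interaction maps** — per-SNP information gain and signed pairwise
  synergy/redundancy as percentages of the phenotype entropy.
* **A penetrance-model simulator** — HWE genotypes at configurable minor
  allele frequencies with plantable marginal or purely epistatic
  (XOR-pattern) penetrance, so every stage is testable without external data.

## The method

MDR reduces a k-locus genotype table to one dimension. For a SNP combination
(X₁, …, X_k), each multilocus cell *c* of the 3^k table is labelled

> high-risk iff (cases in *c* / total cases) ⁄ (controls in *c* / total
> controls) ≥ T, with T = 1 by default,

which turns the combination into a binary classifier. Its quality is the
cross-validated **balanced accuracy** BA = (sensitivity + specificity)/2,
appropriate when cases and controls are unequal. Within each of 10 stratified
folds the labelling is learned on 90% of subjects and evaluated on the held
out 10%; the **cross-validation consistency** (CVC) counts the folds in which
the same combination is the fold's best. Across model sizes the final model
maximises testing BA, breaking ties by CVC and then by parsimony (smaller k).
Significance comes from permuting phenotype labels and re-running the search:
p = (1 + #{permuted BA ≥ observed}) / (n_perm + 1).

The entropy map reports, per SNP, I(X;C)/H(C) and, per pair, the interaction
information IG(A;B;C) = I(A,B;C) − I(A;C) − I(B;C) as a signed percentage of
the phenotype entropy H(C): positive = synergy, negative =
redundancy/additivity.

## Worked example

Simulate a cohort of 92 cases and 147 controls at the bundled nine-SNP
articular-cartilage panel, with a purely epistatic XOR interaction planted at
*MMP3* rs679620 × *COL3A1* rs1800255, then run the full MDR analysis:

```r
library(mdrkit)

ds <- simulate_case_control(
  n_cases = 92, n_controls = 147,
  penetrance = xor_penetrance(c("rs679620", "rs1800255"),
                              baseline = 0.10, effect = 0.35),
  seed = 42)

res <- mdr_search(ds, k_min = 1, k_max = 3, folds = 10, seed = 42)
res
#> <mdr_search_result>
#> <mdr_model> k=1 [rs679620]: train BA 0.6159, test BA 0.6177, CVC 10/10
#> <mdr_model> k=2 [rs1800255, rs679620]: train BA 0.7789, test BA 0.7587, CVC 10/10
#> <mdr_model> k=3 [rs1800255, rs2297518, rs679620]: train BA 0.7944, test BA 0.7404, CVC 3/10

final <- select_final_model(res)          # picks the 2-locus planted pair
permutation_test(ds, k = final$k, n_perm = 99, seed = 42)$perm_p
#> [1] 0.01

interaction_graph(ds, snps = c("rs679620", "rs1800255", "rs699947"))$edges
#>       snp_a     snp_b    gain_bits pct_entropy
#> 1  rs679620 rs1800255  ...          21.93
#> 2  rs679620  rs699947  ...           0.63
#> 3 rs1800255  rs699947  ...           0.67
```

The search recovers the planted pair at every fold (CVC 10/10), its testing
balanced accuracy (0.76) beats all 99 permutations (p = 0.01), and the
interaction map assigns the planted edge ~22% of the phenotype entropy while
null edges stay under 1%. Descriptive statistics work on the same object:

```r
hwe_chisq(genotype_counts(ds, "rs679620", "control"))
#> <hwe_result> rs679620: chi2 = 1.5751 (df = 1), p = 0.2095
```

A command-line front end is installed at `exec/mdrkit`
(`mdrkit simulate|describe|assoc|mdr|interactions`); every subcommand takes
`--seed` and writes a JSON manifest so runs are exactly reproducible.

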