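---
title: "Detecting gene–gene interactions in case-control data with mdrkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting gene–gene interactions in case-control data with mdrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrkit)
```

# The problem

Candidate-gene case-control studies genotype a small panel of biallelic SNPs
in a few hundred subjects and ask whether genotypes are associated with
disease. Single-locus tests miss *epistasis* — joint genotype effects with
weak or absent marginal signal — and parametric interaction models (logistic
regression with product terms) need large samples and can only comfortably
examine pairs. Multifactor dimensionality reduction (MDR) is the standard
model-free alternative at this scale: it is non-parametric, assumes no
inheritance model, and evaluates every k-locus combination directly.

`mdrkit` implements the full analysis pipeline of such a study: descriptive
genetics, single-SNP inference, the MDR search, entropy-based interaction
maps, and a simulator that generates data with exactly the structure the
analysis assumes.

# The MDR procedure

For a combination of k SNPs (genotypes coded 0/1/2 as minor-allele counts),
the 3^k multilocus cells are pooled into one binary attribute:

* a non-empty cell is **high-risk** when the ratio of its within-case
  percentage to its within-control percentage meets or exceeds a threshold
  T (default 1.0). Ties at the threshold are high-risk ("met or exceeded");
  cells with cases but no controls are high-risk; empty cells are *unknown*.
  Using percentages rather than raw counts makes the rule invariant to the
  case:control imbalance; with equal group sizes it reduces to the raw
  case:control ratio.
* classifier quality is the **balanced accuracy**
  BA = (sensitivity + specificity)/2, with high-risk predicting case — the
  appropriate measure when the case:control ratio differs from one (here
  92:147 by default).

Evaluation uses **stratified 10-fold cross-validation**: folds are assigned
by a seeded shuffle within cases and within controls separately, then the
labelling is learned on each training 90% and scored on both partitions.
The per-size best model maximises the mean training BA; the
**cross-validation consistency** (CVC) counts folds whose fold-best
combination (by fold training BA) coincides with the overall best. The
final model across sizes maximises mean testing BA, breaking ties by CVC
and then by the smaller k (statistical parsimony).

Significance is assessed by a **permutation test**: phenotype labels are
permuted (genotypes and covariates stay attached to their subjects), the
size-k search is re-run on each permuted dataset with freshly assigned
stratified folds, and p = (1 + #{permuted best test BA ≥ observed}) /
(n_perm + 1). This is exact under exchangeability and anti-conservative
never: ties count against the observed statistic.

## Numerical and design choices

Several points are under-determined by convention and fixed here
deliberately:

* **Unknown cells at test time** are predicted *low-risk* by default — the
  conservative choice, since an unseen genotype combination carries no
  evidence of risk. `unknown = "high"` and `"exclude"` are available; the
  choice can shift test BA by a few points in sparse tables, so it is a
  documented, user-visible option.
* **Missing genotypes** are excluded per combination (an individual missing
  one SNP still contributes to combinations not involving it). This
  maximises data use and matches genotyping reports whose per-SNP totals
  vary; whole-row deletion can be emulated by pre-filtering the dataset.
* **Tie-breaking**: combinations are enumerated in lexicographic SNP-id
  order and the first maximum wins, both per fold and overall. CVC depends
  on this rule, so it is fixed rather than left to floating-point accident.
* **Folds are assigned once per run** and shared across all sizes and all
  combinations, so CVC values are comparable between models.
* **Reported train/test BA** is the mean over folds. The per-fold vectors
  are kept on every `mdr_model`, so a consumer preferring the best-fold
  convention can compute it.
* The whole pipeline is a pure function of (dataset, configuration, seed);
  the test suite asserts byte-identical repeat runs.

The engine itself is vectorised: per combination, case and control counts
per (cell, fold) are formed in a single tabulation pass and training counts
are obtained by subtracting the held-out fold from the totals, which makes
the permutation test (100 searches of all 36 two-locus combinations at
n = 239) run in under half a second. A deliberately naive per-individual
reference implementation lives in the test helpers and the suite checks
exact agreement of cell tables, risk labels, per-fold accuracies and
rankings on 100 random small instances.

# Entropy interaction maps

The interaction graph reports, for each SNP A, the main-effect information
gain I(A;C) and, for each pair, the interaction information

IG(A;B;C) = I(A,B;C) − I(A;C) − I(B;C),

where (A,B) is the joint (≤ 9-level) attribute, both expressed as
percentages of the phenotype entropy H(C). Positive edges indicate synergy
(non-additive joint information), negative edges redundancy. The identity
I(A,B;C) = I(A;C) + I(B;C) + IG(A;B;C) holds algebraically on any sample
and is asserted in the tests.

Entropies are **plug-in (maximum-likelihood) estimates in bits**, the
convention of MDR-style interaction maps, with no bias correction by
default. The plug-in estimator of IG has a positive bias of roughly
(m_AB − m_A − m_B + 1)/(2N ln 2) bits (m = cell counts), about +1.3% of
H(C) at N ≈ 240 — so near-zero edges at candidate-gene sample sizes should
be read with that in mind. A Miller–Madow correction is available via
`miller_madow = TRUE`; null-centring of edges is verified in validation at
n = 10 000 per group, where the bias is negligible. Missing genotypes are
dropped listwise per node or per pair; H(C) uses the full phenotype.

# Descriptive and parametric stages

* **HWE**: Pearson chi-square of observed genotype counts against
  (p², 2pq, q²) at the sample allele frequency, 1 df, *no* continuity
  correction — the uncorrected statistic is what published control-group
  HWE columns reproduce. Monomorphic SNPs are in trivial equilibrium
  (chi² = 0, p = 1). Applied to controls by default, configurable.
* **Fisher tests**: the 2×2 p-value sums hypergeometric probabilities of
  tables no more probable than the observed one (the probability-mass
  criterion; alternatives such as doubling the one-sided tail differ and
  are not used). The r×c test enumerates all tables with the observed
  margins (Freeman–Halton); enumeration is guarded and falls back, on
  request, to Monte-Carlo sampling of the null table distribution. The
  reported 2×2 odds ratio is the sample cross-product ratio by default
  (conditional-MLE available), since frequency-table ORs in the field are
  cross-product ratios.
* **Codominant logistic regression**: the SNP enters as heterozygote and
  minor-homozygote indicators against the major-homozygote reference,
  adjusted by arbitrary covariates (age, sex, BMI, admixture proportions —
  supplied pre-computed; ancestry inference itself is out of scope, and
  only 2 of 3 admixture proportions should enter a model to avoid
  collinearity). Confidence intervals are Wald (symmetric on the log-odds
  scale, as published candidate-gene tables are). **Complete separation**
  (a genotype class with zero cases or zero controls) is detected from the
  class table and the term is reported non-estimable — deliberately *not*
  rescued by penalisation, mirroring how such rows are published as "–".
* **Allele-level odds ratios** are reported unadjusted (each subject
  contributes two alleles; Woolf confidence intervals): whether published
  allele rows are covariate-adjusted is typically ambiguous, so the
  unambiguous unadjusted quantity is computed.
* **Interaction corroboration**: a logistic model with per-SNP codes plus
  their product term, returning the Wald p of the highest-order product.
  Codes are additive (0/1/2) by default; a dominant (carrier) coding is
  available, which is the natural scale when the suspected interaction is
  of XOR type in carrier status. Aliased or quasi-separated fits return a
  diagnostic instead of a number.
* **Summary-statistics t-test**: pooled-variance Student's t from group
  means/SDs/sizes, for re-testing published demographic tables.
* **Multiple testing**: Bonferroni over the SNP panel (alpha/m), with the
  conventional 3-decimal truncated presentation available; no FDR.

# The synthetic-data generator

The generator emulates the study design the analysis assumes, and its
defaults are the package's reference conditions:

* **92 cases / 147 controls** at the bundled nine-SNP articular-cartilage
  extracellular-matrix panel (`osteo_snp_panel()`), with Mexican-population
  minor allele frequencies (0.13–0.42) and minor/reference alleles per SNP.
* **Genotypes** are drawn per locus under HWE, loci in linkage equilibrium
  (the panel was selected to avoid LD; simulating LD is a non-goal).
* **Disease** is assigned by a `penetrance_model` mapping multilocus
  genotypes to disease probability; subjects are accumulated by rejection
  sampling until the exact group sizes are reached, mirroring case-control
  ascertainment (capped at 10⁷ draws; an unreachable group errors). With
  no penetrance model the phenotype is independent of all genotypes and
  labels are assigned directly — distributionally identical to
  constant-penetrance rejection sampling and much faster.
* **The XOR penetrance** (`xor_penetrance`) adds `effect` to `baseline`
  exactly when one of the two loci is heterozygous — a checkerboard with
  provably equal marginal penetrances when P(het) = 1/2, the canonical
  purely epistatic pattern for validating an interaction search. An
  additive single-locus model covers the marginal-effect case.
* **Covariates** are drawn independently of genotype: age 47.2 ± 12.4
  years in cases vs 40.9 ± 12.0 in controls, BMI 29.0 ± 4.19 vs
  24.8 ± 4.38 kg/m², sex Bernoulli with 87% vs 71.4% female — typical
  knee-osteoarthritis cohort demographics — and three admixture
  proportions from a Dirichlet(11, 8, 1) (mean 0.55/0.40/0.05 with
  realistic spread for an admixed Latin-American sample). Missing
  genotypes are masked completely at random at `missing_rate`.

What the generator does **not** emulate — and hence what passing validation
does not establish about real data: linkage disequilibrium between panel
SNPs, population stratification (admixture is drawn independently of
genotype, so there is no confounding unless the user wires it in),
genotype-dependent missingness or genotyping error, and
covariate–genotype correlation. Results on real cohorts additionally
depend on those features.

# Validation conditions

The simulation suites run at fixed, stated sizes chosen as this package's
reference validation conditions:

* **Planted-epistasis recovery**: XOR penetrance (baseline 0.05, effect
  0.40) planted at two panel loci set to MAF 0.30, 400 cases/400 controls,
  100 replicates; the best two-locus model must be the planted pair and
  its interaction information positive in ≥ 95 replicates.
* **Permutation calibration**: null generator at the 92/147 study size,
  size-2 search, 99 permutations, 200 replicates; the rejection rate at
  alpha = 0.05 must sit within 5% ± 3% (the binomial band at 200
  replicates).
* **Null entropy centring**: independent SNPs at 5 000 per group, where
  plug-in bias is negligible; mean edge percentage within ±1% of zero.
* **Oracle equivalence**: 100 random instances of ≤ 40 individuals × ≤ 4
  SNPs against the naive reference implementation, exact agreement.

All of these are recomputed from scratch by `scripts/acceptance.R`, seeded
from its `--seed` argument.

# Known limitations

* The exact (Wigginton-type) HWE test is not provided; at very low minor
  allele counts the chi-square approximation is anti-conservative.
* The r×c Fisher enumeration is exponential in table size; beyond the
  guard it requires the Monte-Carlo fallback.
* MDR here is the classical balanced-accuracy formulation: covariates do
  not enter the search itself (no score-based generalisation), only the
  parametric corroboration stage.
* Three-way and higher entropy decompositions, LD-aware simulation, and
  VCF/PLINK input are out of scope; the flat-file and CSV dialects cover
  the candidate-gene scale the package targets.
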