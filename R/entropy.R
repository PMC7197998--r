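#' Shannon entropy of a discrete sample
#'
#' Plug-in (maximum-likelihood) estimate in bits: `-sum p_i log2 p_i` over
#' the observed category frequencies, with `0 log 0 = 0`. No small-sample
#' bias correction is applied (the convention of MDR-style interaction
#' maps); see `miller_madow` for the optional correction.
#'
#' @param values discrete sample (any atomic vector; `NA` dropped).
#' @param miller_madow add the Miller-Madow bias correction
#'   `(m - 1) / (2 n ln 2)` where `m` is the number of observed categories.
#' @return entropy in bits.
#' @export
shannon_entropy <- function(values, miller_madow = FALSE) {
  values <- values[!is.na(values)]
  if (!length(values)) stop_mdr("empty sample: entropy undefined")
  p <- tabulate(factor(values))
  p <- p[p > 0] / length(values)
  h <- -sum(p * log2(p))
  if (miller_madow) h <- h + (length(p) - 1) / (2 * length(values) * log(2))
  h
}

#' Mutual information between an attribute and the phenotype
#'
#' `I(X; C) = H(X) + H(C) - H(X, C)` in bits, from the plug-in entropies of
#' the paired sample (pairs with a missing value are dropped).
#'
#' @param x discrete attribute sample.
#' @param c phenotype (class) sample of the same length.
#' @param miller_madow apply the Miller-Madow correction to each entropy
#'   term.
#' @return mutual information in bits (non-negative up to the correction).
#' @export
mutual_information <- function(x, c, miller_madow = FALSE) {
  if (length(x) != length(c)) stop_mdr("samples differ in length")
  keep <- !is.na(x) & !is.na(c)
  x <- x[keep]; c <- c[keep]
  if (!length(x)) stop_mdr("no complete pairs")
  shannon_entropy(x, miller_madow) + shannon_entropy(c, miller_madow) -
    shannon_entropy(paste(x, c, sep = "\r"), miller_madow)
}

#' Pairwise interaction information gain
#'
#' `IG(A; B; C) = I(A,B; C) - I(A; C) - I(B; C)`, where `(A, B)` is the
#' joint (up to 9-level) two-locus attribute. Positive values indicate
#' synergy (non-additive joint information about the phenotype), negative
#' values redundancy; all terms are computed on the pair's complete cases.
#'
#' @param a,b discrete SNP genotype samples.
#' @param c phenotype sample of the same length.
#' @inheritParams mutual_information
#' @return signed information gain in bits.
#' @export
pairwise_gain <- function(a, b, c, miller_madow = FALSE) {
  if (length(a) != length(c) || length(b) != length(c)) {
    stop_mdr("samples differ in length")
  }
  keep <- !is.na(a) & !is.na(b) & !is.na(c)
  a <- a[keep]; b <- b[keep]; c <- c[keep]
  if (!length(a)) stop_mdr("no complete triples")
  ab <- paste(a, b, sep = "\r")
  mutual_information(ab, c, miller_madow) -
    mutual_information(a, c, miller_madow) -
    mutual_information(b, c, miller_madow)
}

#' Entropy-based interaction graph
#'
#' The interaction map customary in MDR reports: each node carries the main
#' effect of one SNP as the percentage of the phenotype entropy `H(C)`
#' explained (`100 I(A;C) / H(C)`), each edge the pairwise interaction gain
#' as a signed percentage of `H(C)` — positive for synergy, negative for
#' redundancy/additivity. Missing genotypes are dropped listwise per node or
#' per pair; `H(C)` is computed on the full phenotype.
#'
#' @inheritParams n_individuals
#' @param snps SNP ids to include (default: all; at least 2).
#' @inheritParams mutual_information
#' @return an `interaction_graph`: list with `nodes` (`data.frame`: `snp_id`,
#'   `gain_bits`, `pct_entropy`), `edges` (`data.frame`: `snp_a`, `snp_b`,
#'   `gain_bits`, `pct_entropy`), `base_entropy` (bits).
#' @export
interaction_graph <- function(dataset, snps = NULL, miller_madow = FALSE) {
  snps <- snps %||% snp_ids(dataset)
  if (length(snps) < 2L) stop_mdr("need at least 2 SNPs")
  bad <- setdiff(snps, snp_ids(dataset))
  if (length(bad)) stop_mdr("unknown SNP(s): ", paste(bad, collapse = ", "))
  pheno <- dataset$phenotype
  h_c <- shannon_entropy(pheno)
  if (h_c == 0) stop_mdr("phenotype entropy is zero: single-class data")
  nodes <- data.frame(
    snp_id = snps,
    gain_bits = vapply(snps, function(s) {
      mutual_information(dataset$genotypes[, s], pheno, miller_madow)
    }, numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  nodes$pct_entropy <- 100 * nodes$gain_bits / h_c
  pairs <- utils::combn(snps, 2L)
  edges <- data.frame(
    snp_a = pairs[1, ], snp_b = pairs[2, ],
    gain_bits = apply(pairs, 2L, function(pq) {
      pairwise_gain(dataset$genotypes[, pq[1]], dataset$genotypes[, pq[2]],
                    pheno, miller_madow)
    }),
    stringsAsFactors = FALSE, row.names = NULL
  )
  edges$pct_entropy <- 100 * edges$gain_bits / h_c
  structure(list(nodes = nodes, edges = edges, base_entropy = h_c),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d SNPs, H(C) = %.4f bits\n",
              nrow(x$nodes), x$base_entropy))
  cat("nodes (% of phenotype entropy):\n")
  print(x$nodes)
  cat("edges (signed %, + synergy / - redundancy):\n")
  print(x$edges)
  invisible(x)
}

#' Write an interaction graph as Graphviz DOT
#'
#' Nodes are labelled with their main-effect percentage; edges with the
#' signed pairwise percentage, coloured red for synergy and green for
#' redundancy (sign only — no magnitude-based colour scale).
#'
#' @param graph an [interaction_graph()].
#' @param path output `.dot` file.
#' @return invisibly, `path`.
#' @export
write_interaction_dot <- function(graph, path) {
  lines <- c("graph interactions {")
  lines <- c(lines, sprintf('  "%s" [label="%s\\n%.2f%%"];',
                            graph$nodes$snp_id, graph$nodes$snp_id,
                            graph$nodes$pct_entropy))
  lines <- c(lines, sprintf('  "%s" -- "%s" [label="%.2f%%", color=%s];',
                            graph$edges$snp_a, graph$edges$snp_b,
                            graph$edges$pct_entropy,
                            ifelse(graph$edges$gain_bits >= 0,
                                   "red", "green")))
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}
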