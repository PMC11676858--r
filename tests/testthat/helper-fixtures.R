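# Small graph fixtures and file writers used across the suite.

triangle_network <- function() {
  buildNetwork(data.frame(gene_a = c("A", "B", "A"),
                          gene_b = c("B", "C", "C")))
}

two_node_network <- function() {
  buildNetwork(data.frame(gene_a = "A", gene_b = "B"))
}

complete_network <- function(n) {
  genes <- sprintf("K%02d", seq_len(n))
  pairs <- t(combn(genes, 2))
  buildNetwork(data.frame(gene_a = pairs[, 1], gene_b = pairs[, 2]))
}

# Erdos-Renyi graph as a GeneNetwork (isolated nodes retained).
random_network <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  genes <- sprintf("R%04d", seq_len(n))
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) {
    return(buildNetwork(data.frame(gene_a = genes[1], gene_b = genes[2]),
                        extraNodes = genes))
  }
  buildNetwork(cbind(genes[el[, 1]], genes[el[, 2]]), extraNodes = genes)
}

write_string_fixture <- function(path, rows) {
  df <- data.frame(protein1 = rows$a, protein2 = rows$b,
                   experimental = rows$exp, combined_score = rows$comb)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_rnainter_fixture <- function(path, rows) {
  df <- data.frame(gene1 = rows$a, gene2 = rows$b, score = rows$score)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Truncated Taylor series for exp(-alpha * L); independent of the
# eigendecomposition path under test.
taylor_heat_kernel <- function(L, alpha, terms = 60) {
  n <- nrow(L)
  W <- diag(n)
  term <- diag(n)
  for (m in seq_len(terms)) {
    term <- term %*% (-alpha * L) / m
    W <- W + term
  }
  W
}

# Standard planted-module fixture: network + signature + truth + pathways.
standard_fixture <- function(seed) {
  sim <- makeSbmNetwork(500, 5, pIn = 0.2, pOut = 0.01, seed = seed)
  sig <- makeSignature(sim$truth, sim$network, observeFrac = 0.6,
                       nBackground = 20, seed = seed + 1000L)
  coll <- makePathwayCollection(sig$truth, nRandom = 20,
                                sizeRange = c(10, 50), seed = seed + 2000L)
  list(network = sim$network, truth = sig$truth,
       signature = sig$signature, collection = coll)
}

# Exhaustive upper-tail hypergeometric sum P(X >= k); enumeration oracle.
enum_tail <- function(k, K, N, n) {
  i <- seq(k, min(K, n))
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}
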