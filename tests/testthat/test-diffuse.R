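test_that("Laplacian is D - A with the expected toy values", {
  two <- two_node_network()
  expect_equal(unname(laplacianMatrix(two)),
               matrix(c(1, -1, -1, 1), 2))

  tri <- triangle_network()
  L <- laplacianMatrix(tri)
  expect_equal(unname(diag(L)), c(2, 2, 2))
  expect_equal(unname(L[upper.tri(L)]), rep(-1, 3))
  expect_equal(unname(rowSums(L)), rep(0, 3))

  iso <- buildNetwork(data.frame(gene_a = "A", gene_b = "B"),
                      extraNodes = "C")
  Li <- laplacianMatrix(iso)
  expect_equal(unname(Li["C", ]), rep(0, 3))
  expect_equal(unname(Li[, "C"]), rep(0, 3))
})

test_that("alpha = 0 yields the identity kernel exactly", {
  net <- triangle_network()
  expect_identical(unname(kernelMatrix(heatKernel(net, alpha = 0))),
                   diag(3))
})

test_that("two-node kernel matches its closed form", {
  k <- heatKernel(two_node_network(), alpha = 0.1)
  W <- kernelMatrix(k)
  off <- (1 - exp(-0.2)) / 2
  dia <- (1 + exp(-0.2)) / 2
  expect_equal(unname(W), matrix(c(dia, off, off, dia), 2),
               tolerance = 1e-12)
  # spot values from the eigenvalue pair {0, 2}
  expect_equal(W[1, 2], 0.0906346, tolerance = 1e-6)
  expect_equal(W[1, 1], 0.9093654, tolerance = 1e-6)
  # independent truncated-Taylor oracle
  expect_equal(W, taylor_heat_kernel(laplacianMatrix(two_node_network()),
                                     0.1),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("complete-graph kernel matches its closed form", {
  for (n in c(3, 5, 10)) {
    alpha <- 0.1
    W <- kernelMatrix(heatKernel(complete_network(n), alpha = alpha))
    J <- matrix(1 / n, n, n)
    expected <- J + exp(-alpha * n) * (diag(n) - J)
    expect_equal(unname(W), expected, tolerance = 1e-10)
  }
})

test_that("asymmetric Laplacians are rejected", {
  M <- matrix(c(1, -1, 0, 1), 2)
  expect_error(heatKernel(M, 0.1), "undirected")
})

test_that("kernel is doubly stochastic on random graphs", {
  for (i in 1:12) {
    n <- 10 + 17 * i
    net <- random_network(n, p = 3 / n, seed = i)
    W <- kernelMatrix(heatKernel(net, 0.1))
    expect_lt(max(abs(W - t(W))), 1e-10)
    expect_lt(max(abs(rowSums(W) - 1)), 1e-10)
    expect_lt(max(abs(colSums(W) - 1)), 1e-10)
    expect_gte(min(W), -1e-10)
    expect_lte(max(W), 1 + 1e-10)
  }
})

test_that("eigendecomposition kernel agrees with the matrix-exponential oracle", {
  skip_if_not_installed("Matrix")
  for (i in 1:5) {
    net <- random_network(40 + 10 * i, p = 0.08, seed = 100 + i)
    L <- laplacianMatrix(net)
    W <- kernelMatrix(heatKernel(net, 0.1))
    oracle <- as.matrix(Matrix::expm(Matrix::Matrix(-0.1 * L)))
    expect_lt(max(abs(W - oracle)), 1e-8)
  }
})

test_that("kernel approaches the identity monotonically as alpha -> 0", {
  net <- random_network(60, 0.1, seed = 9)
  alphas <- c(0.4, 0.2, 0.1, 0.05, 0.025, 0.0125)
  devs <- vapply(alphas, function(a) {
    max(abs(kernelMatrix(heatKernel(net, a)) - diag(length(net))))
  }, numeric(1))
  expect_true(all(diff(devs) < 0))
  expect_lt(devs[length(devs)], devs[1])
})

test_that("large alpha equilibrates scores to the component mean", {
  net <- random_network(15, 0.4, seed = 21)
  sig <- data.frame(gene = networkNodes(net)[1:3],
                    log2fc = c(1, 2, 3), p = 1e-4, p_adj = 1e-3)
  rv <- relevanceVector(sig, net)
  res <- diffuseScores(heatKernel(net, alpha = 50), rv)
  p <- setNames(scoreTable(res)$score, scoreTable(res)$gene)
  s <- relevanceScores(rv)
  g <- igraph::graph_from_data_frame(
    as.data.frame(networkEdges(net)), directed = FALSE,
    vertices = data.frame(name = networkNodes(net)))
  membership <- igraph::components(g)$membership[networkNodes(net)]
  for (cc in unique(membership)) {
    idx <- networkNodes(net)[membership == cc]
    expect_lt(max(abs(p[idx] - mean(s[idx]))), 1e-6)
  }
})

test_that("diffusion never leaks across components", {
  # two disjoint communities plus an isolated node
  net <- buildNetwork(data.frame(
    gene_a = c("A1", "A1", "A2", "B1", "B1", "B2"),
    gene_b = c("A2", "A3", "A3", "B2", "B3", "B3")),
    extraNodes = "LONER")
  sig <- data.frame(gene = c("A1", "A2"), log2fc = c(1, 2),
                    p = 1e-4, p_adj = 1e-3)
  res <- diffuseScores(heatKernel(net, 0.1), relevanceVector(sig, net))
  p <- setNames(scoreTable(res)$score, scoreTable(res)$gene)
  expect_lte(max(abs(p[c("B1", "B2", "B3", "LONER")])), 1e-12)
  expect_equal(sum(p[c("A1", "A2", "A3")]), 3, tolerance = 1e-8)
})

test_that("diffusion conserves mass and honors the tie rule", {
  fx <- standard_fixture(1)
  rv <- relevanceVector(filterSignature(fx$signature), fx$network)
  res <- diffuseScores(heatKernel(fx$network, 0.1), rv)
  tb <- scoreTable(res)
  expect_equal(sum(tb$score), sum(relevanceScores(rv)), tolerance = 1e-8)
  expect_setequal(tb$rank, seq_len(nrow(tb)))
  expect_true(all(tb$score >= 0))

  # zero seed diffuses to zero
  net <- triangle_network()
  rv0 <- new("RelevanceVector",
             score = setNames(rep(0, 3), networkNodes(net)),
             coverage = list(n_mapped = 0L, n_unmapped = 0L,
                             unmapped = character(0)))
  tb0 <- scoreTable(suppressWarnings(
    diffuseScores(heatKernel(net, 0.1), rv0)))
  expect_equal(tb0$score, rep(0, 3))

  # equal scores: lexicographically smaller symbol ranks first
  expect_equal(tb0$gene[order(tb0$rank)], c("A", "B", "C"))
})

test_that("two-node diffusion matches the closed-form kernel", {
  net <- two_node_network()
  sig <- data.frame(gene = "A", log2fc = 1, p = 1e-4, p_adj = 1e-3)
  res <- diffuseScores(heatKernel(net, 0.1), relevanceVector(sig, net))
  tb <- scoreTable(res)
  expect_equal(tb$score[tb$gene == "A"], 0.9093654, tolerance = 1e-6)
  expect_equal(tb$score[tb$gene == "B"], 0.0906346, tolerance = 1e-6)
})

test_that("node-order mismatches are a hard error, never reindexed", {
  netAB <- two_node_network()
  netAC <- buildNetwork(data.frame(gene_a = "A", gene_b = "C"))
  sig <- data.frame(gene = "A", log2fc = 1, p = 1e-4, p_adj = 1e-3)
  expect_error(diffuseScores(heatKernel(netAB, 0.1),
                             relevanceVector(sig, netAC)),
               "node order")
})

test_that("score scaling standardizes without changing ranks", {
  fx <- standard_fixture(2)
  rv <- relevanceVector(filterSignature(fx$signature), fx$network)
  res <- diffuseScores(heatKernel(fx$network, 0.1), rv)
  tb <- scoreTable(res)
  expect_lt(abs(mean(tb$scaled)), 1e-10)
  expect_lt(abs(sd(tb$scaled) - 1), 1e-10)

  mm <- scaleScores(res, method = "minmax")
  tmm <- scoreTable(mm)
  expect_equal(range(tmm$scaled), c(0, 1))
  expect_identical(tmm$rank, tb$rank)

  net <- triangle_network()
  rv0 <- new("RelevanceVector",
             score = setNames(rep(0, 3), networkNodes(net)),
             coverage = list(n_mapped = 0L, n_unmapped = 0L,
                             unmapped = character(0)))
  z0 <- suppressWarnings(diffuseScores(heatKernel(net, 0), rv0))
  expect_warning(z <- scaleScores(z0), "zero variance")
  expect_equal(scoreTable(z)$scaled, rep(0, 3))
})

test_that("topGenes keeps signature genes and bounds n", {
  fx <- standard_fixture(4)
  rv <- relevanceVector(filterSignature(fx$signature), fx$network)
  res <- diffuseScores(heatKernel(fx$network, 0.1), rv)
  all_genes <- topGenes(res, n = length(networkNodes(fx$network)))
  expect_equal(nrow(all_genes), 500L)
  expect_identical(all_genes$rank, seq_len(500L))

  top <- topGenes(res, 200)
  expect_true(any(top$in_signature))   # input genes stay eligible
  expect_error(topGenes(res, 501), "exceeds")
})

test_that("rank AUROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  score <- withr::with_seed(8, c(rnorm(40, 1), rnorm(60)))
  truth <- rep(c(TRUE, FALSE), c(40, 60))
  ours <- rankAuroc(score, truth)
  theirs <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                           predictor = score,
                                           quiet = TRUE,
                                           direction = "<")))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("diffusion ranks recover hidden module genes above chance", {
  fx <- standard_fixture(7)
  rv <- relevanceVector(filterSignature(fx$signature), fx$network)
  res <- diffuseScores(heatKernel(fx$network, 0.1), rv)
  tb <- scoreTable(res)
  sc <- setNames(tb$score, tb$gene)
  ma <- moduleAssignment(fx$truth)
  hid <- hiddenGenes(fx$truth)
  neg <- setdiff(names(ma)[ma != phenotypeModule(fx$truth)],
                 fx$signature$gene)
  auc <- rankAuroc(sc[c(hid, neg)],
                   rep(c(TRUE, FALSE), c(length(hid), length(neg))))
  expect_gt(auc, 0.9)

  top <- topGenes(res, 200)
  frac_hidden_top <- mean(hid %in% top$gene)
  expect_gt(frac_hidden_top, 200 / 500)  # enriched relative to chance
})
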