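test_that("degenerate SBM probabilities force the graph", {
  sim <- makeSbmNetwork(4, 2, pIn = 1.0, pOut = 0.0, seed = 42)
  expect_equal(nrow(networkEdges(sim$network)), 2L)
  comp <- igraph::components(
    igraph::graph_from_edgelist(networkEdges(sim$network), directed = FALSE))
  expect_equal(comp$no, 2L)
  expect_equal(sort(unique(moduleAssignment(sim$truth))), c(1L, 2L))
})

test_that("SBM edge count concentrates around the binomial expectation", {
  sim <- makeSbmNetwork(500, 5, pIn = 0.2, pOut = 0.01, seed = 7)
  n_in_pairs <- 5 * choose(100, 2)
  n_out_pairs <- choose(500, 2) - n_in_pairs
  expected <- n_in_pairs * 0.2 + n_out_pairs * 0.01
  sd_edges <- sqrt(n_in_pairs * 0.2 * 0.8 + n_out_pairs * 0.01 * 0.99)
  observed <- nrow(networkEdges(sim$network))
  expect_lt(abs(observed - expected), 4 * sd_edges)
})

test_that("generators are pure functions of their seed", {
  a <- makeSbmNetwork(80, 4, 0.3, 0.02, seed = 11)
  b <- makeSbmNetwork(80, 4, 0.3, 0.02, seed = 11)
  c <- makeSbmNetwork(80, 4, 0.3, 0.02, seed = 12)
  expect_identical(networkEdges(a$network), networkEdges(b$network))
  expect_false(identical(networkEdges(a$network), networkEdges(c$network)))

  s1 <- makeSignature(a$truth, a$network, seed = 5)
  s2 <- makeSignature(a$truth, a$network, seed = 5)
  expect_identical(s1$signature, s2$signature)

  cn1 <- makeCounts(a$truth, cellsPerGroup = 5, seed = 3)
  cn2 <- makeCounts(a$truth, cellsPerGroup = 5, seed = 3)
  expect_identical(cn1$counts, cn2$counts)
})

test_that("SBM generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(makeSbmNetwork(20, 2, 0.5, 0.1, seed = 1))
  expect_identical(runif(1), before)
})

test_that("SBM rejects invalid probabilities and module counts", {
  expect_error(makeSbmNetwork(10, 2, pIn = 0.1, pOut = 0.5, seed = 1),
               "pOut < pIn")
  expect_error(makeSbmNetwork(10, 2, pIn = 1.2, pOut = 0, seed = 1))
  expect_error(makeSbmNetwork(5, 6, pIn = 0.5, pOut = 0.1, seed = 1),
               "nModules")
})

test_that("signature generator plants dropouts as specified", {
  sim <- makeSbmNetwork(500, 5, 0.2, 0.01, seed = 7)

  full <- makeSignature(sim$truth, sim$network, observeFrac = 1.0, seed = 1)
  expect_length(hiddenGenes(full$truth), 0L)

  part <- makeSignature(sim$truth, sim$network, observeFrac = 0.6, seed = 1)
  ma <- moduleAssignment(part$truth)
  module_genes <- names(ma)[ma == phenotypeModule(part$truth)]
  observed_module <- intersect(part$signature$gene, module_genes)
  expect_length(observed_module, 60L)
  expect_length(hiddenGenes(part$truth), 40L)
  expect_true(all(hiddenGenes(part$truth) %in% module_genes))
  expect_length(intersect(hiddenGenes(part$truth), part$signature$gene), 0L)

  # constructed to satisfy the signature filter unchanged
  expect_true(all(part$signature$log2fc > 0))
  expect_true(all(part$signature$p_adj < 0.05))
  expect_identical(filterSignature(part$signature)$gene,
                   part$signature$gene)
})

test_that("signature generator rejects tiny phenotype modules", {
  sim <- makeSbmNetwork(3, 3, 0.9, 0.1, seed = 1)
  expect_error(makeSignature(sim$truth, sim$network, seed = 1),
               "fewer than 2")
})

test_that("pathway generator emits planted modules plus decoys", {
  sim <- makeSbmNetwork(100, 5, 0.4, 0.02, seed = 3)
  pure <- makePathwayCollection(sim$truth, nRandom = 0, seed = 1)
  expect_length(pure, 5L)
  all_genes <- sort(unlist(lapply(pathwayNames(pure),
                                  function(nm) pathwayGenes(pure, nm))))
  expect_identical(unname(all_genes), networkNodes(sim$network))

  pm <- phenotypeModule(sim$truth)
  ma <- moduleAssignment(sim$truth)
  planted <- pathwayGenes(pure, sprintf("MODULE_%d", pm))
  expect_setequal(planted, names(ma)[ma == pm])

  mixed <- makePathwayCollection(sim$truth, nRandom = 7,
                                 sizeRange = c(5, 20), seed = 2)
  expect_length(mixed, 12L)
  expect_true(all(grepl("^MODULE_|^RANDOM_", pathwayNames(mixed))))
  expect_error(makePathwayCollection(sim$truth, sizeRange = c(1, 5)),
               "sizeRange")
})

test_that("pathway GMT serialization is byte-identical under a fixed seed", {
  sim <- makeSbmNetwork(60, 3, 0.4, 0.05, seed = 5)
  f1 <- withr::local_tempfile()
  f2 <- withr::local_tempfile()
  writeGmt(makePathwayCollection(sim$truth, nRandom = 5, sizeRange = c(3, 10),
                                 seed = 9), f1)
  writeGmt(makePathwayCollection(sim$truth, nRandom = 5, sizeRange = c(3, 10),
                                 seed = 9), f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("count generator applies effect and dropout as specified", {
  sim <- makeSbmNetwork(50, 2, 0.5, 0.05, seed = 2)
  allzero <- makeCounts(sim$truth, cellsPerGroup = 4, dropoutRate = 1,
                        seed = 1)
  expect_true(all(allzero$counts == 0))
  expect_equal(dim(allzero$counts), c(50L, 8L))

  cg <- makeCounts(sim$truth, cellsPerGroup = 50, baseMean = 20,
                   effectLog2fc = 2, dropoutRate = 0, seed = 4)
  ma <- moduleAssignment(sim$truth)
  in_mod <- ma == phenotypeModule(sim$truth)
  g1 <- cg$labels == "group1"
  ratio <- mean(cg$counts[in_mod, g1]) / mean(cg$counts[in_mod, !g1])
  expect_gt(ratio, 2.5)   # planted 4-fold effect, allowing sampling noise

  expect_error(makeCounts(sim$truth, cellsPerGroup = 1), ">= 2")
  expect_error(makeCounts(sim$truth, cellsPerGroup = 4, baseMean = -1))
})
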