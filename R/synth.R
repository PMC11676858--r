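#' Simulate a modular gene network (stochastic block model)
#'
#' Samples an undirected simple graph with `nModules` planted modules:
#' within-module edges appear with probability `pIn`, between-module
#' edges with probability `pOut`. Module sizes are as even as possible.
#' Gene symbols are "G0001", "G0002", ... Isolated nodes are retained —
#' the diffusion kernel treats them as singleton components — so the
#' disconnected-graph contract is exercised by construction.
#'
#' @param nGenes number of genes (nodes).
#' @param nModules number of planted modules; must not exceed `nGenes`.
#' @param pIn within-module edge probability.
#' @param pOut between-module edge probability; `0 <= pOut < pIn <= 1`.
#' @param seed integer seed; the same call with the same seed yields an
#'   identical edge set.
#' @return a list with elements `network` ([GeneNetwork-class]) and
#'   `truth` ([SyntheticTruth-class]; phenotype module = 1, no hidden
#'   genes yet — [makeSignature()] fills those in).
#' @examples
#' sim <- makeSbmNetwork(40, 4, pIn = 0.5, pOut = 0.02, seed = 1)
#' sim$network
#' @export
makeSbmNetwork <- function(nGenes, nModules, pIn, pOut, seed) {
  if (!(pOut >= 0 && pOut < pIn && pIn <= 1)) {
    stop("need 0 <= pOut < pIn <= 1", call. = FALSE)
  }
  if (nModules > nGenes) stop("nModules > nGenes", call. = FALSE)
  width <- max(4L, nchar(as.character(nGenes)))
  genes <- sprintf(paste0("G%0", width, "d"), seq_len(nGenes))
  sizes <- rep(nGenes %/% nModules, nModules) +
    c(rep(1L, nGenes %% nModules), rep(0L, nModules - nGenes %% nModules))
  membership <- rep(seq_len(nModules), times = sizes)
  pref <- matrix(pOut, nModules, nModules)
  diag(pref) <- pIn
  g <- with_seed(seed, igraph::sample_sbm(nGenes, pref.matrix = pref,
                                          block.sizes = sizes,
                                          directed = FALSE, loops = FALSE))
  el <- igraph::as_edgelist(g, names = FALSE)
  edges <- cbind(genes[el[, 1L]], genes[el[, 2L]])
  network <- if (nrow(edges) > 0L) {
    buildNetwork(edges, extraNodes = genes)
  } else {
    new("GeneNetwork", nodes = genes,
        edges = matrix(character(0), ncol = 2))
  }
  truth <- new("SyntheticTruth",
               moduleAssignment = setNames(as.integer(membership), genes),
               phenotypeModule = 1L, hiddenGenes = character(0),
               seed = as.integer(seed))
  list(network = network, truth = truth)
}

#' Simulate an up-regulated signature with planted dropouts
#'
#' Draws an observed signature from the phenotype module of a simulated
#' network: a `round(observeFrac * |module|)`-sized random subset of
#' module genes receives a positive log2 fold change from a log-normal
#' distribution `exp(Normal(lfcMeanlog, lfcSdlog))` (guaranteed
#' positive, as the signature filter demands) and an adjusted p-value
#' drawn strictly below 0.05. The remaining module genes are recorded
#' as `hiddenGenes` — they emulate scRNA-seq dropout events that the
#' propagation is expected to surface. `nBackground` off-module genes
#' receive positive log2 fold changes from the same distribution scaled
#' by 0.5, so the ranking problem is non-trivial.
#'
#' @param truth a [SyntheticTruth-class] from [makeSbmNetwork()].
#' @param network the matching [GeneNetwork-class].
#' @param observeFrac fraction of phenotype-module genes observed,
#'   in (0, 1].
#' @param lfcMeanlog,lfcSdlog location and scale of the log-normal
#'   effect-size distribution (log2 units after exponentiation).
#' @param nBackground number of off-module noise genes in the signature.
#' @param seed integer seed.
#' @return a list with `signature` (a signature data.frame with columns
#'   `gene`, `log2fc`, `p`, `p_adj` and attribute `provenance`) and
#'   `truth` (the input truth with `hiddenGenes` filled in).
#' @export
makeSignature <- function(truth, network, observeFrac = 0.6,
                          lfcMeanlog = 0, lfcSdlog = 0.5,
                          nBackground = 20, seed = 1) {
  stopifnot(is(truth, "SyntheticTruth"), is(network, "GeneNetwork"))
  if (!(observeFrac > 0 && observeFrac <= 1)) {
    stop("observeFrac must be in (0, 1]", call. = FALSE)
  }
  ma <- truth@moduleAssignment
  module_genes <- names(ma)[ma == truth@phenotypeModule]
  if (length(module_genes) < 2L) {
    stop("phenotype module has fewer than 2 genes", call. = FALSE)
  }
  n_obs <- round(observeFrac * length(module_genes))
  n_obs <- max(1L, min(length(module_genes), n_obs))
  off_module <- names(ma)[ma != truth@phenotypeModule]
  nBackground <- min(nBackground, length(off_module))
  sig <- with_seed(seed, {
    observed <- sort(sample(module_genes, n_obs))
    background <- sort(sample(off_module, nBackground))
    lfc <- c(exp(rnorm(n_obs, lfcMeanlog, lfcSdlog)),
             0.5 * exp(rnorm(nBackground, lfcMeanlog, lfcSdlog)))
    p_adj <- runif(n_obs + nBackground, min = 1e-12, max = 0.05 - 1e-9)
    data.frame(gene = c(observed, background), log2fc = lfc,
               p = p_adj / 10, p_adj = p_adj, stringsAsFactors = FALSE)
  })
  attr(sig, "provenance") <- sprintf("synthetic_module_%d_vs_background",
                                     truth@phenotypeModule)
  truth@hiddenGenes <- setdiff(module_genes, sig$gene)
  validObject(truth)
  list(signature = sig, truth = truth)
}

#' Simulate a pathway collection aligned to the planted modules
#'
#' Emits one pathway per planted module (its exact gene set, named
#' `MODULE_k`) plus `nRandom` decoy pathways (`RANDOM_j`) of uniform
#' random sizes drawn from `sizeRange` with genes sampled from the whole
#' gene universe.
#'
#' @param truth a [SyntheticTruth-class].
#' @param nRandom number of random decoy pathways.
#' @param sizeRange length-2 integer vector, inclusive size range of the
#'   decoys; must lie within `[2, nGenes]`.
#' @param seed integer seed.
#' @return a [PathwayCollection-class].
#' @export
makePathwayCollection <- function(truth, nRandom = 20,
                                  sizeRange = c(10, 50), seed = 1) {
  stopifnot(is(truth, "SyntheticTruth"), length(sizeRange) == 2L)
  ma <- truth@moduleAssignment
  universe <- names(ma)
  if (sizeRange[1L] < 2 || sizeRange[2L] > length(universe) ||
      sizeRange[1L] > sizeRange[2L]) {
    stop("sizeRange must lie within [2, nGenes]", call. = FALSE)
  }
  modules <- sort(unique(ma))
  sets <- lapply(modules, function(k) sort(names(ma)[ma == k]))
  names(sets) <- sprintf("MODULE_%d", modules)
  descs <- setNames(rep("planted module", length(sets)), names(sets))
  if (nRandom > 0) {
    random <- with_seed(seed, {
      lapply(seq_len(nRandom), function(j) {
        sz <- sample(seq(sizeRange[1L], sizeRange[2L]), 1L)
        sort(sample(universe, sz))
      })
    })
    names(random) <- sprintf("RANDOM_%d", seq_len(nRandom))
    sets <- c(sets, random)
    descs <- c(descs, setNames(rep("random decoy", nRandom), names(random)))
  }
  new("PathwayCollection", sets = sets, description = descs)
}

#' Simulate a two-group count matrix with zero inflation
#'
#' Negative-binomial counts for every gene of the simulated network over
#' two cell groups. Phenotype-module genes have their group-1 mean
#' multiplied by `2^effectLog2fc`; all counts are independently zeroed
#' with probability `dropoutRate` (the simulated dropout process). With
#' `effectLog2fc = 0` the groups are exchangeable, which provides the
#' null model for calibrating the built-in marker test.
#'
#' @param truth a [SyntheticTruth-class].
#' @param cellsPerGroup cells per group (>= 2).
#' @param baseMean baseline negative-binomial mean per gene.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param effectLog2fc log2 fold change applied to phenotype-module
#'   genes in group 1.
#' @param dropoutRate probability that any count is replaced by zero.
#' @param seed integer seed.
#' @return list with `counts` (genes x cells integer matrix) and
#'   `labels` (factor of length `2 * cellsPerGroup`, levels
#'   `"group1"`, `"group2"`).
#' @export
makeCounts <- function(truth, cellsPerGroup = 100, baseMean = 5,
                       dispersion = 0.4, effectLog2fc = 1,
                       dropoutRate = 0.1, seed = 1) {
  stopifnot(is(truth, "SyntheticTruth"))
  if (cellsPerGroup < 2) stop("cellsPerGroup must be >= 2", call. = FALSE)
  if (baseMean < 0 || dispersion < 0 || dropoutRate < 0 || dropoutRate > 1) {
    stop("negative or out-of-range count parameters", call. = FALSE)
  }
  ma <- truth@moduleAssignment
  genes <- names(ma)
  n_genes <- length(genes)
  n_cells <- 2L * cellsPerGroup
  in_module <- ma == truth@phenotypeModule
  mu <- matrix(baseMean, n_genes, n_cells)
  mu[in_module, seq_len(cellsPerGroup)] <- baseMean * 2^effectLog2fc
  counts <- with_seed(seed, {
    x <- if (dispersion > 0) {
      matrix(rnbinom(n_genes * n_cells, mu = mu, size = 1 / dispersion),
             n_genes, n_cells)
    } else {
      matrix(stats::rpois(n_genes * n_cells, lambda = mu),
             n_genes, n_cells)
    }
    if (dropoutRate > 0) {
      x[matrix(runif(n_genes * n_cells) < dropoutRate,
               n_genes, n_cells)] <- 0L
    }
    x
  })
  dimnames(counts) <- list(genes,
                           sprintf("cell%04d", seq_len(n_cells)))
  labels <- factor(rep(c("group1", "group2"), each = cellsPerGroup))
  list(counts = counts, labels = labels)
}
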