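#' GeneNetwork: an undirected simple graph over gene symbols
#'
#' Central network container. Nodes are upper-cased gene symbols held in
#' canonical (lexicographic) order fixed at build time, so that every
#' derived matrix (adjacency, degree, Laplacian, heat kernel) is
#' reproducible byte-for-byte. Edges are unordered pairs stored with the
#' lexicographically smaller symbol first; self-loops and duplicates are
#' impossible by validity. Isolated nodes are retained: the diffusion
#' kernel treats them as singleton components.
#'
#' @slot nodes character vector of gene symbols, sorted, unique.
#' @slot edges two-column character matrix; each row one undirected edge,
#'   column 1 lexicographically before column 2.
#' @seealso [buildNetwork()], [adjacencyMatrix()], [laplacianMatrix()]
#' @export
setClass("GeneNetwork",
  representation(nodes = "character", edges = "matrix"))

setValidity("GeneNetwork", function(object) {
  n <- object@nodes
  e <- object@edges
  if (anyDuplicated(n)) return("duplicate node symbols")
  if (is.unsorted(n)) return("nodes must be in lexicographic order")
  if (ncol(e) != 2L) return("edges must have two columns")
  if (nrow(e) > 0L) {
    if (!all(e %in% n)) return("edge endpoint not among nodes")
    if (any(e[, 1L] == e[, 2L])) return("self-loop present")
    if (any(e[, 1L] > e[, 2L])) return("edges not in canonical order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L]))) return("duplicate edges")
  }
  TRUE
})

#' PathwayCollection: named gene sets (GMT-style)
#'
#' @slot sets named list of character vectors (unique gene symbols).
#' @slot description named character vector, one free-text description
#'   per set.
#' @seealso [readGmt()], [writeGmt()], [fisherEnrichment()]
#' @export
setClass("PathwayCollection",
  representation(sets = "list", description = "character"))

setValidity("PathwayCollection", function(object) {
  s <- object@sets
  if (length(s) == 0L) return(TRUE)
  if (is.null(names(s)) || any(names(s) == "")) return("sets must be named")
  if (anyDuplicated(names(s))) return("pathway names must be unique")
  if (any(vapply(s, length, 1L) < 1L)) return("empty pathway set")
  if (any(vapply(s, anyDuplicated, 1L) > 0L)) {
    return("duplicate gene within a set")
  }
  if (!identical(names(object@description), names(s))) {
    return("description names must match set names")
  }
  TRUE
})

#' SyntheticTruth: ground truth of a simulated benchmark
#'
#' Records what the synthetic generators planted so downstream recovery
#' can be scored: which module every gene belongs to, which module
#' carries the phenotype, and which phenotype-module genes were withheld
#' from the observed signature (the simulated dropouts).
#'
#' @slot moduleAssignment named integer vector, gene -> module index.
#' @slot phenotypeModule integer, the module the signature is drawn from.
#' @slot hiddenGenes character, phenotype-module genes withheld from the
#'   observed signature.
#' @slot seed integer seed that fully determines the generated artifacts.
#' @export
setClass("SyntheticTruth",
  representation(moduleAssignment = "integer", phenotypeModule = "integer",
                 hiddenGenes = "character", seed = "integer"))

setValidity("SyntheticTruth", function(object) {
  ma <- object@moduleAssignment
  if (is.null(names(ma))) return("moduleAssignment must be named by gene")
  if (anyDuplicated(names(ma))) return("gene assigned twice")
  pm <- object@phenotypeModule
  if (length(pm) != 1L || !(pm %in% ma)) {
    return("phenotypeModule must be one of the module indices")
  }
  mod_genes <- names(ma)[ma == pm]
  if (!all(object@hiddenGenes %in% mod_genes)) {
    return("hiddenGenes must lie in the phenotype module")
  }
  TRUE
})

#' RelevanceVector: biological-relevance scores over network nodes
#'
#' The seed vector S of the propagation: the log2 fold change of each
#' signature gene present in the network and 0 for all other nodes.
#' Aligned to the network's canonical node order. Signature genes absent
#' from the network are never silently dropped; they are counted in the
#' coverage report.
#'
#' @slot score named numeric vector in network node order; non-negative.
#' @slot coverage list with elements `n_mapped`, `n_unmapped`,
#'   `unmapped` (the unmapped gene symbols).
#' @seealso [relevanceVector()], [diffuseScores()]
#' @export
setClass("RelevanceVector",
  representation(score = "numeric", coverage = "list"))

setValidity("RelevanceVector", function(object) {
  if (is.null(names(object@score))) return("score must be named by node")
  if (any(object@score < 0)) return("relevance scores must be >= 0")
  TRUE
})

#' DiffusionKernel: the heat-kernel similarity matrix W = exp(-alpha L)
#'
#' Symmetric, doubly stochastic (rows and columns sum to 1) similarity
#' matrix obtained by exponentiating the negative scaled graph
#' Laplacian. Entry (g, k) measures how much influence node k exerts on
#' node g after diffusion. Computed per connected component, so entries
#' linking distinct components are exactly zero.
#'
#' @slot matrix the |V| x |V| kernel, dimnames = node symbols.
#' @slot alpha the decay factor of the diffusion (default 0.1).
#' @slot nodes node order reference (canonical network order).
#' @seealso [heatKernel()], [diffuseScores()]
#' @export
setClass("DiffusionKernel",
  representation(matrix = "matrix", alpha = "numeric", nodes = "character"))

setValidity("DiffusionKernel", function(object) {
  W <- object@matrix
  if (nrow(W) != ncol(W)) return("kernel must be square")
  if (length(object@nodes) != nrow(W)) return("node order length mismatch")
  if (length(object@alpha) != 1L || object@alpha < 0) {
    return("alpha must be a single non-negative number")
  }
  if (nrow(W) > 0L) {
    if (max(abs(W - t(W))) > 1e-8) return("kernel must be symmetric")
    if (max(abs(rowSums(W) - 1)) > 1e-8) return("kernel rows must sum to 1")
  }
  TRUE
})

#' DiffusionResult: per-gene diffusion scores, scaled scores and ranks
#'
#' @slot table data.frame with columns `gene`, `score` (P = W S),
#'   `scaled` (standardized score), `rank` (1 = highest score, ties
#'   broken lexicographically by symbol), `in_signature` (was the gene
#'   in the input signature).
#' @slot alpha decay factor used.
#' @slot scaling `"zscore"` or `"minmax"`.
#' @seealso [diffuseScores()], [scaleScores()], [topGenes()]
#' @export
setClass("DiffusionResult",
  representation(table = "data.frame", alpha = "numeric",
                 scaling = "character"))

setValidity("DiffusionResult", function(object) {
  tb <- object@table
  need <- c("gene", "score", "scaled", "rank", "in_signature")
  if (!all(need %in% names(tb))) {
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  }
  if (nrow(tb) > 0L && !setequal(tb$rank, seq_len(nrow(tb)))) {
    return("rank must be a permutation of 1..|V|")
  }
  TRUE
})
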