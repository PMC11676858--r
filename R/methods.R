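#' @rdname GeneNetwork-class
#' @aliases networkNodes,GeneNetwork-method
setMethod("networkNodes", "GeneNetwork", function(x) x@nodes)

#' @rdname GeneNetwork-class
#' @aliases networkEdges,GeneNetwork-method
setMethod("networkEdges", "GeneNetwork", function(x) x@edges)

#' @rdname GeneNetwork-class
#' @aliases adjacencyMatrix,GeneNetwork-method
setMethod("adjacencyMatrix", "GeneNetwork", function(x) {
  n <- length(x@nodes)
  A <- matrix(0, n, n, dimnames = list(x@nodes, x@nodes))
  if (nrow(x@edges) > 0L) {
    i <- match(x@edges[, 1L], x@nodes)
    j <- match(x@edges[, 2L], x@nodes)
    A[cbind(i, j)] <- 1
    A[cbind(j, i)] <- 1
  }
  A
})

#' @rdname GeneNetwork-class
#' @aliases degreeVector,GeneNetwork-method
setMethod("degreeVector", "GeneNetwork", function(x) {
  d <- setNames(numeric(length(x@nodes)), x@nodes)
  if (nrow(x@edges) > 0L) {
    tab <- table(factor(c(x@edges[, 1L], x@edges[, 2L]), levels = x@nodes))
    d[] <- as.numeric(tab)
  }
  d
})

setMethod("length", "GeneNetwork", function(x) length(x@nodes))

setMethod("show", "GeneNetwork", function(object) {
  comp <- network_components(object)
  cat("GeneNetwork with", length(object@nodes), "nodes and",
      nrow(object@edges), "edges;", max(comp$no, 0L),
      "connected component(s)\n")
})

#' @rdname DiffusionKernel-class
#' @aliases kernelMatrix,DiffusionKernel-method
setMethod("kernelMatrix", "DiffusionKernel", function(x) x@matrix)

#' @rdname DiffusionKernel-class
#' @aliases decayFactor,DiffusionKernel-method
setMethod("decayFactor", "DiffusionKernel", function(x) x@alpha)

setMethod("show", "DiffusionKernel", function(object) {
  cat("DiffusionKernel W = exp(-alpha L): ", nrow(object@matrix), " x ",
      ncol(object@matrix), ", alpha = ", object@alpha, "\n", sep = "")
})

#' @rdname DiffusionResult-class
#' @aliases scoreTable,DiffusionResult-method
setMethod("scoreTable", "DiffusionResult", function(x) x@table)

setMethod("show", "DiffusionResult", function(object) {
  cat("DiffusionResult over", nrow(object@table), "genes (alpha =",
      object@alpha, ", scaling =", object@scaling, ")\n")
  cat("Top genes:\n")
  tb <- object@table[order(object@table$rank), , drop = FALSE]
  print(utils::head(tb, 5L), row.names = FALSE)
})

#' @rdname PathwayCollection-class
#' @aliases pathwayNames,PathwayCollection-method
setMethod("pathwayNames", "PathwayCollection", function(x) names(x@sets))

#' @rdname PathwayCollection-class
#' @aliases pathwayGenes,PathwayCollection-method
setMethod("pathwayGenes", "PathwayCollection", function(x, name) {
  if (!name %in% names(x@sets)) stop("no pathway named '", name, "'")
  x@sets[[name]]
})

setMethod("length", "PathwayCollection", function(x) length(x@sets))

setMethod("show", "PathwayCollection", function(object) {
  sizes <- vapply(object@sets, length, 1L)
  cat("PathwayCollection with", length(object@sets), "sets")
  if (length(sizes)) {
    cat(" (sizes ", min(sizes), "-", max(sizes), ")", sep = "")
  }
  cat("\n")
})

#' @rdname RelevanceVector-class
#' @aliases relevanceScores,RelevanceVector-method
setMethod("relevanceScores", "RelevanceVector", function(x) x@score)

#' @rdname RelevanceVector-class
#' @aliases coverageReport,RelevanceVector-method
setMethod("coverageReport", "RelevanceVector", function(x) x@coverage)

setMethod("show", "RelevanceVector", function(object) {
  cat("RelevanceVector over", length(object@score), "nodes;",
      sum(object@score > 0), "non-zero;",
      object@coverage$n_unmapped, "signature gene(s) unmapped\n")
})

#' @rdname SyntheticTruth-class
#' @aliases moduleAssignment,SyntheticTruth-method
setMethod("moduleAssignment", "SyntheticTruth", function(x) x@moduleAssignment)

#' @rdname SyntheticTruth-class
#' @aliases hiddenGenes,SyntheticTruth-method
setMethod("hiddenGenes", "SyntheticTruth", function(x) x@hiddenGenes)

#' @rdname SyntheticTruth-class
#' @aliases phenotypeModule,SyntheticTruth-method
setMethod("phenotypeModule", "SyntheticTruth", function(x) x@phenotypeModule)

setMethod("show", "SyntheticTruth", function(object) {
  cat("SyntheticTruth:", length(object@moduleAssignment), "genes in",
      length(unique(object@moduleAssignment)), "modules; phenotype module",
      object@phenotypeModule, "with", length(object@hiddenGenes),
      "hidden gene(s); seed", object@seed, "\n")
})

# igraph view of a GeneNetwork (isolated nodes included).
as_igraph <- function(network) {
  igraph::graph_from_data_frame(
    d = as.data.frame(network@edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = network@nodes, stringsAsFactors = FALSE)
  )
}

network_components <- function(network) {
  if (length(network@nodes) == 0L) {
    return(list(membership = integer(0), no = 0L))
  }
  comp <- igraph::components(as_igraph(network))
  list(membership = setNames(as.integer(comp$membership), network@nodes),
       no = comp$no)
}
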