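#' Graph Laplacian of a gene network
#'
#' Returns L = D - A in the canonical node order: diagonal = node
#' degrees, off-diagonal -1 for adjacent pairs, 0 otherwise. Symmetric
#' with zero row sums; rows/columns of isolated nodes are all zero.
#'
#' @param network a [GeneNetwork-class].
#' @return a base matrix with node-symbol dimnames.
#' @export
laplacianMatrix <- function(network) {
  stopifnot(is(network, "GeneNetwork"))
  A <- adjacencyMatrix(network)
  L <- -A
  diag(L) <- rowSums(A)
  L
}

#' Heat-kernel diffusion matrix W = exp(-alpha L)
#'
#' Computes the similarity matrix of a lazy random walk on the network:
#' the matrix exponential of the negative scaled graph Laplacian,
#' evaluated by symmetric eigendecomposition
#' (W = Q exp(-alpha Lambda) Q'). Requires an undirected network: only
#' then is L symmetric, which the kernel construction needs. W is
#' symmetric and doubly stochastic (each row and column sums to 1
#' because the constant vector is a null eigenvector of L).
#'
#' The kernel is assembled per connected component, so entries linking
#' distinct components are exactly zero and disconnected or isolated
#' nodes are handled without special-casing. `alpha = 0` returns the
#' identity exactly.
#'
#' @param x a [GeneNetwork-class], or a symmetric Laplacian matrix with
#'   dimnames (as from [laplacianMatrix()]).
#' @param alpha decay factor of the diffusion; default 0.1.
#' @return a [DiffusionKernel-class].
#' @examples
#' net <- buildNetwork(data.frame(gene_a = "A", gene_b = "B"))
#' kernelMatrix(heatKernel(net, alpha = 0.1))
#' @export
heatKernel <- function(x, alpha = 0.1) {
  if (length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single non-negative number", call. = FALSE)
  }
  if (is(x, "GeneNetwork")) {
    nodes <- x@nodes
    n <- length(nodes)
    W <- matrix(0, n, n, dimnames = list(nodes, nodes))
    if (alpha == 0) {
      diag(W) <- 1
      return(new("DiffusionKernel", matrix = W, alpha = 0, nodes = nodes))
    }
    comp <- network_components(x)$membership
    L <- laplacianMatrix(x)
    for (k in unique(comp)) {
      idx <- which(comp == k)
      W[idx, idx] <- dense_heat_kernel(L[idx, idx, drop = FALSE], alpha)
    }
  } else if (is.matrix(x)) {
    if (nrow(x) != ncol(x) || max(abs(x - t(x))) > 1e-10) {
      stop("Laplacian must be symmetric: the heat kernel is defined ",
           "only for undirected networks", call. = FALSE)
    }
    nodes <- rownames(x)
    if (is.null(nodes)) nodes <- sprintf("V%d", seq_len(nrow(x)))
    W <- if (alpha == 0) {
      diag(nrow(x))
    } else {
      dense_heat_kernel(x, alpha)
    }
    dimnames(W) <- list(nodes, nodes)
  } else {
    stop("x must be a GeneNetwork or a symmetric matrix", call. = FALSE)
  }
  new("DiffusionKernel", matrix = W, alpha = alpha, nodes = nodes)
}

# exp(-alpha L) for one symmetric block; entries within 1e-10 of zero
# from below are clipped to 0.
dense_heat_kernel <- function(L, alpha) {
  n <- nrow(L)
  if (n == 1L) return(matrix(1, 1, 1))
  eig <- eigen(L, symmetric = TRUE)
  W <- eig$vectors %*% (exp(-alpha * eig$values) * t(eig$vectors))
  W <- (W + t(W)) / 2
  W[W < 0 & W > -1e-10] <- 0
  W
}

#' Propagate relevance scores through the network
#'
#' Computes the diffusion score P = W S: for gene g,
#' `P_g = sum_k w_gk * score_k`, the relevance of every node after
#' propagating the seed scores through the kernel. Because W is doubly
#' stochastic, the total score mass is conserved: sum(P) = sum(S).
#' Genes are ranked by decreasing P, ties broken lexicographically by
#' symbol. The node orders of the kernel and the relevance vector must
#' be identical — a mismatch is an error, never a silent reindexing.
#'
#' @param kernel a [DiffusionKernel-class].
#' @param relevance a [RelevanceVector-class] on the same node order.
#' @return a [DiffusionResult-class] whose table holds `gene`, `score`
#'   (P), `scaled` (z-standardized by default, see [scaleScores()]),
#'   `rank` and `in_signature`.
#' @export
diffuseScores <- function(kernel, relevance) {
  stopifnot(is(kernel, "DiffusionKernel"), is(relevance, "RelevanceVector"))
  s <- relevance@score
  if (!identical(kernel@nodes, names(s))) {
    stop("node order of kernel and relevance vector differ; ",
         "rebuild both from the same network", call. = FALSE)
  }
  p <- as.numeric(kernel@matrix %*% s)
  tb <- data.frame(gene = kernel@nodes, score = p, scaled = NA_real_,
                   rank = NA_integer_, in_signature = s > 0,
                   stringsAsFactors = FALSE)
  ord <- order(-tb$score, tb$gene)
  tb$rank[ord] <- seq_len(nrow(tb))
  res <- new("DiffusionResult", table = tb, alpha = kernel@alpha,
             scaling = "zscore")
  scaleScores(res, method = "zscore")
}

#' Scale diffusion scores
#'
#' Recomputes the `scaled` column of a diffusion result. The default is
#' z-standardization, `(P - mean(P)) / sd(P)`, which preserves the
#' shape of the score distribution (and therefore the rank decay used
#' to motivate a top-N cutoff); min-max scaling to \[0, 1\] is
#' available behind the `method` flag. Scaling is affine and monotone,
#' so ranks are unchanged. A zero-variance score vector scales to all
#' zeros with a warning.
#'
#' @param result a [DiffusionResult-class].
#' @param method `"zscore"` (default) or `"minmax"`.
#' @return the result with its `scaled` column and scaling label updated.
#' @export
scaleScores <- function(result, method = c("zscore", "minmax")) {
  stopifnot(is(result, "DiffusionResult"))
  method <- match.arg(method)
  p <- result@table$score
  if (length(p) < 2L) stop("need at least 2 genes to scale", call. = FALSE)
  rng <- if (method == "zscore") sd(p) else diff(range(p))
  if (rng == 0) {
    warning("diffusion scores have zero variance; scaled scores set to 0")
    scaled <- rep(0, length(p))
  } else if (method == "zscore") {
    scaled <- (p - mean(p)) / rng
  } else {
    scaled <- (p - min(p)) / rng
  }
  result@table$scaled <- scaled
  result@scaling <- method
  result
}

#' Top-ranked genes after propagation
#'
#' Returns the first `n` genes by diffusion rank (default 200, where
#' the scaled-score decay typically flattens). Input-signature genes
#' are *not* excluded — genes seeding the diffusion legitimately
#' persist in the refined signature — and the `in_signature` flag is
#' retained so callers can tell them apart.
#'
#' @param result a [DiffusionResult-class].
#' @param n number of genes to keep; must not exceed the network size.
#' @return a data.frame, rows ordered by rank.
#' @export
topGenes <- function(result, n = 200) {
  stopifnot(is(result, "DiffusionResult"))
  nv <- nrow(result@table)
  if (n > nv) stop("n = ", n, " exceeds network size ", nv, call. = FALSE)
  tb <- result@table[order(result@table$rank), , drop = FALSE]
  out <- head(tb, n)
  rownames(out) <- NULL
  out
}
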