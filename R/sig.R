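#' Two-group marker test (rank-sum)
#'
#' A simple, transparent marker test for a two-group count matrix:
#' counts are normalized to counts-per-10k per cell, each gene gets a
#' two-sided Wilcoxon rank-sum p-value, a log2 fold change
#' `log2((mean1 + 1) / (mean2 + 1))` on normalized means (pseudocount 1,
#' stable at zero), and a Bonferroni-adjusted p-value
#' (`min(p * nGenes, 1)`). This is a deliberately plain stand-in for
#' hurdle-model single-cell DE machinery; its type-I error under the
#' null generator is calibrated by the test suite.
#'
#' @param counts genes x cells numeric matrix with gene rownames.
#' @param labels factor/character of length `ncol(counts)` with exactly
#'   two levels; the first level is "group 1" (the signature direction).
#' @return a signature data.frame with columns `gene`, `log2fc`, `p`,
#'   `p_adj` and attribute `provenance = "rank_sum_markers"`.
#' @seealso [filterSignature()], [makeCounts()]
#' @export
rankSumMarkers <- function(counts, labels) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  labels <- as.factor(labels)
  if (nlevels(labels) != 2L) {
    stop("labels must define exactly two groups", call. = FALSE)
  }
  if (length(labels) != ncol(counts)) {
    stop("labels length must equal ncol(counts)", call. = FALSE)
  }
  if (min(table(labels)) < 2L) {
    stop("need at least 2 cells per group", call. = FALSE)
  }
  lib <- colSums(counts)
  lib[lib == 0] <- 1          # all-zero cells contribute zeros either way
  norm <- sweep(counts, 2L, lib, "/") * 1e4
  g1 <- labels == levels(labels)[1L]
  m1 <- rowMeans(norm[, g1, drop = FALSE])
  m2 <- rowMeans(norm[, !g1, drop = FALSE])
  p <- apply(norm, 1L, function(x) {
    if (all(x == x[1L])) return(1)          # constant gene: no evidence
    suppressWarnings(
      wilcox.test(x[g1], x[!g1], exact = FALSE)$p.value)
  })
  n_genes <- nrow(counts)
  out <- data.frame(gene = rownames(counts),
                    log2fc = log2((m1 + 1) / (m2 + 1)),
                    p = unname(p),
                    p_adj = pmin(unname(p) * n_genes, 1),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "provenance") <- "rank_sum_markers"
  out
}

#' Filter a signature to significant up-regulated genes
#'
#' Keeps genes with a log2 fold change strictly greater than
#' `minLog2fc` (default 0 — "positive") and an adjusted p-value strictly
#' below `maxPAdj` (default 0.05). Both boundaries are exclusive.
#' Idempotent: filtering a filtered table is a no-op.
#'
#' @param table a signature data.frame with columns `gene`, `log2fc`,
#'   `p`, `p_adj`.
#' @param minLog2fc exclusive lower bound on log2 fold change.
#' @param maxPAdj exclusive upper bound on the adjusted p-value.
#' @return the filtered signature data.frame (provenance attribute
#'   preserved); a warning is emitted if nothing survives.
#' @export
filterSignature <- function(table, minLog2fc = 0, maxPAdj = 0.05) {
  stopifnot(all(c("gene", "log2fc", "p_adj") %in% names(table)))
  if (nrow(table) == 0L) stop("empty signature table", call. = FALSE)
  if (anyDuplicated(table$gene)) {
    stop("duplicate gene symbols in signature table", call. = FALSE)
  }
  keep <- table$log2fc > minLog2fc & table$p_adj < maxPAdj
  keep[is.na(keep)] <- FALSE
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L) warning("no genes pass the signature filter")
  attr(out, "provenance") <- attr(table, "provenance")
  out
}

# Exclusion patterns for immunoglobulin, ribosomal-protein and T cell
# receptor genes, as conventionally applied to variable-gene selection.
# The ribosomal pattern's digit range is ASCII [0-9].
GENE_EXCLUSION_PATTERNS <- c(
  immunoglobulin = "^IGK|^IGH|^IGL|^IGJ|^IGS|^IGD|IGFN1",
  ribosomal      = "^RP([0-9]+-|[LS])",
  tcr            = "^TRA|^TRB|^TRG"
)

#' Drop immunoglobulin / ribosomal-protein / TCR gene symbols
#'
#' Removes symbols matching any of the three standard exclusion regexes
#' (immunoglobulin chains, ribosomal proteins, T cell receptor chains).
#' Note the TCR pattern `^TRA` intentionally matches as printed, so
#' e.g. TRAF-family symbols are excluded too. Off by default in the
#' pipeline (the exclusion is a variable-gene-selection convention, not
#' a signature filter).
#'
#' @param genes character vector of gene symbols.
#' @param patterns regexes to exclude; defaults to
#'   `GENE_EXCLUSION_PATTERNS`.
#' @return the symbols not matching any pattern, original order kept.
#' @examples
#' excludeGenePatterns(c("IGHM", "RPL13", "CD8A", "TRAF1"))
#' @export
excludeGenePatterns <- function(genes, patterns = GENE_EXCLUSION_PATTERNS) {
  if (length(genes) == 0L) return(character(0))
  hit <- Reduce(`|`, lapply(patterns, function(p) grepl(p, genes)))
  genes[!hit]
}

#' Biological-relevance vector over network nodes
#'
#' Converts a filtered signature into the seed vector S of the
#' propagation: each signature gene present in the network carries its
#' log2 fold change; every other node scores 0. Signature genes missing
#' from the network are counted (and listed) in the coverage report,
#' never silently dropped.
#'
#' @param signature a filtered signature data.frame (all `log2fc > 0`).
#' @param network a [GeneNetwork-class].
#' @return a [RelevanceVector-class] aligned to the canonical node
#'   order.
#' @export
relevanceVector <- function(signature, network) {
  stopifnot(is(network, "GeneNetwork"),
            all(c("gene", "log2fc") %in% names(signature)))
  if (any(signature$log2fc <= 0)) {
    stop("signature must be filtered to positive log2 fold changes",
         call. = FALSE)
  }
  genes <- clean_symbols(signature$gene)
  nodes <- network@nodes
  s <- setNames(numeric(length(nodes)), nodes)
  idx <- match(genes, nodes)
  mapped <- !is.na(idx)
  if (!any(mapped)) {
    stop("no signature gene maps to the network", call. = FALSE)
  }
  s[idx[mapped]] <- signature$log2fc[mapped]
  unmapped <- genes[!mapped]
  if (length(unmapped)) {
    msg(length(unmapped), " signature gene(s) absent from the network")
  }
  new("RelevanceVector", score = s,
      coverage = list(n_mapped = sum(mapped),
                      n_unmapped = length(unmapped),
                      unmapped = unmapped))
}
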