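#' Fisher-exact gene-set over-representation
#'
#' For every pathway in the collection, builds the 2x2 table
#' (k, n-k; K-k, N-K-n+k) — overlap, query-only, pathway-only,
#' neither — over the supplied gene universe and computes the one-sided
#' (enrichment-direction) Fisher exact p-value, i.e. the hypergeometric
#' tail P(X >= k). The test deliberately ignores expression levels or
#' diffusion scores: only set membership enters.
#'
#' Reported per pathway: the overlap `k`, pathway size within the
#' universe `K`, query size `n`, universe size `N`, the gene ratio
#' `k / K` (overlap over pathway size, as in "6 of its 11 genes hit";
#' `k / n` is available via `geneRatioBy = "query"`), the odds ratio (cross-product ratio,
#' with a Haldane-Anscombe 0.5 added to every cell when any cell is
#' zero), and Benjamini-Hochberg adjusted p-values across the
#' collection.
#'
#' @param query character vector of query genes; genes outside the
#'   universe are dropped with a logged count.
#' @param collection a [PathwayCollection-class]; each set is
#'   intersected with the universe.
#' @param universe character vector of background genes (typically all
#'   network genes, the space diffusion scores are defined on).
#' @param geneRatioBy `"pathway"` (default, k/K) or `"query"` (k/n).
#' @param alternative `"greater"` (default, one-sided enrichment) or
#'   `"two.sided"`.
#' @return an enrichment data.frame with columns `pathway`, `k`, `K`,
#'   `n`, `N`, `gene_ratio`, `odds_ratio`, `p`, `p_adj`, `genes`
#'   (comma-separated overlap).
#' @seealso [filterAndRank()], [pathwayConcordance()]
#' @export
fisherEnrichment <- function(query, collection, universe,
                             geneRatioBy = c("pathway", "query"),
                             alternative = c("greater", "two.sided")) {
  stopifnot(is(collection, "PathwayCollection"))
  geneRatioBy <- match.arg(geneRatioBy)
  alternative <- match.arg(alternative)
  universe <- unique(clean_symbols(universe))
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query0 <- unique(clean_symbols(query))
  query <- intersect(query0, universe)
  dropped <- length(query0) - length(query)
  if (dropped > 0L) msg(dropped, " query gene(s) outside the universe dropped")
  if (length(query) == 0L) {
    stop("no query gene lies in the universe", call. = FALSE)
  }
  N <- length(universe)
  n <- length(query)
  nms <- names(collection@sets)
  sets <- lapply(collection@sets,
                 function(g) intersect(clean_symbols(g), universe))
  K <- vapply(sets, length, 1L)
  overlaps <- lapply(sets, function(pw) intersect(query, pw))
  k <- vapply(overlaps, length, 1L)
  p <- if (alternative == "greater") {
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  } else {
    vapply(seq_along(k), function(i) {
      stats::fisher.test(
        matrix(c(k[i], n - k[i], K[i] - k[i], N - K[i] - n + k[i]), 2L),
        alternative = "two.sided")$p.value
    }, numeric(1))
  }
  c11 <- k
  c12 <- n - k
  c21 <- K - k
  c22 <- N - K - n + k
  zero <- c11 == 0 | c12 == 0 | c21 == 0 | c22 == 0
  h <- ifelse(zero, 0.5, 0)      # Haldane-Anscombe correction
  or <- ((c11 + h) * (c22 + h)) / ((c12 + h) * (c21 + h))
  out <- data.frame(
    pathway = nms, k = k, K = K, n = n, N = N,
    gene_ratio = if (geneRatioBy == "pathway") {
      ifelse(K > 0, k / K, NA_real_)
    } else k / n,
    odds_ratio = or, p = p,
    p_adj = p.adjust(p, method = "BH"),
    genes = vapply(overlaps, function(g) paste(sort(g), collapse = ","),
                   character(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Filter and order an enrichment table
#'
#' Applies the standard reporting rule: keep pathways with an adjusted
#' p-value strictly below `maxPAdj` and an overlap count of at least
#' `minCount` ("count > 2" read as k >= 3), order by decreasing gene
#' ratio (ties by increasing adjusted p, then name), and truncate to
#' the `top` pathways.
#'
#' @param table an enrichment data.frame from [fisherEnrichment()].
#' @param maxPAdj exclusive upper bound on the adjusted p-value.
#' @param minCount inclusive lower bound on the overlap count k.
#' @param top number of pathways to report.
#' @return the filtered, ordered, truncated table (possibly empty).
#' @export
filterAndRank <- function(table, maxPAdj = 0.05, minCount = 3, top = 10) {
  stopifnot(all(c("pathway", "k", "gene_ratio", "p_adj") %in% names(table)))
  keep <- table$p_adj < maxPAdj & table$k >= minCount
  out <- table[keep, , drop = FALSE]
  ord <- order(-out$gene_ratio, out$p_adj, out$pathway)
  out <- head(out[ord, , drop = FALSE], max(0L, top))
  rownames(out) <- NULL
  out
}
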