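#' Venn counts of two gene sets
#'
#' @param setA,setB character vectors (deduplicated internally).
#' @return a list with `size_a`, `size_b`, `shared`, `exclusive_a`,
#'   `exclusive_b`; `exclusive_a + shared + exclusive_b = |A U B|`.
#' @examples
#' vennCounts(letters[1:5], letters[3:8])
#' @export
vennCounts <- function(setA, setB) {
  a <- unique(setA)
  b <- unique(setB)
  shared <- length(intersect(a, b))
  list(size_a = length(a), size_b = length(b), shared = shared,
       exclusive_a = length(a) - shared, exclusive_b = length(b) - shared)
}

#' Overlap fraction of two equal-length ranked lists
#'
#' Fraction of genes shared between two top-N lists (e.g. two top-200
#' propagated signatures): `|intersection| / N`.
#'
#' @param topA,topB character vectors of the same length.
#' @return a number in \[0, 1\].
#' @export
overlapFraction <- function(topA, topB) {
  if (length(topA) != length(topB)) {
    stop("ranked lists must have equal length", call. = FALSE)
  }
  if (length(topA) == 0L) stop("empty ranked lists", call. = FALSE)
  length(intersect(unique(topA), unique(topB))) / length(topA)
}

#' Before/after-propagation enrichment concordance
#'
#' Pairs the two enrichment tables by pathway name and reports how
#' propagation reshaped the enrichment landscape: counts of represented
#' pathways (overlap k >= 1) and significantly represented pathways
#' (adjusted p < `maxPAdj`) in each state, the paired (before, after)
#' gene ratios and odds ratios for pathways represented in both states,
#' and tallies of significant pathways above/below the identity line
#' (the first bisector) for both metrics. Pathways represented in only
#' one state are listed as missing on the other side — absence is never
#' imputed as a zero ratio, which would distort the bisector tallies.
#'
#' @param before,after enrichment data.frames from [fisherEnrichment()]
#'   computed on the same collection and universe.
#' @param maxPAdj significance threshold for the "significant" tallies.
#' @return a list (comparison report) with elements `n_represented`,
#'   `n_significant` (each before/after), `represented_ratio`
#'   (before / after represented counts), `paired` (data.frame of
#'   pathways represented in both states with before/after gene and
#'   odds ratios and significance flags), `bisector` (above/on/below
#'   counts among pathways significant in either state, for gene ratio
#'   and odds ratio; "above" means after > before), `missing_after`,
#'   `missing_before`.
#' @export
pathwayConcordance <- function(before, after, maxPAdj = 0.05) {
  need <- c("pathway", "k", "gene_ratio", "odds_ratio", "p_adj")
  stopifnot(all(need %in% names(before)), all(need %in% names(after)))
  if (!setequal(before$pathway, after$pathway)) {
    stop("enrichment tables were not computed on the same collection",
         call. = FALSE)
  }
  rep_b <- before[before$k >= 1L, ]
  rep_a <- after[after$k >= 1L, ]
  both <- intersect(rep_b$pathway, rep_a$pathway)
  ib <- match(both, before$pathway)
  ia <- match(both, after$pathway)
  paired <- data.frame(
    pathway = both,
    gene_ratio_before = before$gene_ratio[ib],
    gene_ratio_after = after$gene_ratio[ia],
    odds_ratio_before = before$odds_ratio[ib],
    odds_ratio_after = after$odds_ratio[ia],
    significant_before = before$p_adj[ib] < maxPAdj,
    significant_after = after$p_adj[ia] < maxPAdj,
    stringsAsFactors = FALSE)
  sig <- paired$significant_before | paired$significant_after
  tally <- function(b, a) {
    c(above = sum(sig & a > b), on = sum(sig & a == b),
      below = sum(sig & a < b))
  }
  list(
    n_represented = c(before = nrow(rep_b), after = nrow(rep_a)),
    n_significant = c(before = sum(rep_b$p_adj < maxPAdj),
                      after = sum(rep_a$p_adj < maxPAdj)),
    represented_ratio = if (nrow(rep_a) > 0) {
      nrow(rep_b) / nrow(rep_a)
    } else NA_real_,
    paired = paired,
    bisector = list(
      gene_ratio = tally(paired$gene_ratio_before, paired$gene_ratio_after),
      odds_ratio = tally(paired$odds_ratio_before, paired$odds_ratio_after)),
    missing_after = setdiff(rep_b$pathway, rep_a$pathway),
    missing_before = setdiff(rep_a$pathway, rep_b$pathway)
  )
}

#' Composition proportions and rounded percentage split
#'
#' Turns per-category cell counts into proportions and a rounded
#' percentage split that always sums to 100 (largest-remainder
#' rounding). E.g. counts of 129977 CD4+ and 117731 CD8+ cells give a
#' 52:48 split.
#'
#' @param counts non-negative numeric vector (optionally named), total
#'   greater than zero.
#' @return a list with `proportion` (counts / total) and `percent`
#'   (integer split summing to 100).
#' @examples
#' compositionRatio(c(CD4 = 129977, CD8 = 117731))$percent
#' @export
compositionRatio <- function(counts) {
  if (any(counts < 0) || any(is.na(counts))) {
    stop("counts must be non-negative", call. = FALSE)
  }
  total <- sum(counts)
  if (total <= 0) stop("total count must be positive", call. = FALSE)
  prop <- counts / total
  exact <- 100 * prop
  base <- floor(exact)
  remainder <- exact - base
  shortfall <- as.integer(round(100 - sum(base)))
  if (shortfall > 0) {
    # largest remainders get the leftover points; ties go to the larger
    # category, then to the earlier one, for a deterministic split
    ord <- order(-remainder, -counts, seq_along(counts))
    base[ord[seq_len(shortfall)]] <- base[ord[seq_len(shortfall)]] + 1
  }
  list(proportion = prop,
       percent = setNames(as.integer(base), names(counts)))
}
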