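#' @import methods
#' @importFrom stats rnorm runif rnbinom rbinom wilcox.test phyper
#'   p.adjust sd setNames
#' @importFrom utils head read.delim write.table packageVersion
NULL

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route randomness through this so a seed argument fully
# determines the artifact without touching global state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Rank-based AUROC
#'
#' Area under the ROC curve computed from ranks (the Mann-Whitney
#' statistic divided by the number of positive/negative pairs). Used to
#' quantify how well diffusion scores recover hidden (dropout) genes
#' relative to a baseline ranking.
#'
#' @param score numeric vector of scores (higher = more likely positive).
#' @param positive logical vector, same length, flagging the true
#'   positives.
#' @return a single number in \[0, 1\]; 0.5 is chance level. Ties are
#'   handled by midranks.
#' @examples
#' rankAuroc(c(3, 2, 1), c(TRUE, FALSE, FALSE))
#' @export
rankAuroc <- function(score, positive) {
  stopifnot(length(score) == length(positive), is.logical(positive))
  keep <- !is.na(score) & !is.na(positive)
  score <- score[keep]
  positive <- positive[keep]
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("need at least one positive and one negative observation",
         call. = FALSE)
  }
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Clean gene symbols: trim whitespace, upper-case. Exact-match namespace;
# no alias resolution.
clean_symbols <- function(x) toupper(trimws(as.character(x)))

msg <- function(...) message("[sigprop] ", ...)
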