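#' Read and threshold a STRING-like edge table
#'
#' Parses a tab-separated interaction table in the STRING dialect
#' (columns `protein1`, `protein2`, `experimental`, `combined_score`)
#' and keeps links with a combined score strictly greater than
#' `minCombinedScore` and, when `requireExperimental` is on, an
#' experimental-channel score greater than 0. The defaults mirror the
#' standard curation choice of experimental-evidence links with
#' combined score above 300.
#'
#' @param path path to the TSV file.
#' @param minCombinedScore keep rows with combined score strictly
#'   greater than this (default 300).
#' @param requireExperimental if `TRUE` (default), additionally require
#'   experimental-channel score > 0.
#' @return a data.frame of edge records with columns `gene_a`, `gene_b`,
#'   `score`, `source`; rows that could not be parsed are skipped and
#'   their count reported in a message and in attribute `n_skipped`.
#' @seealso [readRnainterEdges()], [buildNetwork()]
#' @export
readStringEdges <- function(path, minCombinedScore = 300,
                            requireExperimental = TRUE) {
  df <- read_edge_table(path, c("protein1", "protein2", "experimental",
                                "combined_score"))
  comb <- suppressWarnings(as.numeric(df$combined_score))
  expe <- suppressWarnings(as.numeric(df$experimental))
  bad <- is.na(comb) | is.na(expe)
  if (any(bad)) msg(sum(bad), " unreadable row(s) skipped in ", path)
  keep <- !bad & comb > minCombinedScore
  if (requireExperimental) keep <- keep & expe > 0
  out <- data.frame(gene_a = df$protein1[keep], gene_b = df$protein2[keep],
                    score = comb[keep],
                    source = rep("string_like", sum(keep)),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) warning("no edges passed the STRING-like filters")
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Read and threshold an RNAinter-like edge table
#'
#' Parses a tab-separated interaction table in the RNAinter dialect
#' (columns `gene1`, `gene2`, `score`) and keeps links with a confidence
#' score strictly greater than `minConfidence` (default 0.25).
#'
#' @param path path to the TSV file.
#' @param minConfidence strict lower bound on the confidence score.
#' @return a data.frame of edge records (see [readStringEdges()]).
#' @export
readRnainterEdges <- function(path, minConfidence = 0.25) {
  df <- read_edge_table(path, c("gene1", "gene2", "score"))
  conf <- suppressWarnings(as.numeric(df$score))
  bad <- is.na(conf)
  if (any(bad)) msg(sum(bad), " unreadable row(s) skipped in ", path)
  keep <- !bad & conf > minConfidence
  out <- data.frame(gene_a = df$gene1[keep], gene_b = df$gene2[keep],
                    score = conf[keep],
                    source = rep("rnainter_like", sum(keep)),
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L) warning("no edges passed the RNAinter-like filters")
  attr(out, "n_skipped") <- sum(bad)
  out
}

read_edge_table <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE,
                   comment.char = "#")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("format error in ", path, ": missing column(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) warning("empty edge table: ", path)
  df
}

#' Assemble the undirected gene network from edge records
#'
#' Cleans symbols (trimmed, upper-cased), drops self-loops, collapses
#' (a,b)/(b,a) and cross-source duplicates to a single undirected edge,
#' and fixes the canonical node order (lexicographic) that every derived
#' matrix uses. The resulting adjacency is binary: edge scores only
#' gate inclusion, they do not weight the diffusion.
#'
#' @param records a data.frame of edge records with columns `gene_a`,
#'   `gene_b` (e.g. from [readStringEdges()] / [readRnainterEdges()], or
#'   several of them `rbind`-ed together), or a two-column character
#'   matrix of gene pairs.
#' @param extraNodes optional gene symbols to include as (possibly
#'   isolated) nodes.
#' @return a [GeneNetwork-class] object.
#' @examples
#' net <- buildNetwork(data.frame(gene_a = c("a", "B", "A"),
#'                                gene_b = c("B", "A", "C")))
#' networkEdges(net)
#' @export
buildNetwork <- function(records, extraNodes = character(0)) {
  if (is.matrix(records)) {
    records <- data.frame(gene_a = records[, 1L], gene_b = records[, 2L],
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_a", "gene_b") %in% names(records)))
  if (nrow(records) == 0L) stop("no edge records supplied")
  a <- clean_symbols(records$gene_a)
  b <- clean_symbols(records$gene_b)
  ok <- a != b & a != "" & b != ""
  a <- a[ok]
  b <- b[ok]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  key <- !duplicated(paste(lo, hi, sep = "\r"))
  lo <- lo[key]
  hi <- hi[key]
  if (length(lo) == 0L) {
    stop("no edges survive cleaning (self-loops/duplicates removed)")
  }
  nodes <- sort(unique(c(lo, hi, clean_symbols(extraNodes))))
  ord <- order(lo, hi)
  new("GeneNetwork", nodes = nodes,
      edges = cbind(lo, hi, deparse.level = 0)[ord, , drop = FALSE])
}

#' Write / read the canonical network TSV
#'
#' `writeNetwork()` serializes a [GeneNetwork-class] as a two-column
#' edge list with header plus a sidecar file `<path>.nodes` listing all
#' node symbols (so isolated nodes survive the round trip).
#' `readNetwork()` reverses it; the sidecar is optional.
#'
#' @param network a [GeneNetwork-class].
#' @param path TSV file path.
#' @return `readNetwork()` returns a [GeneNetwork-class];
#'   `writeNetwork()` returns `path` invisibly.
#' @export
writeNetwork <- function(network, path) {
  stopifnot(is(network, "GeneNetwork"))
  df <- data.frame(gene_a = network@edges[, 1L],
                   gene_b = network@edges[, 2L], stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(network@nodes, paste0(path, ".nodes"))
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character")
  if (!all(c("gene_a", "gene_b") %in% names(df))) {
    stop("format error in ", path, ": expected columns gene_a, gene_b")
  }
  sidecar <- paste0(path, ".nodes")
  extra <- if (file.exists(sidecar)) readLines(sidecar) else character(0)
  buildNetwork(df, extraNodes = extra)
}

#' Read / write gene-set collections in GMT format
#'
#' Standard GMT dialect: one set per line, `name<TAB>description<TAB>`
#' then tab-separated gene symbols. Duplicate genes within a line are
#' stored once; lines with fewer than three fields are rejected with
#' their line number.
#'
#' @param path GMT file path.
#' @return `readGmt()` returns a [PathwayCollection-class];
#'   `writeGmt()` returns `path` invisibly.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L) {
      stop("GMT parse error at line ", i, ": fewer than 3 fields",
           call. = FALSE)
    }
    nm <- fields[[1]]
    sets[[nm]] <- unique(fields[-(1:2)])
    descs[[nm]] <- fields[[2]]
  }
  new("PathwayCollection", sets = sets, description = descs)
}

#' @rdname readGmt
#' @param collection a [PathwayCollection-class].
#' @export
writeGmt <- function(collection, path) {
  stopifnot(is(collection, "PathwayCollection"))
  lines <- vapply(names(collection@sets), function(nm) {
    paste(c(nm, collection@description[[nm]], collection@sets[[nm]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Construct a PathwayCollection from a named list
#'
#' @param sets named list of character vectors of gene symbols.
#' @param description optional character vector of descriptions (recycled
#'   empty string by default).
#' @return a [PathwayCollection-class].
#' @export
pathwayCollection <- function(sets, description = NULL) {
  sets <- lapply(sets, function(g) unique(as.character(g)))
  if (is.null(description)) {
    description <- setNames(rep("", length(sets)), names(sets))
  } else {
    description <- setNames(as.character(description), names(sets))
  }
  new("PathwayCollection", sets = sets, description = description)
}
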