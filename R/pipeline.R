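#' Pipeline configuration
#'
#' Builds and validates the single configuration object driving
#' [runPipeline()]. Defaults follow the reference analysis: STRING-like
#' combined score > 300, RNAinter-like confidence > 0.25, diffusion
#' decay alpha = 0.1, top 200 genes, enrichment filter adjusted
#' p < 0.05 with overlap count >= 3. Either supply input files
#' (`stringEdges`/`rnainterEdges` plus `signatureFile`, and `gmtFile`)
#' or leave them `NULL` to run on the seeded synthetic fixture.
#'
#' @param outdir output directory (created if needed).
#' @param seed integer seed governing every random stage.
#' @param stringEdges,rnainterEdges,signatureFile,gmtFile optional input
#'   paths; all `NULL` (default) switches on simulation.
#' @param nGenes,nModules,pIn,pOut,observeFrac,nBackground,
#'   nRandomPathways,sizeRange synthetic-fixture parameters (see the
#'   `make*` generators).
#' @param stringMin,rnainterMin edge-score thresholds.
#' @param alpha diffusion decay factor (>= 0).
#' @param topN number of top-ranked genes forming the propagated
#'   signature.
#' @param maxPAdj,minCount enrichment reporting thresholds.
#' @param scaling `"zscore"` or `"minmax"` score scaling.
#' @param geneRatioBy `"pathway"` or `"query"` gene-ratio convention.
#' @param excludePatterns apply [excludeGenePatterns()] to the filtered
#'   signature (off by default).
#' @return a validated `sigprop_config` list.
#' @export
pipelineConfig <- function(outdir, seed = 7,
                           stringEdges = NULL, rnainterEdges = NULL,
                           signatureFile = NULL, gmtFile = NULL,
                           nGenes = 500, nModules = 5, pIn = 0.2,
                           pOut = 0.01, observeFrac = 0.6,
                           nBackground = 20, nRandomPathways = 20,
                           sizeRange = c(10, 50),
                           stringMin = 300, rnainterMin = 0.25,
                           alpha = 0.1, topN = 200, maxPAdj = 0.05,
                           minCount = 3, scaling = "zscore",
                           geneRatioBy = "pathway",
                           excludePatterns = FALSE) {
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              stringEdges = stringEdges, rnainterEdges = rnainterEdges,
              signatureFile = signatureFile, gmtFile = gmtFile,
              nGenes = nGenes, nModules = nModules, pIn = pIn, pOut = pOut,
              observeFrac = observeFrac, nBackground = nBackground,
              nRandomPathways = nRandomPathways,
              sizeRange = as.numeric(unlist(sizeRange)),
              stringMin = stringMin, rnainterMin = rnainterMin,
              alpha = alpha, topN = topN, maxPAdj = maxPAdj,
              minCount = minCount, scaling = scaling,
              geneRatioBy = geneRatioBy,
              excludePatterns = isTRUE(excludePatterns))
  validateConfig(cfg)
  class(cfg) <- "sigprop_config"
  cfg
}

validateConfig <- function(cfg) {
  check <- function(ok, what) {
    if (!ok) stop("invalid config: ", what, call. = FALSE)
  }
  check(is.character(cfg$outdir) && length(cfg$outdir) == 1L,
        "outdir must be a single path")
  check(cfg$alpha >= 0, "alpha must be >= 0")
  check(cfg$topN >= 1, "topN must be >= 1")
  check(cfg$maxPAdj > 0 && cfg$maxPAdj <= 1, "maxPAdj must be in (0, 1]")
  check(cfg$minCount >= 0, "minCount must be >= 0")
  check(cfg$pOut >= 0 && cfg$pOut < cfg$pIn && cfg$pIn <= 1,
        "need 0 <= pOut < pIn <= 1")
  check(cfg$observeFrac > 0 && cfg$observeFrac <= 1,
        "observeFrac must be in (0, 1]")
  check(cfg$scaling %in% c("zscore", "minmax"), "unknown scaling mode")
  check(cfg$geneRatioBy %in% c("pathway", "query"),
        "unknown gene-ratio convention")
  invisible(TRUE)
}

#' Read / write a pipeline configuration as YAML
#'
#' @param cfg a config from [pipelineConfig()].
#' @param path YAML file path.
#' @return `readPipelineConfig()` returns a validated config;
#'   `writePipelineConfig()` returns `path` invisibly.
#' @export
writePipelineConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname writePipelineConfig
#' @export
readPipelineConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipelineConfig, raw)
}

#' Run the full propagation pipeline
#'
#' Orchestrates simulate (or load) -> build network -> filter
#' signature -> diffuse -> enrich (before and after propagation) ->
#' compare, writing every intermediate artifact plus a run manifest to
#' `cfg$outdir`. The same config and seed always produce byte-identical
#' artifacts.
#'
#' Artifacts: `network.tsv` (+`.nodes` sidecar), `pathways.gmt`,
#' `truth.json` (synthetic runs), `signature.tsv`,
#' `signature_filtered.tsv`, `ranked.tsv`,
#' `enrichment_signature.tsv`, `enrichment_propagated.tsv`,
#' `comparison_report.json`, `venn.tsv`, `paired_ratios.tsv`,
#' `manifest.json`.
#'
#' @param cfg a config from [pipelineConfig()].
#' @return invisibly, a list with the main in-memory objects
#'   (`network`, `signature`, `result`, `enrichBefore`, `enrichAfter`,
#'   `report`, `manifest`).
#' @export
runPipeline <- function(cfg) {
  if (!inherits(cfg, "sigprop_config")) cfg <- do.call(pipelineConfig, cfg)
  validateConfig(cfg)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outdir, f)
  stage_rows <- list()
  simulate <- is.null(cfg$stringEdges) && is.null(cfg$rnainterEdges)

  # stage 1: network (+ synthetic truth and pathway collection)
  truth <- NULL
  if (simulate) {
    sim <- makeSbmNetwork(cfg$nGenes, cfg$nModules, cfg$pIn, cfg$pOut,
                          seed = cfg$seed)
    network <- sim$network
    truth <- sim$truth
  } else {
    records <- list()
    if (!is.null(cfg$stringEdges)) {
      records <- c(records, list(readStringEdges(cfg$stringEdges,
                                                 cfg$stringMin)))
    }
    if (!is.null(cfg$rnainterEdges)) {
      records <- c(records, list(readRnainterEdges(cfg$rnainterEdges,
                                                   cfg$rnainterMin)))
    }
    network <- buildNetwork(do.call(rbind, records))
  }
  writeNetwork(network, out("network.tsv"))
  stage_rows$network <- nrow(networkEdges(network))

  # stage 2: pathway collection
  collection <- if (!is.null(cfg$gmtFile)) {
    readGmt(cfg$gmtFile)
  } else if (simulate) {
    makePathwayCollection(truth, nRandom = cfg$nRandomPathways,
                          sizeRange = cfg$sizeRange, seed = cfg$seed + 1L)
  } else {
    stop("pipeline stage 'pathways': no GMT file supplied for a ",
         "non-synthetic run", call. = FALSE)
  }
  writeGmt(collection, out("pathways.gmt"))
  stage_rows$pathways <- length(collection)

  # stage 3: signature
  if (!is.null(cfg$signatureFile)) {
    signature <- read.delim(cfg$signatureFile, sep = "\t",
                            stringsAsFactors = FALSE)
  } else if (simulate) {
    sig <- makeSignature(truth, network, observeFrac = cfg$observeFrac,
                         nBackground = cfg$nBackground,
                         seed = cfg$seed + 2L)
    signature <- sig$signature
    truth <- sig$truth
  } else {
    stop("pipeline stage 'signature': no signature file supplied for a ",
         "non-synthetic run", call. = FALSE)
  }
  if (simulate) {
    jsonlite::write_json(
      list(module_assignment = as.list(moduleAssignment(truth)),
           phenotype_module = phenotypeModule(truth),
           hidden_genes = hiddenGenes(truth), seed = truth@seed),
      out("truth.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  write_tsv(signature, out("signature.tsv"))
  stage_rows$signature <- nrow(signature)

  # stage 4: filter (+ optional pattern exclusion)
  filtered <- filterSignature(signature, maxPAdj = 0.05)
  if (cfg$excludePatterns) {
    filtered <- filtered[filtered$gene %in%
                           excludeGenePatterns(filtered$gene), ,
                         drop = FALSE]
  }
  write_tsv(filtered, out("signature_filtered.tsv"))
  stage_rows$signature_filtered <- nrow(filtered)

  # stage 5: diffusion
  relevance <- relevanceVector(filtered, network)
  kernel <- heatKernel(network, alpha = cfg$alpha)
  result <- scaleScores(diffuseScores(kernel, relevance),
                        method = cfg$scaling)
  ranked <- scoreTable(result)[order(scoreTable(result)$rank), ]
  write_tsv(ranked, out("ranked.tsv"))
  top <- topGenes(result, n = min(cfg$topN, length(networkNodes(network))))
  stage_rows$ranked <- nrow(ranked)

  # stage 6: enrichment before/after propagation
  universe <- networkNodes(network)
  enrich_before <- fisherEnrichment(filtered$gene, collection, universe,
                                    geneRatioBy = cfg$geneRatioBy)
  enrich_after <- fisherEnrichment(top$gene, collection, universe,
                                   geneRatioBy = cfg$geneRatioBy)
  write_tsv(enrich_before, out("enrichment_signature.tsv"))
  write_tsv(enrich_after, out("enrichment_propagated.tsv"))
  stage_rows$enrichment <- nrow(enrich_before)

  # stage 7: comparison report
  report <- pathwayConcordance(enrich_before, enrich_after,
                               maxPAdj = cfg$maxPAdj)
  venn <- vennCounts(filtered$gene, top$gene)
  write_tsv(as.data.frame(venn), out("venn.tsv"))
  write_tsv(report$paired, out("paired_ratios.tsv"))
  jsonlite::write_json(
    list(venn = venn, n_represented = as.list(report$n_represented),
         n_significant = as.list(report$n_significant),
         represented_ratio = report$represented_ratio,
         bisector = report$bisector,
         missing_after = report$missing_after,
         missing_before = report$missing_before),
    out("comparison_report.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  stage_rows$comparison <- nrow(report$paired)

  manifest <- list(
    package = "sigprop",
    version = as.character(packageVersion("sigprop")),
    r_version = R.version.string,
    config = unclass(cfg),
    stage_rows = stage_rows,
    artifacts = c("network.tsv", "network.tsv.nodes", "pathways.gmt",
                  if (simulate) "truth.json", "signature.tsv",
                  "signature_filtered.tsv", "ranked.tsv",
                  "enrichment_signature.tsv", "enrichment_propagated.tsv",
                  "comparison_report.json", "venn.tsv",
                  "paired_ratios.tsv"))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(network = network, truth = truth, signature = filtered,
                 result = result, enrichBefore = enrich_before,
                 enrichAfter = enrich_after, report = report,
                 manifest = manifest))
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
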