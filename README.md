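# sigprop

Network propagation of single-cell gene signatures by heat-kernel
diffusion.

Gene signatures pulled out of single-cell RNA-seq differential
expression (say, markers of tumor-infiltrating regulatory T cells or of
exhausted CD8+ T cells) are large, noisy, and miss genes lost to
dropout. `sigprop` rescues them with a protein–protein interaction
network: signature genes seed the network with their log2 fold changes,
a graph heat kernel diffuses those scores, and every gene in the network
is re-ranked by how connected it is to the weighted input signature.
Genes that never made the signature but sit in its interaction
neighborhood — dropout candidates — rise; isolated false positives sink.

## The method

For an undirected PPI network with adjacency `A` and degree matrix `D`,
the package computes the graph Laplacian `L = D − A` and the diffusion
kernel

```
W = exp(−αL),   α = 0.1 by default
```

(symmetric, doubly stochastic; evaluated by symmetric
eigendecomposition per connected component). A signature filtered to
up-regulated genes (log2FC > 0, Bonferroni-adjusted p < 0.05) becomes
the seed vector `S` (log2FC on signature genes, 0 elsewhere), and each
gene g receives the diffusion score

```
P_g = Σ_k w_gk · score_k        (P = W·S)
```

Scores are z-scaled, the top 200 genes form the refined signature, and
Fisher-exact over-representation (gene ratio k/K, odds ratio, BH
adjustment) before vs after propagation quantifies the refinement.
A seeded synthetic benchmark — stochastic-block-model networks with a
planted module, signatures with withheld "dropout" genes, decoy pathway
collections, zero-inflated negative-binomial counts — makes every stage
testable with known ground truth.

## Worked example

```r
library(sigprop)

sim <- makeSbmNetwork(500, 5, pIn = 0.2, pOut = 0.01, seed = 7)
sim$network
#> GeneNetwork with 500 nodes and 5922 edges; 1 connected component(s)

sg  <- makeSignature(sim$truth, sim$network, observeFrac = 0.6, seed = 7)
rv  <- relevanceVector(filterSignature(sg$signature), sim$network)
res <- diffuseScores(heatKernel(sim$network, alpha = 0.1), rv)

sum(scoreTable(res)$score) - sum(relevanceScores(rv))
#> [1] 1.136868e-13      # diffusion conserves score mass

hid <- hiddenGenes(sg$truth)        # 40 module genes withheld as dropouts
sc  <- setNames(scoreTable(res)$score, scoreTable(res)$gene)
ma  <- moduleAssignment(sg$truth)
neg <- setdiff(names(ma)[ma != phenotypeModule(sg$truth)], sg$signature$gene)
lab <- rep(c(TRUE, FALSE), c(length(hid), length(neg)))
rankAuroc(sc[c(hid, neg)], lab)
#> [1] 1                 # diffusion rank recovers every hidden gene
rankAuroc(degreeVector(sim$network)[c(hid, neg)], lab)
#> [1] 0.4817763         # a degree-ranked baseline is at chance
```

The hidden-gene AUROC of 1 versus ≈ 0.48 for degree says the recovery
comes from connectivity to the seeded signature, not from generic
hubness. The same objects drive enrichment and comparison:

```r
coll <- makePathwayCollection(sg$truth, nRandom = 20, sizeRange = c(10, 50),
                              seed = 8)
et <- fisherEnrichment(topGenes(res, 200)$gene, coll,
                       networkNodes(sim$network))
head(et[order(et$p_adj), c("pathway", "k", "K", "gene_ratio", "p_adj")], 1)
#>    pathway   k   K gene_ratio        p_adj
#> 1 MODULE_1 100 100          1 1.108742e-47
```

The planted-module pathway dominates the post-propagation enrichment.
An end-to-end run (`runPipeline(pipelineConfig(outdir, seed = 7))`)
writes all intermediates plus a manifest and is byte-reproducible under
a fixed seed; `inst/scripts/sigprop-cli.R` exposes the stages as shell
subcommands.

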