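#' @rdname GeneNetwork-class
#' @param x a sigprop object.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))

#' @rdname GeneNetwork-class
#' @export
setGeneric("degreeVector", function(x) standardGeneric("degreeVector"))

#' @rdname DiffusionKernel-class
#' @param x a sigprop object.
#' @export
setGeneric("kernelMatrix", function(x) standardGeneric("kernelMatrix"))

#' @rdname DiffusionKernel-class
#' @export
setGeneric("decayFactor", function(x) standardGeneric("decayFactor"))

#' @rdname DiffusionResult-class
#' @param x a sigprop object.
#' @export
setGeneric("scoreTable", function(x) standardGeneric("scoreTable"))

#' @rdname PathwayCollection-class
#' @param x a sigprop object.
#' @export
setGeneric("pathwayNames", function(x) standardGeneric("pathwayNames"))

#' @rdname PathwayCollection-class
#' @param name pathway name.
#' @export
setGeneric("pathwayGenes", function(x, name) standardGeneric("pathwayGenes"))

#' @rdname RelevanceVector-class
#' @param x a sigprop object.
#' @export
setGeneric("relevanceScores", function(x) standardGeneric("relevanceScores"))

#' @rdname RelevanceVector-class
#' @export
setGeneric("coverageReport", function(x) standardGeneric("coverageReport"))

#' @rdname SyntheticTruth-class
#' @param x a sigprop object.
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("hiddenGenes", function(x) standardGeneric("hiddenGenes"))

#' @rdname SyntheticTruth-class
#' @export
setGeneric("phenotypeModule", function(x) standardGeneric("phenotypeModule"))
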