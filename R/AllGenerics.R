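#' @include AllClasses.R
NULL

#' @rdname CitationGraph-class
#' @param x a \code{CitationGraph}, \code{InvertedIndex} or
#'   \code{PageRankResult} object
#' @export
setGeneric("nodes", function(x) standardGeneric("nodes"))

#' @rdname CitationGraph-class
#' @export
setGeneric("edges", function(x) standardGeneric("edges"))

#' @rdname CitationGraph-class
#' @export
setGeneric("outDegree", function(x) standardGeneric("outDegree"))

#' @rdname CitationGraph-class
#' @export
setGeneric("isSource", function(x) standardGeneric("isSource"))

#' @rdname CitationGraph-class
#' @export
setGeneric("numNodes", function(x) standardGeneric("numNodes"))

#' @rdname CitationGraph-class
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' @rdname InvertedIndex-class
#' @param x an \code{InvertedIndex}
#' @export
setGeneric("inbound", function(x) standardGeneric("inbound"))

#' @rdname InvertedIndex-class
#' @export
setGeneric("citationCount", function(x) standardGeneric("citationCount"))

#' @rdname PageRankResult-class
#' @param x a \code{PageRankResult}
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname PageRankResult-class
#' @export
setGeneric("iterations", function(x) standardGeneric("iterations"))

#' @rdname PageRankResult-class
#' @export
setGeneric("converged", function(x) standardGeneric("converged"))

#' @rdname PageRankResult-class
#' @export
setGeneric("residual", function(x) standardGeneric("residual"))

#' @rdname PageRankResult-class
#' @export
setGeneric("residualTrace", function(x) standardGeneric("residualTrace"))

#' @rdname SyntheticCorpus-class
#' @param x a \code{SyntheticCorpus}
#' @export
setGeneric("articleRecords", function(x) standardGeneric("articleRecords"))

#' @rdname SyntheticCorpus-class
#' @export
setGeneric("citationGraph", function(x) standardGeneric("citationGraph"))

#' @rdname writeJATS
#' @export
setGeneric("writeJATS", function(x, dir, ...) standardGeneric("writeJATS"))
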