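#' @include AllClasses.R AllGenerics.R
NULL

#' @rdname CitationGraph-class
#' @export
setMethod("nodes", "CitationGraph", function(x) x@nodes)

#' @rdname CitationGraph-class
#' @export
setMethod("edges", "CitationGraph", function(x) x@edges)

#' @rdname CitationGraph-class
#' @export
setMethod("outDegree", "CitationGraph", function(x) {
  structure(x@outDegree, names = as.character(x@nodes))
})

#' @rdname CitationGraph-class
#' @export
setMethod("isSource", "CitationGraph", function(x) {
  structure(x@isSource, names = as.character(x@nodes))
})

#' @rdname CitationGraph-class
#' @export
setMethod("numNodes", "CitationGraph", function(x) length(x@nodes))

#' @rdname CitationGraph-class
#' @export
setMethod("numEdges", "CitationGraph", function(x) nrow(x@edges))

#' @rdname InvertedIndex-class
#' @export
setMethod("nodes", "InvertedIndex", function(x) x@pmids)

#' @rdname InvertedIndex-class
#' @export
setMethod("inbound", "InvertedIndex", function(x) {
  structure(x@inbound, names = as.character(x@pmids))
})

#' @rdname InvertedIndex-class
#' @export
setMethod("citationCount", "InvertedIndex", function(x) {
  structure(x@citationCount, names = as.character(x@pmids))
})

#' @rdname PageRankResult-class
#' @export
setMethod("scores", "PageRankResult", function(x) x@scores)

#' @rdname PageRankResult-class
#' @export
setMethod("nodes", "PageRankResult", function(x) as.integer(names(x@scores)))

#' @rdname PageRankResult-class
#' @export
setMethod("iterations", "PageRankResult", function(x) x@iterations)

#' @rdname PageRankResult-class
#' @export
setMethod("converged", "PageRankResult", function(x) x@converged)

#' @rdname PageRankResult-class
#' @export
setMethod("residual", "PageRankResult", function(x) x@residual)

#' @rdname PageRankResult-class
#' @export
setMethod("residualTrace", "PageRankResult", function(x) x@residualTrace)

setMethod("show", "ArticleRecord", function(object) {
  cat("ArticleRecord pmid=", object@pmid,
      " outbound=", length(object@outbound), " citation(s)\n", sep = "")
})

setMethod("show", "CitationGraph", function(object) {
  cat("CitationGraph with ", length(object@nodes), " node(s) and ",
      nrow(object@edges), " edge(s)\n", sep = "")
  cat("  source articles: ", sum(object@isSource),
      "; cited-only (dangling): ", sum(!object@isSource), "\n", sep = "")
})

setMethod("show", "InvertedIndex", function(object) {
  cat("InvertedIndex over ", length(object@pmids), " node(s); total inbound citations: ",
      sum(object@citationCount), "\n", sep = "")
})

setMethod("show", "PageRankParams", function(object) {
  cat("PageRankParams: d=", object@d, ", epsilon=", object@epsilon,
      ", maxIterations=", object@maxIterations, "\n", sep = "")
})

setMethod("show", "PageRankResult", function(object) {
  cat("PageRankResult over ", length(object@scores), " node(s): ",
      if (object@converged) "converged" else "NOT converged",
      " after ", object@iterations, " iteration(s), final L1 residual ",
      format(object@residual, digits = 4), "\n", sep = "")
})

setMethod("show", "CorrelationReport", function(object) {
  cat("CorrelationReport (", object@direction, ")\n", sep = "")
  cat(sprintf("  n = %d\n  Pearson R = %.4f (p = %.3g)\n  R^2 = %.4f\n",
              object@n, object@pearsonR, object@pCorrelation, object@rSquared))
  cat(sprintf("  slope = %.6g (p = %.3g), intercept = %.6g\n",
              object@slope, object@pRegression, object@intercept))
})

setMethod("show", "SyntheticCorpus", function(object) {
  cat("SyntheticCorpus: ", length(object@pmids), " article(s), seed ",
      object@params$seed, "\n", sep = "")
})
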