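#' ArticleRecord: one parsed article
#'
#' A single full-text article reduced to its citation payload: the article's
#' own PMID and the deduplicated, self-loop-free set of PMIDs it cites.
#' Records are produced by [parseArticle()]/[parseCorpus()] (from JATS XML)
#' or by [articleRecords()] (from a synthetic corpus), and consumed by
#' [buildGraph()].
#'
#' @slot pmid integer(1), the article's own positive PubMed identifier.
#' @slot outbound integer vector of distinct cited PMIDs, never containing
#'   \code{pmid} itself.
#' @slot sourcePath character(1) provenance string for diagnostics (file
#'   path, or a synthetic label).
#'
#' @seealso [parseArticle()], [buildGraph()]
#' @export
setClass("ArticleRecord",
  representation(
    pmid = "integer",
    outbound = "integer",
    sourcePath = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@pmid) != 1L || is.na(object@pmid) || object@pmid <= 0L)
      msg <- c(msg, "pmid must be a single positive integer")
    if (anyNA(object@outbound) || any(object@outbound <= 0L))
      msg <- c(msg, "outbound PMIDs must be positive integers")
    if (anyDuplicated(object@outbound))
      msg <- c(msg, "outbound PMIDs must be distinct")
    if (length(object@pmid) == 1L && object@pmid %in% object@outbound)
      msg <- c(msg, "outbound must not contain the article's own pmid")
    if (length(msg)) msg else TRUE
  }
)

#' ArticleRecord constructor
#'
#' Builds a validated [ArticleRecord-class], deduplicating the outbound list
#' and dropping self-citations (the same normalisation the JATS parser
#' applies), so raw reference lists can be passed directly.
#'
#' @param pmid positive integer, the article's own PMID.
#' @param outbound integer vector of cited PMIDs; duplicates and
#'   self-citations are removed.
#' @param sourcePath provenance string.
#' @return an \code{ArticleRecord}.
#' @examples
#' articleRecord(111, c(222, 333, 222, 111))  # outbound becomes {222, 333}
#' @export
articleRecord <- function(pmid, outbound = integer(), sourcePath = NA_character_) {
  pmid <- as.integer(pmid)
  outbound <- as.integer(outbound)
  outbound <- unique(outbound[!is.na(outbound) & outbound != pmid])
  new("ArticleRecord", pmid = pmid, outbound = outbound,
      sourcePath = as.character(sourcePath))
}

#' CitationGraph: directed graph over unique PMIDs
#'
#' The citation network: nodes are the unique PMIDs appearing either as
#' parsed articles or as cited references, and each directed edge
#' \code{(citing, cited)} is one deduplicated citation. PMIDs that were
#' cited but never parsed ("cited-only" nodes) are genuine nodes of the
#' graph — they receive a PageRank — and are dangling by construction
#' (out-degree zero).
#'
#' Nodes are kept in ascending PMID order; edges are kept sorted by
#' (citing, cited), with no duplicates and no self-loops.
#'
#' @slot nodes sorted integer vector of unique PMIDs (the set \eqn{p_i},
#'   size N).
#' @slot edges integer matrix with columns \code{citing}, \code{cited}.
#' @slot outDegree integer vector parallel to \code{nodes}: the number of
#'   outbound citations \eqn{L(p_j)} of each node.
#' @slot isSource logical vector parallel to \code{nodes}: TRUE iff the node
#'   appeared as a parsed article (rather than cited-only).
#'
#' @seealso [buildGraph()], [invertedIndex()], [pageRank()]
#' @aliases nodes edges outDegree isSource numNodes numEdges
#' @export
setClass("CitationGraph",
  representation(
    nodes = "integer",
    edges = "matrix",
    outDegree = "integer",
    isSource = "logical"
  ),
  validity = function(object) {
    msg <- character()
    n <- object@nodes
    e <- object@edges
    if (is.unsorted(n, strictly = TRUE))
      msg <- c(msg, "nodes must be strictly ascending PMIDs")
    if (ncol(e) != 2L)
      msg <- c(msg, "edges must have two columns (citing, cited)")
    if (length(object@outDegree) != length(n) ||
        length(object@isSource) != length(n))
      msg <- c(msg, "outDegree and isSource must be parallel to nodes")
    if (nrow(e) > 0L) {
      if (!all(e %in% n))
        msg <- c(msg, "every edge endpoint must be a node")
      if (any(e[, 1L] == e[, 2L]))
        msg <- c(msg, "self-loop edges are not allowed")
      if (anyDuplicated(e))
        msg <- c(msg, "duplicate edges are not allowed")
    }
    if (sum(object@outDegree) != nrow(e))
      msg <- c(msg, "sum of out-degrees must equal the edge count")
    if (any(object@outDegree[!object@isSource] > 0L))
      msg <- c(msg, "cited-only nodes must have out-degree 0")
    if (length(msg)) msg else TRUE
  }
)

#' InvertedIndex: inbound citations per node
#'
#' The transpose view of a [CitationGraph-class]: for each node \eqn{p_i},
#' the set of citing PMIDs \eqn{M(p_i)} and its size, the citation count
#' \eqn{|M(p_i)|} (the node's in-degree). Every node of the graph appears,
#' including those with zero inbound citations.
#'
#' @slot pmids sorted integer vector of node PMIDs (identical to the graph's
#'   node set).
#' @slot inbound list parallel to \code{pmids}; element i is the integer
#'   vector of PMIDs citing \code{pmids[i]}.
#' @slot citationCount integer vector parallel to \code{pmids}, the
#'   in-degrees.
#'
#' @seealso [invertedIndex()]
#' @aliases inbound citationCount
#' @export
setClass("InvertedIndex",
  representation(
    pmids = "integer",
    inbound = "list",
    citationCount = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@inbound) != length(object@pmids) ||
        length(object@citationCount) != length(object@pmids))
      msg <- c(msg, "inbound and citationCount must be parallel to pmids")
    if (!all(lengths(object@inbound) == object@citationCount))
      msg <- c(msg, "citationCount must equal the length of each inbound set")
    if (length(msg)) msg else TRUE
  }
)

#' PageRankParams: damping, tolerance and iteration cap
#'
#' Parameter block for the PageRank recurrence. Defaults follow the
#' standard bibliometric setting: damping \code{d = 0.85} (probability the
#' random surfer follows a citation rather than teleporting) and a
#' convergence tolerance \code{epsilon = 1e-5} on the L1 change between
#' successive iterates.
#'
#' @slot d numeric(1) damping factor, strictly between 0 and 1.
#' @slot epsilon numeric(1) positive convergence tolerance.
#' @slot maxIterations integer(1) positive iteration cap.
#' @export
setClass("PageRankParams",
  representation(
    d = "numeric",
    epsilon = "numeric",
    maxIterations = "integer"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@d) != 1L || is.na(object@d) ||
        object@d <= 0 || object@d >= 1)
      msg <- c(msg, "d must lie strictly in (0, 1)")
    if (length(object@epsilon) != 1L || is.na(object@epsilon) ||
        object@epsilon <= 0)
      msg <- c(msg, "epsilon must be > 0")
    if (length(object@maxIterations) != 1L || is.na(object@maxIterations) ||
        object@maxIterations < 1L)
      msg <- c(msg, "maxIterations must be a positive integer")
    if (length(msg)) msg else TRUE
  }
)

#' PageRankParams constructor
#'
#' @param d damping factor in (0, 1); default 0.85.
#' @param epsilon L1 convergence tolerance; default 1e-5.
#' @param maxIterations iteration cap; default 100.
#' @return a \code{PageRankParams}.
#' @examples
#' pageRankParams()
#' pageRankParams(epsilon = 1e-12, maxIterations = 1000)
#' @export
pageRankParams <- function(d = 0.85, epsilon = 1e-5, maxIterations = 100L) {
  new("PageRankParams", d = as.numeric(d), epsilon = as.numeric(epsilon),
      maxIterations = as.integer(maxIterations))
}

#' PageRankResult: per-node PageRank with convergence metadata
#'
#' Scores are probabilities: they sum to one over the node set, and every
#' node's score is at least the teleportation floor \eqn{(1-d)/N}.
#'
#' @slot scores numeric vector of \eqn{PR(p_i)}, named by PMID, sorted in
#'   the graph's (ascending-PMID) node order.
#' @slot iterations integer(1), number of power-iteration steps taken.
#' @slot converged logical(1), TRUE iff the L1 change fell below epsilon
#'   within the iteration cap.
#' @slot residual numeric(1), final L1 change between successive iterates.
#' @slot residualTrace numeric vector, the L1 change after each iteration.
#' @slot params the [PageRankParams-class] used.
#'
#' @seealso [pageRank()], [pageRankExact()]
#' @aliases scores iterations converged residual residualTrace
#' @export
setClass("PageRankResult",
  representation(
    scores = "numeric",
    iterations = "integer",
    converged = "logical",
    residual = "numeric",
    residualTrace = "numeric",
    params = "PageRankParams"
  ),
  validity = function(object) {
    msg <- character()
    if (is.null(names(object@scores)))
      msg <- c(msg, "scores must be named by PMID")
    if (length(object@scores) &&
        abs(sum(object@scores) - 1) > 1e-9)
      msg <- c(msg, "scores must sum to 1 (within 1e-9)")
    if (length(msg)) msg else TRUE
  }
)

#' CorrelationReport: PageRank-vs-citation-count validation statistics
#'
#' The output of [correlateRanks()]: Pearson correlation with a two-sided
#' t-test, and the ordinary-least-squares fit of PageRank on citation count
#' (the regression direction is recorded). For simple linear regression the
#' coefficient of determination equals the squared Pearson correlation, and
#' the class validity enforces that identity.
#'
#' @slot n integer(1) sample size.
#' @slot pearsonR numeric(1) Pearson correlation in \eqn{[-1, 1]}.
#' @slot rSquared numeric(1) coefficient of determination of the fit.
#' @slot slope,intercept numeric(1) OLS coefficients.
#' @slot pCorrelation,pRegression numeric(1) two-sided p-values for the
#'   correlation and the slope.
#' @slot direction character(1), e.g. \code{"pagerank ~ citation_count"}.
#' @export
setClass("CorrelationReport",
  representation(
    n = "integer",
    pearsonR = "numeric",
    rSquared = "numeric",
    slope = "numeric",
    intercept = "numeric",
    pCorrelation = "numeric",
    pRegression = "numeric",
    direction = "character"
  ),
  validity = function(object) {
    msg <- character()
    if (abs(object@pearsonR) > 1 + 1e-12)
      msg <- c(msg, "pearsonR must lie in [-1, 1]")
    if (abs(object@rSquared - object@pearsonR^2) > 1e-12)
      msg <- c(msg, "rSquared must equal pearsonR^2 (simple regression)")
    if (object@n < 3L)
      msg <- c(msg, "n must be at least 3 for reported p-values")
    if (length(msg)) msg else TRUE
  }
)

#' SyntheticCorpus: a simulated growing citation corpus
#'
#' Articles appear sequentially and cite earlier articles with
#' cumulative-advantage (Price model) preferential attachment; a fraction
#' of references point at fresh out-of-corpus PMIDs. The stored reference
#' lists are \emph{raw}: injected duplicate and self references are kept so
#' that downstream normalisation (parser or [articleRecords()]) can be
#' exercised.
#'
#' @slot pmids integer vector of article PMIDs in appearance order.
#' @slot refs list parallel to \code{pmids}: raw reference lists (may
#'   contain duplicates/self-citations by design).
#' @slot params named list of the generator parameters, including the seed.
#'
#' @seealso [simulateCorpus()], [writeJATS()]
#' @aliases articleRecords citationGraph
#' @export
setClass("SyntheticCorpus",
  representation(
    pmids = "integer",
    refs = "list",
    params = "list"
  ),
  validity = function(object) {
    msg <- character()
    if (length(object@refs) != length(object@pmids))
      msg <- c(msg, "refs must be parallel to pmids")
    if (anyDuplicated(object@pmids))
      msg <- c(msg, "article PMIDs must be unique")
    if (length(msg)) msg else TRUE
  }
)
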