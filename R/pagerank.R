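#' @include AllClasses.R AllGenerics.R
NULL

# Column-stochastic-with-dangling transition pieces for a CitationGraph:
# a sparse matrix M with M[i, j] = 1/L(j) for each edge j -> i, plus the
# dangling indicator (L = 0). Used by both the power iteration and the
# dense oracle so the two share one reading of the graph, while remaining
# independent solvers.
transitionPieces <- function(graph) {
  n <- length(graph@nodes)
  e <- graph@edges
  from <- match(e[, 1L], graph@nodes)
  to <- match(e[, 2L], graph@nodes)
  M <- Matrix::sparseMatrix(i = to, j = from,
                            x = 1 / graph@outDegree[from],
                            dims = c(n, n))
  list(M = M, dangling = graph@outDegree == 0L, n = n)
}

#' Compute PageRank by power iteration
#'
#' Iterates the PageRank recurrence
#' \deqn{PR(p_i) = \frac{1-d}{N} + d \sum_{p_j \in M(p_i)}
#'   \frac{PR(p_j)}{L(p_j)}}
#' from the uniform vector \eqn{1/N} until the L1 norm of the change
#' between successive iterates falls below `epsilon`, or `maxIterations`
#' is reached. Dangling nodes — in a citation corpus typically the many
#' PMIDs that were cited but never parsed — hold rank mass with nowhere to
#' send it; that mass is redistributed uniformly over all nodes at each
#' step, the standard convention that keeps the scores a probability
#' distribution (the "random surfer" restarts from a dead end anywhere).
#'
#' The result satisfies \eqn{\sum_i PR(p_i) = 1} and
#' \eqn{PR(p_i) \ge (1-d)/N} for every node.
#'
#' @param graph a non-empty [CitationGraph-class].
#' @param params a [PageRankParams-class]; defaults to `pageRankParams()`
#'   (d = 0.85, epsilon = 1e-5, maxIterations = 100).
#' @return a [PageRankResult-class]. If the iteration cap is hit first, the
#'   result is returned with `converged = FALSE` and a warning, leaving the
#'   decision to the caller.
#' @examples
#' g <- buildGraph(list(articleRecord(1, 2), articleRecord(2, 1)))
#' scores(pageRank(g))  # symmetric 2-cycle: 0.5 each
#' @seealso [pageRankExact()] for the dense stationary solve used as a test
#'   oracle.
#' @export
pageRank <- function(graph, params = pageRankParams()) {
  stopifnot(is(graph, "CitationGraph"), is(params, "PageRankParams"))
  n <- length(graph@nodes)
  if (n == 0L) stop("cannot compute PageRank of an empty graph")
  tp <- transitionPieces(graph)
  d <- params@d
  pr <- rep(1 / n, n)
  teleport <- (1 - d) / n
  trace <- numeric(params@maxIterations)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    danglingMass <- sum(pr[tp$dangling])
    prNew <- teleport + d * (as.numeric(tp$M %*% pr) + danglingMass / n)
    trace[iter] <- sum(abs(prNew - pr))
    pr <- prNew
    if (trace[iter] < params@epsilon || iter >= params@maxIterations) break
  }
  conv <- trace[iter] < params@epsilon
  if (!conv)
    warning("PageRank did not converge within ", params@maxIterations,
            " iterations (final L1 residual ", format(trace[iter]), ")")
  names(pr) <- as.character(graph@nodes)
  new("PageRankResult", scores = pr, iterations = iter, converged = conv,
      residual = trace[iter], residualTrace = trace[seq_len(iter)],
      params = params)
}

#' Exact PageRank by dense linear solve (test oracle)
#'
#' Solves the stationary equations of the same transition model directly:
#' \deqn{(I - d\,P^\top - \tfrac{d}{N}\,\mathbf{1}a^\top)\,\pi =
#'   \tfrac{1-d}{N}\,\mathbf{1}}
#' where \eqn{P^\top} carries \eqn{1/L(p_j)} for each edge and \eqn{a}
#' indicates dangling nodes (uniform redistribution, as in [pageRank()]).
#' Row sums of the system force \eqn{\sum_i \pi_i = 1}; the result is
#' normalised once more against floating-point drift.
#'
#' This is an independent dense-algebra route to the same quantity, kept
#' deliberately small: it refuses graphs with more than `maxNodes` nodes
#' because it exists to cross-check the power iteration in tests, not to
#' rank corpora.
#'
#' @param graph a non-empty [CitationGraph-class] with at most `maxNodes`
#'   nodes.
#' @param d damping factor in (0, 1); default 0.85.
#' @param maxNodes refusal bound on the dense solve; default 200.
#' @return a [PageRankResult-class] with `converged = TRUE`,
#'   `iterations = 0` and zero residual (the solve is direct).
#' @export
pageRankExact <- function(graph, d = 0.85, maxNodes = 200L) {
  stopifnot(is(graph, "CitationGraph"), d > 0, d < 1)
  n <- length(graph@nodes)
  if (n == 0L) stop("cannot compute PageRank of an empty graph")
  if (n > maxNodes)
    stop("pageRankExact is a dense test oracle; refusing graph with ", n,
         " > ", maxNodes, " nodes")
  tp <- transitionPieces(graph)
  A <- diag(n) - d * as.matrix(tp$M) -
    (d / n) * matrix(1, n, 1) %*% matrix(as.numeric(tp$dangling), 1, n)
  pr <- solve(A, rep((1 - d) / n, n))
  pr <- pr / sum(pr)
  names(pr) <- as.character(graph@nodes)
  new("PageRankResult", scores = pr, iterations = 0L, converged = TRUE,
      residual = 0, residualTrace = numeric(),
      params = pageRankParams(d = d, epsilon = .Machine$double.eps,
                              maxIterations = 1L))
}

#' Write and read PageRank score tables
#'
#' `writeScores()` emits a TSV with columns `pmid`, `pagerank`,
#' `citation_count`, the PageRank printed in scientific notation with six
#' decimal digits of mantissa, sorted by descending PageRank then ascending
#' PMID — a deterministic, diff-stable ranking file. `readScores()` reads
#' such a file back into a data frame.
#'
#' @param pr a [PageRankResult-class].
#' @param index the matching [InvertedIndex-class] (same node set).
#' @param path output path.
#' @return `writeScores()` returns `path` invisibly; `readScores()` returns
#'   a `data.frame` with columns `pmid`, `pagerank`, `citation_count`.
#' @export
writeScores <- function(pr, index, path) {
  stopifnot(is(pr, "PageRankResult"), is(index, "InvertedIndex"))
  pmids <- as.integer(names(pr@scores))
  cc <- index@citationCount[match(pmids, index@pmids)]
  if (anyNA(cc)) stop("index node set does not match the score vector")
  ord <- order(-pr@scores, pmids)
  writeLines(sprintf("%d\t%.6e\t%d", pmids[ord], pr@scores[ord], cc[ord]),
             path, sep = "\n")
  invisible(path)
}

#' @rdname writeScores
#' @export
readScores <- function(path) {
  if (!file.exists(path)) stop("score file not found: ", path)
  if (length(readLines(path, n = 1L)) == 0L)
    return(data.frame(pmid = integer(), pagerank = numeric(),
                      citation_count = integer()))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          colClasses = c("integer", "numeric", "integer"),
                          col.names = c("pmid", "pagerank", "citation_count"))
  df
}
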