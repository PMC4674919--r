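#' @include AllClasses.R AllGenerics.R
NULL

# Canonical constructor: sorts/dedups edges, derives node set, out-degrees
# and source flags. `sourcePmids` are nodes known to be parsed articles
# (they stay in the graph even with an empty reference list).
newCitationGraph <- function(edgeMat, sourcePmids = integer()) {
  storage.mode(edgeMat) <- "integer"
  if (length(edgeMat) == 0L) edgeMat <- matrix(integer(), ncol = 2L)
  colnames(edgeMat) <- c("citing", "cited")
  keep <- edgeMat[, 1L] != edgeMat[, 2L]
  edgeMat <- edgeMat[keep, , drop = FALSE]
  edgeMat <- unique(edgeMat)
  ord <- order(edgeMat[, 1L], edgeMat[, 2L])
  edgeMat <- edgeMat[ord, , drop = FALSE]
  nodeSet <- sort(unique(c(as.integer(sourcePmids), as.vector(edgeMat))))
  outDeg <- tabulate(match(edgeMat[, 1L], nodeSet), nbins = length(nodeSet))
  srcFlag <- nodeSet %in% sourcePmids | outDeg > 0L
  new("CitationGraph", nodes = nodeSet, edges = edgeMat,
      outDegree = as.integer(outDeg), isSource = srcFlag)
}

#' Build the citation graph from parsed article records
#'
#' Nodes are the union of all article PMIDs and all cited PMIDs: a PMID that
#' is cited but has no parsed article of its own becomes a genuine
#' ("cited-only") node, dangling by construction. Edges are the union of
#' each record's outbound pairs. Node order is ascending PMID, so the
#' result is independent of record order.
#'
#' @param records a list of [ArticleRecord-class] objects (or a single
#'   record).
#' @return a [CitationGraph-class].
#' @details Two records with the same PMID are an error, not a merge:
#'   duplicate parsed articles indicate a corpus defect that silent merging
#'   would hide.
#' @examples
#' g <- buildGraph(list(articleRecord(111, c(999)), articleRecord(222, c(999))))
#' numNodes(g)   # 3: node 999 exists although never parsed
#' outDegree(g)  # 999 is dangling
#' @export
buildGraph <- function(records) {
  if (is(records, "ArticleRecord")) records <- list(records)
  stopifnot(all(vapply(records, is, logical(1), "ArticleRecord")))
  pmids <- vapply(records, function(r) r@pmid, integer(1))
  if (anyDuplicated(pmids)) {
    dup <- unique(pmids[duplicated(pmids)])
    stop("duplicate article record(s) for PMID ", paste(dup, collapse = ", "))
  }
  citing <- rep.int(pmids, vapply(records, function(r) length(r@outbound),
                                  integer(1)))
  cited <- unlist(lapply(records, function(r) r@outbound), use.names = FALSE)
  if (is.null(cited)) cited <- integer()
  newCitationGraph(cbind(citing, cited), sourcePmids = pmids)
}

#' Invert a citation graph into inbound citation lists
#'
#' For every node \eqn{v} the inverted index records the set of citing
#' PMIDs \eqn{M(v)} and the citation count \eqn{|M(v)|} (the in-degree).
#' Every node of the graph appears in the index, with count zero permitted,
#' and the counts conserve the edge total:
#' \eqn{\sum_v |M(v)| = |edges|}.
#'
#' @param graph a [CitationGraph-class].
#' @return an [InvertedIndex-class].
#' @examples
#' g <- buildGraph(list(articleRecord(1, 3), articleRecord(2, 3)))
#' citationCount(invertedIndex(g))  # node 3 has count 2
#' @export
invertedIndex <- function(graph) {
  stopifnot(is(graph, "CitationGraph"))
  n <- graph@nodes
  e <- graph@edges
  inb <- rep(list(integer()), length(n))
  if (nrow(e) > 0L) {
    byCited <- split(e[, 1L], factor(match(e[, 2L], n), levels = seq_along(n)))
    inb <- lapply(byCited, function(v) sort(as.integer(v)))
    names(inb) <- NULL
  }
  new("InvertedIndex", pmids = n, inbound = inb,
      citationCount = lengths(inb))
}

#' Read and write edge-list TSV files
#'
#' The interchange format is a two-column TSV, `citing_pmid<TAB>cited_pmid`,
#' one edge per line, no header, LF line endings. The writer emits edges in
#' canonical order (ascending citing, then cited PMID); the reader
#' deduplicates and drops self-loop lines, reporting how many via a
#' message. Writing then re-reading reproduces an identical graph when the
#' node manifest is used.
#'
#' Because an edge list alone cannot represent a parsed article with an
#' empty reference list, both functions take an optional node *manifest* — a
#' one-column TSV of article PMIDs seen as citing sources — which completes
#' the round trip and preserves `isSource` flags exactly.
#'
#' @param path edge-list file path.
#' @param manifestPath optional path of the source-article manifest.
#' @param graph a [CitationGraph-class].
#' @return `readEdgeList()` returns a [CitationGraph-class];
#'   `writeEdgeList()` returns `path` invisibly.
#' @export
readEdgeList <- function(path, manifestPath = NULL) {
  if (!file.exists(path)) stop("edge list not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  nr <- length(lines)
  citing <- integer(nr); cited <- integer(nr)
  if (nr > 0L) {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad))
      stop("malformed edge list line ", bad[1L], " in ", path,
           ": expected 2 tab-separated fields")
    citing <- suppressWarnings(as.integer(vapply(parts, `[`, "", 1L)))
    cited <- suppressWarnings(as.integer(vapply(parts, `[`, "", 2L)))
    bad <- which(is.na(citing) | is.na(cited))
    if (length(bad))
      stop("non-integer PMID on edge list line ", bad[1L], " in ", path)
  }
  nSelf <- sum(citing == cited)
  nDup <- sum(duplicated(cbind(citing, cited)[citing != cited, , drop = FALSE]))
  if (nSelf + nDup > 0L)
    message("readEdgeList: dropped ", nSelf, " self-loop and ",
            nDup, " duplicate line(s)")
  sources <- citing
  if (!is.null(manifestPath)) {
    mf <- readLines(manifestPath)
    mf <- mf[nzchar(mf)]
    mfi <- suppressWarnings(as.integer(mf))
    if (anyNA(mfi)) stop("non-integer PMID in manifest ", manifestPath)
    sources <- c(sources, mfi)
  }
  newCitationGraph(cbind(citing, cited), sourcePmids = unique(sources))
}

#' @rdname readEdgeList
#' @export
writeEdgeList <- function(graph, path, manifestPath = NULL) {
  stopifnot(is(graph, "CitationGraph"))
  e <- graph@edges
  writeLines(sprintf("%d\t%d", e[, 1L], e[, 2L]), path, sep = "\n")
  if (!is.null(manifestPath))
    writeLines(sprintf("%d", graph@nodes[graph@isSource]), manifestPath,
               sep = "\n")
  invisible(path)
}

#' Write per-node citation counts as TSV
#'
#' Emits `pmid<TAB>count`, sorted by descending count then ascending PMID —
#' the conventional "most cited first" listing.
#'
#' @param index an [InvertedIndex-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCitationCounts <- function(index, path) {
  stopifnot(is(index, "InvertedIndex"))
  ord <- order(-index@citationCount, index@pmids)
  writeLines(sprintf("%d\t%d", index@pmids[ord], index@citationCount[ord]),
             path, sep = "\n")
  invisible(path)
}
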