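# Hand-built JATS fixture text, independent of the package's own JATS
# writer so parser tests do not lean on the code they check.
#
# `pmid` may be given as a string (to exercise non-numeric ids); `refs`
# likewise. `bodyExtra` injects markup outside the ref-list.
jatsFixture <- function(pmid, refs = character(), bodyExtra = "") {
  refXml <- paste(vapply(as.character(refs), function(r) {
    sprintf(paste0("<ref><mixed-citation>Some paper. ",
                   "<pub-id pub-id-type=\"pmid\">%s</pub-id>",
                   "<pub-id pub-id-type=\"doi\">10.1000/x</pub-id>",
                   "</mixed-citation></ref>"), r)
  }, ""), collapse = "\n")
  sprintf('<?xml version="1.0"?>
<article>
  <front>
    <article-meta>
      <article-id pub-id-type="pmc">PMC%s</article-id>
      <article-id pub-id-type="pmid">%s</article-id>
    </article-meta>
  </front>
  <body><p>text</p>%s</body>
  <back>
    <ref-list>
%s
    </ref-list>
  </back>
</article>', pmid, pmid, bodyExtra, refXml)
}

writeFixture <- function(dir, name, text) {
  path <- file.path(dir, name)
  writeLines(text, path)
  path
}

# Independent in-degree computation straight from the edge matrix.
inDegreeFromEdges <- function(graph) {
  e <- edges(graph)
  n <- nodes(graph)
  structure(tabulate(match(e[, 2L], n), nbins = length(n)),
            names = as.character(n))
}

# Small hand-built graphs used across PageRank tests.
twoCycleGraph <- function() {
  buildGraph(list(articleRecord(1, 2), articleRecord(2, 1)))
}

kCycleGraph <- function(k) {
  buildGraph(lapply(seq_len(k), function(i) {
    articleRecord(i, if (i == k) 1L else i + 1L)
  }))
}

chainGraph <- function() {
  buildGraph(list(articleRecord(1, 2), articleRecord(2, 3)))
}

starGraph <- function(leaves = 5L) {
  buildGraph(lapply(seq_len(leaves), function(i) {
    articleRecord(100 + i, 1L)
  }))
}

# 2-cycle plus a node that neither cites nor is cited by it (it must still
# carry a record so it enters the graph).
isolatedPlusCycleGraph <- function() {
  buildGraph(list(articleRecord(1, 2), articleRecord(2, 1),
                  articleRecord(3)))
}

# A batch of seeded small Price-model graphs (all well under the dense
# oracle's refusal bound).
smallPriceGraphs <- function(n = 100L, seedBase = 1000L) {
  lapply(seq_len(n), function(i) {
    sim <- simulateCorpus(3 + (i %% 18), meanRefs = 2,
                          externalFraction = 0.15, seed = seedBase + i)
    citationGraph(sim)
  })
}

# High-precision power iteration settings for oracle comparisons: the
# convergence tolerance bounds attainable accuracy, so comparisons at the
# 1e-8 level run the iteration well below that.
tightParams <- function(d = 0.85) {
  pageRankParams(d = d, epsilon = 1e-12, maxIterations = 5000L)
}
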