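#' @include AllClasses.R AllGenerics.R
NULL

# PMID layout for synthetic corpora: in-corpus articles occupy a low range,
# out-of-corpus (cited-only) PMIDs a disjoint high range, so source status
# is auditable by eye.
.articleBase <- 100000L
.externalBase <- 900000000L

#' Simulate a growing citation corpus (Price model)
#'
#' Generates `nArticles` articles appearing sequentially in time. Article
#' t draws its reference-list length from a Poisson law with mean
#' `meanRefs`; each reference points, with probability `externalFraction`,
#' at a fresh out-of-corpus PMID (a node that will be cited-only, hence
#' dangling), and otherwise at a distinct earlier article chosen with
#' probability proportional to its current in-degree plus
#' `attachmentOffset` — cumulative advantage, the minimal mechanism that
#' produces the heavy-tailed citation-count distributions real corpora
#' show. Early articles with fewer predecessors than requested simply cite
#' fewer. In-corpus citations always point backwards in time.
#'
#' To exercise parser normalisation, dirty references are then injected:
#' with probability `dupRate` an article repeats one of its references,
#' and with probability `selfRate` it cites itself. The stored reference
#' lists are raw; [articleRecords()] and the JATS round trip apply the same
#' dedup/self-loop rules the parser does.
#'
#' Everything is reproducible from `seed`; the caller's RNG state is left
#' untouched.
#'
#' @param nArticles number of in-corpus articles (at least 1).
#' @param meanRefs expected reference-list length; default 8.
#' @param attachmentOffset additive constant \eqn{a \ge 0} in the
#'   attachment kernel \eqn{k + a}; default 1.
#' @param externalFraction proportion of references pointing outside the
#'   corpus; default 0.15.
#' @param dupRate,selfRate per-article probabilities of an injected
#'   duplicate / self reference; defaults 0.02 and 0.01.
#' @param seed integer RNG seed; default 1.
#' @return a [SyntheticCorpus-class].
#' @examples
#' sim <- simulateCorpus(50, seed = 7)
#' g <- citationGraph(sim)
#' @export
simulateCorpus <- function(nArticles, meanRefs = 8, attachmentOffset = 1,
                           externalFraction = 0.15, dupRate = 0.02,
                           selfRate = 0.01, seed = 1L) {
  stopifnot(nArticles >= 1, meanRefs >= 0, attachmentOffset >= 0,
            externalFraction >= 0, externalFraction <= 1,
            dupRate >= 0, dupRate <= 1, selfRate >= 0, selfRate <= 1)
  nArticles <- as.integer(nArticles)
  pmids <- .articleBase + seq_len(nArticles)
  params <- list(nArticles = nArticles, meanRefs = meanRefs,
                 attachmentOffset = attachmentOffset,
                 externalFraction = externalFraction,
                 dupRate = dupRate, selfRate = selfRate,
                 seed = as.integer(seed))
  refs <- withSeed(seed, {
    inDeg <- numeric(nArticles)  # in-corpus in-degree, drives attachment
    nextExternal <- .externalBase
    out <- vector("list", nArticles)
    for (t in seq_len(nArticles)) {
      k <- stats::rpois(1L, meanRefs)
      ext <- if (k > 0L) stats::runif(k) < externalFraction else logical()
      nExt <- sum(ext)
      extRefs <- if (nExt > 0L) nextExternal + seq_len(nExt) else integer()
      nextExternal <- nextExternal + nExt
      nInt <- min(k - nExt, t - 1L)
      intRefs <- integer()
      if (nInt > 0L) {
        w <- inDeg[seq_len(t - 1L)] + attachmentOffset
        intIdx <- if (t - 1L == 1L) 1L else
          sample(seq_len(t - 1L), nInt, prob = w)
        inDeg[intIdx] <- inDeg[intIdx] + 1
        intRefs <- pmids[intIdx]
      }
      r <- c(intRefs, as.integer(extRefs))
      # injected dirt, resolved downstream by parser-equivalent dedup rules
      if (length(r) > 0L && stats::runif(1L) < dupRate)
        r <- c(r, r[sample.int(length(r), 1L)])
      if (stats::runif(1L) < selfRate)
        r <- c(r, pmids[t])
      out[[t]] <- r
    }
    out
  })
  new("SyntheticCorpus", pmids = pmids, refs = refs, params = params)
}

#' @rdname SyntheticCorpus-class
#' @export
setMethod("articleRecords", "SyntheticCorpus", function(x) {
  lapply(seq_along(x@pmids), function(i) {
    articleRecord(x@pmids[i], x@refs[[i]],
                  sourcePath = sprintf("synthetic:%d", x@pmids[i]))
  })
})

#' @rdname SyntheticCorpus-class
#' @export
setMethod("citationGraph", "SyntheticCorpus", function(x) {
  buildGraph(articleRecords(x))
})

#' Write a synthetic corpus as minimal JATS article files
#'
#' Emits one minimal, well-formed JATS XML file per source article, with
#' the article's PMID in the front-matter `article-id` and its (raw,
#' possibly dirty) reference list as back-matter `ref-list` entries.
#' [parseCorpus()] on the output directory recovers exactly the graph
#' [citationGraph()] gives, including dedup/self-loop normalisation.
#' Cited-only PMIDs produce no files: they exist only as references.
#'
#' @param x a [SyntheticCorpus-class].
#' @param dir output directory (created if needed).
#' @param ... unused.
#' @return character vector of the written file paths, invisibly.
#' @export
setMethod("writeJATS", "SyntheticCorpus", function(x, dir, ...) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create directory: ", dir)
  paths <- file.path(dir, sprintf("PMC%09d.xml", x@pmids))
  for (i in seq_along(x@pmids)) {
    writeLines(jatsArticleXML(x@pmids[i], x@refs[[i]]), paths[i], sep = "\n")
  }
  invisible(paths)
})

# Minimal JATS article document as a character vector of lines.
jatsArticleXML <- function(pmid, refPmids) {
  refBlock <- character()
  if (length(refPmids) > 0L) {
    # interleave the three-line ref blocks in order
    refBlock <- as.vector(rbind(
      sprintf('      <ref id="r%d">', seq_along(refPmids)),
      sprintf('        <element-citation publication-type="journal"><pub-id pub-id-type="pmid">%d</pub-id></element-citation>',
              refPmids),
      rep("      </ref>", length(refPmids))
    ))
  }
  c('<?xml version="1.0" encoding="UTF-8"?>',
    '<article article-type="research-article">',
    "  <front>",
    "    <article-meta>",
    sprintf('      <article-id pub-id-type="pmid">%d</article-id>', pmid),
    "      <title-group><article-title>Synthetic article</article-title></title-group>",
    "    </article-meta>",
    "  </front>",
    "  <body><p>Synthetic body text.</p></body>",
    "  <back>",
    "    <ref-list>",
    refBlock,
    "    </ref-list>",
    "  </back>",
    "</article>")
}
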