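#' @include AllClasses.R
NULL

# Read an XML document from a path, transparently handling .gz files.
readArticleXML <- function(path) {
  if (grepl("\\.gz$", path)) {
    con <- gzfile(path, "rb")
    on.exit(close(con))
    xml2::read_xml(con)
  } else {
    xml2::read_xml(path)
  }
}

#' Parse one JATS/NLM article into an ArticleRecord
#'
#' Extracts the article's own PMID from the front matter
#' (`front/article-meta/article-id[@pub-id-type="pmid"]`) and the PMIDs of
#' its outbound citations from any `pub-id[@pub-id-type="pmid"]` element
#' under a back-matter `ref-list` — the PMC open-access convention.
#' References carrying no PMID (books, URLs, DOI-only entries) are skipped:
#' the citation network is keyed exclusively on PMIDs. Duplicate references
#' are collapsed and self-citations removed at parse time, since both would
#' distort the out-degree \eqn{L(p_j)} entering the PageRank recurrence.
#'
#' @param x a file path to a JATS XML document (optionally
#'   gzip-compressed), an XML string, or an `xml2::xml_document`.
#' @param sourcePath provenance string recorded in the result (defaults to
#'   the path when `x` is one).
#' @return an [ArticleRecord-class].
#' @section Errors: malformed XML raises a parse error naming the source
#'   path; a missing or non-numeric own PMID raises an
#'   "unidentifiable article" error (callers such as [parseCorpus()] may
#'   skip and log).
#' @export
parseArticle <- function(x, sourcePath = NULL) {
  if (inherits(x, "xml_document")) {
    doc <- x
    if (is.null(sourcePath)) sourcePath <- NA_character_
  } else {
    stopifnot(is.character(x), length(x) == 1L)
    isPath <- file.exists(x) || !grepl("<", x, fixed = TRUE)
    if (isPath) {
      if (is.null(sourcePath)) sourcePath <- x
      doc <- tryCatch(readArticleXML(x), error = function(e) {
        stop("malformed XML in ", sourcePath, ": ", conditionMessage(e),
             call. = FALSE)
      })
    } else {
      if (is.null(sourcePath)) sourcePath <- "<inline>"
      doc <- tryCatch(xml2::read_xml(x), error = function(e) {
        stop("malformed XML in ", sourcePath, ": ", conditionMessage(e),
             call. = FALSE)
      })
    }
  }
  # strip any default namespace so plain JATS XPaths work on both flavours
  xml2::xml_ns_strip(doc)
  own <- xml2::xml_find_first(
    doc, "./front/article-meta/article-id[@pub-id-type='pmid']")
  ownPmid <- suppressWarnings(as.integer(xml2::xml_text(own)))
  if (length(ownPmid) != 1L || is.na(ownPmid) || ownPmid <= 0L)
    stop("unidentifiable article (missing or non-numeric PMID) in ",
         sourcePath, call. = FALSE)
  refNodes <- xml2::xml_find_all(
    doc, "./back//ref-list//pub-id[@pub-id-type='pmid']")
  cited <- suppressWarnings(as.integer(xml2::xml_text(refNodes)))
  cited <- cited[!is.na(cited) & cited > 0L]  # non-numeric pub-id: absent
  articleRecord(ownPmid, cited, sourcePath = sourcePath)
}

#' Parse a directory of JATS article XML files
#'
#' Streams over every `*.xml` / `*.xml.gz` file in `dir`, in sorted path
#' order (so results are independent of filesystem enumeration order), and
#' parses each with [parseArticle()]. Per-file failures are handled
#' according to `onError`: `"skip"` logs the file and continues, `"abort"`
#' rethrows. A summary message reports parsed and skipped counts, which are
#' also attached as attributes `parsed` and `skipped` on the result.
#'
#' @param dir directory containing article XML files.
#' @param onError `"skip"` (skip-and-log, the default) or `"abort"`.
#' @return a list of [ArticleRecord-class] objects with attributes
#'   `parsed` and `skipped`.
#' @export
parseCorpus <- function(dir, onError = c("skip", "abort")) {
  onError <- match.arg(onError)
  if (!dir.exists(dir)) stop("cannot read directory: ", dir)
  paths <- list.files(dir, pattern = "\\.xml(\\.gz)?$", full.names = TRUE)
  paths <- paths[order(basename(paths), method = "radix")]
  records <- vector("list", length(paths))
  ok <- logical(length(paths))
  for (i in seq_along(paths)) {
    rec <- tryCatch(parseArticle(paths[[i]]), error = function(e) {
      if (onError == "abort") stop(e)
      message("parseCorpus: skipping ", paths[[i]], " (",
              conditionMessage(e), ")")
      NULL
    })
    if (!is.null(rec)) {
      records[[i]] <- rec
      ok[i] <- TRUE
    }
  }
  records <- records[ok]
  message("parseCorpus: parsed ", sum(ok), " file(s), skipped ",
          sum(!ok), " of ", length(paths))
  structure(records, parsed = sum(ok), skipped = sum(!ok))
}
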