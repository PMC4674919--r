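#' @include AllClasses.R AllGenerics.R
NULL

#' Draw a seeded random sample of (PageRank, citation count) pairs
#'
#' Takes a uniform sample without replacement of
#' \eqn{\lceil fraction \cdot N \rceil} nodes and returns their PageRank
#' and citation count, aligned by node. The sample is fully reproducible
#' from `seed`; with `fraction = 1` the whole population is returned in
#' deterministic ascending-PMID order without touching the RNG.
#'
#' @param pr a [PageRankResult-class].
#' @param index the matching [InvertedIndex-class].
#' @param fraction sampling proportion in (0, 1]; default 0.05 (a 5%
#'   sample, the conventional validation split for this analysis).
#' @param seed integer RNG seed; recorded as an attribute of the result.
#' @param sourcesOnly if TRUE, sample only nodes flagged as parsed source
#'   articles instead of all network nodes; requires `graph`.
#' @param graph the [CitationGraph-class], needed only when
#'   `sourcesOnly = TRUE`.
#' @return a `data.frame` with columns `pmid`, `pagerank`,
#'   `citation_count`, and attributes `seed` and `fraction`.
#' @export
sampleNodes <- function(pr, index, fraction = 0.05, seed = 1L,
                        sourcesOnly = FALSE, graph = NULL) {
  stopifnot(is(pr, "PageRankResult"), is(index, "InvertedIndex"))
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  pmids <- as.integer(names(pr@scores))
  cc <- index@citationCount[match(pmids, index@pmids)]
  if (anyNA(cc)) stop("index node set does not match the score vector")
  pool <- seq_along(pmids)
  if (sourcesOnly) {
    if (is.null(graph)) stop("sourcesOnly = TRUE requires the graph")
    pool <- pool[graph@isSource[match(pmids, graph@nodes)]]
  }
  size <- as.integer(ceiling(fraction * length(pool)))
  if (fraction >= 1) {
    idx <- pool
  } else {
    idx <- withSeed(seed, sort(sample(pool, size)))
  }
  out <- data.frame(pmid = pmids[idx], pagerank = unname(pr@scores[idx]),
                    citation_count = cc[idx])
  attr(out, "seed") <- as.integer(seed)
  attr(out, "fraction") <- fraction
  out
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards.
withSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Finite-population sample-size calculation
#'
#' Computes the required sample size for estimating a proportion at a given
#' confidence level and margin of error in a finite population:
#' \deqn{n = \left\lceil \frac{N x}{(N-1)E^2 + x} \right\rceil,
#'   \quad x = Z^2 p (1-p)}
#' with \eqn{Z} the two-sided normal quantile for the confidence level,
#' \eqn{E} the margin of error and \eqn{p} the assumed response
#' distribution — the formula published by the Raosoft calculator. At the
#' conventional 95% / 5% / 50% setting the infinite-population asymptote is
#' \eqn{\lceil 384.16 \rceil = 385}.
#'
#' @param population population size N (at least 1).
#' @param confidence confidence level in (0, 1); default 0.95.
#' @param margin margin of error in (0, 1); default 0.05.
#' @param p assumed response distribution in (0, 1); default 0.5 (the
#'   most conservative choice).
#' @return the required sample size, a positive integer.
#' @examples
#' requiredSampleSize(6293819)  # 385
#' requiredSampleSize(100)      # 80
#' @export
requiredSampleSize <- function(population, confidence = 0.95,
                               margin = 0.05, p = 0.5) {
  if (!is.numeric(population) || length(population) != 1L || population < 1)
    stop("population must be a positive integer")
  if (confidence <= 0 || confidence >= 1) stop("confidence must lie in (0, 1)")
  if (margin <= 0 || margin >= 1) stop("margin must lie in (0, 1)")
  if (p <= 0 || p >= 1) stop("response distribution must lie in (0, 1)")
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  x <- z^2 * p * (1 - p)
  n <- population * x / ((population - 1) * margin^2 + x)
  as.integer(ceiling(n))
}

#' Correlate PageRank with citation count
#'
#' Computes the Pearson correlation (with its two-sided t-test) between the
#' paired PageRank and citation-count values, and fits the ordinary
#' least-squares line of PageRank on citation count. No transform is
#' applied: the fit is on the raw pairs. For simple linear regression the
#' coefficient of determination equals the squared Pearson correlation;
#' the returned report carries both and enforces that identity.
#'
#' @param sample a `data.frame` with numeric columns `pagerank` and
#'   `citation_count`, as produced by [sampleNodes()].
#' @return a [CorrelationReport-class].
#' @section Errors: fewer than 3 pairs raises an insufficient-data error;
#'   a constant variable (zero variance) raises an undefined-correlation
#'   error.
#' @export
correlateRanks <- function(sample) {
  stopifnot(is.data.frame(sample),
            all(c("pagerank", "citation_count") %in% names(sample)))
  x <- sample$citation_count
  y <- sample$pagerank
  if (length(x) < 3L)
    stop("insufficient data: need at least 3 pairs, got ", length(x))
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: a variable is constant")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  r <- unname(ct$estimate)
  new("CorrelationReport",
      n = length(x),
      pearsonR = r,
      rSquared = r^2,
      slope = unname(stats::coef(fit)[2L]),
      intercept = unname(stats::coef(fit)[1L]),
      pCorrelation = ct$p.value,
      pRegression = sm$coefficients[2L, 4L],
      direction = "pagerank ~ citation_count")
}

#' Export a correlation report as JSON
#'
#' Writes the report's fields (n, pearson_r, r_squared, slope, intercept,
#' p_correlation, p_regression, plus the sample's seed and fraction when
#' supplied) as a flat JSON object.
#'
#' @param report a [CorrelationReport-class].
#' @param path output path; if NULL the JSON string is returned instead.
#' @param seed,fraction optional sampling provenance to record.
#' @return the path (invisibly), or the JSON string when `path` is NULL.
#' @export
writeReport <- function(report, path = NULL, seed = NULL, fraction = NULL) {
  stopifnot(is(report, "CorrelationReport"))
  obj <- list(n = report@n, pearson_r = report@pearsonR,
              r_squared = report@rSquared, slope = report@slope,
              intercept = report@intercept,
              p_correlation = report@pCorrelation,
              p_regression = report@pRegression,
              direction = report@direction)
  if (!is.null(seed)) obj$seed <- as.integer(seed)
  if (!is.null(fraction)) obj$fraction <- fraction
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Top-N ranking table
#'
#' Returns the `n` highest-PageRank nodes as a table with columns `rank`,
#' `pmid`, `pagerank`, `citation_count`, sorted by descending PageRank with
#' ties broken by ascending PMID — the side-by-side "top of the corpus"
#' comparison of the two importance metrics.
#'
#' @param pr a [PageRankResult-class].
#' @param index the matching [InvertedIndex-class].
#' @param n number of rows requested; if it exceeds the node count the
#'   table is truncated with a warning.
#' @return a `data.frame` with `n` (or fewer) rows.
#' @export
topRanked <- function(pr, index, n = 10L) {
  stopifnot(is(pr, "PageRankResult"), is(index, "InvertedIndex"), n >= 1L)
  pmids <- as.integer(names(pr@scores))
  cc <- index@citationCount[match(pmids, index@pmids)]
  if (anyNA(cc)) stop("index node set does not match the score vector")
  if (n > length(pmids)) {
    warning("requested top ", n, " of only ", length(pmids),
            " nodes; truncating")
    n <- length(pmids)
  }
  ord <- order(-pr@scores, pmids)[seq_len(n)]
  data.frame(rank = seq_len(n), pmid = pmids[ord],
             pagerank = unname(pr@scores[ord]), citation_count = cc[ord])
}

#' @rdname topRanked
#' @param table a rank table from `topRanked()`.
#' @param path output TSV path.
#' @export
writeRankTable <- function(table, path) {
  stopifnot(is.data.frame(table))
  lines <- c("rank\tpmid\tpagerank\tcitation_count",
             sprintf("%d\t%d\t%.6e\t%d", table$rank, table$pmid,
                     table$pagerank, table$citation_count))
  writeLines(lines, path, sep = "\n")
  invisible(path)
}
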