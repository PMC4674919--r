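test_that("sampleNodes takes ceiling-sized, seed-reproducible samples", {
  g <- citationGraph(simulateCorpus(500, seed = 14))
  pr <- pageRank(g)
  idx <- invertedIndex(g)
  n <- numNodes(g)

  s1 <- sampleNodes(pr, idx, fraction = 0.05, seed = 77)
  expect_identical(nrow(s1), as.integer(ceiling(0.05 * n)))
  s2 <- sampleNodes(pr, idx, fraction = 0.05, seed = 77)
  expect_identical(s1, s2)
  s3 <- sampleNodes(pr, idx, fraction = 0.05, seed = 78)
  expect_false(identical(s1$pmid, s3$pmid))

  # whole population, deterministic ascending-PMID order, no RNG touched
  sAll <- sampleNodes(pr, idx, fraction = 1)
  expect_identical(sAll$pmid, nodes(g))
  expect_identical(sAll$citation_count,
                   unname(citationCount(idx)))

  expect_error(sampleNodes(pr, idx, fraction = 0), "fraction")
  expect_error(sampleNodes(pr, idx, fraction = 1.2), "fraction")
})

test_that("sampleNodes can restrict to parsed source articles", {
  g <- citationGraph(simulateCorpus(200, seed = 4))
  pr <- pageRank(g)
  idx <- invertedIndex(g)
  s <- sampleNodes(pr, idx, fraction = 1, sourcesOnly = TRUE, graph = g)
  expect_identical(sort(s$pmid), sort(nodes(g)[unname(isSource(g))]))
})

test_that("finite-population sample size reproduces the standard values", {
  # 95% confidence, 5% margin, p = 0.5 over a multi-million population
  expect_identical(requiredSampleSize(6293819, 0.95, 0.05, 0.5), 385L)
  # infinite-population asymptote: ceil(384.16) = 385
  expect_identical(requiredSampleSize(1e15, 0.95, 0.05, 0.5), 385L)
  # small population: finite-population correction bites (closed form
  # 100*x/(99*0.0025 + x), x = 1.959964^2 * 0.25 -> 79.5 -> 80)
  expect_identical(requiredSampleSize(100, 0.95, 0.05, 0.5), 80L)
})

test_that("required sample size is monotone in population and margin", {
  pops <- c(10, 100, 1000, 1e5, 1e7)
  ns <- vapply(pops, requiredSampleSize, integer(1))
  expect_true(all(diff(ns) >= 0L))
  margins <- c(0.01, 0.02, 0.05, 0.1)
  ns2 <- vapply(margins, function(m) requiredSampleSize(1e6, margin = m),
                integer(1))
  expect_true(all(diff(ns2) <= 0L))
  expect_error(requiredSampleSize(0), "population")
  expect_error(requiredSampleSize(100, confidence = 1), "confidence")
  expect_error(requiredSampleSize(100, margin = 0), "margin")
})

test_that("correlateRanks recovers exact fits on collinear data", {
  df <- data.frame(citation_count = 1:6, pagerank = 2 * (1:6) + 1)
  # a perfect fit makes lm's summary grumble; the point is the exactness
  rep <- suppressWarnings(correlateRanks(df))
  expect_equal(rep@pearsonR, 1, tolerance = 1e-12)
  expect_equal(rep@slope, 2, tolerance = 1e-12)
  expect_equal(rep@intercept, 1, tolerance = 1e-12)

  dfn <- data.frame(citation_count = 1:5, pagerank = -(1:5))
  expect_equal(suppressWarnings(correlateRanks(dfn))@pearsonR, -1,
               tolerance = 1e-12)
})

test_that("correlateRanks matches a from-scratch least-squares computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 3, 4, 5)
  # closed-form OLS and Pearson moments, computed independently
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  r <- sxy / sqrt(sxx * syy)
  tstat <- r * sqrt((length(x) - 2) / (1 - r^2))
  pval <- 2 * stats::pt(abs(tstat), df = length(x) - 2, lower.tail = FALSE)

  rep <- correlateRanks(data.frame(citation_count = x, pagerank = y))
  expect_equal(rep@pearsonR, r, tolerance = 1e-12)
  expect_equal(rep@slope, slope, tolerance = 1e-12)
  expect_equal(rep@intercept, intercept, tolerance = 1e-12)
  expect_equal(rep@rSquared, r^2, tolerance = 1e-14)
  expect_equal(rep@pCorrelation, pval, tolerance = 1e-10)
  expect_equal(rep@pRegression, pval, tolerance = 1e-10)
  expect_identical(rep@n, 5L)
})

test_that("correlateRanks rejects degenerate samples", {
  expect_error(correlateRanks(data.frame(citation_count = 1:2,
                                         pagerank = 2:3)),
               "insufficient")
  expect_error(correlateRanks(data.frame(citation_count = c(1, 1, 1),
                                         pagerank = 1:3)),
               "constant")
})

test_that("correlation reports serialise to flat JSON", {
  dir <- withr::local_tempdir()
  rep <- correlateRanks(data.frame(citation_count = 1:5,
                                   pagerank = c(2, 1, 3, 4, 5)))
  f <- file.path(dir, "report.json")
  writeReport(rep, f, seed = 42, fraction = 0.05)
  obj <- jsonlite::read_json(f)
  expect_equal(obj$pearson_r, rep@pearsonR, tolerance = 1e-12)
  expect_equal(obj$r_squared, rep@rSquared, tolerance = 1e-12)
  expect_identical(obj$seed, 42L)
  expect_identical(obj$direction, "pagerank ~ citation_count")
})

test_that("topRanked orders by descending PageRank with PMID tiebreak", {
  g <- twoCycleGraph()
  pr <- pageRank(g)
  idx <- invertedIndex(g)
  tab <- topRanked(pr, idx, 2)
  expect_identical(tab$pmid, c(1L, 2L))
  expect_identical(tab$rank, 1:2)

  star <- starGraph(5)
  t1 <- topRanked(pageRank(star), invertedIndex(star), 1)
  expect_identical(t1$pmid, 1L)
  expect_identical(t1$citation_count, 5L)

  expect_warning(tBig <- topRanked(pr, idx, 10), "truncat")
  expect_identical(nrow(tBig), 2L)
})

test_that("top tables are deterministic across repeated runs", {
  sim <- simulateCorpus(300, seed = 55)
  g <- citationGraph(sim)
  idx <- invertedIndex(g)
  t1 <- topRanked(pageRank(g), idx, 10)
  t2 <- topRanked(pageRank(g), idx, 10)
  expect_identical(t1, t2)
  expect_true(all(diff(t1$pagerank) <= 0))
  dir <- withr::local_tempdir()
  f <- file.path(dir, "top.tsv")
  writeRankTable(t1, f)
  expect_identical(readLines(f)[1], "rank\tpmid\tpagerank\tcitation_count")
  expect_identical(length(readLines(f)), 11L)
})
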