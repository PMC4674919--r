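test_that("symmetric graphs get their analytic PageRank", {
  # single node: whole mass, immediate convergence
  pr1 <- pageRank(buildGraph(list(articleRecord(9))))
  expect_equal(unname(scores(pr1)), 1, tolerance = 1e-12)
  expect_lte(iterations(pr1), 2L)
  expect_true(converged(pr1))

  # two nodes citing each other: 0.5 each
  expect_equal(unname(scores(pageRank(twoCycleGraph()))), c(0.5, 0.5),
               tolerance = 1e-12)

  # K-node directed cycle: uniform 1/K
  for (k in c(3L, 7L)) {
    expect_equal(unname(scores(pageRank(kCycleGraph(k)))), rep(1 / k, k),
                 tolerance = 1e-12)
  }
})

test_that("power iteration matches the dense stationary solve", {
  # hand-built shapes: chain, star, isolated node beside a 2-cycle
  for (g in list(chainGraph(), starGraph(5), isolatedPlusCycleGraph())) {
    expect_equal(scores(pageRank(g, tightParams())),
                 scores(pageRankExact(g)), tolerance = 1e-10)
  }
})

test_that("power iteration agrees with the oracle on many seeded Price graphs", {
  graphs <- smallPriceGraphs(100L)
  worst <- 0
  for (g in graphs) {
    expect_lte(numNodes(g), 50L)
    err <- max(abs(scores(pageRank(g, tightParams())) -
                     scores(pageRankExact(g))))
    worst <- max(worst, err)
  }
  expect_lt(worst, 1e-8)
})

test_that("the exact solver refuses graphs beyond its dense bound", {
  g <- citationGraph(simulateCorpus(300, seed = 2))
  expect_error(pageRankExact(g, maxNodes = 200L), "refusing")
})

test_that("scores stay normalised and above the teleport floor mid-run", {
  g <- citationGraph(simulateCorpus(100, seed = 6))
  n <- numNodes(g)
  for (k in 1:5) {
    pr <- suppressWarnings(
      pageRank(g, pageRankParams(epsilon = 1e-300, maxIterations = k)))
    expect_identical(iterations(pr), k)
    expect_lt(abs(sum(scores(pr)) - 1), 1e-9)
    expect_gte(min(scores(pr)), (1 - 0.85) / n - 1e-12)
  }
})

test_that("teleport-dominated limit is uniform and the star hub dominates", {
  g <- citationGraph(simulateCorpus(40, seed = 12))
  n <- numNodes(g)
  prLow <- pageRank(g, pageRankParams(d = 1e-6, epsilon = 1e-12,
                                      maxIterations = 100L))
  expect_lt(max(abs(scores(prLow) - 1 / n)), 1e-4)

  star <- starGraph(5)
  s <- scores(pageRank(star))
  expect_true(all(s[["1"]] > s[names(s) != "1"]))
})

test_that("relabeling nodes permutes PageRank scores identically", {
  recs <- articleRecords(simulateCorpus(50, seed = 31))
  relabel <- function(p) 2L * p + 5L
  recs2 <- lapply(recs, function(r) articleRecord(relabel(r@pmid),
                                                  relabel(r@outbound)))
  s1 <- scores(pageRank(buildGraph(recs), tightParams()))
  s2 <- scores(pageRank(buildGraph(recs2), tightParams()))
  expect_equal(unname(s2[as.character(relabel(as.integer(names(s1))))]),
               unname(s1), tolerance = 1e-12)
})

test_that("convergence metadata is honest: monotone residuals, epsilon met", {
  g <- citationGraph(simulateCorpus(200, seed = 17))
  pr <- pageRank(g)
  tr <- residualTrace(pr)
  expect_identical(length(tr), as.integer(iterations(pr)))
  expect_true(all(diff(tr) <= 1e-15))
  expect_true(converged(pr))
  expect_lt(residual(pr), 1e-5)

  # iteration cap reached: returned anyway, flagged, with a warning
  expect_warning(prCap <- pageRank(g, pageRankParams(epsilon = 1e-300,
                                                     maxIterations = 3L)),
                 "did not converge")
  expect_false(converged(prCap))
  expect_identical(iterations(prCap), 3L)
})

test_that("empty graphs are rejected", {
  g0 <- buildGraph(list())
  expect_error(pageRank(g0), "empty")
  expect_error(pageRankExact(g0), "empty")
})

test_that("an independent graph library agrees on a dangling-free graph", {
  skip_if_not_installed("igraph")
  # strongly connected, no dangling nodes, so all conventions coincide
  recs <- list(articleRecord(1, c(2, 3)), articleRecord(2, c(3, 4)),
               articleRecord(3, 4), articleRecord(4, 1))
  g <- buildGraph(recs)
  ig <- igraph::graph_from_edgelist(apply(edges(g), 2, as.character))
  ref <- igraph::page_rank(ig, damping = 0.85)$vector
  mine <- scores(pageRank(g, tightParams()))
  expect_equal(unname(mine[names(ref)]), unname(ref), tolerance = 1e-8)
})

test_that("score TSV files are deterministic and round-trip to printed precision", {
  dir <- withr::local_tempdir()
  g <- twoCycleGraph()
  pr <- pageRank(g)
  idx <- invertedIndex(g)
  f <- file.path(dir, "scores.tsv")
  writeScores(pr, idx, f)
  expect_identical(readLines(f), c("1\t5.000000e-01\t1", "2\t5.000000e-01\t1"))

  g2 <- citationGraph(simulateCorpus(80, seed = 23))
  pr2 <- pageRank(g2)
  idx2 <- invertedIndex(g2)
  f2 <- file.path(dir, "s2.tsv")
  writeScores(pr2, idx2, f2)
  back <- readScores(f2)
  expect_equal(back$pagerank[match(as.integer(names(scores(pr2))), back$pmid)],
               unname(scores(pr2)), tolerance = 1e-6)
  # descending pagerank, PMID tiebreak; identical bytes on rerun
  expect_true(all(diff(back$pagerank) <= 0))
  f3 <- file.path(dir, "s3.tsv")
  writeScores(pageRank(g2), idx2, f3)
  expect_identical(readLines(f3), readLines(f2))
})
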