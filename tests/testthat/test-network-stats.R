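netFromDb <- function(db, listGenes, start, d = 10L) {
  g <- buildBasicGraph(db, geneList(listGenes))
  expandNetwork(g, dNeighbours(g, start, d))
}

test_that("the network score is the mean citation count per edge", {
  g <- buildBasicGraph(iisDb(), iisList())
  net <- expandNetwork(g, dNeighbours(g, "daf-16", 1))
  expect_equal(round(networkScore(net), 2), 23.33)

  db <- dbFromEdges("a", "b")
  expect_equal(networkScore(netFromDb(db, c("a", "b"), "a")), 1.0)

  db <- dbFromEdges(c("a", "b"), c("b", "c"), cit = c(3L, 5L))
  expect_equal(networkScore(netFromDb(db, c("a", "b", "c"), "a")), 4.0)

  empty <- new("GeneNetwork",
               nodes = data.frame(gene = "a", isList = TRUE,
                                  isLinker = FALSE),
               edges = linkernet:::emptyEdgeFrame(),
               startGene = NA_character_, depth = NA_integer_)
  expect_error(networkScore(empty), "undefined")
})

test_that("permutation p-value is 1 on degenerate nulls and matches enumeration", {
  # all citations equal: every simulated score equals the observed score
  db <- dbFromEdges(c("a", "b", "c"), c("b", "c", "d"))
  net <- netFromDb(db, c("a", "b"), "a")
  expect_equal(scorePvalue(net, db, nSim = 200, seed = 1), 1.0)

  # tiny db, single-edge network with the unique 9-citation edge: exact 1/4
  db <- dbFromEdges(c("a", "c", "e", "g"), c("b", "d", "f", "h"),
                    cit = c(9L, 1L, 1L, 1L))
  net <- netFromDb(db, c("a", "b"), "a")
  exact <- oracleScorePvalue(c(9, 1, 1, 1), 1L, networkScore(net))
  expect_equal(exact, 1 / 4)
  mc <- scorePvalue(net, db, nSim = 10000, seed = 42)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(mc - exact), 3 * se)

  # reproducibility and the add-one option
  expect_identical(scorePvalue(net, db, nSim = 500, seed = 9),
                   scorePvalue(net, db, nSim = 500, seed = 9))
  expect_gt(scorePvalue(net, db, nSim = 100, seed = 9, addOne = TRUE), 0)
})

test_that("a network larger than the database cannot be simulated", {
  db <- dbFromEdges("a", "b")
  # a 2-edge network from a different database vs the 1-edge db
  db2 <- dbFromEdges(c("a", "b"), c("b", "c"))
  net2 <- netFromDb(db2, c("a", "b", "c"), "a")
  expect_error(scorePvalue(net2, db, nSim = 10, seed = 1), "cannot simulate")
})

test_that("the connectivity-preserving null variant also works", {
  db <- dbFromEdges(c("a", "b", "c", "d"), c("b", "c", "d", "e"),
                    cit = c(5L, 1L, 1L, 1L))
  net <- netFromDb(db, c("a", "b"), "a")
  p <- scorePvalue(net, db, nSim = 300, seed = 4, method = "connected")
  expect_true(p >= 0 && p <= 1)
})

test_that("the induced 1-neighbourhood follows its set definition", {
  db <- dbFromEdges(c("a", "b"), c("b", "c"))
  net <- netFromDb(db, c("a", "b"), "a")
  expect_equal(inducedNeighbourhood(net, db), c("a", "b", "c"))
  expect_equal(inducedNeighbourhood(net, db, includeNetwork = FALSE), "c")

  # an isolated component is its own closure
  db <- dbFromEdges(c("a", "x"), c("b", "y"))
  net <- netFromDb(db, c("a", "b"), "a")
  expect_equal(inducedNeighbourhood(net, db), c("a", "b"))

  # star: hub h with leaves x1..x5, network {h, x1} reaches every leaf
  db <- dbFromEdges(rep("h", 5), paste0("x", 1:5))
  net <- netFromDb(db, c("h", "x1"), "h", d = 1L)
  expect_equal(inducedNeighbourhood(net, db),
               sort(c("h", paste0("x", 1:5))))
})

test_that("hypergeometric pmf matches exhaustive enumeration and normalizes", {
  expect_equal(hypergeomPmf(3, 10, 10, 3), 1.0)
  for (N in c(6, 9, 12)) for (m in c(2, 4, N)) for (l in c(2, 5)) {
    for (k in 0:min(m, l))
      expect_equal(hypergeomPmf(k, N, m, l), oraclePmf(N, m, l, k),
                   tolerance = 1e-12)
  }
  for (N in c(10, 57, 200)) for (m in c(0, 3, N %/% 2)) for (l in c(1, N %/% 3)) {
    ks <- 0:min(m, l)
    expect_equal(sum(hypergeomPmf(ks, N, m, l)), 1.0, tolerance = 1e-12)
  }
  expect_error(hypergeomPmf(5, 10, 4, 4), "out of range")
  expect_error(hypergeomPmf(1, 10, 11, 4), "neighbourhood")
})

test_that("the list p-value is the upper hypergeometric tail", {
  expect_equal(listPvalue(0, 50, 10, 5), 1.0)
  # single-term tail at the top of the support
  expect_equal(listPvalue(4, 10, 4, 5), hypergeomPmf(4, 10, 4, 5))
  # term-by-term summation oracle
  terms <- vapply(4:6, function(k) oraclePmf(20, 6, 8, k), numeric(1))
  expect_equal(listPvalue(4, 20, 6, 8), sum(terms), tolerance = 1e-12)
  # monotone non-increasing in k
  ps <- vapply(0:6, listPvalue, numeric(1), universe = 40,
               neighbourhood = 10, listSize = 6)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("the list p-value is super-uniform under a uniformly drawn list", {
  N <- 80L; m <- 12L; l <- 10L
  set.seed(202)
  ks <- stats::rhyper(10000, m, N - m, l)
  ps <- vapply(ks, listPvalue, numeric(1), universe = N,
               neighbourhood = m, listSize = l)
  for (alpha in c(0.01, 0.05))
    expect_lte(mean(ps <= alpha), alpha)
})

test_that("evaluateNetwork assembles all statistics consistently", {
  db <- iisDb()
  gl <- iisList()
  cfg0 <- searchConfig(maxDepth = 1, nSim = 0, seed = 5)
  an <- analyzeNetworks(db, gl, cfg0)
  s <- statsList(an)[[1]]
  expect_equal(round(s@score, 2), 23.33)
  expect_true(is.na(s@scorePvalue))        # permutation test skipped
  expect_equal(s@neighbourhoodSize, 6L)
  expect_equal(s@listOverlap, 5L)
  expect_true(s@listPvalue > 0 && s@listPvalue <= 1)

  # all-unit-citation database: score exactly 1, score p-value exactly 1
  db1 <- dbFromEdges(c("a", "b", "c"), c("b", "c", "d"))
  gl1 <- geneList(c("a", "b", "c", "d"))
  an1 <- analyzeNetworks(db1, gl1, searchConfig(maxDepth = 2, nSim = 300,
                                                seed = 8))
  for (s in statsList(an1)) {
    expect_identical(s@score, 1.0)
    expect_identical(s@scorePvalue, 1.0)
  }
})
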