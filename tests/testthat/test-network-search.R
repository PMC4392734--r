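pathGraph <- function() {
  db <- dbFromEdges(c("a", "b", "c"), c("b", "c", "d"))
  buildBasicGraph(db, geneList(c("a", "b", "c", "d")))
}

test_that("d-neighbours count both edge kinds as single steps", {
  g <- pathGraph()
  expect_equal(dNeighbours(g, "c", 0), "c")
  expect_equal(dNeighbours(g, "a", 2), c("a", "b", "c"))
  expect_equal(dNeighbours(g, "a", 3), c("a", "b", "c", "d"))
  expect_error(dNeighbours(g, "zz", 1), "zz")

  # an indirect edge is one step, and the linker is not a neighbour here
  db <- dbFromEdges(c("a", "x"), c("x", "b"))
  g2 <- buildBasicGraph(db, geneList(c("a", "b")))
  expect_equal(dNeighbours(g2, "a", 1), c("a", "b"))
})

test_that("d-neighbours agree with breadth-first search on random graphs", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(5:12, 1)
    sim <- generateDatabase(n, runif(1, 0.2, 0.5),
                            citationSpec("constant"), seed = seed + 50)
    gl <- generateList(sim$db, sim$truth,
                       listSize = sample(3:min(8, n), 1), seed = seed + 99)
    g <- buildBasicGraph(sim$db, gl)
    adj <- oracleAdjacency(sim$db, members(gl))
    for (start in g@nodes)
      for (d in 0:3)
        expect_equal(dNeighbours(g, start, d),
                     if (d == 0) start else oracleBfs(adj, start, d))
  }
})

test_that("expansion replaces indirect edges by their legs plus linker nodes", {
  db <- dbFromEdges("a", "b")
  g <- buildBasicGraph(db, geneList(c("a", "b")))
  net <- expandNetwork(g, c("a", "b"))
  expect_equal(nrow(networkNodes(net)), 2L)
  expect_equal(nrow(networkEdges(net)), 1L)

  db <- dbFromEdges(c("a", "x"), c("x", "b"), cit = c(2L, 3L))
  g <- buildBasicGraph(db, geneList(c("a", "b")))
  net <- expandNetwork(g, c("a", "b"))
  nd <- networkNodes(net)
  expect_equal(nd$gene, c("a", "b", "x"))
  expect_equal(nd$isLinker, c(FALSE, FALSE, TRUE))
  expect_equal(networkEdges(net)$citations, c(2L, 3L))

  # disconnected member sets violate the contract
  db <- dbFromEdges(c("a", "c"), c("b", "d"))
  g <- buildBasicGraph(db, geneList(c("a", "b", "c", "d")))
  expect_error(expandNetwork(g, c("a", "c")), "not connected")
})

test_that("the worked-example expansion yields 6 nodes and 6 edges", {
  g <- buildBasicGraph(iisDb(), iisList())
  net <- expandNetwork(g, dNeighbours(g, "daf-16", 1))
  expect_equal(nrow(networkNodes(net)), 6L)
  expect_equal(nrow(networkEdges(net)), 6L)
  expect_true("daf-2" %in% networkNodes(net)$gene[networkNodes(net)$isLinker])
})

test_that("disjoint components give one network each, in list order semantics", {
  db <- dbFromEdges(c("a", "c"), c("b", "d"))
  g <- buildBasicGraph(db, geneList(c("a", "b", "c", "d")))
  nets <- findNetworks(g, searchConfig(maxDepth = 1, seed = 1))
  expect_length(nets, 2L)
  sets <- lapply(nets, function(n) networkNodes(n)$gene)
  expect_setequal(vapply(sets, paste, character(1), collapse = ","),
                  c("a,b", "c,d"))
})

test_that("depth passes nest and never emit duplicate node sets", {
  # one five-gene component: largest depth covers it, smaller depths add
  # only strictly different (smaller) node sets
  db <- dbFromEdges(c("a", "b", "c", "d"), c("b", "c", "d", "e"))
  g <- buildBasicGraph(db, geneList(c("a", "b", "c", "d", "e")))
  nets <- findNetworks(g, searchConfig(maxDepth = 4, seed = 1))
  sets <- lapply(nets, function(n) sort(networkNodes(n)$gene))
  expect_equal(anyDuplicated(vapply(sets, paste, character(1),
                                    collapse = ",")), 0L)
  expect_true(any(vapply(sets, length, integer(1)) == 5L))
  # nesting of the start gene's neighbourhood in d
  for (d in 1:3)
    expect_true(all(dNeighbours(g, "a", d) %in% dNeighbours(g, "a", d + 1)))
  # every emitted network is internally connected (validity already
  # enforces it; validObject would error otherwise)
  for (n in nets) expect_true(validObject(n))
})

test_that("depth-unlimited discovery equals union-find connected components", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(6:12, 1)
    sim <- generateDatabase(n, runif(1, 0.1, 0.35),
                            citationSpec("constant"), seed = seed + 500)
    gl <- generateList(sim$db, sim$truth,
                       listSize = sample(4:min(10, n), 1), seed = seed + 777)
    g <- buildBasicGraph(sim$db, gl)
    D <- max(2L, length(g@nodes))
    nets <- findNetworks(g, searchConfig(maxDepth = D, seed = 1))
    got <- lapply(nets[vapply(nets, function(n) n@depth == D, logical(1))],
                  function(n) sort(networkNodes(n)$gene[networkNodes(n)$isList]))
    adj <- oracleAdjacency(sim$db, members(gl))
    want <- Filter(function(cc) length(cc) >= 2, oracleComponents(adj))
    expect_setequal(vapply(got, paste, character(1), collapse = ","),
                    vapply(want, paste, character(1), collapse = ","))
  }
})

test_that("degenerate inputs: single-gene lists yield no networks", {
  db <- dbFromEdges("a", "b")
  g <- buildBasicGraph(db, geneList("a"))
  expect_length(findNetworks(g, searchConfig(seed = 3)), 0L)
})
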