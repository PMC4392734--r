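test_that("reading handles empty, duplicated and predicted rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  hdr <- "gene_a\tgene_b\tinteraction_class\tevidence_class\tpublications"

  writeLines(hdr, f)
  expect_equal(nrow(readInteractionTable(f)), 0L)

  writeLines(c(hdr,
    "a\tb\tgenetic\texperimental\tP1",
    "b\ta\tphysical\texperimental\tP2",
    "a\tc\tgenetic\tpredicted\t"), f)
  rec <- readInteractionTable(f)
  expect_equal(nrow(rec), 3L)          # dedup happens at build time
  expect_equal(rec$publications[[3]], character(0))
  expect_equal(rec$evidenceClass[3], "predicted")
})

test_that("malformed tables fail fast with line numbers, or skip when lenient", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene_a\tgene_b\tevidence_class\tpublications", "a\tb\texperimental\tP1"), f)
  expect_error(readInteractionTable(f), "interaction_class")

  hdr <- "gene_a\tgene_b\tinteraction_class\tevidence_class\tpublications"
  writeLines(c(hdr,
    "a\tb\tgenetic\texperimental\tP1",
    "a\tc\tweird\texperimental\tP2"), f)
  expect_error(readInteractionTable(f), "line 3.*weird")
  expect_warning(rec <- readInteractionTable(f, lenient = TRUE), "line 3")
  expect_equal(nrow(rec), 1L)

  # an experimental interaction must carry at least one publication
  writeLines(c(hdr, "a\tb\tgenetic\texperimental\t"), f)
  expect_error(readInteractionTable(f), "without supporting publications")
})

test_that("evidence filtering keeps exactly the experimental records", {
  rec <- makeRecords(letters[1:5], letters[2:6],
                     evidence = c("experimental", "predicted",
                                  "experimental", "predicted",
                                  "experimental"))
  expect_equal(filterExperimental(rec)$geneA, c("a", "c", "e"))
  expect_equal(filterExperimental(rec[rec$evidenceClass ==
                                        "experimental", ])$geneA,
               c("a", "c", "e"))
  expect_equal(nrow(filterExperimental(
    makeRecords("a", "b", evidence = "predicted"))), 0L)
})

test_that("building merges duplicate pairs and drops self-interactions", {
  rec <- rbind(makeRecords("a", "b", pubPrefix = "X"),
               makeRecords("b", "a", pubPrefix = "Y"),
               makeRecords("c", "c", pubPrefix = "Z"))
  db <- buildInteractionDb(rec)
  e <- dbEdges(db)
  expect_equal(nrow(e), 1L)
  expect_equal(e$citations, 2L)        # union of the two publication sets
  expect_equal(dbGenes(db), c("a", "b"))

  # merging is order-independent
  set.seed(1)
  rec2 <- makeRecords(c("a", "a", "b", "c"), c("b", "c", "c", "d"),
                      cit = c(2L, 1L, 3L, 1L))
  db1 <- buildInteractionDb(rec2)
  db2 <- buildInteractionDb(rec2[sample(nrow(rec2)), ])
  expect_identical(dbEdges(db1), dbEdges(db2))
  expect_true(all(dbEdges(db1)$citations ==
                    lengths(dbEdges(db1)$publications)))
})

test_that("the worked-example database has the published citation profile", {
  db <- iisDb()
  e <- dbEdges(db)
  expect_equal(nrow(e), 6L)
  expect_equal(sort(e$citations), c(1L, 1L, 1L, 1L, 1L, 135L))
})

test_that("universe size defaults to the gene count and rejects undersized overrides", {
  rec <- makeRecords(c("a", "b"), c("b", "c"))
  expect_equal(universeSize(buildInteractionDb(rec)), 3L)
  expect_equal(universeSize(buildInteractionDb(rec, universeSize = 100)),
               100L)
  expect_error(buildInteractionDb(rec, universeSize = 2), "smaller")
})

test_that("a database round-trips through the table dialect", {
  rec <- makeRecords(c("a", "a", "b", "a"), c("b", "c", "c", "b"),
                     cit = c(2L, 1L, 5L, 3L),
                     class = c("genetic", "physical", "genetic",
                               "physical"))
  db <- buildInteractionDb(rec, universeSize = 10)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeInteractionTable(db, f)
  back <- buildInteractionDb(readInteractionTable(f), universeSize = 10)
  expect_identical(dbEdges(db), dbEdges(back))
  expect_identical(dbGenes(db), dbGenes(back))
})

test_that("gene lists preserve order, drop duplicates and ignore comments", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# header comment", "z", "", "a", "z", "  m  "), f)
  gl <- readGeneList(f)
  expect_equal(members(gl), c("z", "a", "m"))
  expect_equal(members(geneList(c("b", "b", "a"))), c("b", "a"))
})
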