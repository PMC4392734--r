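# In-code fixtures shared across test files.

# Quick record table: one row per interaction, publications minted so that
# each row carries `cit` distinct publication identifiers.
makeRecords <- function(geneA, geneB, cit = 1L,
                        evidence = "experimental",
                        class = "genetic", pubPrefix = "T") {
  n <- length(geneA)
  cit <- rep_len(cit, n)
  evidence <- rep_len(evidence, n)
  class <- rep_len(class, n)
  pubs <- mapply(function(i, k) {
    if (k == 0L) character(0) else sprintf("%s%03d_%03d", pubPrefix, i,
                                           seq_len(k))
  }, seq_len(n), cit, SIMPLIFY = FALSE)
  out <- data.frame(geneA = geneA, geneB = geneB,
                    interactionClass = class, evidenceClass = evidence,
                    stringsAsFactors = FALSE)
  out$publications <- pubs
  out
}

# Database straight from an edge list with citation counts.
dbFromEdges <- function(geneA, geneB, cit = 1L, universeSize = NULL) {
  buildInteractionDb(makeRecords(geneA, geneB, cit),
                     universeSize = universeSize)
}

iisDb <- function() {
  buildInteractionDb(filterExperimental(
    readInteractionTable(iisExample()$db)))
}

iisList <- function() readGeneList(iisExample()$genes)
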