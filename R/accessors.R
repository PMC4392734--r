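#' Accessors for linkernet classes
#'
#' Small accessor functions so user code never touches slots directly.
#'
#' @param x an object of the class named by each accessor.
#' @return \code{dbEdges}: the canonical edge data.frame; \code{dbGenes}:
#'   character vector of database genes; \code{universeSize}: integer N;
#'   \code{members}: the gene list members in input order;
#'   \code{networkNodes} / \code{networkEdges}: node and edge tables of a
#'   network; \code{networks} / \code{statsList}: the sorted network and
#'   statistics lists of an analysis; \code{resultTable}: the result
#'   data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
dbEdges <- function(x) { stopifnot(is(x, "InteractionDb")); x@edges }

#' @rdname accessors
#' @export
dbGenes <- function(x) { stopifnot(is(x, "InteractionDb")); x@genes }

#' @rdname accessors
#' @export
universeSize <- function(x) {
  if (is(x, "InteractionDb") || is(x, "NetworkAnalysis")) return(x@universeSize)
  stop("no universeSize for class ", class(x))
}

#' @rdname accessors
#' @export
members <- function(x) { stopifnot(is(x, "GeneList")); x@members }

#' @rdname accessors
#' @export
networkNodes <- function(x) { stopifnot(is(x, "GeneNetwork")); x@nodes }

#' @rdname accessors
#' @export
networkEdges <- function(x) { stopifnot(is(x, "GeneNetwork")); x@edges }

#' @rdname accessors
#' @export
networks <- function(x) { stopifnot(is(x, "NetworkAnalysis")); x@networks }

#' @rdname accessors
#' @export
statsList <- function(x) { stopifnot(is(x, "NetworkAnalysis")); x@stats }

#' @rdname accessors
#' @export
resultTable <- function(x) { stopifnot(is(x, "NetworkAnalysis")); x@table }

setMethod("show", "InteractionDb", function(object) {
  cat(sprintf(
    "InteractionDb: %d edges among %d genes (universe N = %d)\n",
    nrow(object@edges), length(object@genes), object@universeSize))
  if (nrow(object@edges)) {
    cit <- object@edges$citations
    cat(sprintf("  citations per edge: min %d, median %s, max %d\n",
                min(cit), format(stats::median(cit)), max(cit)))
  }
})

setMethod("show", "GeneList", function(object) {
  cat(sprintf("GeneList of %d genes (source: %s)\n",
              length(object@members), object@sourcePath))
  if (length(object@members))
    cat("  ", paste(head(object@members, 6L), collapse = ", "),
        if (length(object@members) > 6L) ", ..." else "", "\n", sep = "")
})

setMethod("show", "BasicGraph", function(object) {
  cat(sprintf(
    "BasicGraph: %d list genes in database, %d direct and %d indirect edges\n",
    length(object@nodes), nrow(object@directEdges),
    nrow(object@indirectEdges)))
  if (length(object@missingGenes))
    cat(sprintf("  %d list genes not found in the database\n",
                length(object@missingGenes)))
})

setMethod("show", "GeneNetwork", function(object) {
  nl <- sum(object@nodes$isList)
  cat(sprintf(
    "GeneNetwork: %d nodes (%d list, %d linker), %d edges%s\n",
    nrow(object@nodes), nl, sum(object@nodes$isLinker), nrow(object@edges),
    if (!is.na(object@startGene))
      sprintf(" [start %s, depth %d]", object@startGene, object@depth)
    else ""))
})

setMethod("show", "NetworkStats", function(object) {
  cat(sprintf(
    "NetworkStats: score %.4g, score p %s (n_sim %d), |N1| %d, k %d, list p %.4g\n",
    object@score,
    if (is.na(object@scorePvalue)) "NA" else format(object@scorePvalue),
    object@nSim, object@neighbourhoodSize, object@listOverlap,
    object@listPvalue))
})

setMethod("show", "NetworkAnalysis", function(object) {
  cat(sprintf(
    "NetworkAnalysis: %d networks from a %d-gene list (universe N = %d)\n",
    length(object@networks), length(object@geneList@members),
    object@universeSize))
  if (nrow(object@table)) {
    cat("Top networks:\n")
    print(head(object@table[, c("rank", "nodes", "edges", "score",
                                "p_score", "p_list")], 5L),
          row.names = FALSE)
  }
})

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d planted network(s), background n = %s genes\n",
              length(object@planted),
              format(object@backgroundParams$nGenes)))
})
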