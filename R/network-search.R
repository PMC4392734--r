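#' Search configuration
#'
#' @param maxDepth maximum iteration depth D: the number of steps allowed
#'   from a start gene (one direct or indirect edge = one step). Default 2.
#' @param minListGenes smallest number of list genes a reported network
#'   must contain; default 2 (singletons are never reported).
#' @param nSim number of permutation draws for the score p-value
#'   (default 10000; 0 skips the permutation test).
#' @param seed random seed (mandatory).
#' @return a [SearchConfig-class].
#' @export
searchConfig <- function(maxDepth = 2L, minListGenes = 2L, nSim = 10000L,
                         seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  new("SearchConfig", maxDepth = asCount(maxDepth, "maxDepth"),
      minListGenes = asCount(minListGenes, "minListGenes"),
      nSim = asCount(nSim, "nSim"), seed = asCount(seed, "seed"))
}

#' Discover networks by depth-limited search
#'
#' For each depth d from \code{maxDepth} down to 1, the search walks the
#' candidate list in its input order; for each list gene that is present
#' in the graph and not yet absorbed into a network in the current depth
#' pass, it collects the gene's d-neighbours, expands them into a network
#' (replacing indirect edges by their legs plus linker nodes), and emits
#' the network if it contains at least \code{minListGenes} list genes and
#' its exact node set (list members plus linkers) has not been emitted
#' before. Consumption resets between depth passes; duplicate node sets
#' across passes are suppressed, so lower depths contribute only genuinely
#' smaller networks.
#'
#' @param g a [BasicGraph-class].
#' @param cfg a [SearchConfig-class].
#' @param list optional [GeneList-class] giving the iteration order;
#'   defaults to the list the graph was built from.
#' @return list of [GeneNetwork-class], sorted by network score
#'   (descending), ties broken by node count (descending) then by the
#'   lexicographically smallest gene. (The full tie-break including the
#'   list p-value is applied by [analyzeNetworks()], which has the
#'   statistics at hand.)
#' @examples
#' db <- buildInteractionDb(filterExperimental(
#'   readInteractionTable(iisExample()$db)))
#' gl <- readGeneList(iisExample()$genes)
#' g <- buildBasicGraph(db, gl)
#' nets <- findNetworks(g, searchConfig(maxDepth = 1, seed = 1))
#' nets[[1]]
#' @export
findNetworks <- function(g, cfg, list = NULL) {
  stopifnot(is(g, "BasicGraph"), is(cfg, "SearchConfig"))
  ord <- if (is.null(list)) g@listGenes else {
    stopifnot(is(list, "GeneList")); list@members
  }
  ord <- ord[ord %in% g@nodes]
  out <- list()
  seen <- character(0)
  for (d in seq.int(cfg@maxDepth, 1L)) {
    consumed <- character(0)
    for (start in ord) {
      if (start %in% consumed) next
      memb <- dNeighbours(g, start, d)
      if (length(memb) < cfg@minListGenes) next
      consumed <- union(consumed, memb)
      net <- expandNetwork(g, memb, startGene = start, depth = d)
      key <- paste(net@nodes$gene, collapse = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      out[[length(out) + 1L]] <- net
    }
  }
  if (!length(out)) return(out)
  score <- vapply(out, networkScore, numeric(1))
  nn <- vapply(out, function(n) nrow(n@nodes), integer(1))
  mg <- vapply(out, function(n) n@nodes$gene[1L], character(1))
  out[order(-score, -nn, mg, method = "radix")]
}
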