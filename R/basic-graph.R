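#' Build the candidate-list graph G
#'
#' Constructs the basic graph over the candidate list: a node for every
#' list gene present in the database, a \emph{direct} edge for every
#' database interaction joining two list genes, and an \emph{indirect}
#' edge for every length-2 database path joining two list genes through a
#' single non-list \emph{linker} gene. Linker chains (two or more
#' consecutive non-list genes) are never edges. A pair may carry both a
#' direct edge and several indirect edges; all linkers are retained.
#'
#' List genes absent from the database are recorded in the graph's
#' diagnostics (\code{missingGenes}) and excluded from the node set.
#'
#' @param db an [InteractionDb-class].
#' @param list a [GeneList-class] (non-empty).
#' @return a [BasicGraph-class].
#' @examples
#' db <- buildInteractionDb(filterExperimental(
#'   readInteractionTable(iisExample()$db)))
#' gl <- readGeneList(iisExample()$genes)
#' g <- buildBasicGraph(db, gl)
#' g
#' @export
buildBasicGraph <- function(db, list) {
  stopifnot(is(db, "InteractionDb"), is(list, "GeneList"))
  mem <- list@members
  if (!length(mem)) stop("candidate gene list is empty", call. = FALSE)
  present <- mem[mem %in% db@genes]
  missing <- setdiff(mem, present)
  if (!length(present))
    warning("no candidate gene was found in the interaction database; ",
            "the graph is empty", call. = FALSE)

  e <- db@edges
  aIn <- e$geneA %in% present
  bIn <- e$geneB %in% present
  direct <- e[aIn & bIn, c("geneA", "geneB", "citations")]
  rownames(direct) <- NULL

  # one endpoint in the list, the other a potential linker
  half <- e[xor(aIn, bIn), , drop = FALSE]
  listEnd <- ifelse(half$geneA %in% present, half$geneA, half$geneB)
  other <- ifelse(half$geneA %in% present, half$geneB, half$geneA)
  ok <- !(other %in% mem)            # a linker is never a list member
  listEnd <- listEnd[ok]; other <- other[ok]
  legCit <- half$citations[ok]

  indirect <- data.frame(geneA = character(0), geneB = character(0),
                         linker = character(0), citationsA = integer(0),
                         citationsB = integer(0), stringsAsFactors = FALSE)
  if (length(other)) {
    byLinker <- split(seq_along(other),
                      factor(other, levels = sortLex(unique(other))))
    rows <- lapply(byLinker, function(ix) {
      if (length(ix) < 2L) return(NULL)
      ord <- ix[orderLex(listEnd[ix])]
      prs <- utils::combn(seq_along(ord), 2L)
      i <- ord[prs[1L, ]]; j <- ord[prs[2L, ]]
      data.frame(geneA = listEnd[i], geneB = listEnd[j],
                 linker = other[i], citationsA = legCit[i],
                 citationsB = legCit[j], stringsAsFactors = FALSE)
    })
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      indirect <- do.call(rbind, rows)
      indirect <- indirect[orderLex(indirect$geneA, indirect$geneB,
                                    indirect$linker), , drop = FALSE]
      rownames(indirect) <- NULL
    }
  }

  pairs <- unique(rbind(direct[, c("geneA", "geneB")],
                        indirect[, c("geneA", "geneB")]))
  traversal <- igraph::graph_from_data_frame(
    pairs, directed = FALSE,
    vertices = data.frame(name = present, stringsAsFactors = FALSE))

  new("BasicGraph", nodes = present, directEdges = direct,
      indirectEdges = indirect, listGenes = mem, missingGenes = missing,
      db = db, traversal = traversal)
}

#' Linker genes used by a basic graph
#'
#' All non-list genes that mediate at least one indirect edge.
#'
#' @param g a [BasicGraph-class].
#' @return sorted character vector (possibly empty).
#' @export
listLinkers <- function(g) {
  stopifnot(is(g, "BasicGraph"))
  sortLex(unique(g@indirectEdges$linker))
}

#' d-neighbours of a start gene
#'
#' All list genes reachable from \code{start} in at most \code{d} steps in
#' the basic graph, where traversing one direct \emph{or} one indirect
#' edge counts as one step. The start gene itself is included. Linker
#' genes are not nodes of the basic graph and are therefore not returned
#' here; they are materialized later by [expandNetwork()].
#'
#' @param g a [BasicGraph-class].
#' @param start a gene identifier in \code{g}'s node set.
#' @param d non-negative integer number of steps.
#' @return sorted character vector of gene identifiers.
#' @export
dNeighbours <- function(g, start, d) {
  stopifnot(is(g, "BasicGraph"))
  d <- asCount(d, "d")
  if (d < 0L) stop("d must be non-negative", call. = FALSE)
  if (!start %in% g@nodes)
    stop(sprintf("gene '%s' is not a node of the basic graph", start),
         call. = FALSE)
  if (d == 0L) return(start)
  nb <- igraph::ego(g@traversal, order = d, nodes = start, mode = "all")[[1]]
  sortLex(names(nb))
}

#' Expand a member set into a network
#'
#' Builds the reported network N from a set of list genes: all direct
#' edges among the members, plus, for every indirect edge between two
#' members, its two database legs and a new node for the linker gene.
#' Shared legs are emitted once.
#'
#' @param g a [BasicGraph-class].
#' @param memberGenes character vector of list genes, a subset of
#'   \code{g}'s nodes that is connected in the basic graph.
#' @param startGene,depth provenance of the search that produced the set
#'   (optional; recorded in the network).
#' @return a [GeneNetwork-class].
#' @export
expandNetwork <- function(g, memberGenes, startGene = NA_character_,
                          depth = NA_integer_) {
  stopifnot(is(g, "BasicGraph"))
  memberGenes <- unique(as.character(memberGenes))
  if (!all(memberGenes %in% g@nodes))
    stop("memberGenes must be nodes of the basic graph", call. = FALSE)

  d <- g@directEdges
  direct <- d[d$geneA %in% memberGenes & d$geneB %in% memberGenes, ,
              drop = FALSE]
  ind <- g@indirectEdges
  ind <- ind[ind$geneA %in% memberGenes & ind$geneB %in% memberGenes, ,
             drop = FALSE]

  # connectivity contract: the member set must be one component of G
  if (length(memberGenes) > 1L) {
    prs <- unique(rbind(direct[, c("geneA", "geneB")],
                        ind[, c("geneA", "geneB")]))
    gr <- igraph::graph_from_data_frame(
      prs, directed = FALSE,
      vertices = data.frame(name = memberGenes, stringsAsFactors = FALSE))
    if (!igraph::is_connected(gr))
      stop("memberGenes are not connected in the basic graph; ",
           "pass one connected component", call. = FALSE)
  }

  legs <- if (nrow(ind)) {
    rbind(
      data.frame(geneA = pmin(ind$geneA, ind$linker),
                 geneB = pmax(ind$geneA, ind$linker),
                 citations = ind$citationsA, stringsAsFactors = FALSE),
      data.frame(geneA = pmin(ind$geneB, ind$linker),
                 geneB = pmax(ind$geneB, ind$linker),
                 citations = ind$citationsB, stringsAsFactors = FALSE))
  } else emptyEdgeFrame()
  edges <- rbind(direct[, c("geneA", "geneB", "citations")], legs)
  edges <- edges[!duplicated(paste(edges$geneA, edges$geneB, sep = "\r")), ,
                 drop = FALSE]
  edges <- edges[orderLex(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL

  linkers <- sortLex(unique(ind$linker))
  nodes <- data.frame(
    gene = c(sortLex(memberGenes), linkers),
    isList = c(rep(TRUE, length(memberGenes)), rep(FALSE, length(linkers))),
    isLinker = c(rep(FALSE, length(memberGenes)),
                 rep(TRUE, length(linkers))),
    stringsAsFactors = FALSE)

  new("GeneNetwork", nodes = nodes, edges = edges,
      startGene = as.character(startGene), depth = as.integer(depth))
}
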