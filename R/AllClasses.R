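#' @import methods
#' @importFrom stats dhyper rgeom runif
#' @importFrom utils head read.delim write.table packageVersion
NULL

setOldClass("igraph")

#' InteractionDb: a deduplicated, evidence-filtered interaction database
#'
#' Canonical container for a molecular-interaction database after parsing,
#' evidence filtering and merging. Edges are undirected and keyed by the
#' alphabetically ordered gene pair; duplicate records for the same pair are
#' merged by union of their publication sets, so \code{citations} is the
#' number of distinct supporting publications.
#'
#' @slot edges data.frame with columns \code{geneA}, \code{geneB}
#'   (\code{geneA < geneB}), \code{classes} (list of interaction classes,
#'   subset of \code{c("genetic", "physical")}), \code{publications}
#'   (list of character vectors of publication identifiers) and
#'   \code{citations} (integer, \code{lengths(publications)}).
#' @slot genes character vector of all gene identifiers known to the
#'   database; a superset of the edge endpoints (isolated genes allowed).
#' @slot universeSize integer, the total number of genes N against which
#'   list enrichment is tested. Defaults to \code{length(genes)} at build
#'   time; override it with a genome-wide count when the database covers
#'   only part of the genome.
#'
#' @seealso [buildInteractionDb()], [readInteractionTable()]
#' @exportClass InteractionDb
setClass("InteractionDb",
  slots = c(edges = "data.frame", genes = "character",
            universeSize = "integer"))

setValidity("InteractionDb", function(object) {
  e <- object@edges
  need <- c("geneA", "geneB", "classes", "publications", "citations")
  if (!all(need %in% names(e)))
    return(paste("edges must have columns:", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$geneA >= e$geneB))
      return("edges must be canonical: geneA < geneB, no self-pairs")
    if (anyDuplicated(paste(e$geneA, e$geneB)))
      return("duplicate gene pairs in edge table")
    if (!all(e$citations == lengths(e$publications)) ||
        any(e$citations < 1L))
      return("citations must equal the number of distinct publications (>= 1)")
    if (!all(c(e$geneA, e$geneB) %in% object@genes))
      return("every edge endpoint must be listed in genes")
  }
  if (length(object@universeSize) != 1L || is.na(object@universeSize) ||
      object@universeSize < length(object@genes))
    return("universeSize must be a single integer >= number of genes")
  TRUE
})

#' GeneList: an ordered candidate gene list
#'
#' The user-supplied list of candidate (e.g. differentially expressed)
#' genes. Order is preserved from the input because the network search
#' iterates the list from its first gene onward.
#'
#' @slot members character vector of unique gene identifiers, input order.
#' @slot sourcePath provenance string (file path or description).
#'
#' @seealso [readGeneList()], [geneList()]
#' @exportClass GeneList
setClass("GeneList",
  slots = c(members = "character", sourcePath = "character"))

setValidity("GeneList", function(object) {
  m <- object@members
  if (anyDuplicated(m)) return("members must be unique")
  if (length(m) && any(!nzchar(m) | is.na(m)))
    return("members must be non-empty strings")
  TRUE
})

#' BasicGraph: the candidate-list graph with direct and indirect edges
#'
#' The graph G = (V, E) whose vertices are the list genes found in the
#' database and whose edges are either \emph{direct} (a single database
#' interaction between two list genes) or \emph{indirect} (two database
#' interactions joining two list genes through one non-list linker gene).
#' A pair may carry a direct edge and any number of indirect edges at the
#' same time; traversal treats the pair as adjacent either way.
#'
#' @slot nodes character, list genes present in the database.
#' @slot directEdges data.frame: \code{geneA}, \code{geneB}, \code{citations}.
#' @slot indirectEdges data.frame: \code{geneA}, \code{geneB} (the two list
#'   genes), \code{linker}, \code{citationsA} (list-gene-A--linker leg),
#'   \code{citationsB}.
#' @slot listGenes the full candidate list (order preserved), including
#'   genes absent from the database.
#' @slot missingGenes list genes not found in the database (diagnostics).
#' @slot db back-reference to the [InteractionDb-class] the graph was
#'   built from.
#' @slot traversal igraph object over \code{nodes} with one edge per
#'   adjacent pair, used for reachability queries.
#'
#' @seealso [buildBasicGraph()], [dNeighbours()], [listLinkers()]
#' @exportClass BasicGraph
setClass("BasicGraph",
  slots = c(nodes = "character", directEdges = "data.frame",
            indirectEdges = "data.frame", listGenes = "character",
            missingGenes = "character", db = "InteractionDb",
            traversal = "igraph"))

setValidity("BasicGraph", function(object) {
  ind <- object@indirectEdges
  if (nrow(ind) && any(ind$linker %in% object@listGenes))
    return("an indirect edge's linker can never be a candidate-list member")
  if (!all(object@nodes %in% object@listGenes))
    return("graph nodes must be candidate-list members")
  d <- object@directEdges
  if (nrow(d) && !all(c(d$geneA, d$geneB) %in% object@nodes))
    return("direct-edge endpoints must be graph nodes")
  TRUE
})

#' GeneNetwork: one discovered network after linker expansion
#'
#' A connected subgraph N = (V_N, E_N) discovered by the depth-limited
#' search, after every indirect edge has been replaced by its two database
#' legs plus a node for the linker gene.
#'
#' @slot nodes data.frame: \code{gene}, \code{isList} (candidate-list
#'   member), \code{isLinker}. Linkers are never list members.
#' @slot edges data.frame: \code{geneA}, \code{geneB} (canonical order),
#'   \code{citations} (distinct supporting publications of that database
#'   edge).
#' @slot startGene the list gene the search was seeded at (may be NA for
#'   networks constructed directly).
#' @slot depth the iteration depth d the network was found at (NA if not
#'   applicable).
#'
#' @seealso [expandNetwork()], [findNetworks()], [networkScore()]
#' @exportClass GeneNetwork
setClass("GeneNetwork",
  slots = c(nodes = "data.frame", edges = "data.frame",
            startGene = "character", depth = "integer"))

setValidity("GeneNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("gene", "isList", "isLinker") %in% names(nd)))
    return("nodes needs columns gene, isList, isLinker")
  if (!all(c("geneA", "geneB", "citations") %in% names(ed)))
    return("edges needs columns geneA, geneB, citations")
  if (any(nd$isLinker & nd$isList))
    return("a linker node cannot be a list member")
  if (nrow(ed)) {
    if (!all(c(ed$geneA, ed$geneB) %in% nd$gene))
      return("every edge endpoint must be a network node")
    gr <- igraph::graph_from_data_frame(ed[, c("geneA", "geneB")],
      directed = FALSE, vertices = data.frame(name = nd$gene))
    if (!igraph::is_connected(gr))
      return("network node set must be connected under its edge set")
  } else if (nrow(nd) > 1L) {
    return("a multi-node network must have edges (connectivity)")
  }
  TRUE
})

#' SearchConfig: parameters of the network search and its statistics
#'
#' @slot maxDepth maximum number of steps D allowed from a start gene;
#'   one direct or one indirect edge is one step.
#' @slot minListGenes smallest number of list genes a reported network may
#'   contain (default 2; singletons are never reported).
#' @slot nSim number of permutation draws for the score p-value; 0 skips
#'   the permutation test (score p-value reported as NA).
#' @slot seed random seed, mandatory for reproducibility.
#'
#' @seealso [searchConfig()], [findNetworks()]
#' @exportClass SearchConfig
setClass("SearchConfig",
  slots = c(maxDepth = "integer", minListGenes = "integer",
            nSim = "integer", seed = "integer"))

setValidity("SearchConfig", function(object) {
  if (object@maxDepth < 1L) return("maxDepth must be >= 1")
  if (object@minListGenes < 2L) return("minListGenes must be >= 2")
  if (object@nSim < 0L) return("nSim must be >= 0")
  if (is.na(object@seed)) return("seed is mandatory")
  TRUE
})

#' NetworkStats: the two statistical assessments of one network
#'
#' @slot score mean number of distinct supporting publications per edge.
#' @slot scorePvalue fraction of randomly simulated networks whose score is
#'   at least the observed score (NA when the permutation test was skipped).
#' @slot nSim number of simulations used for \code{scorePvalue}.
#' @slot neighbourhoodSize |N^1|, size of the induced 1-neighbourhood of
#'   the network in the full database graph (network nodes included).
#' @slot listOverlap k, number of distinct candidate-list genes inside N^1.
#' @slot listPvalue upper-tail hypergeometric probability of observing at
#'   least k list genes in N^1.
#'
#' @seealso [evaluateNetwork()]
#' @exportClass NetworkStats
setClass("NetworkStats",
  slots = c(score = "numeric", scorePvalue = "numeric", nSim = "integer",
            neighbourhoodSize = "integer", listOverlap = "integer",
            listPvalue = "numeric"))

setValidity("NetworkStats", function(object) {
  p <- c(object@scorePvalue, object@listPvalue)
  p <- p[!is.na(p)]
  if (length(p) && (any(p < 0) || any(p > 1)))
    return("p-values must lie in [0, 1]")
  if (!is.na(object@score) && object@score < 0)
    return("score must be non-negative")
  TRUE
})

#' NetworkAnalysis: full result of one discovery run
#'
#' Networks (sorted by score, ties broken by list p-value, node count and
#' gene names), their statistics, and the result table.
#'
#' @slot networks list of [GeneNetwork-class], sorted.
#' @slot stats list of [NetworkStats-class], parallel to \code{networks}.
#' @slot table data.frame, one row per network (see [resultTable()]).
#' @slot config the [SearchConfig-class] used.
#' @slot geneList the [GeneList-class] analysed.
#' @slot universeSize universe size N used for the enrichment tests.
#'
#' @seealso [analyzeNetworks()]
#' @exportClass NetworkAnalysis
setClass("NetworkAnalysis",
  slots = c(networks = "list", stats = "list", table = "data.frame",
            config = "SearchConfig", geneList = "GeneList",
            universeSize = "integer"))

#' SyntheticTruth: ground truth of a generated database
#'
#' Records what the synthetic-data generator planted, so recovery can be
#' checked exactly.
#'
#' @slot planted list of truth entries; each has \code{listNodes},
#'   \code{linkers}, \code{edges} (data.frame geneA/geneB/citations),
#'   \code{shape}.
#' @slot backgroundParams list: \code{nGenes}, \code{edgeProbability},
#'   \code{citationDist}.
#' @slot seed generator seed.
#'
#' @seealso [generateDatabase()], [plantNetwork()]
#' @exportClass SyntheticTruth
setClass("SyntheticTruth",
  slots = c(planted = "list", backgroundParams = "list", seed = "integer"))

#' RunConfig: configuration of a full command-line style run
#'
#' @slot dbPath path to the interaction TSV.
#' @slot genesPath path to the gene-list file.
#' @slot outDir output directory (created if absent).
#' @slot maxDepth,minListGenes,nSim,seed as in [SearchConfig-class].
#' @slot universeSize optional override of the enrichment universe
#'   (NA = number of genes in the database).
#' @slot keepPredicted if TRUE, computationally predicted interactions are
#'   retained (default FALSE: they are ignored).
#' @slot alpha report threshold used to flag significant networks.
#'
#' @seealso [validateConfig()], [runAnalysis()]
#' @exportClass RunConfig
setClass("RunConfig",
  slots = c(dbPath = "character", genesPath = "character",
            outDir = "character", maxDepth = "integer",
            minListGenes = "integer", nSim = "integer", seed = "integer",
            universeSize = "integer", keepPredicted = "logical",
            alpha = "numeric"))
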