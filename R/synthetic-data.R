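# Synthetic databases, planted networks and candidate lists with ground
# truth, so the whole method is testable without any external download.

#' Citation-count distribution specification
#'
#' Three supported regimes: \code{constant} (every edge has \code{value}
#' citations), \code{geometric} (1 + geometric, mean \code{mean}), and
#' \code{two_point} (1 citation with probability \code{q}, otherwise
#' \code{high}) — the last mimics curated interactomes where most
#' interactions have a single report and a few hubs have very many
#' (e.g. one 135-citation edge among unit edges).
#'
#' @param kind one of \code{"constant"}, \code{"geometric"},
#'   \code{"two_point"}.
#' @param value citations per edge for \code{constant} (default 1).
#' @param mean mean citations for \code{geometric} (default 3).
#' @param q,high unit-probability and high value for \code{two_point}
#'   (defaults 0.95 and 135).
#' @return a validated spec list.
#' @export
citationSpec <- function(kind = c("two_point", "constant", "geometric"),
                         value = 1L, mean = 3, q = 0.95, high = 135L) {
  kind <- match.arg(kind)
  spec <- switch(kind,
    constant = {
      value <- asCount(value, "value")
      if (value < 1L) stop("constant citation value must be >= 1",
                           call. = FALSE)
      list(kind = kind, value = value)
    },
    geometric = {
      if (!is.numeric(mean) || mean < 1)
        stop("geometric citation mean must be >= 1", call. = FALSE)
      list(kind = kind, mean = mean)
    },
    two_point = {
      if (q <= 0 || q > 1) stop("q must be in (0, 1]", call. = FALSE)
      high <- asCount(high, "high")
      if (high < 1L) stop("high must be >= 1", call. = FALSE)
      list(kind = kind, q = q, high = high)
    })
  spec
}

drawCitations <- function(spec, n) {
  if (!n) return(integer(0))
  switch(spec$kind,
    constant = rep(spec$value, n),
    # 1 + geometric(prob = 1/mean) has mean exactly `mean`
    geometric = 1L + rgeom(n, prob = 1 / spec$mean),
    two_point = ifelse(runif(n) < spec$q, 1L, spec$high),
    stop("unknown citation spec kind: ", spec$kind, call. = FALSE))
}

mintPublications <- function(counts, prefix) {
  total <- sum(counts)
  ids <- sprintf("%s%07d", prefix, seq_len(total))
  split(ids, rep(seq_along(counts), counts))
}

#' Generate a random background interaction database
#'
#' Erdős–Rényi background: each unordered gene pair becomes an edge
#' independently with probability \code{edgeProbability}; each edge's
#' citation count is drawn from \code{citationDist} and materialized as
#' that many synthetic publication identifiers, so the citation count of
#' every edge equals the size of its publication set. All
#' \code{nGenes} genes are recorded in the database (isolated genes
#' included), and output is deterministic under \code{seed}.
#'
#' @param nGenes number of genes (>= 2).
#' @param edgeProbability per-pair edge probability in [0, 1].
#' @param citationDist a [citationSpec()] list.
#' @param seed random seed (mandatory).
#' @return list with elements \code{db} ([InteractionDb-class]) and
#'   \code{truth} ([SyntheticTruth-class]).
#' @examples
#' sim <- generateDatabase(30, 0.1, citationSpec("constant"), seed = 1)
#' sim$db
#' @export
generateDatabase <- function(nGenes, edgeProbability,
                             citationDist = citationSpec("two_point"),
                             seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  nGenes <- asCount(nGenes, "nGenes")
  if (nGenes < 2L) stop("nGenes must be >= 2", call. = FALSE)
  if (edgeProbability < 0 || edgeProbability > 1)
    stop("edgeProbability must be in [0, 1]", call. = FALSE)
  genes <- sprintf("g%04d", seq_len(nGenes))
  prs <- utils::combn(genes, 2L)
  withSeed(seed, {
    sel <- runif(ncol(prs)) < edgeProbability
    a <- prs[1L, sel]; b <- prs[2L, sel]
    cit <- as.integer(drawCitations(citationDist, length(a)))
    pubs <- mintPublications(cit, "SP")
    edges <- data.frame(geneA = a, geneB = b, stringsAsFactors = FALSE)
    edges$classes <- rep(list("physical"), length(a))
    edges$publications <- unname(pubs)
    edges$citations <- cit
    edges <- edges[orderLex(edges$geneA, edges$geneB), , drop = FALSE]
    rownames(edges) <- NULL
    db <- new("InteractionDb", edges = edges, genes = genes,
              universeSize = as.integer(nGenes))
    truth <- new("SyntheticTruth", planted = list(),
                 backgroundParams = list(nGenes = nGenes,
                                         edgeProbability = edgeProbability,
                                         citationDist = citationDist),
                 seed = as.integer(seed))
    list(db = db, truth = truth)
  })
}

motifEdges <- function(shape, listNodes, linkers) {
  nl <- length(listNodes); nk <- length(linkers)
  pair <- function(a, b) data.frame(geneA = pmin(a, b), geneB = pmax(a, b),
                                    stringsAsFactors = FALSE)
  switch(shape,
    path = {
      # interleave linkers between the leading list genes: a1-x1-a2-x2-a3-a4...
      if (nk > nl - 1L)
        stop("a path of ", nl, " list genes can host at most ", nl - 1L,
             " linkers", call. = FALSE)
      seqNodes <- character(0)
      li <- 1L
      for (i in seq_len(nl)) {
        seqNodes <- c(seqNodes, listNodes[i])
        if (li <= nk && i < nl) { seqNodes <- c(seqNodes, linkers[li]); li <- li + 1L }
      }
      pair(seqNodes[-length(seqNodes)], seqNodes[-1L])
    },
    star = {
      if (nl + nk < 3L || nl < 2L)
        stop("a star needs at least 3 nodes and 2 list genes", call. = FALSE)
      hub <- listNodes[1L]; leaves <- listNodes[-1L]
      if (nk > length(leaves))
        stop("a star of ", nl, " list genes can host at most ", nl - 1L,
             " linkers", call. = FALSE)
      ed <- NULL
      for (i in seq_along(leaves)) {
        if (i <= nk) {
          # reach this leaf through a linker: hub - linker - leaf
          ed <- rbind(ed, pair(hub, linkers[i]), pair(linkers[i], leaves[i]))
        } else {
          ed <- rbind(ed, pair(hub, leaves[i]))
        }
      }
      ed
    },
    clique = {
      if (nl < 2L) stop("a clique needs >= 2 list genes", call. = FALSE)
      prs <- utils::combn(listNodes, 2L)
      ed <- pair(prs[1L, ], prs[2L, ])
      # each linker bridges one list pair, adding an indirect route
      if (nk) {
        if (nk > ncol(prs))
          stop("more linkers than list pairs in clique", call. = FALSE)
        for (i in seq_len(nk))
          ed <- rbind(ed, pair(prs[1L, i], linkers[i]),
                      pair(linkers[i], prs[2L, i]))
      }
      ed
    },
    stop("unknown shape: ", shape, call. = FALSE))
}

#' Plant a ground-truth network into a database
#'
#' Inserts a connected motif on freshly minted gene identifiers: its list
#' nodes are intended for the generated candidate list, its linker nodes
#' are excluded from it. Every motif edge gets \code{1 + citationBoost}
#' citations (materialized as synthetic publications). The truth entry
#' records the exact network expected after linker expansion.
#'
#' @param db an [InteractionDb-class] (typically from
#'   [generateDatabase()]).
#' @param shape \code{"path"}, \code{"star"} or \code{"clique"}.
#' @param nListNodes number of planted list genes (>= 2).
#' @param nLinkers number of planted linker genes (shape-dependent cap).
#' @param citationBoost added citations per motif edge (0 = unit edges).
#' @param seed random seed (kept for interface symmetry; planting is
#'   deterministic).
#' @param truth optional existing [SyntheticTruth-class] to append to.
#' @return list with the modified \code{db} and the updated \code{truth}.
#' @export
plantNetwork <- function(db, shape = c("path", "star", "clique"),
                         nListNodes, nLinkers = 0L, citationBoost = 10L,
                         seed = 0L, truth = NULL) {
  stopifnot(is(db, "InteractionDb"))
  shape <- match.arg(shape)
  nListNodes <- asCount(nListNodes, "nListNodes")
  nLinkers <- asCount(nLinkers, "nLinkers")
  citationBoost <- asCount(citationBoost, "citationBoost")
  if (nListNodes < 2L) stop("nListNodes must be >= 2", call. = FALSE)
  if (is.null(truth))
    truth <- new("SyntheticTruth", planted = list(),
                 backgroundParams = list(nGenes = length(db@genes)),
                 seed = as.integer(seed))
  idx <- length(truth@planted) + 1L
  listNodes <- sprintf("pl%02d_%03d", idx, seq_len(nListNodes))
  linkers <- if (nLinkers) sprintf("lk%02d_%03d", idx, seq_len(nLinkers))
    else character(0)
  if (any(c(listNodes, linkers) %in% db@genes))
    stop("planted gene identifiers collide with existing genes",
         call. = FALSE)

  ed <- motifEdges(shape, listNodes, linkers)
  ed <- ed[!duplicated(paste(ed$geneA, ed$geneB, sep = "\r")), , drop = FALSE]
  cit <- rep(1L + citationBoost, nrow(ed))
  pubs <- mintPublications(cit, sprintf("PP%02d", idx))
  ed$classes <- rep(list("genetic"), nrow(ed))
  ed$publications <- unname(pubs)
  ed$citations <- cit
  ed <- ed[, c("geneA", "geneB", "classes", "publications", "citations")]

  edges <- rbind(db@edges, ed)
  edges <- edges[orderLex(edges$geneA, edges$geneB), , drop = FALSE]
  rownames(edges) <- NULL
  genes <- sortLex(c(db@genes, listNodes, linkers))
  newDb <- new("InteractionDb", edges = edges, genes = genes,
               universeSize = max(db@universeSize, length(genes)))

  entry <- list(shape = shape, listNodes = listNodes, linkers = linkers,
                edges = data.frame(geneA = ed$geneA, geneB = ed$geneB,
                                   citations = ed$citations,
                                   stringsAsFactors = FALSE))
  truth@planted <- c(truth@planted, list(entry))
  list(db = newDb, truth = truth)
}

#' Generate a candidate gene list with planted genes
#'
#' Includes planted list genes (up to \code{plantedFraction * listSize} of
#' them), pads with genes sampled uniformly from the background, always
#' excludes planted linkers, and shuffles deterministically under
#' \code{seed}.
#'
#' @param db the [InteractionDb-class] (possibly with planted networks).
#' @param truth the matching [SyntheticTruth-class].
#' @param listSize total list length.
#' @param plantedFraction maximum fraction of the list taken up by planted
#'   genes (default 1: all planted list genes if they fit).
#' @param seed random seed (mandatory).
#' @return a [GeneList-class].
#' @export
generateList <- function(db, truth, listSize, plantedFraction = 1,
                         seed) {
  stopifnot(is(db, "InteractionDb"), is(truth, "SyntheticTruth"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  listSize <- asCount(listSize, "listSize")
  plantedList <- unlist(lapply(truth@planted, `[[`, "listNodes"),
                        use.names = FALSE)
  plantedLinkers <- unlist(lapply(truth@planted, `[[`, "linkers"),
                           use.names = FALSE)
  nTake <- min(length(plantedList), floor(plantedFraction * listSize))
  take <- head(plantedList, nTake)
  pool <- setdiff(db@genes, c(plantedList, plantedLinkers))
  nPad <- listSize - length(take)
  if (nPad < 0L || nPad > length(pool))
    stop(sprintf(
      "infeasible list: need %d background genes but only %d available",
      nPad, length(pool)), call. = FALSE)
  withSeed(seed, {
    pad <- if (nPad) sample(pool, nPad) else character(0)
    memb <- sample(c(take, pad))
    geneList(memb, sourcePath = sprintf("<synthetic seed=%d>", seed))
  })
}
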