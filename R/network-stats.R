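#' Network score
#'
#' The score of a network is the average number of distinct publications
#' (citations) supporting its edges — a measure of the strength of
#' experimental evidence for the network.
#'
#' @param n a [GeneNetwork-class] with at least one edge.
#' @return non-negative numeric.
#' @export
networkScore <- function(n) {
  stopifnot(is(n, "GeneNetwork"))
  if (!nrow(n@edges))
    stop("network score is undefined for a network without edges",
         call. = FALSE)
  mean(n@edges$citations)
}

#' Permutation p-value for a network score
#'
#' Tests whether the observed score is larger than expected by chance:
#' \code{nSim} simulated networks are drawn, each is scored, and the
#' p-value is the fraction of simulated scores at least as large as the
#' observed one. The default null draws, for each simulated network, the
#' same number of edges as the observed network uniformly without
#' replacement from the database's (experimental) edge set, preserving the
#' only quantity the score uses — the edge count. \code{method =
#' "connected"} instead grows a random connected edge set of the same size
#' on the database graph.
#'
#' @param n a [GeneNetwork-class].
#' @param db the [InteractionDb-class] the null is drawn from; must have
#'   at least as many edges as the network.
#' @param nSim number of simulated networks (default 10000).
#' @param seed random seed (mandatory).
#' @param method \code{"resample"} (default) or \code{"connected"}.
#' @param addOne if TRUE, applies the add-one correction
#'   \code{(1 + hits) / (nSim + 1)} so the estimate is never exactly 0.
#'   Default FALSE: the literal fraction, which can be 0.
#' @return numeric p-value in [0, 1].
#' @export
scorePvalue <- function(n, db, nSim = 10000L, seed, method = c("resample",
                        "connected"), addOne = FALSE) {
  stopifnot(is(n, "GeneNetwork"), is(db, "InteractionDb"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  method <- match.arg(method)
  nSim <- asCount(nSim, "nSim")
  k <- nrow(n@edges)
  m <- nrow(db@edges)
  if (m < k)
    stop(sprintf(
      "cannot simulate: database has %d edges but the network has %d",
      m, k), call. = FALSE)
  obs <- networkScore(n)
  cit <- db@edges$citations
  sims <- withSeed(seed, {
    if (method == "resample") {
      vapply(seq_len(nSim),
             function(i) mean(cit[sample.int(m, k)]), numeric(1))
    } else {
      simulateConnectedScores(db, k, nSim)
    }
  })
  hits <- sum(sims >= obs)
  if (addOne) (1 + hits) / (nSim + 1) else hits / nSim
}

# Grow nSim random connected edge sets of size k on the database graph and
# return their scores. Growth: start from a uniformly chosen edge, then
# repeatedly add an edge chosen uniformly among edges incident to the
# current vertex set; restart if the component is exhausted early.
simulateConnectedScores <- function(db, k, nSim) {
  e <- db@edges
  m <- nrow(e)
  incident <- c(split(seq_len(m), factor(e$geneA, levels = db@genes)),
                split(seq_len(m), factor(e$geneB, levels = db@genes)))
  adj <- tapply(unlist(incident, use.names = FALSE),
                rep(names(incident), lengths(incident)), c)
  vapply(seq_len(nSim), function(i) {
    repeat {
      picked <- sample.int(m, 1L)
      verts <- c(e$geneA[picked], e$geneB[picked])
      while (length(picked) < k) {
        cand <- setdiff(unique(unlist(adj[verts], use.names = FALSE)),
                        picked)
        if (!length(cand)) break
        nxt <- if (length(cand) == 1L) cand else sample(cand, 1L)
        picked <- c(picked, nxt)
        verts <- unique(c(verts, e$geneA[nxt], e$geneB[nxt]))
      }
      if (length(picked) == k) return(mean(e$citations[picked]))
    }
  }, numeric(1))
}

#' Induced 1-neighbourhood of a network
#'
#' N^1: every database gene at distance one (one database edge) from any
#' network node, unioned with the network's own nodes. The neighbourhood
#' is computed on the full database graph, not on the list-restricted
#' basic graph, because the enrichment null compares the candidate list
#' against the whole gene universe.
#'
#' @param n a [GeneNetwork-class].
#' @param db an [InteractionDb-class].
#' @param includeNetwork if FALSE, the network's own nodes are excluded
#'   from the result (non-default variant).
#' @return sorted character vector of gene identifiers.
#' @export
inducedNeighbourhood <- function(n, db, includeNetwork = TRUE) {
  stopifnot(is(n, "GeneNetwork"), is(db, "InteractionDb"))
  vn <- n@nodes$gene
  e <- db@edges
  touch <- e$geneA %in% vn | e$geneB %in% vn
  nb <- unique(c(e$geneA[touch], e$geneB[touch]))
  if (includeNetwork) sortLex(unique(c(vn, nb)))
  else sortLex(setdiff(nb, vn))
}

#' Hypergeometric density of the list overlap
#'
#' Probability that exactly \code{k} of the \code{listSize} candidate
#' genes fall inside a neighbourhood of size \code{neighbourhood} when the
#' list is drawn uniformly from a universe of \code{universe} genes:
#' \deqn{f(k) = \frac{\binom{N - |N^1|}{|L| - k} \binom{|N^1|}{k}}
#'                   {\binom{N}{|L|}}}
#'
#' @param k integer (vectorized), number of list genes in the
#'   neighbourhood; each value must lie in
#'   \code{0:min(neighbourhood, listSize)}.
#' @param universe universe size N.
#' @param neighbourhood neighbourhood size |N^1| (at most N).
#' @param listSize candidate list size |L| (at most N).
#' @return numeric vector of probabilities.
#' @export
hypergeomPmf <- function(k, universe, neighbourhood, listSize) {
  universe <- asCount(universe, "universe")
  neighbourhood <- asCount(neighbourhood, "neighbourhood")
  listSize <- asCount(listSize, "listSize")
  if (neighbourhood < 0L || neighbourhood > universe)
    stop("need 0 <= neighbourhood <= universe", call. = FALSE)
  if (listSize < 0L || listSize > universe)
    stop("need 0 <= listSize <= universe", call. = FALSE)
  if (any(k < 0L) || any(k > min(neighbourhood, listSize)))
    stop("k out of range 0..min(neighbourhood, listSize)", call. = FALSE)
  dhyper(k, m = neighbourhood, n = universe - neighbourhood, k = listSize)
}

#' Upper-tail hypergeometric p-value of the list overlap
#'
#' Tests the null hypothesis that the proportion of genes belonging to the
#' neighbourhood N^1 is the same in the candidate list as in the whole
#' universe: the p-value is the sum of the hypergeometric density from the
#' observed overlap k up to the top of the support,
#' n = min(|N^1|, |L|).
#'
#' @inheritParams hypergeomPmf
#' @param k observed overlap (single integer).
#' @return numeric p-value in [0, 1].
#' @export
listPvalue <- function(k, universe, neighbourhood, listSize) {
  k <- asCount(k, "k")
  top <- min(neighbourhood, listSize)
  p <- sum(hypergeomPmf(seq.int(k, top), universe, neighbourhood, listSize))
  min(p, 1)
}

#' Full statistical assessment of one network
#'
#' Computes the network score, its permutation p-value (unless
#' \code{cfg@nSim} is 0), the induced 1-neighbourhood, the overlap k of
#' the candidate list with that neighbourhood, and the hypergeometric
#' list p-value. The enrichment universe is \code{universeSize(db)} and
#' the list size is the full candidate list length.
#'
#' @param n a [GeneNetwork-class].
#' @param db an [InteractionDb-class].
#' @param list the analysed [GeneList-class].
#' @param cfg a [SearchConfig-class] (supplies nSim and seed).
#' @return a [NetworkStats-class].
#' @export
evaluateNetwork <- function(n, db, list, cfg) {
  stopifnot(is(n, "GeneNetwork"), is(db, "InteractionDb"),
            is(list, "GeneList"), is(cfg, "SearchConfig"))
  score <- networkScore(n)
  sp <- if (cfg@nSim > 0L)
    scorePvalue(n, db, nSim = cfg@nSim, seed = cfg@seed)
  else NA_real_
  nb <- inducedNeighbourhood(n, db)
  k <- length(intersect(nb, list@members))
  lp <- listPvalue(k, universe = db@universeSize,
                   neighbourhood = length(nb),
                   listSize = length(list@members))
  new("NetworkStats", score = score, scorePvalue = sp, nSim = cfg@nSim,
      neighbourhoodSize = length(nb), listOverlap = as.integer(k),
      listPvalue = lp)
}

#' Run the full discovery-and-assessment pipeline in memory
#'
#' Builds the basic graph, discovers networks at depths D..1, evaluates
#' every network, and sorts the results by score (descending), list
#' p-value (ascending), node count (descending) and lexicographically
#' smallest gene — a deterministic total order.
#'
#' @param db an [InteractionDb-class].
#' @param list a [GeneList-class].
#' @param cfg a [SearchConfig-class].
#' @return a [NetworkAnalysis-class].
#' @examples
#' db <- buildInteractionDb(filterExperimental(
#'   readInteractionTable(iisExample()$db)))
#' gl <- readGeneList(iisExample()$genes)
#' an <- analyzeNetworks(db, gl, searchConfig(maxDepth = 1, seed = 7))
#' resultTable(an)
#' @export
analyzeNetworks <- function(db, list, cfg) {
  g <- buildBasicGraph(db, list)
  nets <- findNetworks(g, cfg)
  stats <- lapply(nets, evaluateNetwork, db = db, list = list, cfg = cfg)
  if (length(nets)) {
    score <- vapply(stats, function(s) s@score, numeric(1))
    lp <- vapply(stats, function(s) s@listPvalue, numeric(1))
    nn <- vapply(nets, function(n) nrow(n@nodes), integer(1))
    mg <- vapply(nets, function(n) n@nodes$gene[1L], character(1))
    ord <- order(-score, lp, -nn, mg, method = "radix")
    nets <- nets[ord]; stats <- stats[ord]
  }
  tab <- buildResultTable(nets, stats)
  new("NetworkAnalysis", networks = nets, stats = stats, table = tab,
      config = cfg, geneList = list, universeSize = db@universeSize)
}
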