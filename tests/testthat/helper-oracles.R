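# Independent brute-force oracles. These deliberately re-derive everything
# from first principles (definitions, exhaustive enumeration) and share no
# code with the implementation they check.

# Adjacency among list genes by definition: direct = a database edge joins
# two list genes; indirect = some non-list gene has a database edge to both.
oracleAdjacency <- function(db, listGenes) {
  e <- dbEdges(db)
  nodes <- intersect(listGenes, unique(c(e$geneA, e$geneB)))
  adj <- setNames(vector("list", length(nodes)), nodes)
  hasEdge <- function(x, y)
    any((e$geneA == x & e$geneB == y) | (e$geneA == y & e$geneB == x))
  nonList <- setdiff(dbGenes(db), listGenes)
  for (a in nodes) for (b in nodes) {
    if (a >= b) next
    direct <- hasEdge(a, b)
    indirect <- any(vapply(nonList,
      function(x) hasEdge(a, x) && hasEdge(x, b), logical(1)))
    if (direct || indirect) {
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
  }
  adj
}

# Plain breadth-first reachability in <= d steps over an adjacency list.
oracleBfs <- function(adj, start, d) {
  frontier <- start
  seen <- start
  steps <- 0L
  while (length(frontier) && steps < d) {
    frontier <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                        seen)
    seen <- c(seen, frontier)
    steps <- steps + 1L
  }
  sort(seen)
}

# Union-find connected components over an adjacency list.
oracleComponents <- function(adj) {
  nodes <- names(adj)
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (a in nodes) for (b in adj[[a]]) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), sort))
}

# Exhaustive hypergeometric pmf: draw every size-l subset of 1:N, with the
# "neighbourhood" being 1:m, and count overlaps.
oraclePmf <- function(N, m, l, k) {
  subs <- utils::combn(N, l)
  overlap <- colSums(subs <= m)
  mean(overlap == k)
}

# Exact permutation p-value by enumerating every k-subset of the edges.
oracleScorePvalue <- function(citations, k, observed) {
  subs <- utils::combn(length(citations), k)
  sims <- apply(subs, 2L, function(ix) mean(citations[ix]))
  mean(sims >= observed)
}
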