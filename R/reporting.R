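# Result table, DOT export, JSON report.

# "Genes involved" string: list members first, then linkers, each block
# lexicographic.
genesInvolved <- function(n) {
  nd <- n@nodes
  paste(c(sortLex(nd$gene[nd$isList]), sortLex(nd$gene[nd$isLinker])),
        collapse = ", ")
}

buildResultTable <- function(nets, stats) {
  if (!length(nets)) {
    return(data.frame(rank = integer(0), genes = character(0),
                      nodes = integer(0), edges = integer(0),
                      score = numeric(0), p_score = numeric(0),
                      p_list = numeric(0), p_score_adj = numeric(0),
                      p_list_adj = numeric(0), stringsAsFactors = FALSE))
  }
  pScore <- vapply(stats, function(s) s@scorePvalue, numeric(1))
  pList <- vapply(stats, function(s) s@listPvalue, numeric(1))
  data.frame(
    rank = seq_along(nets),
    genes = vapply(nets, genesInvolved, character(1)),
    nodes = vapply(nets, function(n) nrow(n@nodes), integer(1)),
    edges = vapply(nets, function(n) nrow(n@edges), integer(1)),
    score = vapply(stats, function(s) s@score, numeric(1)),
    p_score = pScore,
    p_list = pList,
    # Benjamini-Hochberg adjusted columns: an extension beyond the raw
    # per-network p-values; clearly labeled in the written table.
    p_score_adj = if (all(is.na(pScore))) NA_real_ else
      stats::p.adjust(pScore, method = "BH"),
    p_list_adj = stats::p.adjust(pList, method = "BH"),
    stringsAsFactors = FALSE)
}

renderScore <- function(x) sprintf("%.2f", roundHalfUp(x, 2L))

# p-values below the resolution bound (1/nSim for permutation p-values)
# are rendered "<bound"; NA renders as NA.
renderPvalue <- function(p, bound = 1e-4) {
  vapply(p, function(pi) {
    if (is.na(pi)) return("NA")
    if (pi < bound)
      return(paste0("<", format(bound, scientific = FALSE, trim = TRUE)))
    sprintf("%.4f", roundHalfUp(pi, 4L))
  }, character(1))
}

#' Write the results table
#'
#' One row per discovered network, in the analysis' sorted order, with the
#' genes involved, node and edge counts, the network score (rounded half
#' away from zero to 2 decimals) and both p-values rendered to 4 decimals;
#' p-values below the permutation resolution 1/nSim are written as
#' \code{"<bound"}. Benjamini-Hochberg adjusted columns are appended as a
#' labeled extension.
#'
#' @param x a [NetworkAnalysis-class] (or a pre-built result data.frame).
#' @param path output TSV path.
#' @return invisibly, the path.
#' @export
writeResultsTable <- function(x, path) {
  tab <- if (is(x, "NetworkAnalysis")) x@table else x
  bound <- if (is(x, "NetworkAnalysis") && x@config@nSim > 0L)
    1 / x@config@nSim else 1e-4
  out <- data.frame(
    rank = tab$rank, genes = tab$genes, nodes = tab$nodes,
    edges = tab$edges,
    score = if (nrow(tab)) renderScore(tab$score) else character(0),
    p_score = if (nrow(tab)) renderPvalue(tab$p_score, bound) else character(0),
    p_list = if (nrow(tab)) renderPvalue(tab$p_list, bound) else character(0),
    p_score_adj_BH = if (nrow(tab)) renderPvalue(tab$p_score_adj, bound)
      else character(0),
    p_list_adj_BH = if (nrow(tab)) renderPvalue(tab$p_list_adj, bound)
      else character(0),
    stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Render a network as GraphViz DOT
#'
#' Candidate-list nodes are drawn filled red (or red/blue when a per-gene
#' direction is supplied), linker nodes white. Edges supported by a single
#' publication are drawn as thin grey lines; edges described in two or
#' more publications are drawn bold and labeled with their citation count.
#' Nodes and edges are emitted in a stable lexicographic order, so the
#' output is byte-identical across runs.
#'
#' @param n a [GeneNetwork-class].
#' @param name graph name (e.g. the network's rank).
#' @param directions optional named character vector mapping gene
#'   identifiers to \code{"up"} or \code{"down"}; list genes then render
#'   red/blue. Genes not named default to red.
#' @return a single character string of DOT text.
#' @export
networkToDot <- function(n, name = "network", directions = NULL) {
  stopifnot(is(n, "GeneNetwork"))
  nd <- n@nodes[orderLex(n@nodes$gene), , drop = FALSE]
  ed <- n@edges[orderLex(n@edges$geneA, n@edges$geneB), , drop = FALSE]
  fill <- ifelse(nd$isLinker, "white", "red")
  if (!is.null(directions)) {
    dir <- directions[nd$gene]
    fill[!nd$isLinker & !is.na(dir) & dir == "down"] <- "blue"
  }
  nodeLines <- sprintf('  "%s" [fillcolor="%s"];', nd$gene, fill)
  edgeLines <- ifelse(
    ed$citations >= 2L,
    sprintf('  "%s" -- "%s" [style="bold", label="%d"];',
            ed$geneA, ed$geneB, ed$citations),
    sprintf('  "%s" -- "%s" [color="grey"];', ed$geneA, ed$geneB))
  paste(c(sprintf('graph "%s" {', name),
          "  graph [overlap=false];",
          "  node [style=filled, color=black];",
          nodeLines, edgeLines, "}", ""), collapse = "\n")
}

#' Write the machine-readable JSON report
#'
#' A single JSON document embedding the configuration (including the
#' seed), per-network membership and edges with citation counts, and all
#' statistics at full precision. The shipped file
#' \code{inst/extdata/report_schema.json} lists the required structure.
#'
#' @param analysis a [NetworkAnalysis-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeJsonReport <- function(analysis, path) {
  stopifnot(is(analysis, "NetworkAnalysis"))
  cfg <- analysis@config
  nets <- mapply(function(n, s, rank) {
    list(rank = rank,
         startGene = n@startGene,
         depth = n@depth,
         nodes = lapply(seq_len(nrow(n@nodes)), function(i)
           list(gene = n@nodes$gene[i], isList = n@nodes$isList[i],
                isLinker = n@nodes$isLinker[i])),
         edges = lapply(seq_len(nrow(n@edges)), function(i)
           list(geneA = n@edges$geneA[i], geneB = n@edges$geneB[i],
                citations = n@edges$citations[i])),
         stats = list(score = s@score, scorePvalue = s@scorePvalue,
                      nSim = s@nSim,
                      neighbourhoodSize = s@neighbourhoodSize,
                      listOverlap = s@listOverlap,
                      listPvalue = s@listPvalue))
  }, analysis@networks, analysis@stats, seq_along(analysis@networks),
  SIMPLIFY = FALSE)
  report <- list(
    package = "linkernet",
    version = as.character(packageVersion("linkernet")),
    config = list(maxDepth = cfg@maxDepth,
                  minListGenes = cfg@minListGenes, nSim = cfg@nSim,
                  seed = cfg@seed, universeSize = analysis@universeSize,
                  listSize = length(analysis@geneList@members)),
    geneList = analysis@geneList@members,
    networks = nets)
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Reload a JSON report
#' @param path report path written by [writeJsonReport()].
#' @return the report as a nested list.
#' @export
readJsonReport <- function(path) {
  jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Per-network gene-list files
#'
#' Writes one plain gene-list text file per network (list members plus
#' linkers, one per line), suitable for pasting into any functional
#' enrichment service.
#'
#' @param analysis a [NetworkAnalysis-class].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeNetworkGeneLists <- function(analysis, dir) {
  stopifnot(is(analysis, "NetworkAnalysis"))
  paths <- vapply(seq_along(analysis@networks), function(i) {
    p <- file.path(dir, sprintf("network_%03d_genes.txt", i))
    writeLines(analysis@networks[[i]]@nodes$gene, p)
    p
  }, character(1))
  invisible(paths)
}

#' Paths of the worked-example fixture
#'
#' A six-edge interaction database around the \emph{C. elegans}
#' insulin/IGF-signalling hub \code{daf-16} and a five-gene candidate
#' list. The citation counts (one edge supported by 135 publications, five
#' edges by one each) follow the published description of this network;
#' the exact wiring of the unit edges is one admissible synthetic layout,
#' and the publication identifiers are synthetic. Running the pipeline at
#' depth 1 yields a single network of 6 nodes and 6 edges with score
#' 23.33, with \code{daf-2} appearing as a linker gene.
#'
#' @return named list with elements \code{db} and \code{genes}.
#' @export
iisExample <- function() {
  list(db = system.file("extdata", "iis_synthetic_interactions.tsv",
                        package = "linkernet", mustWork = TRUE),
       genes = system.file("extdata", "iis_example_genes.txt",
                           package = "linkernet", mustWork = TRUE))
}
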