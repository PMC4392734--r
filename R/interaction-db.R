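INTERACTION_CLASSES <- c("genetic", "physical")
EVIDENCE_CLASSES <- c("experimental", "predicted")
REQUIRED_COLUMNS <- c("gene_a", "gene_b", "interaction_class",
                      "evidence_class", "publications")

#' Read an interaction table
#'
#' Parses a tab-separated interaction database into one record per row.
#' The table must have a header naming the five required columns
#' \code{gene_a}, \code{gene_b}, \code{interaction_class}
#' (\code{genetic}/\code{physical}), \code{evidence_class}
#' (\code{experimental}/\code{predicted}) and \code{publications}
#' (delimiter-separated publication identifiers; may be empty only for
#' predicted interactions). Duplicate pairs are kept: merging happens in
#' [buildInteractionDb()].
#'
#' @param path file path.
#' @param sep column separator (default tab).
#' @param pubDelim delimiter between publication identifiers within the
#'   \code{publications} field (default \code{"|"}).
#' @param lenient if TRUE, malformed rows are skipped with a warning
#'   instead of failing.
#' @return data.frame of records with columns \code{geneA}, \code{geneB},
#'   \code{interactionClass}, \code{evidenceClass} and a list column
#'   \code{publications}.
#' @examples
#' tsv <- iisExample()$db
#' rec <- readInteractionTable(tsv)
#' head(rec)
#' @export
readInteractionTable <- function(path, sep = "\t", pubDelim = "|",
                                 lenient = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tab <- read.delim(path, sep = sep, header = TRUE, quote = "",
                    colClasses = "character", check.names = FALSE,
                    comment.char = "", blank.lines.skip = FALSE,
                    stringsAsFactors = FALSE)
  miss <- setdiff(REQUIRED_COLUMNS, names(tab))
  if (length(miss))
    stop("interaction table is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  n <- nrow(tab)
  if (!n) {
    out <- data.frame(geneA = character(0), geneB = character(0),
                      interactionClass = character(0),
                      evidenceClass = character(0),
                      stringsAsFactors = FALSE)
    out$publications <- list()
    return(out)
  }
  geneA <- trimws(tab$gene_a)
  geneB <- trimws(tab$gene_b)
  iclass <- trimws(tab$interaction_class)
  eclass <- trimws(tab$evidence_class)
  pubs <- lapply(strsplit(trimws(tab$publications), pubDelim, fixed = TRUE),
                 function(p) sortLex(unique(p[nzchar(trimws(p))])))
  pubs <- lapply(pubs, trimws)

  # header is file line 1, so data row i sits on file line i + 1
  bad <- character(0)
  line <- function(i) i + 1L
  problems <- !nzchar(geneA) | !nzchar(geneB)
  for (i in which(problems))
    bad[as.character(i)] <- sprintf("line %d: empty gene identifier", line(i))
  for (i in which(!iclass %in% INTERACTION_CLASSES))
    bad[as.character(i)] <- sprintf(
      "line %d: unknown interaction_class '%s'", line(i), iclass[i])
  for (i in which(!eclass %in% EVIDENCE_CLASSES))
    bad[as.character(i)] <- sprintf(
      "line %d: unknown evidence_class '%s'", line(i), eclass[i])
  noPub <- lengths(pubs) == 0L & eclass == "experimental"
  for (i in which(noPub))
    bad[as.character(i)] <- sprintf(
      "line %d: experimental interaction without supporting publications",
      line(i))
  if (length(bad)) {
    if (!lenient)
      stop("malformed interaction table:\n  ",
           paste(bad, collapse = "\n  "), call. = FALSE)
    warning("skipping ", length(bad), " malformed row(s):\n  ",
            paste(bad, collapse = "\n  "), call. = FALSE)
    keep <- setdiff(seq_len(n), as.integer(names(bad)))
  } else keep <- seq_len(n)

  out <- data.frame(geneA = geneA[keep], geneB = geneB[keep],
                    interactionClass = iclass[keep],
                    evidenceClass = eclass[keep],
                    stringsAsFactors = FALSE)
  out$publications <- pubs[keep]
  rownames(out) <- NULL
  out
}

#' Keep only experimentally confirmed interactions
#'
#' Drops records whose evidence class is \code{predicted}: interactions
#' that are only computationally inferred (e.g. from orthologous
#' interactions) carry no direct experimental support in the organism and
#' are excluded from network discovery.
#'
#' @param records record data.frame from [readInteractionTable()].
#' @return the experimental records, input order preserved.
#' @export
filterExperimental <- function(records) {
  stopifnot(is.data.frame(records), "evidenceClass" %in% names(records))
  out <- records[records$evidenceClass == "experimental", , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a canonical interaction database
#'
#' Drops self-interactions, canonicalizes each pair to alphabetical order,
#' and merges duplicate pairs by union of their publication sets and
#' interaction classes. The citation count of an edge is the number of
#' distinct publications supporting it after merging.
#'
#' @param records evidence-filtered record data.frame
#'   (see [filterExperimental()]).
#' @param universeSize optional total number of genes N for the enrichment
#'   universe; defaults to the number of genes in the database. Must not be
#'   smaller than that number.
#' @param caseFold if TRUE, gene identifiers are lower-cased before
#'   matching (default FALSE: distinct case = distinct locus).
#' @return an [InteractionDb-class].
#' @examples
#' rec <- readInteractionTable(iisExample()$db)
#' db <- buildInteractionDb(filterExperimental(rec))
#' db
#' @export
buildInteractionDb <- function(records, universeSize = NULL,
                               caseFold = FALSE) {
  stopifnot(is.data.frame(records))
  a <- trimws(records$geneA); b <- trimws(records$geneB)
  if (isTRUE(caseFold)) { a <- tolower(a); b <- tolower(b) }
  keep <- a != b                     # self-interactions contribute nothing
  a <- a[keep]; b <- b[keep]
  cls <- records$interactionClass[keep]
  pubs <- records$publications[keep]

  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  lv <- sortLex(unique(key))
  grp <- split(seq_along(key), factor(key, levels = lv))
  first <- vapply(grp, `[`, integer(1), 1L)
  edges <- data.frame(geneA = lo[first], geneB = hi[first],
                      stringsAsFactors = FALSE)
  edges$classes <- lapply(grp, function(i) sortLex(unique(cls[i])))
  edges$publications <- lapply(grp,
    function(i) sortLex(unique(unlist(pubs[i], use.names = FALSE))))
  edges$citations <- lengths(edges$publications)
  rownames(edges) <- NULL
  if (nrow(edges) && any(edges$citations == 0L))
    stop("retained edges must be supported by at least one publication; ",
         "did you forget filterExperimental()?", call. = FALSE)

  genes <- sortLex(unique(c(edges$geneA, edges$geneB)))
  if (is.null(universeSize)) {
    universeSize <- length(genes)
  } else {
    universeSize <- asCount(universeSize, "universeSize")
    if (universeSize < length(genes))
      stop(sprintf(
        "universeSize (%d) is smaller than the number of database genes (%d)",
        universeSize, length(genes)), call. = FALSE)
  }
  new("InteractionDb", edges = edges, genes = genes,
      universeSize = as.integer(universeSize))
}

#' Write a database back to the interaction-table dialect
#'
#' Emits one row per (pair, interaction class); re-reading and rebuilding
#' yields an identical database (round-trip).
#'
#' @param db an [InteractionDb-class].
#' @param path output file path.
#' @param pubDelim publication delimiter (default \code{"|"}).
#' @return invisibly, the path.
#' @export
writeInteractionTable <- function(db, path, pubDelim = "|") {
  stopifnot(is(db, "InteractionDb"))
  e <- db@edges
  rows <- if (nrow(e)) {
    reps <- lengths(e$classes)
    data.frame(
      gene_a = rep(e$geneA, reps), gene_b = rep(e$geneB, reps),
      interaction_class = unlist(e$classes, use.names = FALSE),
      evidence_class = "experimental",
      publications = rep(vapply(e$publications, paste,
                                character(1), collapse = pubDelim), reps),
      stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0),
               interaction_class = character(0),
               evidence_class = character(0),
               publications = character(0), stringsAsFactors = FALSE)
  }
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene list
#'
#' @param members character vector of gene identifiers; whitespace is
#'   stripped and duplicates removed, preserving first occurrence order.
#' @param sourcePath provenance string.
#' @return a [GeneList-class].
#' @export
geneList <- function(members, sourcePath = "<memory>") {
  m <- trimws(as.character(members))
  m <- m[nzchar(m)]
  m <- m[!duplicated(m)]
  new("GeneList", members = m, sourcePath = sourcePath)
}

#' Read a candidate gene list
#'
#' Plain text, one identifier per line; lines starting with \code{#} and
#' blank lines are ignored; duplicates are dropped, order preserved.
#'
#' @param path file path.
#' @return a [GeneList-class].
#' @export
readGeneList <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  geneList(lines, sourcePath = path)
}

#' Write a gene list
#' @param list a [GeneList-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGeneList <- function(list, path) {
  stopifnot(is(list, "GeneList"))
  writeLines(list@members, path)
  invisible(path)
}
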