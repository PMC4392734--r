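# Orchestration: config validation and the full load -> graph -> search ->
# stats -> report run. inst/scripts/discover-networks.R wraps this for the
# shell.

CONFIG_KEYS <- c("db", "genes", "out", "depth", "min_genes", "nsim",
                 "seed", "universe_size", "keep_predicted", "alpha")

#' Construct a run configuration
#'
#' @param db path to the interaction TSV.
#' @param genes path to the candidate gene-list file.
#' @param out output directory.
#' @param depth iteration depth D (default 2).
#' @param minGenes minimum list genes per reported network (default 2).
#' @param nsim permutation draws for the score p-value (default 10000).
#' @param seed random seed (mandatory).
#' @param universeSize optional genome-wide gene count for the enrichment
#'   universe; default: the number of genes in the database.
#' @param keepPredicted retain computationally predicted interactions
#'   (default FALSE).
#' @param alpha report significance threshold (default 0.01).
#' @return a [RunConfig-class].
#' @export
newRunConfig <- function(db, genes, out, depth = 2L, minGenes = 2L,
                         nsim = 10000L, seed, universeSize = NA,
                         keepPredicted = FALSE, alpha = 0.01) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  depth <- asCount(depth, "depth")
  if (depth < 1L) stop("depth must be >= 1 (got ", depth, ")", call. = FALSE)
  minGenes <- asCount(minGenes, "min_genes")
  if (minGenes < 2L) stop("min_genes must be >= 2", call. = FALSE)
  nsim <- asCount(nsim, "nsim")
  if (nsim < 0L) stop("nsim must be >= 0", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  us <- if (length(universeSize) == 1L && is.na(universeSize)) NA_integer_
    else asCount(universeSize, "universe_size")
  new("RunConfig", dbPath = as.character(db), genesPath = as.character(genes),
      outDir = as.character(out), maxDepth = depth,
      minListGenes = minGenes, nSim = nsim, seed = asCount(seed, "seed"),
      universeSize = us, keepPredicted = isTRUE(keepPredicted),
      alpha = alpha)
}

#' Validate a YAML run-configuration file
#'
#' Keys are the command-line flag names with dashes replaced by
#' underscores: \code{db}, \code{genes}, \code{out}, \code{depth},
#' \code{min_genes}, \code{nsim}, \code{seed}, \code{universe_size},
#' \code{keep_predicted}, \code{alpha}. Unknown keys and out-of-range
#' values are rejected with an informative error; omitted optional keys
#' get their documented defaults.
#'
#' @param path path to the YAML file.
#' @return a [RunConfig-class].
#' @export
validateConfig <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         "; valid keys are: ", paste(CONFIG_KEYS, collapse = ", "),
         call. = FALSE)
  for (k in c("db", "genes", "out", "seed"))
    if (is.null(raw[[k]]))
      stop("config is missing required key: ", k, call. = FALSE)
  newRunConfig(
    db = raw$db, genes = raw$genes, out = raw$out,
    depth = raw$depth %||% 2L, minGenes = raw$min_genes %||% 2L,
    nsim = raw$nsim %||% 10000L, seed = raw$seed,
    universeSize = raw$universe_size %||% NA,
    keepPredicted = raw$keep_predicted %||% FALSE,
    alpha = raw$alpha %||% 0.01)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stageCall <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("[stage: %s] %s", stage, conditionMessage(e)),
         call. = FALSE))
}

#' Run a full analysis from files to reports
#'
#' Orchestrates the pipeline: read the gene list and interaction table,
#' filter predicted interactions (unless configured otherwise), build the
#' database and the basic graph, discover and evaluate networks, and write
#' the artifacts into the output directory: \code{results.tsv},
#' \code{network_NNN.dot} and \code{network_NNN_genes.txt} per network,
#' \code{report.json}, and \code{run.log} (versions, seed, input digests,
#' stage counts; timestamps are confined to the log). Any failure raises
#' an error naming the failing stage.
#'
#' @param config a [RunConfig-class] (see [newRunConfig()],
#'   [validateConfig()]).
#' @return invisibly, the [NetworkAnalysis-class].
#' @export
runAnalysis <- function(config) {
  stopifnot(is(config, "RunConfig"))

  gl <- stageCall("gene list", {
    x <- readGeneList(config@genesPath)
    if (!length(x@members))
      stop("the candidate gene list is empty", call. = FALSE)
    x
  })

  counts <- list()
  db <- stageCall("interaction database", {
    rec <- readInteractionTable(config@dbPath)
    counts$recordsRead <- nrow(rec)
    if (!config@keepPredicted) rec <- filterExperimental(rec)
    counts$recordsRetained <- nrow(rec)
    us <- if (is.na(config@universeSize)) NULL else config@universeSize
    buildInteractionDb(rec, universeSize = us)
  })
  counts$edgesAfterMerge <- nrow(db@edges)

  cfg <- searchConfig(maxDepth = config@maxDepth,
                      minListGenes = config@minListGenes,
                      nSim = config@nSim, seed = config@seed)
  g <- stageCall("graph", buildBasicGraph(db, gl))
  counts$listGenesMatched <- length(g@nodes)
  nets <- stageCall("search", findNetworks(g, cfg))
  analysis <- stageCall("statistics", {
    stats <- lapply(nets, evaluateNetwork, db = db, list = gl, cfg = cfg)
    if (length(nets)) {
      score <- vapply(stats, function(s) s@score, numeric(1))
      lp <- vapply(stats, function(s) s@listPvalue, numeric(1))
      nn <- vapply(nets, function(n) nrow(n@nodes), integer(1))
      mg <- vapply(nets, function(n) n@nodes$gene[1L], character(1))
      ordn <- order(-score, lp, -nn, mg, method = "radix")
      nets <- nets[ordn]; stats <- stats[ordn]
    }
    new("NetworkAnalysis", networks = nets, stats = stats,
        table = buildResultTable(nets, stats), config = cfg,
        geneList = gl, universeSize = db@universeSize)
  })
  counts$networksFound <- length(analysis@networks)

  stageCall("report", {
    dir.create(config@outDir, recursive = TRUE, showWarnings = FALSE)
    writeResultsTable(analysis, file.path(config@outDir, "results.tsv"))
    for (i in seq_along(analysis@networks)) {
      dot <- networkToDot(analysis@networks[[i]], name = as.character(i))
      writeLines(dot, file.path(config@outDir,
                                sprintf("network_%03d.dot", i)), sep = "")
    }
    writeNetworkGeneLists(analysis, config@outDir)
    writeJsonReport(analysis, file.path(config@outDir, "report.json"))
    writeRunLog(config, counts, file.path(config@outDir, "run.log"))
  })
  invisible(analysis)
}

writeRunLog <- function(config, counts, path) {
  digest <- tools::md5sum(c(config@dbPath, config@genesPath))
  lines <- c(
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    sprintf("linkernet version: %s", packageVersion("linkernet")),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %d", config@seed),
    sprintf("depth: %d", config@maxDepth),
    sprintf("n_simulations: %d", config@nSim),
    sprintf("input %s md5 %s", names(digest), digest),
    vapply(names(counts), function(k)
      sprintf("count %s: %d", k, counts[[k]]), character(1)))
  writeLines(lines, path)
  message(paste(lines[-1L], collapse = "\n"))
  invisible(path)
}
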