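# internal helpers

# Evaluate expr with a fixed seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# Locale-independent lexicographic sort (byte order), for stable output.
sortLex <- function(x) sort(x, method = "radix")

orderLex <- function(...) order(..., method = "radix")

# Round half away from zero (report rendering; R's round() is half-to-even).
# The small fuzz keeps decimal halves like 2.005 (stored just below the
# half in binary) on the away-from-zero side.
roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

# Canonical unordered-pair key.
pairKey <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")

asCount <- function(x, what) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != as.integer(x))
    stop(sprintf("%s must be a single integer, got %s", what,
                 deparse(substitute(x))), call. = FALSE)
  as.integer(x)
}

emptyEdgeFrame <- function() {
  data.frame(geneA = character(0), geneB = character(0),
             citations = integer(0), stringsAsFactors = FALSE)
}
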