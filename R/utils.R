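# Internal helpers shared across modules.

# Deterministic 31-bit string hash (polynomial rolling hash mod 2^31 - 1).
# Used to derive per-event RNG substreams so cohort generation is reproducible
# independently of the order in which events are materialised.
stable_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  h <- 0
  m <- 2147483647
  for (b in utf8ToInt(x)) h <- (h * 31 + b) %% m
  as.integer(h)
}

# Substream seed for one event under a global seed; always < 2^31.
event_seed <- function(seed, event_id) {
  as.integer((as.numeric(seed) + stable_hash(as.character(event_id))) %% 2147483647)
}

# Evaluate `expr` under a local RNG seeded with `seed`, restoring the caller's
# RNG state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Total overlap in seconds between half-open [start, end) and a set of
# half-open intervals given as a 2-column matrix (start, end).
interval_overlap_s <- function(start_s, end_s, intervals) {
  if (is.null(intervals) || length(intervals) == 0L) return(0)
  intervals <- as_interval_matrix(intervals)
  sum(pmax(0, pmin(end_s, intervals[, 2]) - pmax(start_s, intervals[, 1])))
}

# Normalise interval input (list of pairs, vector pair, or matrix) to an
# n x 2 matrix; validates start < end.
as_interval_matrix <- function(x) {
  if (is.null(x)) return(matrix(numeric(0), ncol = 2))
  if (is.list(x)) x <- do.call(rbind, lapply(x, function(p) as.numeric(p)))
  if (is.vector(x) && length(x) == 2L) x <- matrix(as.numeric(x), ncol = 2)
  x <- matrix(as.numeric(x), ncol = 2)
  if (nrow(x) > 0 && any(x[, 1] >= x[, 2]))
    stop("interval start must be < end")
  x
}

# Short fingerprint of a configuration list, recorded in artifact metadata.
config_hash <- function(cfg) {
  json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA, force = TRUE)
  sprintf("%08x", stable_hash(as.character(json)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
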