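# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators do not disturb the global stream.
#' A `NULL` seed evaluates the code with the current stream.
#'
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # initialise the stream so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  code
}

# Clamp values to [lo, hi]; used for reflectance ceilings.
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Stop with a classed condition so callers can test error kinds.
ps_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phenospectra_error")))
}

# Draw a child seed deterministically from a parent seed and a tag, keeping
# the result within 32-bit integer range.
child_seed <- function(seed, tag) {
  if (is.null(seed)) return(NULL)
  ch <- utf8ToInt(as.character(tag))
  h <- sum(ch * seq_along(ch))
  # double-precision arithmetic is exact here; keep within 32-bit range
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}
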