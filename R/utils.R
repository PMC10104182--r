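#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so library functions never disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a named substream seed from a root seed
#'
#' All randomness in a run flows from one root seed; each stage/subject draws
#' from its own substream so cohorts are extensible without reshuffling
#' already-generated subjects.
#'
#' @param root integer root seed.
#' @param stream character stream label (e.g. "subject", "leadfield").
#' @param index integer index within the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(root, stream, index = 0L) {
  stopifnot(is.numeric(root), length(root) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  m <- 2147483647
  # mixed congruential fold; doubles are exact below 2^53 so no overflow
  s <- (abs(root) %% m) * 48271 %% m
  s <- (s + h * 69621 + index * 16807) %% m
  as.integer(s)
}

#' Lightweight checksum of an R object
#'
#' Position-weighted byte checksum of the serialized object, used in run
#' manifests to assert bit-identical re-runs. Not cryptographic.
#'
#' @param x any serializable object.
#' @return a character checksum.
#' @export
object_checksum <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  b <- as.integer(raw)
  n <- length(b)
  w <- (seq_len(n) - 1) %% 9973 + 1
  s1 <- as.integer(sum(b) %% 2147483647)
  s2 <- as.integer(sum(b * w) %% 2147483647)
  sprintf("%08x-%08x-%d", s1, s2, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
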