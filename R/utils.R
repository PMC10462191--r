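#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` with the global RNG seeded at `seed`, then restores the
#' previous RNG state so callers' random streams are unaffected.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a top-level seed and a label
#'
#' One top-level seed deterministically spawns independent sub-streams for
#' per-subject and per-stage randomness, so partial re-runs are reproducible.
#' The result is always in `[1, 2^31 - 2]`.
#'
#' @param seed top-level integer seed.
#' @param ... labels (characters or numbers) identifying the sub-stream.
#' @return integer sub-seed.
#' @export
derive_seed <- function(seed, ...) {
  labs <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  h <- as.numeric(seed) %% 2147483647
  h <- (h * 48271) %% 2147483647
  for (ch in utf8ToInt(labs)) h <- (h * 131 + ch) %% 2147483647
  as.integer(h %% 2147483645 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
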