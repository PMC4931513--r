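#' Run code with a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates \code{expr}
#' and restores the previous state on exit, so seeded helpers do not disturb
#' the session stream.
#'
#' @param seed integer seed, or \code{NULL} to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of \code{expr}.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-stage seed from a master seed
#'
#' All pipeline randomness flows from one top-level seed; each stage (and
#' each field within a stage) gets a deterministic child seed that stays
#' within the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param ... further integer or character stream identifiers.
#' @return an integer seed in \code{[0, 2^31 - 2]}.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) p <- sum(utf8ToInt(p) * seq_along(utf8ToInt(p)))
    for (v in as.double(p)) h <- (h * 48271 + v + 1) %% 2147483647
  }
  as.integer(h)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower)
    stop(sprintf("'%s' must be a single number >= %s", name, lower), call. = FALSE)
  invisible(x)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a
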