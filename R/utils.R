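#' Derive a reproducible substream seed
#'
#' All randomness in a study run descends from one master seed. Each stage,
#' subject or bootstrap draws from its own substream whose seed is a
#' deterministic hash of the master seed and a path of labels, so results do
#' not depend on execution order.
#'
#' @param master integer master seed.
#' @param ... further labels (coerced to character) identifying the stage and
#'   unit, e.g. `derive_seed(1, "simulate", "S007")`.
#' @return An integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  stopifnot(is.numeric(master), length(master) == 1L, is.finite(master))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; keeps seeds in 32-bit range
  h <- as.numeric(master) %% m
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  for (b in utf8ToInt(labels)) {
    h <- (h * 131 + b) %% m
  }
  # final avalanche round so similar paths do not give adjacent seeds
  for (i in 1:3) h <- (h * 48271) %% m
  as.integer(h %% (m - 1L)) + 1L
}

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state, so seeded internals do not
#' disturb user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

stop_if_not_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}
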