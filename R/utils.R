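# internal helpers shared across modules

#' Derive a child seed from a master seed
#'
#' Deterministically maps a master seed and an integer stream label to a new
#' seed in `[1, 2^31 - 2]`, so that independent pipeline stages (lookup-table
#' build, noise, data split, model initialisation) each get their own stream
#' from one user-facing seed.
#'
#' @param seed Master seed (single integer-valued number).
#' @param stream Stream label (single integer-valued number).
#' @return A single integer seed.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.numeric(stream), length(stream) == 1L, is.finite(stream))
  # 64-bit-free mixing that stays exact in doubles (< 2^53)
  x <- (abs(seed) %% 2147483647) + 1
  y <- (abs(stream) %% 2147483647) + 1
  m <- 2147483629
  v <- (x * 48271) %% m
  v <- (v + y * 16807) %% m
  v <- (v * 69621) %% m
  as.integer(v %% 2147483645 + 1)
}

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed` and restores the
#' caller's `.Random.seed` afterwards, so seeded helpers never disturb the
#' surrounding random state.
#'
#' @param seed Seed for the temporary RNG state.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_domain <- function(...) stop(..., call. = FALSE)
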