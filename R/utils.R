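# Internal helpers shared across modules.

#' Evaluate an expression with a temporary, restorable RNG state
#'
#' All stochastic operations in the package funnel their randomness through
#' this helper so that every user-facing function is deterministic given its
#' `seed` argument and leaves the caller's RNG state untouched.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion")
  expr
}

# Mix integers (or strings, hashed bytewise) into one 31-bit seed.
mix_seed <- function(...) {
  xs <- list(...)
  h <- 0
  for (x in xs) {
    if (is.character(x)) x <- sum(utf8ToInt(paste(x, collapse = "")) *
                                    seq_along(utf8ToInt(paste(x, collapse = ""))))
    for (xi in x) h <- (h * 1103515245 + (as.numeric(xi) %% 2147483647)) %% 2147483647
  }
  as.integer(h)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

sigmoid <- function(x) 1 / (1 + exp(-x))

stopifnot_scalar_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x >= 1)
    stop(sprintf("`%s` must be a single number in [0, 1)", name),
         call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
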