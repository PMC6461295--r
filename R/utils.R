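# Internal utilities: seed handling and small helpers.

#' Derive a deterministic sub-seed
#'
#' Derives a child seed from a parent seed and a string key, so that every
#' stochastic stage of an analysis can be seeded independently but
#' reproducibly from one master seed.
#'
#' @param seed Integer master seed.
#' @param key Character key naming the consumer (e.g. `"schedule"`,
#'   `"cond37"`).
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(key)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
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
  set.seed(as.integer(seed %% 2147483647))
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ <- function(...) stop(sprintf(...), call. = FALSE)

# logit / inverse logit used for optimisation of p_common
logit <- function(p) log(p) - log1p(-p)
inv_logit <- function(x) 1 / (1 + exp(-x))
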