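`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG state
#'
#' Runs `expr` after `set.seed(seed)` and restores the caller's random number
#' stream afterwards, so seeded helpers do not perturb outer simulations.
#' With `seed = NULL` the expression runs on the current stream.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  expr
}

## mix a base seed with a stage index, staying inside 32-bit integer range
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + 97 * k) %% 2147483647L)
}

is_count <- function(x, min = 1L) {
  length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

plog2 <- function(p) {
  out <- numeric(length(p))
  pos <- p > 0
  out[pos] <- p[pos] * log2(p[pos])
  out
}
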