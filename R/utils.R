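#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state.  All exported stochastic operations route through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("a seed is required for deterministic generation")
  seed <- check_seed(seed)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

check_seed <- function(seed) {
  if (length(seed) != 1L || !is.finite(seed) || seed != round(seed)) {
    stop("seed must be a single integer")
  }
  as.integer(seed)
}

# Deterministic per-unit sub-seeds derived from one master seed, so that
# every neuron / stage draws from an independent, reproducible stream.
derive_subseeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_num <- function(x, name, min = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x)) {
    stop(sprintf("%s must be a finite numeric scalar", name))
  }
  if (x < min) stop(sprintf("%s must be >= %s", name, format(min)))
  invisible(x)
}
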