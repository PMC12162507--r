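`%||%` <- function(x, y) if (is.null(x)) y else x

#' @keywords internal
assert_that <- function(ok, ..., call. = FALSE) {
  if (!isTRUE(ok)) stop(..., call. = call.)
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)
}
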