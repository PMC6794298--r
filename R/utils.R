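## Seed handling. All stochastic operations take an explicit seed and run in
## a local RNG scope, so library calls never disturb the caller's RNG state
## and the same seed always reproduces the same draws.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Deterministic child seeds from one root seed; stays inside 32-bit range.
derive_seed <- function(root, offset) {
  as.integer((as.numeric(root) * 48271 + as.numeric(offset) * 10007) %%
               2147483563)
}

.assert_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", name, "' must be a single finite number")
  if (positive && x <= 0)
    stop("'", name, "' must be > 0")
  invisible(x)
}
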