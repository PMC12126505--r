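# Internal helpers shared across modules.

# Run `expr` under a temporarily seeded RNG, restoring the caller's RNG state.
# seed = NULL means: use (and advance) the global RNG stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

check_square <- function(x, name = "matrix") {
  if (!is.matrix(x) || nrow(x) != ncol(x))
    stop(sprintf("'%s' must be a square matrix", name), call. = FALSE)
  invisible(x)
}

is_hollow_symmetric <- function(x, tol = 1e-8) {
  isTRUE(all(abs(x - t(x)) <= tol)) && isTRUE(all(abs(diag(x)) <= tol))
}

# Indices of the strict upper triangle in column-major order.
upper_idx <- function(n) which(upper.tri(matrix(0L, n, n)))

# Flatten the strict upper triangle of a square matrix.
ut <- function(a) a[upper.tri(a)]

# Inverse of ut(): build a symmetric hollow matrix from its upper triangle.
sym_from_ut <- function(v, n) {
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- v
  a + t(a)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
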