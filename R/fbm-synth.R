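#' Specification of a fractional Brownian motion ensemble
#'
#' Bundles the parameters of a discrete fractional Brownian motion (fBm)
#' ensemble: trajectories of `n_points` positions in `dim` dimensions whose
#' D-dimensional mean-squared displacement grows as
#' \eqn{\langle r^2(s)\rangle = a^2 s^{2H}} with contour separation `s`,
#' where `a = step_scale` is the typical single-jump displacement and `H` the
#' Hurst (memory) exponent. Each coordinate component is an independent fBm
#' with per-component variance \eqn{a^2 s^{2H} / D}, so the full-dimensional
#' displacement statistics follow the Gaussian propagator of the process.
#'
#' @param hurst Hurst exponent, in (0, 1). `H < 1/2` is subdiffusive
#'   (anti-persistent increments), `H = 1/2` Brownian, `H > 1/2`
#'   superdiffusive. Chromosomes without cohesin-mediated loops are well
#'   described by `H = 1/3` (fractal dimension 3).
#' @param n_points Number of positions per trajectory (>= 2).
#' @param dim Spatial dimension `D` (default 3).
#' @param step_scale Typical single-jump displacement `a` (default 1);
#'   use a length in nm for microscopy-scale fixtures.
#' @param count Ensemble size `M`.
#' @param seed Optional integer seed for reproducible sampling.
#' @return An object of class `"fbm_spec"`.
#' @seealso [sample_fbm()], [edm_from_trajectory()]
#' @export
fbm_spec <- function(hurst, n_points, dim = 3L, step_scale = 1,
                     count = 1L, seed = NULL) {
  stopifnot(is.numeric(hurst), length(hurst) == 1L)
  if (!(hurst > 0 && hurst < 1))
    stop("'hurst' must lie strictly inside (0, 1)", call. = FALSE)
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("'n_points' must be >= 2", call. = FALSE)
  dim <- as.integer(dim)
  if (dim < 1L) stop("'dim' must be >= 1", call. = FALSE)
  if (!(step_scale > 0)) stop("'step_scale' must be positive", call. = FALSE)
  count <- as.integer(count)
  if (count < 1L) stop("'count' must be >= 1", call. = FALSE)
  structure(list(hurst = hurst, n_points = n_points, dim = dim,
                 step_scale = step_scale, count = count, seed = seed),
            class = "fbm_spec")
}

#' @export
print.fbm_spec <- function(x, ...) {
  cat(sprintf("fBm spec: H = %.4g, n = %d, D = %d, a = %g, M = %d\n",
              x$hurst, x$n_points, x$dim, x$step_scale, x$count))
  invisible(x)
}

# Autocovariance of fractional Gaussian noise (unit-variance increments).
fgn_gamma <- function(k, hurst) {
  0.5 * ((k + 1)^(2 * hurst) - 2 * k^(2 * hurst) + abs(k - 1)^(2 * hurst))
}

# Sample M columns of fractional Gaussian noise of length n_inc by circulant
# embedding (Davies-Harte). Returns NULL when the embedding is not PSD.
fgn_davies_harte <- function(n_inc, hurst, m_cols) {
  if (n_inc == 1L)
    return(matrix(stats::rnorm(m_cols), 1L, m_cols))
  m <- 2L * n_inc
  g <- fgn_gamma(0:n_inc, hurst)
  cvec <- c(g, rev(g[2:n_inc]))
  lam <- Re(stats::fft(cvec))
  if (any(lam < -1e-10 * max(lam))) return(NULL)
  lam <- pmax(lam, 0)
  half <- m %/% 2L
  v <- matrix(0 + 0i, m, m_cols)
  v[1L, ] <- sqrt(lam[1L]) * stats::rnorm(m_cols)
  v[half + 1L, ] <- sqrt(lam[half + 1L]) * stats::rnorm(m_cols)
  u <- matrix(stats::rnorm((half - 1L) * m_cols), half - 1L, m_cols)
  w <- matrix(stats::rnorm((half - 1L) * m_cols), half - 1L, m_cols)
  v[2L:half, ] <- sqrt(lam[2L:half] / 2) * (u + 1i * w)
  v[(half + 2L):m, ] <- Conj(v[half:2L, , drop = FALSE])
  x <- Re(stats::mvfft(v)) / sqrt(m)
  x[seq_len(n_inc), , drop = FALSE]
}

# Exact fallback sampler: Cholesky factor of the fGn covariance.
fgn_cholesky <- function(n_inc, hurst, m_cols) {
  gam <- fgn_gamma(0:(n_inc - 1L), hurst)
  sig <- stats::toeplitz(gam)
  l <- chol(sig)
  crossprod(l, matrix(stats::rnorm(n_inc * m_cols), n_inc, m_cols))
}

#' Sample discrete fBm trajectories
#'
#' Draws `spec$count` independent trajectories whose coordinate components
#' are independent discrete fBm paths with the prescribed Hurst exponent,
#' using the Davies-Harte circulant-embedding sampler (exact in
#' distribution). If the circulant embedding fails to be positive
#' semidefinite - possible at extreme `H` with very short trajectories - the
#' sampler falls back to exact Cholesky sampling and emits a warning. The
#' first point of every trajectory is the origin, and the per-component
#' increment scale is `step_scale / sqrt(dim)` so that the full-dimensional
#' mean-squared displacement is \eqn{a^2 s^{2H}}.
#'
#' @param spec An [fbm_spec()].
#' @param seed Integer seed; defaults to `spec$seed`. `NULL` uses the
#'   current RNG stream.
#' @return List of `count` trajectories, each an `n_points x dim` matrix.
#' @export
sample_fbm <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "fbm_spec"))
  n_inc <- spec$n_points - 1L
  m_cols <- spec$count * spec$dim
  with_seed(seed, {
    inc <- fgn_davies_harte(n_inc, spec$hurst, m_cols)
    if (is.null(inc)) {
      warning("circulant embedding not PSD; falling back to exact Cholesky sampling")
      inc <- fgn_cholesky(n_inc, spec$hurst, m_cols)
    }
    inc <- inc * (spec$step_scale / sqrt(spec$dim))
    paths <- rbind(0, apply(inc, 2L, cumsum))
    if (n_inc == 1L) paths <- rbind(0, matrix(inc, 1L, m_cols))
    lapply(seq_len(spec$count), function(j) {
      cols <- ((j - 1L) * spec$dim + 1L):(j * spec$dim)
      paths[, cols, drop = FALSE]
    })
  })
}

#' Squared-distance matrix of a trajectory
#'
#' Builds the Euclidean distance matrix (EDM) of squared pairwise distances
#' \eqn{a_{ij} = \|x_i - x_j\|^2} from a point configuration. The result is
#' symmetric, hollow and non-negative, and for points in general position in
#' `D` dimensions has rank `min(n, D + 2)`.
#'
#' @param points An `n x D` matrix of coordinates (finite).
#' @return An `n x n` squared-distance matrix.
#' @export
edm_from_trajectory <- function(points) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (!all(is.finite(points)))
    stop("trajectory coordinates must be finite", call. = FALSE)
  a <- as.matrix(stats::dist(points))^2
  dimnames(a) <- NULL
  diag(a) <- 0
  a
}

#' EDM ensemble for an fBm specification
#'
#' Convenience wrapper: samples trajectories and converts each to its EDM.
#'
#' @inheritParams sample_fbm
#' @return List of `count` squared-distance matrices.
#' @export
sample_fbm_edms <- function(spec, seed = spec$seed) {
  lapply(sample_fbm(spec, seed = seed), edm_from_trajectory)
}

#' Bernoulli corruption mask
#'
#' Draws an i.i.d. Bernoulli mask on the strict upper triangle - the
#' probability of an entry being unknown (0) equals the requested missing
#' ratio `mu` - and mirrors it to the lower triangle. The diagonal is always
#' 0 by the mask convention (`b_ii = 0`).
#'
#' @param n Matrix size (>= 2).
#' @param mu Target missing ratio in \[0, 1\].
#' @param seed Optional integer seed.
#' @return An `n x n` binary mask matrix (1 = known, 0 = unknown).
#' @seealso [missing_ratio()], [rowcol_mask()]
#' @export
bernoulli_mask <- function(n, mu, seed = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("'n' must be >= 2", call. = FALSE)
  if (!is.numeric(mu) || mu < 0 || mu > 1)
    stop("'mu' must lie in [0, 1]", call. = FALSE)
  with_seed(seed, {
    v <- as.numeric(stats::runif(n * (n - 1L) / 2L) >= mu)
    sym_from_ut(v, n)
  })
}

#' Row/column corruption mask
#'
#' Masks entire rows and the matching columns: entry (i, j) is unknown iff
#' `i` or `j` is a masked index (or `i == j`). This is the corruption pattern
#' of chromatin-tracing experiments, where a locus that fails to image drops
#' a whole row/column of the per-cell distance matrix.
#'
#' @param n Matrix size.
#' @param indices Integer vector of masked row/column indices (1-based).
#' @return An `n x n` binary mask matrix.
#' @export
rowcol_mask <- function(n, indices) {
  n <- as.integer(n)
  indices <- as.integer(indices)
  if (length(indices) && (any(indices < 1L) || any(indices > n)))
    stop("mask indices out of range 1..n", call. = FALSE)
  b <- matrix(1, n, n)
  b[indices, ] <- 0
  b[, indices] <- 0
  diag(b) <- 0
  b
}

#' Corrupt an EDM with a mask
#'
#' Produces a partial EDM: known entries are copied verbatim from `edm`,
#' unknown entries are stored as `NA` and must be ignored by all consumers.
#'
#' @param edm Squared-distance matrix.
#' @param mask Binary mask of the same shape (1 = known).
#' @return An object of class `"partial_edm"` with fields `values` (matrix
#'   with `NA` at unknown entries) and `mask`.
#' @export
corrupt <- function(edm, mask) {
  check_square(edm, "edm"); check_square(mask, "mask")
  if (!identical(dim(edm), dim(mask)))
    stop("'edm' and 'mask' shapes differ", call. = FALSE)
  values <- edm
  unknown <- mask == 0
  diag(unknown) <- FALSE   # the diagonal is structurally zero, not missing
  values[unknown] <- NA_real_
  structure(list(values = values, mask = mask), class = "partial_edm")
}

#' @export
print.partial_edm <- function(x, ...) {
  cat(sprintf("partial EDM: n = %d, missing ratio = %.4f\n",
              nrow(x$values), missing_ratio(x$mask)))
  invisible(x)
}

# Known entries with unknowns zero-filled (the \tilde A . B convention).
zero_filled <- function(partial) {
  v <- partial$values
  v[partial$mask == 0] <- 0
  v
}
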