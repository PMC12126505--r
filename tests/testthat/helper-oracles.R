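# Independent oracles used to freeze expected values; these deliberately
# avoid the code paths they check.

# Exact fGn autocovariance (direct formula).
oracle_fgn_gamma <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Optimal rigid alignment residual (orthogonal Procrustes after centring).
oracle_procrustes_residual <- function(x, y) {
  xc <- scale(x, scale = FALSE); yc <- scale(y, scale = FALSE)
  s <- svd(crossprod(yc, xc))
  rot <- s$u %*% t(s$v)
  sqrt(sum((yc %*% rot - xc)^2) / nrow(x))
}

# Rank of the bar-and-joint rigidity matrix at generic coordinates: one row
# per edge, row for edge (i,j) holds (x_i - x_j) in i's column block and its
# negative in j's. Rank 3n - 6 certifies infinitesimal rigidity in 3-D.
oracle_rigidity_matrix_rank <- function(mask, coords) {
  n <- nrow(mask)
  edges <- which(upper.tri(mask) & mask == 1, arr.ind = TRUE)
  r <- matrix(0, nrow(edges), 3L * n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    d <- coords[i, ] - coords[j, ]
    r[e, (3 * i - 2):(3 * i)] <- d
    r[e, (3 * j - 2):(3 * j)] <- -d
  }
  qr(r)$rank
}

# Exhaustive masked discrepancy of a query against every database entry.
oracle_db_eps <- function(partial, db_list) {
  b <- partial$mask
  atil <- partial$values
  atil[b == 0] <- 0
  vapply(db_list, function(a) sum((b * (a - atil))^2), numeric(1))
}

full_mask <- function(n) {
  m <- matrix(1, n, n); diag(m) <- 0; m
}

ut <- function(a) a[upper.tri(a)]

is_hollow_symmetric_test <- function(a, tol = 1e-9) {
  all(abs(a - t(a)) <= tol) && all(abs(diag(a)) <= tol)
}

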