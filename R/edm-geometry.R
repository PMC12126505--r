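#' Origin-pinned Gram matrix of a complete EDM
#'
#' Converts a complete squared-distance matrix into the (n-1) x (n-1) Gram
#' matrix of inner products relative to the point pinned at the origin:
#' \eqn{\tilde g_{ij} = (a_{1i} - a_{ij} + a_{1j}) / 2}, where index 1 stands
#' for `origin_index`. For an exact EDM of points in `D` dimensions this
#' matrix is positive semidefinite with rank at most `D` (Schoenberg).
#'
#' @param edm Complete squared-distance matrix (no `NA`).
#' @param origin_index Index of the point placed at the origin (default 1).
#' @return `(n-1) x (n-1)` Gram matrix with attribute `origin_index`.
#' @export
gram_from_edm <- function(edm, origin_index = 1L) {
  check_square(edm, "edm")
  if (anyNA(edm))
    stop("'edm' has undefined entries; complete matrices only", call. = FALSE)
  n <- nrow(edm)
  origin_index <- as.integer(origin_index)
  stopifnot(origin_index >= 1L, origin_index <= n)
  rest <- setdiff(seq_len(n), origin_index)
  a1 <- edm[origin_index, rest]
  g <- 0.5 * (outer(a1, rep(1, n - 1L)) - edm[rest, rest, drop = FALSE] +
                outer(rep(1, n - 1L), a1))
  attr(g, "origin_index") <- origin_index
  g
}

#' Schoenberg realizability check
#'
#' A complete symmetric hollow matrix is an EDM of points embeddable in `D`
#' dimensions iff its origin-pinned Gram matrix is positive semidefinite
#' with rank at most `D`. The check uses a relative eigenvalue tolerance:
#' no eigenvalue below `-tol * max|eig|`, and at most `D` eigenvalues above
#' `tol * max|eig|`.
#'
#' @param edm Complete squared-distance matrix.
#' @param D Target embedding dimension (default 3).
#' @param tol Relative eigenvalue tolerance (default 1e-8).
#' @return Logical with attribute `eigenvalues` (sorted decreasing).
#' @export
schoenberg_check <- function(edm, D = 3L, tol = 1e-8) {
  g <- gram_from_edm(edm)
  ev <- eigen((g + t(g)) / 2, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(abs(ev), .Machine$double.eps)
  ok <- all(ev > -tol * scale) && sum(ev > tol * scale) <= D
  structure(ok, eigenvalues = ev)
}

#' Coordinate realization of an EDM (classical MDS)
#'
#' Recovers a point configuration from a complete squared-distance matrix by
#' eigendecomposition of the double-centred Gram matrix
#' \eqn{G = -\frac12 J A J}, keeping the top `D` eigenpairs. For an exact
#' EDM the reconstruction reproduces the input distances to numerical
#' precision (up to a rigid transformation of the points). For noisy or
#' non-EDM input the result is the best rank-`D` Gram approximation and the
#' returned attribute `warning_flag` is set when negative eigenvalues of
#' non-trivial magnitude are discarded.
#'
#' @param edm Complete squared-distance matrix.
#' @param D Embedding dimension (default 3).
#' @return `n x D` coordinate matrix (centred), with attributes
#'   `eigenvalues` and `warning_flag`.
#' @export
realize <- function(edm, D = 3L) {
  check_square(edm, "edm")
  if (anyNA(edm)) stop("'edm' has undefined entries", call. = FALSE)
  n <- nrow(edm)
  D <- as.integer(D)
  g <- -0.5 * edm
  rm_ <- rowMeans(g)
  g <- g - outer(rm_, rep(1, n)) - outer(rep(1, n), rm_) + mean(g)
  e <- eigen((g + t(g)) / 2, symmetric = TRUE)
  lam <- e$values
  top <- seq_len(min(D, n))
  pos <- pmax(lam[top], 0)
  x <- e$vectors[, top, drop = FALSE] %*% diag(sqrt(pos), length(top))
  if (ncol(x) < D) x <- cbind(x, matrix(0, n, D - ncol(x)))
  flag <- min(lam) < -1e-6 * max(abs(lam), .Machine$double.eps)
  structure(x, eigenvalues = lam, warning_flag = flag)
}

#' Fraction of the spectrum carried by the leading singular values
#'
#' Returns \eqn{\sqrt{\sum_{i=1}^r \lambda_i^2} / \sqrt{\sum_i \lambda_i^2}}
#' over singular values sorted in decreasing order. For an exact EDM of
#' 3-D points (`rank <= 5`) the value is 1 at `r = 5`; deviations below 1
#' measure how far a completed matrix is from the low-rank EDM manifold.
#'
#' @param a Square matrix.
#' @param r Number of leading singular values (default 5).
#' @return Value in (0, 1\].
#' @export
rank_fraction <- function(a, r = 5L) {
  check_square(a, "a")
  sv <- svd(a, nu = 0, nv = 0)$d
  r <- min(as.integer(r), length(sv))
  sqrt(sum(sv[seq_len(r)]^2)) / sqrt(sum(sv^2))
}

#' Missing ratio of a mask
#'
#' \eqn{\mu = 2m / (n(n-1))} where `m` is the number of unknown unordered
#' off-diagonal pairs.
#'
#' @param mask Binary mask matrix (1 = known, 0 = unknown; zero diagonal).
#' @return Missing ratio in \[0, 1\].
#' @export
missing_ratio <- function(mask) {
  check_square(mask, "mask")
  n <- nrow(mask)
  m <- sum(ut(mask) == 0)
  2 * m / (n * (n - 1))
}

#' Validate a partial EDM
#'
#' Report-only checks of the necessary conditions for completability:
#' symmetry and hollowness of the stored values, non-negativity over known
#' entries, and the triangle inequality \eqn{\sqrt{a_{ij}} \le
#' \sqrt{a_{ik}} + \sqrt{a_{kj}}} over all triples whose three pairwise
#' entries are known.
#'
#' @param partial A [corrupt()] result (or complete EDM via a full mask).
#' @param tol Absolute tolerance on the triangle slack (default 1e-8,
#'   in units of distance).
#' @return List with logical flags `symmetric`, `hollow`, `nonnegative`,
#'   a matrix `triangle_violations` (one row per violated triple, columns
#'   i, j, k and slack), and `n_triples_checked`.
#' @export
validate_partial <- function(partial, tol = 1e-8) {
  stopifnot(inherits(partial, "partial_edm"))
  v <- partial$values; b <- partial$mask
  n <- nrow(v)
  vz <- v; vz[is.na(vz)] <- 0
  symmetric <- all(abs(vz - t(vz)) <= tol) && identical(is.na(v), is.na(t(v)))
  hollow <- all(abs(diag(vz)) <= tol)
  known <- b == 1 & !is.na(v)
  nonnegative <- all(v[known] >= -tol)
  viol <- matrix(numeric(0), 0L, 4L,
                 dimnames = list(NULL, c("i", "j", "k", "slack")))
  n_checked <- 0L
  if (n >= 3L) {
    trip <- t(utils::combn(n, 3L))
    keep <- b[trip[, c(1L, 2L)]] * b[trip[, c(1L, 3L)]] *
      b[trip[, c(2L, 3L)]] == 1
    trip <- trip[keep, , drop = FALSE]
    n_checked <- nrow(trip)
    if (n_checked) {
      d <- sqrt(pmax(vz, 0))
      dij <- d[trip[, c(1L, 2L)]]
      dik <- d[trip[, c(1L, 3L)]]
      djk <- d[trip[, c(2L, 3L)]]
      slack <- pmax(dij - dik - djk, dik - dij - djk, djk - dij - dik)
      bad <- slack > tol
      if (any(bad)) {
        viol <- cbind(trip[bad, , drop = FALSE], slack[bad])
        colnames(viol) <- c("i", "j", "k", "slack")
      }
    }
  }
  list(symmetric = symmetric, hollow = hollow, nonnegative = nonnegative,
       triangle_violations = viol, n_triples_checked = n_checked,
       ok = symmetric && hollow && nonnegative && nrow(viol) == 0L)
}

#' Squared gyration radius from an EDM
#'
#' \eqn{R_g^2 = \frac{1}{2n^2}\sum_{ij} a_{ij}}, identical to the mean
#' squared distance of the realized points from their centroid.
#'
#' @param edm Complete squared-distance matrix.
#' @return Squared gyration radius (squared length units).
#' @export
gyration_radius <- function(edm) {
  check_square(edm, "edm")
  if (anyNA(edm)) stop("'edm' has undefined entries", call. = FALSE)
  sum(edm) / (2 * nrow(edm)^2)
}

# Greedy clique expansion from a start vertex: repeatedly add the
# highest-degree vertex adjacent to every current member.
grow_clique <- function(adj, start, degree) {
  members <- start
  cand <- which(adj[start, ] == 1)
  while (length(cand)) {
    pick <- cand[which.max(degree[cand])]
    members <- c(members, pick)
    cand <- cand[adj[pick, cand] == 1 & cand != pick]
  }
  sort(members)
}

#' Greedy rigidity certificate for a partial-EDM mask
#'
#' Tests whether the partial graph defined by a mask is (generically) rigid
#' in `D` dimensions, which certifies that the EDM completion is unique.
#' The test grows a rigid subgraph: it seeds with a clique of at least
#' `D + 1` vertices (found by degree-ordered greedy expansion with
#' `restarts` different starting vertices), then repeatedly absorbs the
#' external vertex with the most links into the absorbed set, requiring at
#' least `D + 1` links (ties broken by lowest vertex index). The graph is
#' certified rigid iff all vertices are absorbed. The certificate is
#' sufficient, not necessary: `rigid = FALSE` means "not certified".
#'
#' For graphs with fewer than `D + 1` vertices the report is rigid iff the
#' graph is complete.
#'
#' @param mask Binary mask matrix interpreted as the adjacency matrix of the
#'   partial graph (1 = edge / known distance).
#' @param D Embedding dimension (default 3, so the link threshold is 4).
#' @param restarts Number of seed-clique starting vertices tried (default 32).
#' @return Object of class `"rigidity_report"`: list with `rigid`,
#'   `seed_clique`, `addition_order` (two-column matrix vertex/link_count),
#'   `absorbed`, `n`, `D`.
#' @export
rigidity_test <- function(mask, D = 3L, restarts = 32L) {
  check_square(mask, "mask")
  n <- nrow(mask)
  D <- as.integer(D)
  adj <- (mask != 0) * 1L
  diag(adj) <- 0L
  adj <- ((adj + t(adj)) > 0) * 1L
  if (n < D + 1L) {
    complete <- all(ut(adj) == 1)
    return(structure(list(rigid = complete, seed_clique = seq_len(n),
                          addition_order = matrix(integer(0), 0L, 2L,
                            dimnames = list(NULL, c("vertex", "link_count"))),
                          absorbed = if (complete) seq_len(n) else integer(0),
                          n = n, D = D),
                     class = "rigidity_report"))
  }
  degree <- colSums(adj)
  starts <- order(degree, decreasing = TRUE)[seq_len(min(restarts, n))]
  cliques <- unique(lapply(starts, grow_clique, adj = adj, degree = degree))
  cliques <- cliques[order(vapply(cliques, length, 1L), decreasing = TRUE)]
  best <- list(rigid = FALSE, seed_clique = cliques[[1L]],
               addition_order = matrix(integer(0), 0L, 2L,
                 dimnames = list(NULL, c("vertex", "link_count"))),
               absorbed = integer(0))
  for (cl in cliques) {
    if (length(cl) < D + 1L) next
    absorbed <- logical(n); absorbed[cl] <- TRUE
    links <- colSums(adj[cl, , drop = FALSE])
    links[absorbed] <- -1L
    order_log <- matrix(integer(0), 0L, 2L)
    while (any(!absorbed)) {
      lmax <- max(links[!absorbed])
      if (lmax < D + 1L) break
      v <- which(!absorbed & links == lmax)[1L]
      absorbed[v] <- TRUE
      order_log <- rbind(order_log, c(v, lmax))
      links <- links + adj[v, ]
      links[v] <- -1L
    }
    if (all(absorbed)) {
      colnames(order_log) <- c("vertex", "link_count")
      best <- list(rigid = TRUE, seed_clique = cl,
                   addition_order = order_log, absorbed = which(absorbed))
      break
    }
    if (sum(absorbed) > length(best$absorbed)) {
      colnames(order_log) <- c("vertex", "link_count")
      best <- list(rigid = FALSE, seed_clique = cl,
                   addition_order = order_log, absorbed = which(absorbed))
    }
  }
  structure(c(best, list(n = n, D = D)), class = "rigidity_report")
}

#' @export
print.rigidity_report <- function(x, ...) {
  cat(sprintf("rigidity test (D = %d, n = %d): %s\n", x$D, x$n,
              if (x$rigid) "RIGID (unique completion certified)"
              else "not certified"))
  cat(sprintf("  seed clique size %d, absorbed %d of %d vertices\n",
              length(x$seed_clique), length(x$absorbed), x$n))
  invisible(x)
}
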