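#' Completion result container
#'
#' All completion methods return a `"completion_result"`: the completed
#' squared-distance matrix, the method name, per-entry provenance (`TRUE`
#' where the entry was known and preserved, `FALSE` where imputed) and
#' method diagnostics (loss traces, iteration counts, convergence flags).
#'
#' @param completed Completed squared-distance matrix.
#' @param method Method name.
#' @param partial The input partial EDM.
#' @param diagnostics Free-form list of diagnostics.
#' @return Object of class `"completion_result"`.
#' @keywords internal
completion_result <- function(completed, method, partial, diagnostics = list()) {
  structure(list(completed = completed, method = method,
                 provenance = partial$mask == 1,
                 diagnostics = diagnostics),
            class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf("EDM completion by '%s': n = %d, %d entries imputed\n",
              x$method, nrow(x$completed), sum(!x$provenance & !diag(TRUE, nrow(x$completed)))))
  invisible(x)
}

# Symmetrize the imputed part, zero the diagonal, then restore known
# entries bit-exactly from the input.
finalize_completion <- function(a, partial) {
  a <- (a + t(a)) / 2
  diag(a) <- 0
  known <- partial$mask == 1
  a[known] <- partial$values[known]
  a
}

#' Singular-value soft-thresholding
#'
#' \eqn{D_\beta(A) = U(\Sigma - \beta I)_+ V^T}: shrinks every singular
#' value by `beta` and clips at zero. The proximal operator of the nuclear
#' norm, the workhorse of convex low-rank completion.
#'
#' @param a Matrix.
#' @param beta Shrinkage (>= 0).
#' @return Thresholded matrix.
#' @export
soft_threshold_svd <- function(a, beta) {
  stopifnot(beta >= 0)
  s <- svd(a)
  d <- pmax(s$d - beta, 0)
  keep <- d > 0
  if (!any(keep)) return(matrix(0, nrow(a), ncol(a)))
  s$u[, keep, drop = FALSE] %*% (d[keep] * t(s$v[, keep, drop = FALSE]))
}

# Objective of nuclear-norm regularized completion for a candidate matrix
# whose singular values are `sv`.
fista_loss <- function(a, atil, b, beta, sv) {
  sum((b * (a - atil))^2) + beta * sum(sv)
}

#' Nuclear-norm EDM completion by accelerated proximal gradient (FISTA)
#'
#' Solves \eqn{\min_A \|B \odot (A - \tilde A)\|_F^2 + \beta \|A\|_*} by
#' Nesterov-accelerated singular-value soft-thresholding, with known entries
#' re-imposed at every iterate. The iteration starts from the zero-filled
#' partial matrix. A monotone acceptance guard keeps the previous iterate
#' whenever a candidate would increase the objective, so the recorded loss
#' trace is non-increasing. A geometric continuation schedule
#' \eqn{\beta_k = \beta_0\, 0.7^{\lfloor k/50 \rfloor}} drives the
#' regularization towards zero, which in the rigid (uniquely completable)
#' regime yields exact recovery of the missing entries; the schedule also
#' advances immediately when the loss plateaus at the current `beta`.
#'
#' @param partial Partial EDM from [corrupt()].
#' @param beta0 Initial regularization; default `0.1 * sigma_max(A^0)`.
#' @param max_iter Iteration cap (default 5000).
#' @param stop_ratio Relative loss-change stopping threshold (default 1e-7),
#'   applied once `beta` has reached its floor.
#' @param beta_decay Continuation factor per stage (default 0.7).
#' @param beta_every Iterations per continuation stage (default 50).
#' @param beta_floor Smallest `beta` as a fraction of `beta0` (default 1e-6).
#' @return A `"completion_result"`; diagnostics carry `loss` (trace of the
#'   regularized objective), `fit` (data term), `beta` trace, `iterations`
#'   and `converged`.
#' @export
fista_complete <- function(partial, beta0 = NULL, max_iter = 5000L,
                           stop_ratio = 1e-7, beta_decay = 0.7,
                           beta_every = 50L, beta_floor = 1e-6) {
  stopifnot(inherits(partial, "partial_edm"))
  b <- partial$mask
  if (!any(b == 1)) stop("partial EDM has no known entries", call. = FALSE)
  atil <- zero_filled(partial)
  if (all(b[upper.tri(b)] == 1)) {
    return(completion_result(finalize_completion(atil, partial), "fista",
                             partial,
                             list(loss = numeric(0), fit = numeric(0),
                                  beta = numeric(0), iterations = 0L,
                                  converged = TRUE)))
  }
  if (is.null(beta0)) beta0 <- 0.1 * svd(atil, nu = 0, nv = 0)$d[1L]
  beta_min <- beta0 * beta_floor
  a_prev <- atil
  a_cur <- atil
  z <- atil
  tk <- 1
  beta <- beta0
  sv_cur <- svd(a_cur, nu = 0, nv = 0)$d
  loss_cur <- fista_loss(a_cur, atil, b, beta, sv_cur)
  loss_trace <- numeric(0)
  fit_trace <- numeric(0)
  beta_trace <- numeric(0)
  converged <- FALSE
  stage_iter <- 0L
  for (k in seq_len(max_iter)) {
    y <- b * atil + (1 - b) * z
    s <- svd(y)
    d_shr <- pmax(s$d - beta, 0)
    cand <- s$u %*% (d_shr * t(s$v))
    loss_cand <- fista_loss(cand, atil, b, beta, d_shr)
    t_next <- (1 + sqrt(1 + 4 * tk^2)) / 2
    if (loss_cand <= loss_cur) {        # monotone (MFISTA) acceptance
      a_next <- cand
      loss_next <- loss_cand
    } else {
      a_next <- a_cur
      loss_next <- loss_cur
    }
    z <- a_next + (tk / t_next) * (cand - a_next) +
      ((tk - 1) / t_next) * (a_next - a_prev)
    rel <- abs(loss_cur - loss_next) / max(loss_cur, .Machine$double.eps)
    a_prev <- a_cur
    a_cur <- a_next
    loss_cur <- loss_next
    loss_trace <- c(loss_trace, loss_cur)
    fit_trace <- c(fit_trace, sum((b * (a_cur - atil))^2))
    beta_trace <- c(beta_trace, beta)
    stage_iter <- stage_iter + 1L
    plateau <- rel < stop_ratio
    if (plateau && beta <= beta_min) { converged <- TRUE; break }
    if (plateau || stage_iter >= beta_every) {
      beta <- max(beta * beta_decay, beta_min)
      stage_iter <- 0L
      tk <- 1                           # restart momentum at each stage
      z <- a_cur
      loss_cur <- fista_loss(a_cur, atil, b, beta,
                             svd(a_cur, nu = 0, nv = 0)$d)
    } else {
      tk <- t_next
    }
  }
  completion_result(finalize_completion(a_cur, partial), "fista", partial,
                    list(loss = loss_trace, fit = fit_trace,
                         beta = beta_trace, iterations = length(loss_trace),
                         converged = converged))
}

#' EDM completion by direct trajectory optimization
#'
#' Optimizes `n x D` coordinates against the masked squared-error loss
#' \eqn{L(x) = \|B \odot (A(x) - \tilde A)\|_F^2} with the Adam optimizer,
#' warm-started from the classical-MDS realization of the
#' nearest-neighbour fill (avoids mirror-branch local minima). The output
#' is the EDM of the optimized coordinates, hence an exact rank-(D+2) EDM
#' by construction; set `impose_known = TRUE` to overwrite known entries
#' with the measured values (bit-exact preservation at the cost of leaving
#' the EDM manifold).
#'
#' @param partial Partial EDM.
#' @param D Embedding dimension (default 3).
#' @param steps Adam steps (default 2000).
#' @param lr Adam learning rate (default 0.01, in squared-length gradient
#'   units).
#' @param impose_known Overwrite known entries at the end (default FALSE).
#' @param seed Optional seed (used only if the warm start is degenerate).
#' @return A `"completion_result"` with diagnostics `loss`, `coordinates`,
#'   `converged`.
#' @export
optimize_trajectory <- function(partial, D = 3L, steps = 2000L, lr = 0.01,
                                impose_known = FALSE, seed = NULL) {
  stopifnot(inherits(partial, "partial_edm"))
  b <- partial$mask
  n <- nrow(b)
  if (sum(b == 1) < (D + 1L) * D)
    warning("fewer than D+1 points with known mutual distances; result is weakly constrained")
  atil <- zero_filled(partial)
  x <- with_seed(seed, {
    x0 <- tryCatch(unclass(realize(nn_fill(partial)$completed, D = D)),
                   error = function(e) NULL)
    if (is.null(x0)) matrix(stats::rnorm(n * D), n, D) else
      x0 + 1e-6 * matrix(stats::rnorm(n * D), n, D)
  })
  m <- matrix(0, n, D); v <- matrix(0, n, D)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  loss_trace <- numeric(steps)
  for (k in seq_len(steps)) {
    a <- edm_from_trajectory(x)
    r <- b * (a - atil)
    loss <- sum(r^2)
    if (!is.finite(loss))
      stop("trajectory optimization diverged (non-finite loss) at step ", k,
           call. = FALSE)
    loss_trace[k] <- loss
    e <- 4 * r
    g <- rowSums(e) * x - e %*% x
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    mh <- m / (1 - b1^k); vh <- v / (1 - b2^k)
    x <- x - lr * mh / (sqrt(vh) + eps)
  }
  a_fin <- edm_from_trajectory(x)
  if (impose_known) a_fin <- finalize_completion(a_fin, partial)
  res <- completion_result(a_fin, "opt", partial,
                           list(loss = loss_trace, coordinates = x,
                                converged = length(loss_trace) > 1 &&
                                  utils::tail(loss_trace, 1) <=
                                  min(loss_trace) * (1 + 1e-6)))
  res
}

#' Nearest-neighbour fill
#'
#' Fills every unknown entry of the upper triangle with the value of the
#' known entry closest in index space under the Chebyshev metric
#' \eqn{\max(|i - i'|, |j - j'|)}; ties among equidistant known neighbours
#' are averaged. Known candidates are taken from the full (symmetric)
#' matrix, so entries near the diagonal can borrow from the mirrored
#' triangle. The lower triangle is mirrored.
#'
#' @param partial Partial EDM.
#' @return A `"completion_result"`.
#' @export
nn_fill <- function(partial) {
  stopifnot(inherits(partial, "partial_edm"))
  b <- partial$mask
  n <- nrow(b)
  if (!any(b == 1)) stop("partial EDM has no known entries", call. = FALSE)
  vz <- zero_filled(partial)
  known <- which(b == 1, arr.ind = TRUE)
  kv <- vz[b == 1]
  a <- vz
  unk <- which(upper.tri(b) & b == 0, arr.ind = TRUE)
  if (nrow(unk)) {
    for (r in seq_len(nrow(unk))) {
      i <- unk[r, 1L]; j <- unk[r, 2L]
      d <- pmax(abs(known[, 1L] - i), abs(known[, 2L] - j))
      sel <- d == min(d)
      a[i, j] <- mean(kv[sel])
    }
    a[lower.tri(a)] <- t(a)[lower.tri(a)]
  }
  completion_result(finalize_completion(a, partial), "nn", partial,
                    list(n_filled = nrow(unk)))
}

#' Pre-flattened EDM database
#'
#' Packs an ensemble of complete same-size EDMs into a dense matrix of
#' flattened upper triangles for fast repeated [database_search()] queries.
#'
#' @param edms List of `n x n` squared-distance matrices, or an
#'   `M x n(n-1)/2` matrix of already-flattened upper triangles (with
#'   attribute or argument `n`), or a 3-d array `n x n x M`.
#' @param n Matrix size (required when `edms` is already flattened).
#' @return Object of class `"edm_database"` with fields `flat` (M x P) and `n`.
#' @export
edm_database <- function(edms, n = NULL) {
  if (inherits(edms, "edm_database")) return(edms)
  if (is.list(edms) && length(edms) == 0L)
    stop("empty database", call. = FALSE)
  if (is.list(edms)) {
    n <- nrow(edms[[1L]])
    flat <- t(vapply(edms, ut, numeric(n * (n - 1L) / 2L)))
  } else if (is.array(edms) && length(dim(edms)) == 3L) {
    n <- dim(edms)[1L]
    flat <- t(apply(edms, 3L, ut))
  } else if (is.matrix(edms)) {
    if (is.null(n)) n <- attr(edms, "n")
    if (is.null(n)) stop("'n' required for a flattened database", call. = FALSE)
    flat <- edms
  } else stop("unsupported database representation", call. = FALSE)
  structure(list(flat = flat, n = as.integer(n)), class = "edm_database")
}

#' Database-search completion
#'
#' Scores every database matrix by its masked Frobenius discrepancy from
#' the query, \eqn{\varepsilon_i = \|B \odot (A^{DB}_i - \tilde A)\|_F^2},
#' selects the argmin \eqn{i^*}, and fills the unknown entries from it:
#' \eqn{\hat A = B \odot \tilde A + (1 - B) \odot A^{DB}_{i^*}}. If the
#' query's ground truth is present in the database and the mask is rigid,
#' the reconstruction error is zero.
#'
#' @param partial Partial EDM.
#' @param database An [edm_database()], or any representation it accepts.
#' @return A `"completion_result"`; diagnostics carry `best_index` and
#'   `best_eps`.
#' @export
database_search <- function(partial, database) {
  stopifnot(inherits(partial, "partial_edm"))
  db <- edm_database(database)
  if (nrow(db$flat) == 0L) stop("empty database", call. = FALSE)
  if (db$n != nrow(partial$mask))
    stop("database matrix size does not match the query", call. = FALSE)
  eps <- database_eps(partial, db)
  i_star <- which.min(eps)
  a <- zero_filled(partial)
  fill <- sym_from_ut(db$flat[i_star, ], db$n)
  unknown <- partial$mask == 0
  a[unknown] <- fill[unknown]
  diag(a) <- 0
  completion_result(finalize_completion(a, partial), "dbsearch", partial,
                    list(best_index = i_star, best_eps = eps[i_star],
                         eps = eps))
}

# Masked discrepancies of one query against a flattened database, counting
# each unordered pair once (scores are proportional to the full-matrix
# Frobenius form, preserving the argmin).
database_eps <- function(partial, db) {
  bu <- ut(partial$mask)
  qu <- ut(zero_filled(partial))
  qb <- bu * qu
  as.numeric(db$flat^2 %*% bu - 2 * (db$flat %*% qb) + sum(qb * qu))
}

#' Batched database-search completion
#'
#' Vectorized variant of [database_search()] for many queries against one
#' database: all masked discrepancies are computed with dense matrix
#' products (one pass of level-3 BLAS), which is the only practical route
#' for protocol-scale runs (tens of thousands of database entries times
#' hundreds of queries).
#'
#' @param partials List of partial EDMs of a common size.
#' @param database An [edm_database()] or any representation it accepts.
#' @param chunk Queries per BLAS block (default 128).
#' @return List of `"completion_result"` objects.
#' @export
database_search_many <- function(partials, database, chunk = 128L) {
  db <- edm_database(database)
  p <- ncol(db$flat)
  m <- length(partials)
  if (!m) return(list())
  flat2 <- db$flat^2
  out <- vector("list", m)
  for (lo in seq(1L, m, by = chunk)) {
    hi <- min(lo + chunk - 1L, m)
    idx <- lo:hi
    bu <- vapply(partials[idx], function(q) ut(q$mask), numeric(p))
    qb <- vapply(partials[idx], function(q) ut(q$mask) * ut(zero_filled(q)),
                 numeric(p))
    eps <- flat2 %*% bu - 2 * (db$flat %*% qb)   # constant term drops in argmin
    best <- max.col(-t(eps), ties.method = "first")
    for (k in seq_along(idx)) {
      q <- partials[[idx[k]]]
      a <- zero_filled(q)
      fill <- sym_from_ut(db$flat[best[k], ], db$n)
      unknown <- q$mask == 0
      a[unknown] <- fill[unknown]
      diag(a) <- 0
      out[[idx[k]]] <- completion_result(
        finalize_completion(a, q), "dbsearch", q,
        list(best_index = best[k],
             best_eps = eps[best[k], k] + sum((ut(q$mask) * ut(zero_filled(q)))^2)))
    }
  }
  out
}

#' Ensemble-mean fill
#'
#' Fills each unknown entry with the mean of that entry over the cohort
#' members in which it is known; entries known in no cohort member fall
#' back to the nearest-neighbour fill.
#'
#' @param partial Partial EDM to complete.
#' @param cohort List of partial EDMs of the same size (e.g. the other
#'   cells of a chromatin-tracing experiment).
#' @return A `"completion_result"`; diagnostics carry `n_fallback`, the
#'   number of entries imputed by the nearest-neighbour fallback.
#' @export
ensemble_mean_fill <- function(partial, cohort) {
  stopifnot(inherits(partial, "partial_edm"))
  n <- nrow(partial$mask)
  acc <- matrix(0, n, n); cnt <- matrix(0, n, n)
  for (ce in cohort) {
    stopifnot(inherits(ce, "partial_edm"), nrow(ce$mask) == n)
    acc <- acc + zero_filled(ce)
    cnt <- cnt + ce$mask
  }
  fill <- acc / pmax(cnt, 1)
  a <- zero_filled(partial)
  unknown <- partial$mask == 0
  covered <- unknown & cnt > 0
  a[covered] <- fill[covered]
  holes <- unknown & cnt == 0
  diag(holes) <- FALSE
  n_fallback <- sum(holes)
  if (n_fallback) {
    nn <- nn_fill(partial)$completed
    a[holes] <- nn[holes]
  }
  completion_result(finalize_completion(a, partial), "ensmean", partial,
                    list(n_fallback = n_fallback))
}
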