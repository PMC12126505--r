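make_rigid_instance <- function(n = 64L, mu = 0.1, seed = 21L) {
  a <- sample_fbm_edms(fbm_spec(0.5, n, count = 1L, seed = seed))[[1L]]
  for (k in 0:20) {
    b <- bernoulli_mask(n, mu, seed = seed + 1000L + k)
    if (rigidity_test(b)$rigid) return(list(a = a, b = b, p = corrupt(a, b)))
  }
  stop("no rigid mask found")
}

test_that("singular-value soft-thresholding matches hand computations", {
  set.seed(22)
  a <- matrix(rnorm(36L), 6L)
  expect_equal(soft_threshold_svd(a, 0), a, tolerance = 1e-9)
  smax <- svd(a, nu = 0, nv = 0)$d[1L]
  expect_equal(soft_threshold_svd(a, smax + 1), matrix(0, 6L, 6L))
  expect_equal(soft_threshold_svd(diag(c(3, 1)), 2), diag(c(1, 0)),
               tolerance = 1e-12)
})

test_that("FISTA recovers the unique completion on a rigid instance with a monotone loss", {
  inst <- make_rigid_instance()
  res <- fista_complete(inst$p)
  nrm <- edm_normalizer(scale = max(inst$a))
  expect_lt(rmse_missing(normalize_edm(nrm, res$completed),
                         normalize_edm(nrm, inst$a), inst$b), 1e-2)
  expect_true(all(diff(res$diagnostics$loss) <= 1e-10))
  expect_identical(res$completed[inst$b == 1], inst$a[inst$b == 1])
  expect_true(is_hollow_symmetric_test(res$completed))
  # fully known input returns unchanged with no iterations
  pfull <- corrupt(inst$a, full_mask(64L))
  rfull <- fista_complete(pfull)
  expect_identical(rfull$diagnostics$iterations, 0L)
  expect_equal(rfull$completed, inst$a)
})

test_that("trajectory optimization reconstructs distances and stays on the EDM manifold", {
  inst <- make_rigid_instance(n = 32L, mu = 0.1, seed = 31L)
  pfull <- corrupt(inst$a, full_mask(32L))
  rfull <- optimize_trajectory(pfull, steps = 1500L)
  expect_lt(tail(rfull$diagnostics$loss, 1L) / sum(pfull$values^2, na.rm = TRUE), 1e-6)
  expect_lt(max(abs(sqrt(rfull$completed) - sqrt(inst$a))), 1e-3 * sqrt(max(inst$a)))
  ropt <- optimize_trajectory(inst$p, steps = 2000L)
  expect_equal(rank_fraction(ropt$completed, 5L), 1, tolerance = 1e-9)
  rfis <- fista_complete(inst$p)
  nrm <- edm_normalizer(scale = max(inst$a))
  e_opt <- rmse_missing(normalize_edm(nrm, ropt$completed),
                        normalize_edm(nrm, inst$a), inst$b)
  e_fis <- rmse_missing(normalize_edm(nrm, rfis$completed),
                        normalize_edm(nrm, inst$a), inst$b)
  # both approximate the unique completion
  expect_lt(abs(e_opt - e_fis), 5e-2)
})

test_that("nearest-neighbour fill copies the closest known entry and averages ties", {
  a <- matrix(0, 5L, 5L)
  a[upper.tri(a)] <- 10 * seq_len(10L)
  a <- a + t(a)
  b <- full_mask(5L)
  # isolate (1,2): its only distance-1 Chebyshev known neighbours decide it
  b[1L, 2L] <- b[2L, 1L] <- 0
  p <- corrupt(a, b)
  r <- nn_fill(p)
  nbrs <- c(a[1L, 3L], a[2L, 3L])  # known cells at Chebyshev distance 1
  expect_equal(r$completed[1L, 2L], mean(nbrs))
  expect_identical(r$completed[b == 1], a[b == 1])
  pf <- corrupt(a, full_mask(5L))
  expect_equal(nn_fill(pf)$completed, a)
})

test_that("database search minimizes the masked discrepancy (exhaustive oracle)", {
  db_edms <- sample_fbm_edms(fbm_spec(0.5, 16L, count = 100L, seed = 41L))
  a <- db_edms[[37L]]
  inst_b <- bernoulli_mask(16L, 0.2, seed = 42L)
  stopifnot(rigidity_test(inst_b)$rigid)
  p <- corrupt(a, inst_b)
  res <- database_search(p, db_edms)
  eps_oracle <- oracle_db_eps(p, db_edms)
  expect_equal(res$diagnostics$best_index, which.min(eps_oracle))
  expect_equal(2 * res$diagnostics$eps, eps_oracle, tolerance = 1e-9)
  # the query's truth is in the database: zero reconstruction error
  expect_equal(res$completed, a, tolerance = 1e-12)
  single <- database_search(p, db_edms[5L])
  unknown <- inst_b == 0 & upper.tri(inst_b)
  expect_equal(single$completed[unknown], db_edms[[5L]][unknown])
  expect_error(database_search(p, list()), "empty|unsupported")
})

test_that("batched database search agrees with the single-query path", {
  db <- edm_database(sample_fbm_edms(fbm_spec(0.5, 16L, count = 60L, seed = 43L)))
  queries <- sample_fbm_edms(fbm_spec(0.5, 16L, count = 7L, seed = 44L))
  partials <- lapply(seq_along(queries), function(j)
    corrupt(queries[[j]], bernoulli_mask(16L, 0.3, seed = 45L + j)))
  many <- database_search_many(partials, db, chunk = 3L)
  for (j in seq_along(partials)) {
    one <- database_search(partials[[j]], db)
    expect_identical(many[[j]]$diagnostics$best_index,
                     one$diagnostics$best_index)
    expect_equal(many[[j]]$completed, one$completed, tolerance = 1e-12)
  }
})

test_that("database-search error is non-increasing over nested databases", {
  db_edms <- sample_fbm_edms(fbm_spec(0.5, 16L, count = 80L, seed = 46L))
  q <- sample_fbm_edms(fbm_spec(0.5, 16L, count = 1L, seed = 47L))[[1L]]
  p <- corrupt(q, bernoulli_mask(16L, 0.3, seed = 48L))
  eps <- vapply(c(10L, 40L, 80L), function(m)
    database_search(p, db_edms[seq_len(m)])$diagnostics$best_eps, numeric(1))
  expect_true(all(diff(eps) <= 1e-12))
})

test_that("ensemble-mean fill averages per-entry over cells that know the entry", {
  n <- 6L
  base <- matrix(2, n, n); diag(base) <- 0
  mk <- function(val, known_mask) {
    v <- base; v[1L, 2L] <- v[2L, 1L] <- val
    corrupt(v, known_mask)
  }
  bknow <- full_mask(n)
  bmiss <- full_mask(n); bmiss[1L, 2L] <- bmiss[2L, 1L] <- 0
  cohort <- list(mk(1, bknow), mk(2, bknow), mk(3, bknow), mk(99, bmiss))
  query <- mk(0, bmiss)
  r <- ensemble_mean_fill(query, cohort)
  expect_equal(r$completed[1L, 2L], 2)  # mean of 1, 2, 3; the NA cell ignored
  expect_identical(r$completed[bmiss == 1], query$values[bmiss == 1])
  # entry known nowhere falls back to the nearest-neighbour fill
  cohort_blind <- list(mk(5, bmiss), mk(7, bmiss))
  rb <- ensemble_mean_fill(query, cohort_blind)
  expect_equal(rb$completed[1L, 2L], nn_fill(query)$completed[1L, 2L])
  expect_identical(rb$diagnostics$n_fallback, 2L)
})

test_that("all classical methods keep outputs symmetric and hollow with known entries intact", {
  db <- edm_database(sample_fbm_edms(fbm_spec(0.5, 12L, count = 30L, seed = 51L)))
  cohort_edms <- sample_fbm_edms(fbm_spec(0.5, 12L, count = 10L, seed = 52L))
  cohort <- lapply(seq_along(cohort_edms), function(j)
    corrupt(cohort_edms[[j]], bernoulli_mask(12L, 0.3, seed = 53L + j)))
  for (rep_i in 1:10) {
    a <- sample_fbm_edms(fbm_spec(0.5, 12L, count = 1L, seed = 60L + rep_i))[[1L]]
    b <- bernoulli_mask(12L, 0.4, seed = 70L + rep_i)
    p <- corrupt(a, b)
    runs <- list(fista_complete(p, max_iter = 300L),
                 nn_fill(p),
                 database_search(p, db),
                 ensemble_mean_fill(p, cohort),
                 optimize_trajectory(p, steps = 200L, impose_known = TRUE))
    for (r in runs) {
      expect_true(is_hollow_symmetric_test(r$completed), label = r$method)
      expect_identical(r$completed[b == 1], a[b == 1], label = r$method)
    }
  }
})
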