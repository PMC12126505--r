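test_that("rmse_missing matches hand computations", {
  a <- matrix(0, 3L, 3L)
  b <- full_mask(3L)
  b[1L, 2L] <- b[2L, 1L] <- 0
  b[1L, 3L] <- b[3L, 1L] <- 0
  ahat <- a
  ahat[1L, 2L] <- ahat[2L, 1L] <- 3
  ahat[1L, 3L] <- ahat[3L, 1L] <- 4
  expect_equal(rmse_missing(ahat, a, b), sqrt(12.5), tolerance = 1e-12)
  expect_equal(rmse_missing(a, a, b), 0)
  off <- a; off[b == 0] <- 2.5; diag(off) <- 0
  expect_equal(rmse_missing(off, a, b), 2.5)
  expect_error(rmse_missing(a, a, full_mask(3L)), "missing")
})

test_that("the Frechet distance has its closed-form Gaussian behaviour", {
  set.seed(91)
  f1 <- matrix(rnorm(4000L), 500L, 8L)
  expect_lt(fid(f1, f1), 1e-6)
  mu2 <- rep(c(2, 0), each = 4L)
  f2 <- sweep(matrix(rnorm(4000L), 500L, 8L), 2L, mu2, `+`)
  d <- fid(f1, f2)
  expect_lt(abs(d - sum(mu2^2)) / sum(mu2^2), 0.2)
  expect_equal(as.numeric(fid(f1, f2)), as.numeric(fid(f2, f1)),
               tolerance = 1e-8)
  perm <- f2[sample.int(500L), ]
  expect_equal(as.numeric(fid(f1, perm)), as.numeric(d), tolerance = 1e-8)
})

test_that("the analytic embedding is deterministic with the declared dimension", {
  emb <- analytic_embedding(16L)
  a <- edm_from_trajectory(matrix(rnorm(48L), 16L, 3L))
  expect_length(emb$fn(a), emb$dim)
  expect_identical(emb$fn(a), emb$fn(a))
})

test_that("scaling curves recover known exponents", {
  line <- edm_from_trajectory(cbind(1:32, 0, 0))  # ballistic: r = s
  expect_equal(fit_exponent(scaling_curve(list(line))), 1, tolerance = 1e-9)
  ens <- sample_fbm_edms(fbm_spec(0.5, 64L, count = 5000L, seed = 92L))
  expo <- fit_exponent(scaling_curve(ens), s_range = c(2, 32))
  expect_lt(abs(expo - 0.5), 0.02)
})

test_that("fit_exponent is exact on power laws and scale-invariant", {
  curve <- data.frame(s = 2:20, rms = (2:20)^0.4)
  expect_equal(fit_exponent(curve), 0.4, tolerance = 1e-9)
  curve2 <- curve; curve2$rms <- 7 * curve2$rms
  expect_equal(fit_exponent(curve2), fit_exponent(curve), tolerance = 1e-12)
  set.seed(93)
  noisy <- data.frame(s = 2:32)
  noisy$rms <- noisy$s^0.3 * (1 + rnorm(31L, sd = 0.01))
  expect_lt(abs(fit_exponent(noisy) - 0.3), 0.02)
  expect_error(fit_exponent(data.frame(s = c(2, 3), rms = c(1, 2))), "3 points")
})

test_that("maxwell_collapse calibrates on the null and rejects degenerate input", {
  set.seed(94)
  # direct Maxwell samples: |v| with v ~ N(0, I_3/3) so E|v|^2 = 1
  r <- sqrt(rchisq(3000L, df = 3L) / 3)
  fake <- list()
  n <- 4L
  for (k in seq_len(3000L)) {
    a <- matrix(0, n, n)
    a[1L, 2L] <- a[2L, 1L] <- r[k]^2
    fake[[k]] <- a
  }
  res <- maxwell_collapse(fake, s_values = 1L)
  expect_gt(res$p_value, 0.01)
  flat <- lapply(1:600, function(k) matrix(1, n, n) - diag(n))
  res0 <- maxwell_collapse(flat, s_values = 1L)
  expect_gt(res0$ks_stat, 0.5)
})

test_that("effective database size matches the entropy closed form", {
  # direct evaluation: 2(n-1)/ln(10) * (ln(sqrt(2*pi)) + 1/2)
  expect_equal(effective_db_size_theory(64L),
               126 * (log(sqrt(2 * pi)) + 0.5) / log(10), tolerance = 1e-12)
  expect_equal(round(effective_db_size_theory(64L), 2), 77.65)
  expect_equal(effective_db_size_theory(1L), 0)
  expect_equal(effective_db_size_theory(2L), 1.2324742, tolerance = 1e-6)
  # linear in n, slope = the per-variable entropy constant
  slope <- effective_db_size_theory(11L) - effective_db_size_theory(10L)
  expect_equal(slope, 2 * (log(sqrt(2 * pi)) + 0.5) / log(10),
               tolerance = 1e-12)
})

test_that("the FID power-law fit recovers a generative identity and extrapolates", {
  tbl <- expand.grid(M = c(500, 2000, 20000, 2e5),
                     mu = c(0.05, 0.1, 0.2))
  tbl$fid <- 3.2 * tbl$mu^1.41 * tbl$M^-0.026
  fit <- fit_fid_powerlaw(tbl)
  expect_equal(fit$a, 1.41, tolerance = 1e-6)
  expect_equal(fit$gamma, 0.026, tolerance = 1e-6)
  # extrapolation inverts the law exactly
  mstar <- extrapolate_mstar(fit, reference_fid = 3.2 * 0.1^1.41 * 10^(-0.026 * 70),
                             mu = 0.1)
  expect_equal(mstar, 70, tolerance = 1e-6)
  single <- tbl[tbl$mu == 0.1, ]
  fit1 <- fit_fid_powerlaw(single)
  expect_equal(fit1$gamma, 0.026, tolerance = 1e-6)
  expect_error(fit_fid_powerlaw(tbl[tbl$M == 500, ]), "distinct")
})

test_that("the benchmark harness produces finite, reproducible reports with the expected ordering", {
  mod <- shared_model_h12(); sch <- shared_schedule()
  run <- function() run_benchmark(hurst = 0.5, n = 16L,
                                  mu_grid = c(0.05, 0.5), n_test = 30L,
                                  methods = c("nn", "fista", "ddpm"),
                                  model = mod, schedule = sch,
                                  n_reference = 200L, n_steps = 40L,
                                  seed = 95L)
  rep1 <- run()
  expect_true(all(is.finite(rep1$table$rmse)))
  expect_true(all(is.finite(rep1$table$fid)))
  expect_true(all(is.finite(rep1$table$rank_fraction)))
  # rigid regime: the convex relaxation recovers the unique completion
  t05 <- rep1$table[rep1$table$mu == 0.05, ]
  expect_lt(t05$rmse[t05$method == "fista"], t05$rmse[t05$method == "ddpm"])
  # byte-level reproducibility of the emitted CSV
  d1 <- file.path(tempdir(), "bench1"); d2 <- file.path(tempdir(), "bench2")
  run_benchmark(hurst = 0.5, n = 16L, mu_grid = 0.2, n_test = 10L,
                methods = "nn", seed = 96L, out_dir = d1)
  run_benchmark(hurst = 0.5, n = 16L, mu_grid = 0.2, n_test = 10L,
                methods = "nn", seed = 96L, out_dir = d2)
  expect_identical(readBin(file.path(d1, "benchmark.csv"), "raw", 1e5),
                   readBin(file.path(d2, "benchmark.csv"), "raw", 1e5))
  expect_warning(run_benchmark(n = 8L, mu_grid = 0.2, n_test = 5L,
                               methods = c("nn", "ddrm"), seed = 97L),
                 "skipping")
})
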