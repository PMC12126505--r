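test_that("the coordinate-table dialect round-trips losslessly", {
  cohort <- synth_fish_fixture(n_cells = 12L, n_loci = 10L, dropout = 2L,
                               seed = 101L)
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_fish(cohort, tf)
  expect_no_warning(back <- read_fish(tf))
  expect_identical(length(back$cells), 12L)
  for (j in seq_len(12L)) {
    expect_identical(back$cells[[j]]$missing_loci,
                     cohort$cells[[j]]$missing_loci)
    expect_equal(back$cells[[j]]$coords, cohort$cells[[j]]$coords,
                 tolerance = 1e-9)
  }
})

test_that("missing loci are derived from NaN coordinates", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  df <- expand.grid(locus = 1:8, cell = c("a", "b"))[, c(2L, 1L)]
  set.seed(102)
  df$x <- rnorm(16L); df$y <- rnorm(16L); df$z <- rnorm(16L)
  df[df$cell == "a" & df$locus %in% c(3L, 7L), c("x", "y", "z")] <- NaN
  write.table(df, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  cohort <- read_fish(tf)
  expect_identical(cohort$cells[[1L]]$missing_loci, c(3L, 7L))
  expect_identical(cohort$cells[[2L]]$missing_loci, integer(0))
})

test_that("malformed tables are rejected with informative errors", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("cell\tlocus\tx\ty\tz",
               "a\t1\t0\t0\t0", "a\t2\t1\t1\t1",
               "b\t1\t0\t0\t0"), tf)
  expect_error(read_fish(tf), "inconsistent")
})

test_that("per-cell partial EDMs mirror a direct coordinate computation", {
  cohort <- synth_fish_fixture(n_cells = 6L, n_loci = 12L, dropout = 3L,
                               seed = 103L)
  cell <- cohort$cells[[1L]]
  p <- cell_to_partial_edm(cell)
  k <- length(cell$missing_loci)
  expect_equal(missing_ratio(p$mask),
               1 - choose(12L - k, 2) / choose(12L, 2), tolerance = 1e-12)
  present <- setdiff(1:12, cell$missing_loci)
  for (i in present[1:3]) for (j in present[4:6]) {
    if (i == j) next
    expect_equal(p$values[i, j], sum((cell$coords[i, ] - cell$coords[j, ])^2),
                 tolerance = 1e-9)
  }
  # complete cell: full EDM, mu = 0
  cohort0 <- synth_fish_fixture(n_cells = 1L, n_loci = 12L, dropout = 0L,
                                seed = 104L)
  expect_equal(missing_ratio(cell_to_partial_edm(cohort0$cells[[1L]])$mask), 0)
})

test_that("masking coordinates first or the EDM after gives the same partial matrix", {
  cohort <- synth_fish_fixture(n_cells = 4L, n_loci = 14L, dropout = 0L,
                               seed = 105L)
  cell <- cohort$cells[[2L]]
  full <- edm_from_trajectory(cell$coords)
  drop <- c(2L, 9L)
  via_edm <- corrupt(full, rowcol_mask(14L, drop))
  cell2 <- cell
  cell2$coords[drop, ] <- NA_real_
  cell2$missing_loci <- drop
  via_coords <- cell_to_partial_edm(cell2)
  known <- via_edm$mask == 1
  expect_identical(via_coords$mask, via_edm$mask)
  expect_equal(via_coords$values[known], via_edm$values[known],
               tolerance = 1e-9)
})

test_that("cell selection by dropout count is exact and idempotent", {
  counts <- c(0L, 3L, 3L, 5L, 0L, 3L)
  cohort <- synth_fish_fixture(n_cells = 6L, n_loci = 12L, dropout = counts,
                               seed = 106L)
  sel <- select_cells(cohort, 3L)
  expect_identical(length(sel$cells), 3L)
  expect_identical(select_cells(sel, 3L)$cells, sel$cells)
  sel0 <- select_cells(cohort, 0L)
  expect_true(all(vapply(sel0$cells, function(ce)
    length(ce$missing_loci) == 0L, logical(1))))
  expect_warning(select_cells(cohort, 11L), "no cells")
})

test_that("extra masking reproduces the protocol's missing ratio and scores only fresh entries", {
  cohort <- synth_fish_fixture(n_cells = 1L, n_loci = 64L, dropout = 15L,
                               seed = 107L)
  p <- cell_to_partial_edm(cohort$cells[[1L]])
  mk <- extra_mask(p, 10L, seed = 108L)
  expect_equal(round(missing_ratio(mk$partial$mask), 2), 0.63)
  # evaluation entries are disjoint from the originally missing ones
  expect_true(all(mk$eval_mask[p$mask == 0] == 0))
  expect_true(all(mk$partial$mask[mk$eval_mask == 1] == 0))
  id <- extra_mask(p, 0L)
  expect_identical(id$partial, p)
  expect_identical(sum(id$eval_mask), 0)
  expect_error(extra_mask(p, 47L), "at least 4")
})

test_that("synthetic cohorts carry the subdiffusive scaling and the configured dropout law", {
  cohort <- synth_fish_fixture(n_cells = 2000L, n_loci = 64L, hurst = 1 / 3,
                               dropout = 0L, seed = 109L)
  edms <- lapply(cohort$cells, function(ce) edm_from_trajectory(ce$coords))
  expo <- fit_exponent(scaling_curve(edms))
  expect_lt(abs(expo - 1 / 3), 0.03)
  # binomial dropout counts match their law
  cohort2 <- synth_fish_fixture(n_cells = 2000L, n_loci = 20L,
                                dropout = function(m) rbinom(m, 20L, 0.2),
                                seed = 110L)
  counts <- vapply(cohort2$cells, function(ce) length(ce$missing_loci),
                   integer(1))
  obs <- tabulate(counts + 1L, nbins = 21L)
  expe <- 2000 * dbinom(0:20, 20L, 0.2)
  keep <- expe >= 5
  chi <- sum((obs[keep] - expe[keep])^2 / expe[keep])
  p_val <- pchisq(chi, df = sum(keep) - 1L, lower.tail = FALSE)
  expect_gt(p_val, 0.01)
})

test_that("the imputation protocol ranks the deterministic diffusion completion above the naive fills", {
  mod <- shared_model_h13(); sch <- shared_schedule()
  cohort <- synth_fish_fixture(n_cells = 80L, n_loci = 16L, hurst = 1 / 3,
                               scale_nm = 300, dropout = 3L, seed = 111L)
  rep <- impute_and_score(cohort, methods = c("ensmean", "nn", "ddrm"),
                          model = mod, schedule = sch, k_drop = 3L,
                          n_steps = 200L, n_boot = 200L, seed = 112L)
  tab <- rep$table
  rmse <- setNames(tab$rmse_nm, tab$method)
  expect_lt(rmse[["ddrm"]], rmse[["nn"]])
  expect_lt(rmse[["ddrm"]], rmse[["ensmean"]])
  expect_true(all(tab$rmse_lo <= tab$rmse_nm & tab$rmse_nm <= tab$rmse_hi))
})

test_that("no imputation method alters a known entry of any cell", {
  mod <- shared_model_h13(); sch <- shared_schedule()
  cohort <- synth_fish_fixture(n_cells = 6L, n_loci = 16L, hurst = 1 / 3,
                               scale_nm = 300, dropout = 2L, seed = 113L)
  cells_p <- lapply(cohort$cells, cell_to_partial_edm)
  for (j in seq_along(cells_p)) {
    mk <- extra_mask(cells_p[[j]], 2L, seed = 114L + j)
    p <- mk$partial
    known <- p$mask == 1
    sc <- median(p$values[known]) / mod$train_stats$median
    scaled <- corrupt(p$values / sc, p$mask)
    scaled$values[scaled$mask == 0] <- NA_real_
    runs <- list(nn = nn_fill(p),
                 ensmean = ensemble_mean_fill(p, cells_p[-j]),
                 ddrm = inpaint_ddrm(mod, scaled, sch, 40L, seed = j))
    expect_identical(runs$nn$completed[known], p$values[known])
    expect_identical(runs$ensmean$completed[known], p$values[known])
    expect_equal(runs$ddrm$completed[known] * sc, p$values[known],
                 tolerance = 1e-12)
  }
})
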