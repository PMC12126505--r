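#' Read a chromatin-tracing coordinate table
#'
#' Parses the package's documented tabular dialect for multiplexed FISH
#' chromatin tracing: a header line `cell locus x y z` followed by one row
#' per (cell, locus) with 3-D coordinates in nm; a locus that failed to
#' image carries `NA`/`NaN` coordinates. Every cell must list the same
#' loci `1..L` (30 kb genomic bins in the source experiments). A thin
#' adapter for other layouts can pre-process into this dialect.
#'
#' @param path Path to a TSV/whitespace-delimited file.
#' @return Object of class `"fish_cohort"`: list with `cells` (each a
#'   `"fish_cell"` carrying `cell_id`, `coords` L x 3 matrix in nm,
#'   `missing_loci`), `n_loci`, `source`.
#' @export
read_fish <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "",
                           na.strings = c("NA", "NaN", "nan"),
                           stringsAsFactors = FALSE)
  need <- c("cell", "locus", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("expected columns: ", paste(need, collapse = ", "), call. = FALSE)
  bad <- which(is.na(tab$cell) | is.na(tab$locus))
  if (length(bad))
    stop("malformed rows (missing cell/locus id) at data lines: ",
         paste(utils::head(bad, 10L), collapse = ", "), call. = FALSE)
  counts <- table(tab$cell)
  if (length(unique(counts)) != 1L)
    stop("inconsistent loci counts across cells", call. = FALSE)
  n_loci <- as.integer(counts[1L])
  cells <- lapply(split(tab, tab$cell), function(df) {
    df <- df[order(df$locus), , drop = FALSE]
    if (!identical(as.integer(df$locus), seq_len(n_loci)))
      stop("cell ", df$cell[1L], ": loci are not 1..", n_loci, call. = FALSE)
    coords <- as.matrix(df[, c("x", "y", "z")])
    dimnames(coords) <- NULL
    miss <- which(apply(coords, 1L, function(r) any(is.na(r))))
    coords[miss, ] <- NA_real_
    structure(list(cell_id = df$cell[1L], coords = coords,
                   missing_loci = miss),
              class = "fish_cell")
  })
  cells <- cells[order(vapply(cells, function(ce) ce$cell_id, tab$cell[1L]))]
  structure(list(cells = unname(cells), n_loci = n_loci, source = path),
            class = "fish_cohort")
}

#' @rdname read_fish
#' @param cohort A `"fish_cohort"`.
#' @export
write_fish <- function(cohort, path) {
  stopifnot(inherits(cohort, "fish_cohort"))
  rows <- lapply(cohort$cells, function(ce) {
    data.frame(cell = ce$cell_id, locus = seq_len(nrow(ce$coords)),
               x = ce$coords[, 1L], y = ce$coords[, 2L], z = ce$coords[, 3L])
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.fish_cohort <- function(x, ...) {
  miss <- vapply(x$cells, function(ce) length(ce$missing_loci), integer(1L))
  cat(sprintf("FISH cohort: %d cells x %d loci; missing loci/cell: median %d, max %d\n",
              length(x$cells), x$n_loci, as.integer(stats::median(miss)),
              max(miss)))
  invisible(x)
}

#' Per-cell partial EDM from FISH coordinates
#'
#' Squared pairwise distances in nm^2 between the imaged loci of one cell;
#' loci with missing coordinates mask out their entire row and column
#' ([rowcol_mask()]), the corruption geometry characteristic of
#' chromatin-tracing data.
#'
#' @param cell A `"fish_cell"`.
#' @return A `"partial_edm"` in nm^2 units.
#' @export
cell_to_partial_edm <- function(cell) {
  stopifnot(inherits(cell, "fish_cell"))
  n <- nrow(cell$coords)
  present <- setdiff(seq_len(n), cell$missing_loci)
  if (length(present) < 2L)
    stop("cell has fewer than 2 imaged loci", call. = FALSE)
  a <- matrix(0, n, n)
  a[present, present] <- edm_from_trajectory(cell$coords[present, , drop = FALSE])
  corrupt(a, rowcol_mask(n, cell$missing_loci))
}

#' Select cells by number of missing loci
#'
#' @param cohort A `"fish_cohort"`.
#' @param k_missing Exact number of missing loci per selected cell.
#' @return A `"fish_cohort"` subset (empty with a warning if none match).
#' @export
select_cells <- function(cohort, k_missing) {
  stopifnot(inherits(cohort, "fish_cohort"))
  keep <- vapply(cohort$cells, function(ce)
    length(ce$missing_loci) == k_missing, logical(1L))
  if (!any(keep)) warning("no cells with exactly ", k_missing, " missing loci")
  structure(list(cells = cohort$cells[keep], n_loci = cohort$n_loci,
                 source = cohort$source),
            class = "fish_cohort")
}

#' Hide additional loci for scoring
#'
#' Drops `k_drop` uniformly chosen present loci from a partial EDM
#' (masking their rows and columns) and returns the further-corrupted
#' matrix together with an evaluation mask marking exactly the newly
#' hidden, previously known entries - the ground truth available for
#' scoring an imputation.
#'
#' @param partial A `"partial_edm"` with row/column corruption.
#' @param k_drop Number of additional loci to hide; must leave at least 4
#'   present loci.
#' @param seed Optional seed.
#' @return List with `partial` (further corrupted), `eval_mask` (binary
#'   matrix, 1 = score here), `dropped` (locus indices).
#' @export
extra_mask <- function(partial, k_drop, seed = NULL) {
  stopifnot(inherits(partial, "partial_edm"))
  n <- nrow(partial$mask)
  present <- which(colSums(partial$mask) > 0)
  k_drop <- as.integer(k_drop)
  if (k_drop > length(present) - 4L)
    stop("'k_drop' must leave at least 4 present loci", call. = FALSE)
  if (k_drop == 0L)
    return(list(partial = partial, eval_mask = matrix(0, n, n),
                dropped = integer(0)))
  dropped <- with_seed(seed, sort(sample(present, k_drop)))
  drop_mask <- rowcol_mask(n, dropped)
  new_mask <- partial$mask * drop_mask
  eval_mask <- (partial$mask == 1 & new_mask == 0) * 1
  new_partial <- corrupt(zero_filled(partial), new_mask)
  list(partial = new_partial, eval_mask = eval_mask, dropped = dropped)
}

#' Impute a FISH cohort and score against held-out loci
#'
#' The chromatin-imputation protocol: for each cell, hide `k_drop`
#' additional imaged loci, impute the resulting matrix with each method,
#' and score the RMSE in nm between imputed and measured *distances*
#' (square roots of the matrix entries) over the newly hidden entries,
#' along with the rank fraction of the completed matrix. Cell-level
#' metrics are averaged with bootstrap confidence intervals.
#'
#' Diffusion methods bridge physical units to the model's training range
#' by per-cell scale matching: the cell's nm^2 entries are divided by
#' `median(known entries) / median(training entries)` before inpainting
#' and rescaled afterwards.
#'
#' @param cohort A `"fish_cohort"`.
#' @param methods Methods to run; subset of `"ensmean"`, `"nn"`,
#'   `"ddpm"`, `"repaint"`, `"ddnm"`, `"ddrm"`.
#' @param model Denoising prior trained on an fBm ensemble with the
#'   matching Hurst exponent (H = 1/3 for cohesin-depleted chromatin) and
#'   matching `n`; diffusion methods are skipped with a warning when the
#'   model is absent or its size differs.
#' @param schedule The model's training schedule.
#' @param k_drop Loci hidden per cell for scoring (default 10).
#' @param n_steps Diffusion generation steps (default 200).
#' @param ddrm_eta DDRM stochasticity for imputation (default 0, the
#'   deterministic DDIM limit: point-estimate imputation is scored by
#'   RMSE, which favours posterior-mean-like output over posterior
#'   samples; see the methods vignette).
#' @param n_boot Bootstrap resamples for the CIs (default 1000).
#' @param seed Master seed.
#' @return Object of class `"fish_report"`: `data.frame` `table` with one
#'   row per method (mean RMSE in nm with 95% bootstrap CI, mean rank
#'   fraction), plus `per_cell` matrices of cell-level metrics.
#' @export
impute_and_score <- function(cohort,
                             methods = c("ensmean", "nn", "ddpm",
                                         "repaint", "ddnm", "ddrm"),
                             model = NULL, schedule = NULL, k_drop = 10L,
                             n_steps = 200L, ddrm_eta = 0, n_boot = 1000L,
                             seed = 1L) {
  stopifnot(inherits(cohort, "fish_cohort"))
  diffusion <- c("ddpm", "repaint", "ddnm", "ddrm")
  if (any(methods %in% diffusion)) {
    if (is.null(model) || is.null(schedule) ||
        (!is.null(model$n) && model$n != cohort$n_loci)) {
      warning("diffusion methods skipped: no model or loci-count mismatch")
      methods <- setdiff(methods, diffusion)
    }
  }
  cells_p <- lapply(cohort$cells, cell_to_partial_edm)
  masked <- lapply(seq_along(cells_p), function(j)
    extra_mask(cells_p[[j]], k_drop, seed = seed + j))
  usable <- vapply(masked, function(mk) sum(mk$eval_mask) > 0, logical(1L))
  cells_p <- cells_p[usable]; masked <- masked[usable]
  m <- length(cells_p)
  if (!m) stop("no usable cells after masking", call. = FALSE)
  train_med <- if (!is.null(model)) model$train_stats$median else NA_real_
  score <- function(ahat, j) {
    truth <- cells_p[[j]]$values
    ev <- masked[[j]]$eval_mask
    sel <- upper.tri(ev) & ev == 1
    rmse_nm <- sqrt(mean((sqrt(pmax(ahat[sel], 0)) - sqrt(truth[sel]))^2))
    c(rmse = rmse_nm, rank = rank_fraction(ahat))
  }
  per_cell <- list()
  for (method in methods) {
    vals <- if (method %in% diffusion) {
      scales <- vapply(seq_len(m), function(j) {
        p <- masked[[j]]$partial
        stats::median(p$values[p$mask == 1]) / train_med
      }, numeric(1L))
      scaled <- lapply(seq_len(m), function(j) {
        p <- masked[[j]]$partial
        corrupt(zero_filled(p) / scales[j], p$mask)
      })
      res <- switch(method,
        ddpm = inpaint_ddpm(model, scaled, schedule, n_steps,
                            seed = seed + 101L),
        repaint = inpaint_repaint(model, scaled, schedule, n_steps,
                                  seed = seed + 101L),
        ddrm = inpaint_ddrm(model, scaled, schedule, n_steps,
                            eta = ddrm_eta, seed = seed + 101L),
        ddnm = inpaint_ddnm(model, scaled, schedule, n_steps,
                            seed = seed + 101L))
      vapply(seq_len(m), function(j)
        score(res[[j]]$completed * scales[j], j), numeric(2L))
    } else {
      vapply(seq_len(m), function(j) {
        p <- masked[[j]]$partial
        res <- switch(method,
          nn = nn_fill(p),
          ensmean = ensemble_mean_fill(
            p, lapply(seq_len(m)[-j], function(k) masked[[k]]$partial)))
        score(res$completed, j)
      }, numeric(2L))
    }
    per_cell[[method]] <- vals
  }
  boot_ci <- function(x) {
    bm <- with_seed(seed + 999L, vapply(seq_len(n_boot), function(b)
      mean(x[sample.int(length(x), replace = TRUE)]), numeric(1L)))
    stats::quantile(bm, c(0.025, 0.975), names = FALSE)
  }
  tab <- do.call(rbind, lapply(methods, function(method) {
    vals <- per_cell[[method]]
    ci <- boot_ci(vals["rmse", ])
    data.frame(method = method, rmse_nm = mean(vals["rmse", ]),
               rmse_lo = ci[1L], rmse_hi = ci[2L],
               rank_fraction = mean(vals["rank", ]), n_cells = m)
  }))
  structure(list(table = tab, per_cell = per_cell,
                 config = list(k_drop = k_drop, n_steps = n_steps,
                               seed = seed)),
            class = "fish_report")
}

#' @export
print.fish_report <- function(x, ...) {
  cat("FISH imputation report (RMSE in nm over held-out entries)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Synthetic FISH fixture generator
#'
#' Emulates a chromatin-tracing cohort without any download: per-cell 3-D
#' locus coordinates are fBm trajectories at the requested Hurst exponent
#' (default 1/3, the fractal statistics of cohesin-depleted chromatin)
#' with a typical neighbouring-locus distance `scale_nm`, subjected to
#' per-cell whole-locus dropout. What it emulates - and what it does not
#' (localization noise, cell-to-cell scale heterogeneity, locus-dependent
#' detection efficiency) - is discussed in the methods vignette.
#'
#' @param n_cells Number of cells.
#' @param n_loci Loci per cell (30 kb bins; default 64).
#' @param hurst Hurst exponent (default 1/3).
#' @param scale_nm Typical single-bin displacement in nm (default 300).
#' @param dropout Per-cell missing-locus counts: a single integer
#'   (constant), an integer vector of length `n_cells`, or a function
#'   `function(n_cells)` returning counts. Default: binomial thinning with
#'   per-locus dropout probability 0.1.
#' @param path Optional path; when given, the cohort is also written in
#'   the [read_fish()] dialect.
#' @param seed Optional seed.
#' @return A `"fish_cohort"` (invisibly carries `path` when written).
#' @export
synth_fish_fixture <- function(n_cells, n_loci = 64L, hurst = 1 / 3,
                               scale_nm = 300, dropout = NULL, path = NULL,
                               seed = NULL) {
  n_cells <- as.integer(n_cells); n_loci <- as.integer(n_loci)
  cohort <- with_seed(seed, {
    counts <- if (is.null(dropout))
      stats::rbinom(n_cells, n_loci, 0.1)
    else if (is.function(dropout)) dropout(n_cells)
    else if (length(dropout) == 1L) rep(as.integer(dropout), n_cells)
    else as.integer(dropout)
    stopifnot(length(counts) == n_cells, all(counts >= 0),
              all(counts <= n_loci - 2L))
    trajs <- sample_fbm(fbm_spec(hurst, n_loci, dim = 3L,
                                 step_scale = scale_nm, count = n_cells),
                        seed = NULL)
    cells <- lapply(seq_len(n_cells), function(j) {
      coords <- trajs[[j]]
      miss <- sort(sample.int(n_loci, counts[j]))
      coords[miss, ] <- NA_real_
      structure(list(cell_id = sprintf("cell_%04d", j), coords = coords,
                     missing_loci = miss),
                class = "fish_cell")
    })
    structure(list(cells = cells, n_loci = n_loci, source = "synthetic"),
              class = "fish_cohort")
  })
  if (!is.null(path)) {
    write_fish(cohort, path)
    cohort$source <- path
  }
  cohort
}
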