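#' Root-mean-square error over missing entries
#'
#' RMSE between a completion and the ground truth over the unordered
#' off-diagonal pairs the mask marks unknown, in whatever units the
#' matrices carry (model-range units for the benchmark, nm for FISH
#' distances).
#'
#' @param a_hat Completed matrix.
#' @param a_true Ground-truth matrix.
#' @param mask Binary mask (0 = missing, scored; 1 = known, ignored).
#' @return Non-negative RMSE.
#' @export
rmse_missing <- function(a_hat, a_true, mask) {
  check_square(a_hat); check_square(a_true); check_square(mask)
  stopifnot(identical(dim(a_hat), dim(a_true)),
            identical(dim(a_hat), dim(mask)))
  sel <- upper.tri(mask) & mask == 0
  if (!any(sel)) stop("mask has no missing entries to score", call. = FALSE)
  sqrt(mean((a_hat[sel] - a_true[sel])^2))
}

#' Feature embedding for ensemble-level comparison
#'
#' A `"fid_embedding"` is a deterministic map from an image to a
#' fixed-length feature vector. The default analytic embedding needs no
#' external weights: it concatenates the diagonal-band means of the matrix
#' (the scaling curve sampled at every contour separation) with its top six
#' singular values. An adapter around any pretrained convolutional feature
#' extractor can be plugged in through `fn`.
#'
#' @param fn Function mapping an `n x n` matrix to a numeric vector.
#' @param dim Output dimensionality (>= 2).
#' @param name Embedding name.
#' @return Object of class `"fid_embedding"`.
#' @export
fid_embedding <- function(fn, dim, name = "custom") {
  stopifnot(is.function(fn), dim >= 2L)
  structure(list(fn = fn, dim = as.integer(dim), name = name),
            class = "fid_embedding")
}

#' @rdname fid_embedding
#' @param n Matrix size the embedding will be applied to.
#' @export
analytic_embedding <- function(n) {
  n <- as.integer(n)
  fn <- function(a) {
    bands <- vapply(seq_len(n - 1L), function(s) {
      i <- seq_len(n - s)
      mean(a[cbind(i, i + s)])
    }, numeric(1L))
    sv <- svd(a, nu = 0, nv = 0)$d
    c(bands, sv[seq_len(min(6L, length(sv)))])
  }
  fid_embedding(fn, dim = (n - 1L) + min(6L, n), name = "analytic")
}

# Symmetric PSD matrix square root via eigendecomposition.
sqrtm_psd <- function(s) {
  e <- eigen((s + t(s)) / 2, symmetric = TRUE)
  v <- pmax(e$values, 0)
  e$vectors %*% (sqrt(v) * t(e$vectors))
}

#' Frechet distance between two ensembles
#'
#' Embeds both ensembles, fits a Gaussian to each feature cloud and
#' returns the Frechet distance
#' \eqn{\|\mu_1-\mu_2\|^2 + \mathrm{Tr}(\Sigma_1+\Sigma_2 -
#' 2(\Sigma_1\Sigma_2)^{1/2})}. Symmetric in its arguments and zero for
#' identical ensembles. If the covariance square root is numerically
#' unstable the covariances are regularized diagonally and the result
#' carries attribute `regularized = TRUE`.
#'
#' @param ensemble_a,ensemble_b Lists of matrices (or already-embedded
#'   feature matrices, rows = samples, when `embedding = NULL`).
#' @param embedding A [fid_embedding()]; default [analytic_embedding()]
#'   sized to the data.
#' @return Non-negative scalar.
#' @export
fid <- function(ensemble_a, ensemble_b, embedding = NULL) {
  embed <- function(ens) {
    if (is.matrix(ens) && is.null(embedding)) return(ens)
    emb <- embedding %||% analytic_embedding(nrow(ens[[1L]]))
    t(vapply(ens, emb$fn, numeric(emb$dim)))
  }
  fa <- embed(ensemble_a); fb <- embed(ensemble_b)
  stopifnot(nrow(fa) >= 2L, nrow(fb) >= 2L, ncol(fa) == ncol(fb))
  mu1 <- colMeans(fa); mu2 <- colMeans(fb)
  s1 <- stats::cov(fa); s2 <- stats::cov(fb)
  trace_term <- function(s1, s2) {
    r1 <- sqrtm_psd(s1)
    m <- r1 %*% s2 %*% r1
    sum(diag(s1)) + sum(diag(s2)) - 2 * sum(sqrt(pmax(
      eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values, 0)))
  }
  tt <- tryCatch(trace_term(s1, s2), error = function(e) NA_real_)
  regularized <- FALSE
  if (!is.finite(tt)) {
    lam <- 1e-8 * max(diag(s1), diag(s2), 1)
    tt <- trace_term(s1 + lam * diag(ncol(fa)), s2 + lam * diag(ncol(fa)))
    regularized <- TRUE
  }
  structure(max(sum((mu1 - mu2)^2) + tt, 0), regularized = regularized)
}

#' Ensemble scaling of distance with contour separation
#'
#' For each contour separation `s`, averages the squared distance
#' \eqn{a_{i,i+s}} along the diagonal band and over the ensemble, and
#' returns the RMS distance \eqn{\langle r^2(s)\rangle^{1/2}}. For fBm
#' ensembles the curve follows \eqn{a\,s^H}.
#'
#' @param ensemble List of squared-distance matrices.
#' @return `data.frame` with columns `s`, `msd` (mean squared distance)
#'   and `rms`.
#' @export
scaling_curve <- function(ensemble) {
  stopifnot(length(ensemble) >= 1L)
  n <- nrow(ensemble[[1L]])
  acc <- numeric(n - 1L); cnt <- numeric(n - 1L)
  for (a in ensemble) {
    for (s in seq_len(n - 1L)) {
      i <- seq_len(n - s)
      acc[s] <- acc[s] + sum(a[cbind(i, i + s)])
      cnt[s] <- cnt[s] + length(i)
    }
  }
  msd <- acc / cnt
  data.frame(s = seq_len(n - 1L), msd = msd, rms = sqrt(msd))
}

#' Log-log slope of a scaling curve (Hurst estimate)
#'
#' Ordinary least-squares slope of `log(rms)` against `log(s)` over the
#' fitted window; for fBm data the slope estimates the Hurst exponent.
#'
#' @param curve A [scaling_curve()] result (columns `s` and `rms`).
#' @param s_range Inclusive window `c(s_min, s_max)`; default
#'   `c(2, max(s)/2)` to avoid boundary effects.
#' @return Estimated exponent.
#' @export
fit_exponent <- function(curve, s_range = NULL) {
  s_range <- s_range %||% c(2, max(curve$s) / 2)
  sel <- curve$s >= s_range[1L] & curve$s <= s_range[2L]
  if (sum(sel) < 3L) stop("need at least 3 points in 's_range'", call. = FALSE)
  if (any(curve$rms[sel] <= 0))
    stop("non-positive values in the fitted range", call. = FALSE)
  unname(stats::coef(stats::lm(log(rms) ~ log(s), data = curve[sel, ]))[2L])
}

#' Maxwell collapse of rescaled pairwise distances
#'
#' The Gaussian propagator of fBm implies that the distance between two
#' points separated by contour length `s`, rescaled by its RMS value,
#' follows the 3-D Maxwell(-Boltzmann) law: \eqn{u = r / \langle
#' r^2\rangle^{1/2}} has CDF \eqn{P(\chi^2_3 \le 3u^2)}. For each requested
#' `s`, distances are collected across the ensemble, rescaled by their
#' empirical RMS, and compared to that law with a Kolmogorov-Smirnov test.
#'
#' @param ensemble List of squared-distance matrices.
#' @param s_values Contour separations to test.
#' @param pool `"first"` (default) uses one pair per matrix (`a[1, 1+s]`),
#'   giving independent samples across the ensemble, exactly matching the
#'   KS null; `"all"` pools every diagonal-band entry (correlated within a
#'   matrix, larger nominal sample).
#' @return `data.frame` with columns `s`, `n_samples`, `ks_stat`,
#'   `p_value`.
#' @export
maxwell_collapse <- function(ensemble, s_values, pool = c("first", "all")) {
  pool <- match.arg(pool)
  n <- nrow(ensemble[[1L]])
  out <- lapply(s_values, function(s) {
    stopifnot(s >= 1L, s <= n - 1L)
    r2 <- if (pool == "first")
      vapply(ensemble, function(a) a[1L, 1L + s], numeric(1L))
    else unlist(lapply(ensemble, function(a) {
      i <- seq_len(n - s); a[cbind(i, i + s)]
    }), use.names = FALSE)
    u <- sqrt(r2 / mean(r2))
    if (stats::sd(u) < .Machine$double.eps^0.5) {
      ks <- list(statistic = 1, p.value = 0)
    } else {
      ks <- suppressWarnings(
        stats::ks.test(u, function(q) stats::pchisq(3 * q^2, df = 3)))
    }
    data.frame(s = s, n_samples = length(u),
               ks_stat = unname(ks$statistic), p_value = ks$p.value)
  })
  do.call(rbind, out)
}

#' Theoretical effective database size
#'
#' Entropy-counting bound for the database size needed to reproduce the
#' EDM ensemble of trajectories drawn with ~2(n-1) Gaussian degrees of
#' freedom: \eqn{\log_{10} M^* = \frac{2(n-1)}{\ln 10}(\ln\sqrt{2\pi} +
#' \tfrac12)}, since the expected negative log-likelihood of one standard
#' normal draw is \eqn{\ln\sqrt{2\pi} + 1/2}. Approximately 78.89 for
#' n = 64.
#'
#' @param n Trajectory length.
#' @return `log10` of the effective database size.
#' @export
effective_db_size_theory <- function(n) {
  stopifnot(n >= 1)
  2 * (n - 1) / log(10) * (log(sqrt(2 * pi)) + 0.5)
}

#' Power-law fit of database-search FID
#'
#' Fits \eqn{\log_{10} FID = c + a \log_{10}\mu - \gamma \log_{10} M} to a
#' table of database-search FID measurements across database sizes `M` and
#' missing ratios `mu` (the rigid regime, where the plots for different
#' `mu` collapse after rescaling).
#'
#' @param tbl `data.frame` with columns `M`, `mu`, `fid` (positive).
#' @return Object of class `"fid_powerlaw"` with fields `a`, `gamma`, `c`
#'   and the `lm` fit.
#' @export
fit_fid_powerlaw <- function(tbl) {
  stopifnot(all(c("M", "mu", "fid") %in% names(tbl)),
            all(tbl$fid > 0), all(tbl$M > 0), all(tbl$mu > 0))
  if (length(unique(tbl$M)) < 3L)
    stop("need at least 3 distinct database sizes", call. = FALSE)
  single_mu <- length(unique(tbl$mu)) == 1L
  fit <- if (single_mu)
    stats::lm(log10(fid) ~ log10(M), data = tbl)
  else stats::lm(log10(fid) ~ log10(mu) + log10(M), data = tbl)
  cf <- stats::coef(fit)
  structure(list(a = if (single_mu) NA_real_ else unname(cf[["log10(mu)"]]),
                 gamma = -unname(cf[["log10(M)"]]),
                 c = unname(cf[[1L]]), fit = fit),
            class = "fid_powerlaw")
}

#' @rdname fit_fid_powerlaw
#' @param object A `"fid_powerlaw"` fit.
#' @param reference_fid The FID level to extrapolate to (e.g. the
#'   diffusion-inpainting FID).
#' @param mu Missing ratio at which to extrapolate.
#' @return `log10` of the database size at which the fitted power law
#'   reaches `reference_fid`.
#' @export
extrapolate_mstar <- function(object, reference_fid, mu) {
  stopifnot(inherits(object, "fid_powerlaw"), reference_fid > 0)
  a_term <- if (is.na(object$a)) 0 else object$a * log10(mu)
  (object$c + a_term - log10(reference_fid)) / object$gamma
}

#' Benchmark harness for completion methods
#'
#' Regenerates the comparison protocol at configurable scale: synthesizes
#' a ground-truth fBm test set, corrupts it with Bernoulli masks over a
#' grid of missing ratios, completes with the requested methods and
#' reports per-method, per-mu missing-entry RMSE (model-range units), FID
#' against an independent reference ensemble, mean rank fraction and the
#' fraction of rigidity-certified masks.
#'
#' @param hurst,n Trajectory parameters.
#' @param mu_grid Missing ratios to scan.
#' @param n_test Test matrices per mu.
#' @param methods Methods to run (see [complete_edm()]).
#' @param model,schedule Trained prior for diffusion methods (skipped with
#'   a warning when absent).
#' @param database [edm_database()] for `"dbsearch"` (skipped with a
#'   warning when absent).
#' @param n_reference Size of the independent FID reference ensemble
#'   (default 500).
#' @param n_steps Diffusion generation steps (default 50 at bench scale).
#' @param seed Master seed; every stage derives its own stream from it.
#' @param out_dir Optional directory for the CSV report.
#' @return Object of class `"bench_report"`: list with `table`
#'   (long-format `data.frame`), `rigid_fraction`, `config`.
#' @export
run_benchmark <- function(hurst = 0.5, n = 16L, mu_grid = c(0.1, 0.5),
                          n_test = 50L,
                          methods = c("nn", "fista"),
                          model = NULL, schedule = NULL, database = NULL,
                          n_reference = 500L, n_steps = 50L, seed = 1L,
                          out_dir = NULL) {
  diffusion <- c("ddpm", "repaint", "ddrm", "ddnm")
  methods <- unique(methods)
  if (any(methods %in% diffusion) && is.null(model)) {
    warning("no model supplied; skipping diffusion methods")
    methods <- setdiff(methods, diffusion)
  }
  if ("dbsearch" %in% methods && is.null(database)) {
    warning("no database supplied; skipping dbsearch")
    methods <- setdiff(methods, "dbsearch")
  }
  spec_test <- fbm_spec(hurst, n, count = n_test, seed = seed + 1000L)
  truths <- sample_fbm_edms(spec_test)
  spec_ref <- fbm_spec(hurst, n, count = n_reference, seed = seed + 2000L)
  reference <- sample_fbm_edms(spec_ref)
  nrm <- if (!is.null(model) && !is.null(model$normalizer)) model$normalizer
         else fit_normalizer(reference)
  emb <- analytic_embedding(n)
  ref_feat <- t(vapply(reference, emb$fn, numeric(emb$dim)))
  rows <- list(); rigid_rows <- list()
  for (mi in seq_along(mu_grid)) {
    mu <- mu_grid[mi]
    masks <- lapply(seq_len(n_test), function(j)
      bernoulli_mask(n, mu, seed = seed + 3000L + 1000L * mi + j))
    partials <- Map(corrupt, truths, masks)
    rigid_rows[[mi]] <- data.frame(
      mu = mu,
      rigid_fraction = mean(vapply(masks, function(b)
        rigidity_test(b)$rigid, logical(1L))))
    for (method in methods) {
      res <- switch(method,
        ddpm = inpaint_ddpm(model, partials, schedule, n_steps,
                            seed = seed + 17L),
        repaint = inpaint_repaint(model, partials, schedule, n_steps,
                                  seed = seed + 17L),
        ddrm = inpaint_ddrm(model, partials, schedule, n_steps,
                            seed = seed + 17L),
        ddnm = inpaint_ddnm(model, partials, schedule, n_steps,
                            seed = seed + 17L),
        dbsearch = database_search_many(partials, database),
        lapply(partials, complete_edm, method = method,
               cohort = partials, seed = seed + 17L))
      comp <- lapply(res, `[[`, "completed")
      rmse <- mean(mapply(function(c_, t_, b_) {
        if (!any(upper.tri(b_) & b_ == 0)) return(NA_real_)
        rmse_missing(normalize_edm(nrm, c_), normalize_edm(nrm, t_), b_)
      }, comp, truths, masks), na.rm = TRUE)
      feat <- t(vapply(comp, emb$fn, numeric(emb$dim)))
      rows[[length(rows) + 1L]] <- data.frame(
        mu = mu, method = method, rmse = rmse,
        fid = as.numeric(fid(feat, ref_feat)),
        rank_fraction = mean(vapply(comp, rank_fraction, numeric(1L))))
    }
  }
  report <- structure(list(table = do.call(rbind, rows),
                           rigid_fraction = do.call(rbind, rigid_rows),
                           config = list(hurst = hurst, n = n,
                                         mu_grid = mu_grid, n_test = n_test,
                                         methods = methods,
                                         n_reference = n_reference,
                                         n_steps = n_steps, seed = seed)),
                      class = "bench_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(report$table, file.path(out_dir, "benchmark.csv"),
                     row.names = FALSE)
    utils::write.csv(report$rigid_fraction,
                     file.path(out_dir, "rigid_fraction.csv"),
                     row.names = FALSE)
  }
  report
}

#' @export
print.bench_report <- function(x, ...) {
  cat("completion benchmark (fBm EDMs)\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @describeIn run_benchmark Plot missing-entry RMSE and FID against the
#'   missing ratio, one curve per method, with the rigidity-certified
#'   fraction overlaid on the RMSE panel.
#' @param x A `"bench_report"`.
#' @param ... Unused.
#' @export
plot.bench_report <- function(x, ...) {
  tab <- x$table
  methods <- unique(tab$method)
  cols <- grDevices::hcl.colors(max(3L, length(methods)), "Dark 3")
  old <- graphics::par(mfrow = c(1L, 2L), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (metric in c("rmse", "fid")) {
    graphics::plot(range(tab$mu), range(tab[[metric]]), type = "n",
                   log = if (all(tab[[metric]] > 0)) "y" else "",
                   xlab = expression(mu), ylab = toupper(metric))
    for (k in seq_along(methods)) {
      sub <- tab[tab$method == methods[k], ]
      graphics::lines(sub$mu, sub[[metric]], col = cols[k], type = "b",
                      pch = 16L)
    }
    if (metric == "rmse")
      graphics::lines(x$rigid_fraction$mu,
                      x$rigid_fraction$rigid_fraction *
                        max(tab$rmse, na.rm = TRUE),
                      col = "grey60", lty = 2L)
    graphics::legend("topleft", legend = methods, col = cols[seq_along(methods)],
                     lty = 1L, pch = 16L, bty = "n", cex = 0.8)
  }
  invisible(x)
}
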