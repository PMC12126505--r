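#' Project a generated image onto valid EDM structure
#'
#' Denormalizes a model-range image back to squared-distance units,
#' symmetrizes by \eqn{(A + A^T)/2}, clamps negative entries to zero and
#' zeroes the diagonal.
#'
#' @param x Square image-valued matrix (model range).
#' @param normalizer An [edm_normalizer()]; `NULL` if `x` is already in
#'   raw units.
#' @return A valid (symmetric, hollow, non-negative) squared-distance
#'   matrix.
#' @export
project_edm <- function(x, normalizer = NULL) {
  check_square(x, "x")
  a <- if (is.null(normalizer)) x else denormalize_edm(normalizer, x)
  a <- (a + t(a)) / 2
  a[a < 0] <- 0
  diag(a) <- 0
  a
}

# Shared preparation for the conditional samplers: batch of partials ->
# flattened masks/known images in model range.
prep_inpaint <- function(model, partials, normalizer) {
  single <- inherits(partials, "partial_edm")
  if (single) partials <- list(partials)
  nrm <- normalizer %||% model$normalizer
  if (is.null(nrm))
    stop("no normalizer: supply one or train the model with raw EDMs",
         call. = FALSE)
  n <- nrow(partials[[1L]]$mask)
  if (!is.null(model$n) && model$n != n)
    stop("mask/model shape mismatch", call. = FALSE)
  d <- n * n
  bmat <- t(vapply(partials, function(p) as.numeric(p$mask), numeric(d)))
  ymat <- t(vapply(partials, function(p)
    as.numeric(normalize_edm(nrm, zero_filled(p), clip = TRUE)) *
      as.numeric(p$mask), numeric(d)))
  list(partials = partials, single = single, nrm = nrm, n = n, d = d,
       b = bmat, y = ymat, count = length(partials))
}

finish_inpaint <- function(x, prep, method, diagnostics) {
  out <- lapply(seq_len(prep$count), function(j) {
    img <- matrix(x[j, ], prep$n, prep$n)
    a <- project_edm(img, prep$nrm)
    completion_result(finalize_completion(a, prep$partials[[j]]), method,
                      prep$partials[[j]], diagnostics)
  })
  if (prep$single) out[[1L]] else out
}

# One DDPM inpainting step at respaced position i; consumes, in order, the
# known-pixel noise then (for i > 1) the reverse-step noise. This fixed
# consumption order is what makes RePaint with one loop bit-identical to
# plain DDPM inpainting under a shared seed.
ddpm_inpaint_step <- function(x, i, sch, model, b, y) {
  cnt <- nrow(x); d <- ncol(x)
  ab <- sch$alpha_bars[i]
  ab_prev <- if (i > 1L) sch$alpha_bars[i - 1L] else 1
  eps_k <- matrix(stats::rnorm(cnt * d), cnt, d)
  x_known <- sqrt(ab_prev) * y + sqrt(1 - ab_prev) * eps_k
  eh <- predict_eps(model, x, sch$orig_t[i])
  mu <- (x - sch$betas[i] / sqrt(1 - ab) * eh) / sqrt(sch$alphas[i])
  x_unknown <- if (i > 1L)
    mu + sch$sigmas[i] * matrix(stats::rnorm(cnt * d), cnt, d)
  else mu
  b * x_known + (1 - b) * x_unknown
}

#' Conditional generation by DDPM inpainting
#'
#' At every reverse step the known pixels are re-noised from the measured
#' image at the level of the next timestep, the unknown pixels are drawn
#' from the unconditional reverse step, and the two are merged through the
#' mask. The final image passes through [project_edm()] and the known
#' entries are restored bit-exactly in raw distance units.
#'
#' @param model Trained denoiser (carries its normalizer).
#' @param partial A `"partial_edm"`, or a list of them (batched).
#' @param schedule Parent-chain schedule the model was trained on.
#' @param n_steps Generation steps (default 200; respaced from `T`).
#' @param normalizer Optional override of the model's normalizer.
#' @param seed Optional seed.
#' @return A `"completion_result"` (or list of them for batched input).
#' @export
inpaint_ddpm <- function(model, partial, schedule, n_steps = 200L,
                         normalizer = NULL, seed = NULL) {
  prep <- prep_inpaint(model, partial, normalizer)
  sch <- respace_even(schedule, n_steps)
  with_seed(seed, {
    x <- matrix(stats::rnorm(prep$count * prep$d), prep$count, prep$d)
    for (i in seq(sch$T, 1L))
      x <- ddpm_inpaint_step(x, i, sch, model, prep$b, prep$y)
    finish_inpaint(x, prep, "ddpm", list(n_steps = sch$T))
  })
}

#' Conditional generation by RePaint resampling
#'
#' DDPM inpainting with a back-and-forward refinement: at each timestep the
#' (denoise, re-noise) inner loop runs `repaint_loops` times before the
#' chain advances, harmonizing the inpainted region with the known pixels.
#' With `repaint_loops = 1` the procedure consumes the same noise stream as
#' [inpaint_ddpm()] and is bit-identical to it.
#'
#' @inheritParams inpaint_ddpm
#' @param repaint_loops Resamplings per step `n_t` (default 10).
#' @export
inpaint_repaint <- function(model, partial, schedule, n_steps = 200L,
                            repaint_loops = 10L, normalizer = NULL,
                            seed = NULL) {
  stopifnot(repaint_loops >= 1L)
  prep <- prep_inpaint(model, partial, normalizer)
  sch <- respace_even(schedule, n_steps)
  with_seed(seed, {
    x <- matrix(stats::rnorm(prep$count * prep$d), prep$count, prep$d)
    for (i in seq(sch$T, 1L)) {
      for (u in seq_len(repaint_loops)) {
        x <- ddpm_inpaint_step(x, i, sch, model, prep$b, prep$y)
        if (u < repaint_loops) {
          # one forward step back to level i: q(x_i | x_{i-1})
          x <- sqrt(sch$alphas[i]) * x + sch$sigmas[i] *
            matrix(stats::rnorm(prep$count * prep$d), prep$count, prep$d)
        }
      }
    }
    finish_inpaint(x, prep, "repaint",
                   list(n_steps = sch$T, repaint_loops = repaint_loops))
  })
}

#' Conditional generation by DDRM
#'
#' Works on the unscaled noise ladder \eqn{x_t = x_0 + \sigma_t \epsilon}
#' with \eqn{\sigma_t = \sqrt{(1 - \bar\alpha_t)/\bar\alpha_t}} derived
#' from the trained schedule, so one prior serves all samplers. Each step
#' forms the x0 estimate from the predicted noise, then updates the
#' unknown coordinates by the DDIM-style rule
#' \eqn{x_{t-1} = \hat x_0 + \sqrt{1-\eta^2}\,\sigma_{t-1}
#' (x_t - \hat x_0)/\sigma_t + \eta\,\sigma_{t-1}\epsilon}
#' and drives the known coordinates by the measured values with the same
#' noise mixing. All stochastic terms carry the factor `eta`, so `eta = 0`
#' yields a fully deterministic trajectory. Known entries are restored
#' exactly at output.
#'
#' @inheritParams inpaint_ddpm
#' @param eta Stochasticity parameter in \[0, 1\] (default 0.85).
#' @export
inpaint_ddrm <- function(model, partial, schedule, n_steps = 200L,
                         eta = 0.85, normalizer = NULL, seed = NULL) {
  stopifnot(eta >= 0, eta <= 1)
  prep <- prep_inpaint(model, partial, normalizer)
  sch <- respace_even(schedule, n_steps)
  sig <- sqrt((1 - sch$alpha_bars) / sch$alpha_bars)
  with_seed(seed, {
    x <- prep$y + eta * sig[sch$T] *
      matrix(stats::rnorm(prep$count * prep$d), prep$count, prep$d)
    for (i in seq(sch$T, 1L)) {
      x_vp <- sqrt(sch$alpha_bars[i]) * x
      eh <- predict_eps(model, x_vp, sch$orig_t[i])
      x0h <- x - sig[i] * eh
      sig_prev <- if (i > 1L) sig[i - 1L] else 0
      noise <- if (eta > 0 && sig_prev > 0)
        matrix(stats::rnorm(prep$count * prep$d), prep$count, prep$d)
      else 0
      x_unknown <- x0h + sqrt(1 - eta^2) * sig_prev * (x - x0h) / sig[i] +
        eta * sig_prev * noise
      x_known <- prep$y + sqrt(1 - eta^2) * sig_prev * (x - prep$y) / sig[i] +
        eta * sig_prev * noise
      x <- prep$b * x_known + (1 - prep$b) * x_unknown
    }
    finish_inpaint(x, prep, "ddrm", list(n_steps = sch$T, eta = eta))
  })
}

#' Conditional generation by DDNM with time travel
#'
#' At each reverse step the x0 estimate is range/null-space corrected for
#' the masking operator - its known pixels are replaced by the measured
#' values, \eqn{B \odot x_{0|t} = B \odot y} exactly - before the DDPM
#' posterior step. A time-travel (resampling) loop re-noises the chain
#' back `travel_length` respaced steps and repeats each block
#' `repeat_times` times; `travel = c(1, 1)` reduces to the plain scheme.
#'
#' @inheritParams inpaint_ddpm
#' @param travel Integer pair `(travel_length, repeat_times)`,
#'   default `c(3, 3)`.
#' @return As [inpaint_ddpm()]; diagnostics record the travel schedule and
#'   `consistency_trace`, the per-step maximum deviation
#'   \eqn{\max |B \odot (x_{0|t} - y)|} after correction (identically zero
#'   by construction).
#' @export
inpaint_ddnm <- function(model, partial, schedule, n_steps = 200L,
                         travel = c(3L, 3L), normalizer = NULL, seed = NULL) {
  travel <- as.integer(travel)
  stopifnot(length(travel) == 2L, all(travel >= 1L))
  prep <- prep_inpaint(model, partial, normalizer)
  sch <- respace_even(schedule, n_steps)
  trace <- numeric(0)
  step_fn <- function(x, i) {
    ab <- sch$alpha_bars[i]
    ab_prev <- if (i > 1L) sch$alpha_bars[i - 1L] else 1
    eh <- predict_eps(model, x, sch$orig_t[i])
    x0h <- (x - sqrt(1 - ab) * eh) / sqrt(ab)
    x0h <- prep$b * prep$y + (1 - prep$b) * x0h
    trace <<- c(trace, max(abs(prep$b * (x0h - prep$y))))
    c1 <- sqrt(ab_prev) * sch$betas[i] / (1 - ab)
    c2 <- sqrt(sch$alphas[i]) * (1 - ab_prev) / (1 - ab)
    mu <- c1 * x0h + c2 * x
    if (i > 1L)
      mu + sch$sigmas[i] * matrix(stats::rnorm(prep$count * prep$d),
                                  prep$count, prep$d)
    else mu
  }
  with_seed(seed, {
    x <- matrix(stats::rnorm(prep$count * prep$d), prep$count, prep$d)
    s <- sch$T
    while (s >= 1L) {
      e <- max(s - travel[1L] + 1L, 1L)
      for (rep_i in seq_len(travel[2L])) {
        for (i in seq(s, e)) x <- step_fn(x, i)
        if (rep_i < travel[2L]) {
          # re-noise from level e-1 back to level s: forward marginal ratio
          ab_lo <- if (e > 1L) sch$alpha_bars[e - 1L] else 1
          r <- sch$alpha_bars[s] / ab_lo
          x <- sqrt(r) * x + sqrt(1 - r) *
            matrix(stats::rnorm(prep$count * prep$d), prep$count, prep$d)
        }
      }
      s <- e - 1L
    }
    finish_inpaint(x, prep, "ddnm",
                   list(n_steps = sch$T, travel = travel,
                        consistency_trace = trace))
  })
}

#' Dispatch table over all completion methods
#'
#' Uniform front-end used by the benchmark harness and the FISH pipeline:
#' completes a partial EDM with any of the named methods.
#'
#' @param partial Partial EDM (or list of them for the diffusion methods).
#' @param method One of `"fista"`, `"opt"`, `"nn"`, `"dbsearch"`,
#'   `"ensmean"`, `"ddpm"`, `"repaint"`, `"ddrm"`, `"ddnm"`.
#' @param model,schedule Required for the diffusion methods.
#' @param database Required for `"dbsearch"` ([edm_database()]).
#' @param cohort Required for `"ensmean"` (list of partial EDMs).
#' @param n_steps Diffusion generation steps (default 200).
#' @param seed Optional seed.
#' @param ... Passed to the underlying method.
#' @return A `"completion_result"` (or list for batched diffusion input).
#' @export
complete_edm <- function(partial, method, model = NULL, schedule = NULL,
                         database = NULL, cohort = NULL, n_steps = 200L,
                         seed = NULL, ...) {
  method <- match.arg(method, c("fista", "opt", "nn", "dbsearch", "ensmean",
                                "ddpm", "repaint", "ddrm", "ddnm"))
  if (method %in% c("ddpm", "repaint", "ddrm", "ddnm") &&
      (is.null(model) || is.null(schedule)))
    stop("diffusion methods require 'model' and 'schedule'", call. = FALSE)
  switch(method,
    fista = fista_complete(partial, ...),
    opt = optimize_trajectory(partial, seed = seed, ...),
    nn = nn_fill(partial),
    dbsearch = database_search(partial, database),
    ensmean = ensemble_mean_fill(partial, cohort),
    ddpm = inpaint_ddpm(model, partial, schedule, n_steps, seed = seed, ...),
    repaint = inpaint_repaint(model, partial, schedule, n_steps, seed = seed, ...),
    ddrm = inpaint_ddrm(model, partial, schedule, n_steps, seed = seed, ...),
    ddnm = inpaint_ddnm(model, partial, schedule, n_steps, seed = seed, ...))
}
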