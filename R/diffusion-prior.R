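#' Variance schedule of the forward diffusion process
#'
#' Builds the noising schedule \eqn{\beta_1 \dots \beta_T} (with the
#' \eqn{\beta_0 = 0} convention, i.e. no noise at t = 0) together with the
#' derived \eqn{\alpha_t = 1 - \beta_t} and cumulative products
#' \eqn{\bar\alpha_t = \prod_{i \le t} \alpha_i}. For the default linear
#' schedule with `T = 1000`, \eqn{\bar\alpha_T < 10^{-3}}, so the fully
#' noised sample is indistinguishable from white noise.
#'
#' @param T_steps Number of diffusion steps (default 1000).
#' @param beta_min,beta_max Endpoints of the linear schedule
#'   (defaults 1e-4 and 0.02); must satisfy `0 < beta_min < beta_max < 1`.
#' @param kind Schedule shape; only `"linear"` is provided.
#' @return Object of class `"noise_schedule"`: list with `T`, `betas`,
#'   `alphas`, `alpha_bars` (all length `T`, indexed t = 1..T), `sigmas`
#'   (`sqrt(betas)`), and `orig_t` (the parent-chain timestep of each
#'   position; the identity for a fresh schedule).
#' @export
make_schedule <- function(T_steps = 1000L, beta_min = 1e-4, beta_max = 0.02,
                          kind = "linear") {
  T_steps <- as.integer(T_steps)
  stopifnot(T_steps >= 1L)
  if (!(beta_min > 0 && beta_min < beta_max && beta_max < 1))
    stop("need 0 < beta_min < beta_max < 1", call. = FALSE)
  kind <- match.arg(kind)
  betas <- seq(beta_min, beta_max, length.out = T_steps)
  alphas <- 1 - betas
  structure(list(T = T_steps, betas = betas, alphas = alphas,
                 alpha_bars = cumprod(alphas), sigmas = sqrt(betas),
                 orig_t = seq_len(T_steps)),
            class = "noise_schedule")
}

#' @export
print.noise_schedule <- function(x, ...) {
  cat(sprintf("noise schedule: T = %d, beta in [%.3g, %.3g], alpha_bar_T = %.3g\n",
              x$T, min(x$betas), max(x$betas), x$alpha_bars[x$T]))
  invisible(x)
}

# alpha_bar with the t = 0 convention (no noise).
ab_at <- function(schedule, t) {
  ifelse(t == 0L, 1, schedule$alpha_bars[t])
}

#' Respace a schedule onto a subsequence of timesteps
#'
#' Shortens the diffusion chain to the timesteps `S` while preserving the
#' forward marginals: the new betas are
#' \eqn{\beta_i^{new} = 1 - \bar\alpha_{S_i} / \bar\alpha_{S_{i-1}}}
#' (with \eqn{S_0 = 0}), so the new cumulative \eqn{\bar\alpha_i} equals
#' the original \eqn{\bar\alpha_{S_i}} exactly. The denoiser is queried at
#' the parent-chain timesteps, recorded in `orig_t`.
#'
#' @param schedule A [make_schedule()] result (possibly already respaced).
#' @param S Strictly increasing integer subsequence of `1..schedule$T`.
#' @return A `"noise_schedule"` of length `length(S)`.
#' @export
respace <- function(schedule, S) {
  stopifnot(inherits(schedule, "noise_schedule"))
  S <- as.integer(S)
  if (any(S < 1L) || any(S > schedule$T) || any(diff(S) <= 0L))
    stop("'S' must be a strictly increasing subsequence of 1..T", call. = FALSE)
  ab <- schedule$alpha_bars[S]
  ab_prev <- c(1, ab[-length(ab)])
  betas <- 1 - ab / ab_prev
  structure(list(T = length(S), betas = betas, alphas = 1 - betas,
                 alpha_bars = ab, sigmas = sqrt(betas),
                 orig_t = schedule$orig_t[S]),
            class = "noise_schedule")
}

# Evenly spaced respacing helper used by the samplers.
respace_even <- function(schedule, n_steps) {
  if (n_steps >= schedule$T) return(schedule)
  S <- unique(round(seq(1L, schedule$T, length.out = n_steps)))
  respace(schedule, S)
}

#' Forward noising at an arbitrary timestep
#'
#' Closed-form sample of the forward process:
#' \eqn{x_t = \sqrt{\bar\alpha_t}\, x_0 + \sqrt{1 - \bar\alpha_t}\,\epsilon}.
#'
#' @param x0 Clean image (any numeric array).
#' @param t Timestep in `0..T` (0 returns `x0`).
#' @param eps Standard-normal noise of the same shape as `x0`.
#' @param schedule A `"noise_schedule"`.
#' @return Noised image, same shape as `x0`.
#' @export
q_sample <- function(x0, t, eps, schedule) {
  stopifnot(inherits(schedule, "noise_schedule"))
  t <- as.integer(t)
  if (t < 0L || t > schedule$T) stop("'t' out of range 0..T", call. = FALSE)
  ab <- ab_at(schedule, t)
  sqrt(ab) * x0 + sqrt(1 - ab) * eps
}

#' Intensity normalizer between raw squared distances and model range
#'
#' Affine map between raw squared distances and the `[-1, 1]` value range
#' the diffusion model operates on: `x = 2 (a - offset) / scale - 1`.
#' [fit_normalizer()] sets `scale` to the ensemble's upper quantile
#' (default 99.9th percentile) of matrix entries, so the heavy right tail
#' of large-separation distances does not compress the small-separation
#' structure; values above the quantile are clipped when `clip = TRUE` in
#' [normalize_edm()]. The map itself is exactly invertible.
#'
#' @param scale Positive scale (raw units spanned by the model range).
#' @param offset Raw value mapped to -1 (default 0).
#' @return Object of class `"edm_normalizer"`.
#' @export
edm_normalizer <- function(scale, offset = 0) {
  if (!(is.numeric(scale) && scale > 0))
    stop("'scale' must be positive", call. = FALSE)
  structure(list(scale = scale, offset = offset), class = "edm_normalizer")
}

#' @rdname edm_normalizer
#' @param edms List of squared-distance matrices (a training ensemble).
#' @param q Upper quantile defining the scale (default 0.999).
#' @export
fit_normalizer <- function(edms, q = 0.999) {
  vals <- unlist(lapply(edms, ut), use.names = FALSE)
  edm_normalizer(scale = as.numeric(stats::quantile(vals, q)), offset = 0)
}

#' @rdname edm_normalizer
#' @param norm An `"edm_normalizer"`.
#' @param a Raw squared-distance matrix (or array).
#' @param clip Clip the result into `[-1, 1]` (default FALSE).
#' @export
normalize_edm <- function(norm, a, clip = FALSE) {
  stopifnot(inherits(norm, "edm_normalizer"))
  x <- 2 * (a - norm$offset) / norm$scale - 1
  if (clip) x <- pmin(pmax(x, -1), 1)
  x
}

#' @rdname edm_normalizer
#' @param x Model-range image.
#' @export
denormalize_edm <- function(norm, x) {
  stopifnot(inherits(norm, "edm_normalizer"))
  (x + 1) / 2 * norm$scale + norm$offset
}

#' Noise prediction (DenoiserFn contract)
#'
#' Every denoiser implements `predict_eps(model, x, t)`: given a batch of
#' noised images (rows of `x`, flattened column-major) and a parent-chain
#' timestep `t`, return the predicted noise of identical shape. Predictions
#' are deterministic for fixed parameters and inputs.
#'
#' @param model A denoiser object.
#' @param x Numeric matrix, one flattened image per row.
#' @param t Integer timestep in `1..T` of the model's training schedule.
#' @return Matrix of predicted noise, same shape as `x`.
#' @export
predict_eps <- function(model, x, t) UseMethod("predict_eps")

#' Closed-form oracle denoiser for a single known target
#'
#' The exact noise posterior when the data distribution is a point mass at
#' `target`: \eqn{\hat\epsilon = (x_t - \sqrt{\bar\alpha_t}\,x^\ast) /
#' \sqrt{1 - \bar\alpha_t}}. Ancestral sampling with this denoiser returns
#' the target exactly, for any schedule - which decouples tests of the
#' samplers from training quality.
#'
#' @param target Target image (n x n matrix, model-range units).
#' @param schedule The schedule the sampler will use (parent chain).
#' @return A denoiser implementing [predict_eps()].
#' @export
oracle_denoiser <- function(target, schedule) {
  structure(list(target = as.numeric(target), n = nrow(target),
                 schedule = schedule),
            class = c("oracle_denoiser", "denoiser"))
}

#' @export
predict_eps.oracle_denoiser <- function(model, x, t) {
  ab <- ab_at(model$schedule, t)
  sweep(x, 2L, sqrt(ab) * model$target) / sqrt(1 - ab)
}

# Bin assignment for every parent timestep: equal-width bins in the noise
# magnitude sqrt(1 - alpha_bar_t), finer where the corruption level changes
# fastest.
make_bins <- function(schedule, bins) {
  s <- sqrt(1 - schedule$alpha_bars)
  edges <- seq(min(s), max(s), length.out = bins + 1L)
  k <- findInterval(s, edges, rightmost.closed = TRUE, all.inside = TRUE)
  as.integer(k)
}

# Coerce a dataset of images to a samples-by-pixels matrix: a list of
# n x n images, an n x n x M array, or an already-flattened M x n^2 matrix.
as_image_matrix <- function(images) {
  if (is.list(images))
    return(t(vapply(images, as.numeric, numeric(length(images[[1L]])))))
  if (is.array(images) && length(dim(images)) == 3L) {
    d <- dim(images)
    return(t(matrix(images, d[1L] * d[2L], d[3L])))
  }
  if (is.matrix(images)) return(images)
  stop("unsupported image dataset representation", call. = FALSE)
}

#' Train the denoising prior on an ensemble of EDM images
#'
#' Minimizes the standard denoising objective
#' \eqn{E_{x_0,\epsilon,t}\|\epsilon - Z_\theta(x_t, t)\|^2} with `t`
#' uniform on `1..T`. The predictor is a time-binned affine map: the
#' schedule is partitioned into `bins` noise-level bins, each carrying its
#' own dense weight matrix and bias (\eqn{\hat\epsilon = W_k x_t + b_k}).
#' Because the predictor is affine, the objective is an exact least-squares
#' problem in the ensemble's first two moments, so training proceeds in two
#' stages: (i) a moment step solves the per-bin normal equations
#' \eqn{(\bar\Sigma_k + (q_1 - q_2)\,\bar m \bar m^T) W_k = \bar s_k I}
#' built from the empirical mean and covariance of the training images
#' (with \eqn{\Sigma_t = \bar\alpha_t C + (1-\bar\alpha_t)I} averaged over
#' the bin); (ii) `epochs` rounds of minibatch Adam refine the solution
#' against freshly drawn noise. The recorded loss history starts from the
#' evaluated loss of the untrained (zero) predictor. For ensembles whose
#' images are close to jointly Gaussian - squared-distance matrices of
#' Gaussian processes at desk scale - the optimal noise predictor is
#' affine in `x_t`, so this architecture is well matched to the data while
#' staying tractable on a single CPU.
#'
#' @param images Training images: list of raw n x n squared-distance
#'   matrices (normalized internally), or - with `normalizer = FALSE` -
#'   already-normalized images as a list, an M x n^2 matrix, or an
#'   n x n x M array.
#' @param schedule Training schedule from [make_schedule()].
#' @param epochs Adam refinement epochs after the moment step (default 5).
#' @param batch_size Minibatch size (default 128).
#' @param bins Number of noise-level bins (default 16).
#' @param lr Adam learning rate (default 1e-4; the moment step
#'   already sits near the optimum, so refinement is gentle).
#' @param normalizer `NULL` to fit one from the data, an
#'   `"edm_normalizer"`, or `FALSE` if `images` are already normalized.
#' @param seed Optional seed for data order and noise draws.
#' @param verbose Print per-epoch loss.
#' @return Object of class `"affine_denoiser"` implementing
#'   [predict_eps()], with fields `loss_history` (initial loss, then one
#'   entry per training stage/epoch), `normalizer`, `train_stats`
#'   (median/upper-quantile of raw entries, used by unit bridges), `bins`,
#'   `schedule_T`.
#' @export
train_denoiser <- function(images, schedule, epochs = 5L, batch_size = 128L,
                           bins = 16L, lr = 1e-4, normalizer = NULL,
                           seed = NULL, verbose = FALSE) {
  stopifnot(inherits(schedule, "noise_schedule"))
  train_stats <- NULL
  if (is.list(images) && length(images) == 0L)
    stop("empty training set", call. = FALSE)
  if (is.null(normalizer) || inherits(normalizer, "edm_normalizer")) {
    stopifnot(is.list(images))
    if (is.null(normalizer)) normalizer <- fit_normalizer(images)
    raw <- unlist(lapply(images, ut), use.names = FALSE)
    train_stats <- list(median = stats::median(raw),
                        q99 = as.numeric(stats::quantile(raw, 0.99)))
    images <- lapply(images, function(a) normalize_edm(normalizer, a, clip = TRUE))
  } else {
    normalizer <- NULL
  }
  x0 <- as_image_matrix(images)
  m <- nrow(x0); d <- ncol(x0)
  n_side <- as.integer(round(sqrt(d)))
  if (m < 1L) stop("empty training set", call. = FALSE)
  bin_of <- make_bins(schedule, bins)
  t_by_bin <- split(seq_len(schedule$T), bin_of)
  nb <- length(t_by_bin)
  mu <- colMeans(x0)
  xc <- sweep(x0, 2L, mu)
  cc <- crossprod(xc) / max(m - 1L, 1L)
  eval_loss <- function(W, b0) {
    # one fresh noise draw per sample at a random t of each bin
    tot <- 0
    for (k in seq_len(nb)) {
      tt <- t_by_bin[[k]][sample.int(length(t_by_bin[[k]]), 1L)]
      ab <- schedule$alpha_bars[tt]
      eps <- matrix(stats::rnorm(m * d), m, d)
      xt <- sqrt(ab) * x0 + sqrt(1 - ab) * eps
      pred <- xt %*% W[[k]] + rep(b0[[k]], each = m)
      tot <- tot + mean((pred - eps)^2)
    }
    tot / nb
  }
  with_seed(seed, {
    W0 <- lapply(seq_len(nb), function(k) matrix(0, d, d))
    bz <- lapply(seq_len(nb), function(k) numeric(d))
    loss_history <- eval_loss(W0, bz)            # untrained predictor
    # --- moment step: exact per-bin least squares -------------------------
    W <- vector("list", nb); b0 <- vector("list", nb)
    for (k in seq_len(nb)) {
      ab <- schedule$alpha_bars[t_by_bin[[k]]]
      q1 <- mean(ab); q2 <- mean(sqrt(ab))^2
      sbar <- mean(sqrt(1 - ab))
      a_mat <- q1 * cc + (1 - q1) * diag(d) + (q1 - q2) * tcrossprod(mu)
      diag(a_mat) <- diag(a_mat) + 1e-10 * mean(diag(a_mat))
      W[[k]] <- solve(a_mat, sbar * diag(d))
      b0[[k]] <- -as.numeric(mean(sqrt(ab)) * (mu %*% W[[k]]))
    }
    loss_history <- c(loss_history, eval_loss(W, b0))
    if (verbose)
      message(sprintf("moment step: loss %.5f -> %.5f",
                      loss_history[1L], loss_history[2L]))
    # --- Adam refinement --------------------------------------------------
    if (epochs > 0L) {
      mW <- lapply(seq_len(nb), function(k) matrix(0, d, d))
      vW <- lapply(seq_len(nb), function(k) matrix(0, d, d))
      mb <- lapply(seq_len(nb), function(k) numeric(d))
      vb <- lapply(seq_len(nb), function(k) numeric(d))
      step_count <- integer(nb)
      beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
      for (ep in seq_len(epochs)) {
        perm <- sample.int(m)
        ep_loss <- 0; ep_n <- 0L
        for (lo in seq(1L, m, by = batch_size)) {
          hi <- min(lo + batch_size - 1L, m)
          xb <- x0[perm[lo:hi], , drop = FALSE]
          nr <- nrow(xb)
          for (k in seq_len(nb)) {
            tt <- t_by_bin[[k]][sample.int(length(t_by_bin[[k]]), 1L)]
            ab <- schedule$alpha_bars[tt]
            eps <- matrix(stats::rnorm(nr * d), nr, d)
            xt <- sqrt(ab) * xb + sqrt(1 - ab) * eps
            pred <- xt %*% W[[k]] + rep(b0[[k]], each = nr)
            resid <- pred - eps
            loss <- mean(resid^2)
            if (!is.finite(loss))
              stop("training diverged (non-finite loss)", call. = FALSE)
            ep_loss <- ep_loss + loss * nr; ep_n <- ep_n + nr
            gscale <- 2 / (nr * d)
            gW <- gscale * crossprod(xt, resid)
            gb <- gscale * colSums(resid)
            step_count[k] <- step_count[k] + 1L
            c1 <- 1 - beta1^step_count[k]; c2 <- 1 - beta2^step_count[k]
            mW[[k]] <- beta1 * mW[[k]] + (1 - beta1) * gW
            vW[[k]] <- beta2 * vW[[k]] + (1 - beta2) * gW^2
            W[[k]] <- W[[k]] - lr * (mW[[k]] / c1) / (sqrt(vW[[k]] / c2) + adam_eps)
            mb[[k]] <- beta1 * mb[[k]] + (1 - beta1) * gb
            vb[[k]] <- beta2 * vb[[k]] + (1 - beta2) * gb^2
            b0[[k]] <- b0[[k]] - lr * (mb[[k]] / c1) / (sqrt(vb[[k]] / c2) + adam_eps)
          }
        }
        loss_history <- c(loss_history, ep_loss / ep_n)
        if (verbose)
          message(sprintf("epoch %d/%d: loss %.5f", ep, epochs,
                          utils::tail(loss_history, 1)))
      }
    }
    structure(list(W = W, b = b0, bin_of = bin_of, n = n_side, d = d,
                   schedule_T = schedule$T, normalizer = normalizer,
                   train_stats = train_stats, loss_history = loss_history,
                   bins = nb),
              class = c("affine_denoiser", "denoiser"))
  })
}

#' @export
predict_eps.affine_denoiser <- function(model, x, t) {
  k <- model$bin_of[t]
  x %*% model$W[[k]] + rep(model$b[[k]], each = nrow(x))
}

#' @export
print.affine_denoiser <- function(x, ...) {
  cat(sprintf("affine denoiser: %d x %d images, %d noise bins, final loss %.5f\n",
              x$n, x$n, x$bins, utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Unconditional ancestral sampling (reverse diffusion)
#'
#' Draws images from the trained prior by ancestral sampling
#' \eqn{x_{t-1} = \mu_\theta(x_t, t) + \sigma_t \epsilon} with
#' \eqn{\mu_\theta} from the predicted noise and \eqn{\sigma_t^2 = \beta_t};
#' the noise term is set to zero at the final step so the output is the
#' deterministic x0 estimate. When `n_steps < T`, the schedule is respaced
#' ([respace()]) and the denoiser queried at the parent timesteps.
#'
#' @param model A denoiser ([train_denoiser()] or [oracle_denoiser()]).
#' @param schedule Parent-chain schedule.
#' @param n_steps Sampling steps (default 150).
#' @param count Number of images to draw (batched; default 1).
#' @param seed Optional seed.
#' @return List of `count` image matrices (model-range units).
#' @export
ddpm_sample <- function(model, schedule, n_steps = 150L, count = 1L,
                        seed = NULL) {
  stopifnot(inherits(schedule, "noise_schedule"))
  sch <- respace_even(schedule, n_steps)
  d <- model$d %||% length(model$target)
  n_side <- model$n
  with_seed(seed, {
    x <- matrix(stats::rnorm(count * d), count, d)
    for (i in seq(sch$T, 1L)) {
      eh <- predict_eps(model, x, sch$orig_t[i])
      mu <- (x - sch$betas[i] / sqrt(1 - sch$alpha_bars[i]) * eh) /
        sqrt(sch$alphas[i])
      x <- if (i > 1L)
        mu + sch$sigmas[i] * matrix(stats::rnorm(count * d), count, d)
      else mu
    }
    lapply(seq_len(count), function(j) matrix(x[j, ], n_side, n_side))
  })
}
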