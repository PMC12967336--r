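## Module 2: conditional denoising diffusion over latent representations.
## The denoiser predicts the clean representation r directly (x0-prediction)
## rather than the added noise; training drops the condition with a fixed
## probability so conditional and unconditional predictions can be combined
## at sampling time (classifier-free guidance). The denoiser is a dense
## network over [r_t, cosine time embedding, learned condition embedding];
## with a single latent vector per example an attention stack over one token
## adds nothing, so the dense completion is used and documented.

#' Cosine/sine timestep embedding
#'
#' Deterministic sinusoidal positional code: half the dimensions carry
#' `sin(t * omega_i)`, half `cos(t * omega_i)` with geometrically spaced
#' frequencies, so distinct timesteps map to distinct vectors and all
#' entries lie in `[-1, 1]`.
#'
#' @param t integer timestep (1-based), possibly a vector.
#' @param dim even embedding dimension.
#' @param T_max largest timestep the code must separate.
#' @return Length-`dim` vector (or `length(t)`-by-`dim` matrix).
#' @export
cosine_time_embedding <- function(t, dim, T_max = 10000) {
  stopifnot(dim %% 2 == 0, dim >= 2)
  if (any(t < 1)) stop("timestep t must be >= 1")
  half <- dim / 2
  omega <- T_max^(-(seq_len(half) - 1) / half)
  ang <- outer(as.numeric(t), omega)
  out <- cbind(sin(ang), cos(ang))
  if (length(t) == 1L) drop(out) else out
}

#' Build a diffusion noise schedule
#'
#' Cumulative signal coefficients `alpha_bar[0..T]` for the forward
#' corruption marginals. The cosine schedule (offset s = 0.008) is the
#' standard partner for x0-prediction: `alpha_bar(t) = f(t)/f(0)` with
#' `f(t) = cos^2(((t/T + s)/(1 + s)) * pi/2)`, clamped away from 0.
#'
#' @param T_steps total timesteps (>= 2).
#' @param name schedule family; `"cosine"` only.
#' @param s cosine offset.
#' @return `rg_schedule`: list with `T`, `alpha_bar` (length T+1, index 1 is
#'   t = 0 and equals 1), `name`.
#' @export
build_schedule <- function(T_steps, name = "cosine", s = 0.008) {
  stopifnot(T_steps >= 2)
  if (!identical(name, "cosine"))
    stop("unknown schedule name: ", name)
  t <- 0:T_steps
  f <- cos(((t / T_steps + s) / (1 + s)) * pi / 2)^2
  ab <- pmin(pmax(f / f[1], 1e-8), 1)
  structure(list(T = as.integer(T_steps), alpha_bar = ab, name = name),
            class = "rg_schedule")
}

#' @keywords internal
sched_ab <- function(schedule, t) schedule$alpha_bar[t + 1L]  # t is 0-based

#' Forward-diffuse clean representations to timestep t
#'
#' `r_t = sqrt(alpha_bar_t) r0 + sqrt(1 - alpha_bar_t) eps`,
#' `eps ~ N(0, I)`.
#'
#' @param r0 n-by-m matrix (or m-vector) of clean representations.
#' @param t timestep in `1..T` (scalar, or one per row).
#' @param schedule an [build_schedule()] result.
#' @param seed optional seed for reproducibility.
#' @return `list(r_t, noise)`, both matching `r0`'s shape.
#' @export
forward_diffuse <- function(r0, t, schedule, seed = NULL) {
  vec <- !is.matrix(r0)
  r0 <- rbind(r0)
  if (any(t < 1 | t > schedule$T)) stop("t out of range 1..T")
  ab <- sched_ab(schedule, t)
  eps <- with_seed(seed, matrix(stats::rnorm(length(r0)), nrow(r0), ncol(r0)))
  r_t <- sqrt(ab) * r0 + sqrt(1 - ab) * eps
  if (vec) list(r_t = drop(r_t), noise = drop(eps))
  else list(r_t = r_t, noise = eps)
}

#' Configure classifier-free guidance
#'
#' @param drop_probability fraction of training examples whose condition is
#'   replaced by the learned null token (default 0.1: the condition is
#'   omitted in 10% of the training steps).
#' @param guidance_weight sampling-time weight w >= 0; `w = 0` is
#'   conditional-only sampling.
#' @return `rg_guidance` list.
#' @export
guidance_config <- function(drop_probability = 0.1, guidance_weight = 1.0) {
  stopifnot(drop_probability >= 0, drop_probability < 1, guidance_weight >= 0)
  structure(list(drop_probability = drop_probability,
                 guidance_weight = guidance_weight),
            class = "rg_guidance")
}

#' Configure the latent diffusion model
#'
#' @param T_steps diffusion timesteps (desk-scale default 200).
#' @param hidden hidden widths of the denoiser network.
#' @param time_dim timestep embedding dimension (even).
#' @param cond_dim learned condition-embedding dimension.
#' @param steps,batch_size,lr training budget.
#' @param clip_x0 clamp range for predicted clean samples at sampling, as
#'   a multiplier of the training data's observed per-dimension range
#'   (1 = clamp to that range, the standard choice); `Inf` disables.
#' @param ema_decay exponential-moving-average decay for the sampling
#'   weights (standard diffusion practice; 0 disables averaging).
#' @details The denoiser output is parameterised as
#'   `r_hat0 = sqrt(ab_t) r_t + sqrt(1 - ab_t) f(r_t, t, y)` and trained
#'   with the x0 loss weighted by `1/(1 - ab_t)`, which is algebraically a
#'   uniform-weight regression on the network's O(1) target at every
#'   timestep (the v-parameterisation). A plain x0 MSE gives low-noise
#'   timesteps almost no gradient weight, starving the small-t denoiser
#'   and collapsing the sampled within-class variance.
#' @param guidance an [guidance_config()].
#' @param seed integer seed.
#' @return `rg_diffusion_config` list.
#' @export
diffusion_config <- function(T_steps = 200L, hidden = c(128L, 128L),
                             time_dim = 32L, cond_dim = 16L,
                             steps = 2000L, batch_size = 128L, lr = 1e-3,
                             clip_x0 = 1.0, ema_decay = 0.999,
                             guidance = guidance_config(), seed = 1L) {
  structure(list(T_steps = as.integer(T_steps), hidden = as.integer(hidden),
                 time_dim = as.integer(time_dim),
                 cond_dim = as.integer(cond_dim), steps = as.integer(steps),
                 batch_size = as.integer(batch_size), lr = lr,
                 clip_x0 = clip_x0, ema_decay = ema_decay,
                 guidance = guidance, seed = as.integer(seed)),
            class = "rg_diffusion_config")
}

## Denoiser forward: model is either a plain function r_hat0(r_t, t, y_or_NULL)
## (used by tests/oracles) or a trained bundle's parameter set.
#' @keywords internal
denoiser_forward <- function(par, net, r_t, t, Ycond, null_mask,
                             time_dim, ab_t, cache = FALSE) {
  n <- nrow(r_t)
  temb <- cosine_time_embedding(t, time_dim)
  if (n == 1L) temb <- rbind(temb)
  cond <- Ycond %*% par$Wy
  if (any(null_mask))
    cond[null_mask, ] <- matrix(par$null_emb, sum(null_mask),
                                length(par$null_emb), byrow = TRUE)
  X <- cbind(r_t, temb, sqrt(ab_t), ab_t, cond)
  fw <- nn_forward(net, X, cache = cache)
  ## v-style parameterisation: r_hat0 = sqrt(ab) r_t + sqrt(1-ab) f(.),
  ## so the network's target is O(1) at every noise level, the small-t
  ## prediction degenerates to the (nearly clean) input, and the
  ## conditional and unconditional branches agree there by construction.
  list(out = fw$out * sqrt(1 - ab_t) + sqrt(ab_t) * r_t,
       cache = fw$cache, X = X)
}

#' Diffusion training loss (x0-prediction)
#'
#' Mean squared error between the denoiser's prediction and the clean
#' representation, over timesteps drawn uniformly from `1..T`; each batch
#' element's condition is independently replaced by the null token with
#' probability `guidance$drop_probability`.
#'
#' @param model either a trained `rg_diffusion` bundle or a function
#'   `f(r_t, t, y)` (with `y = NULL` meaning the null condition) returning
#'   predicted r̂0 — the latter form supports oracle checks.
#' @param r n-by-m matrix of clean representations.
#' @param y n-by-d condition matrix.
#' @param schedule an `rg_schedule`.
#' @param guidance an [guidance_config()].
#' @param seed optional seed.
#' @return Scalar loss with attribute `n_dropped` (how many conditions were
#'   nulled in this evaluation).
#' @export
diffusion_loss <- function(model, r, y, schedule, guidance = guidance_config(),
                           seed = NULL) {
  r <- rbind(r); y <- rbind(y)
  n <- nrow(r)
  if (n == 0L) stop("empty batch")
  with_seed(seed, {
    t <- sample.int(schedule$T, n, replace = TRUE)
    fd <- forward_diffuse(r, t, schedule)
    drop_mask <- stats::runif(n) < guidance$drop_probability
    pred <- if (is.function(model)) {
      out <- matrix(0, n, ncol(r))
      for (i in seq_len(n))
        out[i, ] <- model(fd$r_t[i, ], t[i],
                          if (drop_mask[i]) NULL else y[i, ])
      out
    } else {
      denoiser_forward(model$params, model$net, fd$r_t, t, y, drop_mask,
                       model$cfg$time_dim, sched_ab(schedule, t))$out
    }
    loss <- mean((pred - r)^2)
    if (!is.finite(loss)) stop("diffusion loss is not finite")
    structure(loss, n_dropped = sum(drop_mask))
  })
}

#' Train the conditional latent diffusion model
#'
#' @param r n-by-m matrix of clean latent representations.
#' @param y n-by-d condition (label) matrix.
#' @param cfg an [diffusion_config()].
#' @param standardize z-score each latent dimension before modelling (the
#'   inverse transform is applied at sampling)? Recommended: the corruption
#'   process assumes roughly unit-scale data.
#' @return `rg_diffusion` bundle: denoiser net + condition-embedding
#'   parameters, schedule, guidance, standardisation constants, clamp range
#'   and the per-step loss trace.
#' @export
train_diffusion <- function(r, y, cfg = diffusion_config(),
                            standardize = TRUE) {
  r <- as.matrix(r); y <- as.matrix(y)
  stopifnot(nrow(r) == nrow(y), nrow(r) > 0)
  m <- ncol(r); d <- ncol(y)
  center <- if (standardize) colMeans(r) else numeric(m)
  scale_ <- if (standardize) pmax(apply(r, 2L, stats::sd), 1e-8) else rep(1, m)
  rs <- sweep(sweep(r, 2L, center), 2L, scale_, "/")
  ## per-dimension clamp range for predicted clean samples: the observed
  ## data range per latent dimension, optionally widened by clip_x0
  if (is.finite(cfg$clip_x0)) {
    lo <- apply(rs, 2L, min); hi <- apply(rs, 2L, max)
    mid <- (lo + hi) / 2; half <- cfg$clip_x0 * (hi - lo) / 2
    clip_lo <- mid - half; clip_hi <- mid + half
  } else {
    clip_lo <- rep(-Inf, m); clip_hi <- rep(Inf, m)
  }

  schedule <- build_schedule(cfg$T_steps)
  in_dim <- m + cfg$time_dim + 2L + cfg$cond_dim
  net <- nn_mlp(c(in_dim, cfg$hidden, m), seed = cfg$seed)
  par <- with_seed(cfg$seed + 1L, list(
    Wy = matrix(stats::rnorm(d * cfg$cond_dim, sd = sqrt(1 / d)),
                d, cfg$cond_dim),
    null_emb = stats::rnorm(cfg$cond_dim, sd = 0.1)
  ))
  opt_net <- adam_init(net)
  opt_par <- adam_init_list(par)
  ema_net <- net; ema_par <- par
  dec <- cfg$ema_decay
  ## per-timestep loss weights 1/(1-ab): uniform weight on the network's
  ## own target (see Details in diffusion_config), normalised to mean 1
  ab_t_all <- schedule$alpha_bar[-1L]
  wt_all <- 1 / (1 - ab_t_all)
  wt_all <- wt_all / mean(wt_all)
  n <- nrow(rs)
  trace <- numeric(cfg$steps)

  with_seed(cfg$seed + 2L, {
    for (step in seq_len(cfg$steps)) {
      idx <- sample.int(n, min(cfg$batch_size, n))
      rb <- rs[idx, , drop = FALSE]
      yb <- y[idx, , drop = FALSE]
      t <- sample.int(schedule$T, length(idx), replace = TRUE)
      fd <- forward_diffuse(rb, t, schedule)
      drop_mask <- stats::runif(length(idx)) <
        cfg$guidance$drop_probability
      fw <- denoiser_forward(par, net, fd$r_t, t, yb, drop_mask,
                             cfg$time_dim, sched_ab(schedule, t),
                             cache = TRUE)
      resid <- fw$out - rb
      wt <- wt_all[t]
      loss <- mean(wt * rowMeans(resid^2))
      trace[step] <- loss
      if (!is.finite(loss))
        stop("diffusion training diverged at step ", step)
      ## chain through the sqrt(1-ab) output scaling of the net
      dout <- 2 * wt * sqrt(1 - sched_ab(schedule, t)) * resid /
        length(resid)
      bw <- nn_backward(net, fw$cache, dout)
      dX <- bw$dX
      dcond <- dX[, (m + cfg$time_dim + 3L):ncol(dX), drop = FALSE]
      gpar <- list(Wy = crossprod(yb * (!drop_mask), dcond),
                   null_emb = colSums(dcond[drop_mask, , drop = FALSE]))
      ## linear lr decay over the final third of training
      lr_s <- cfg$lr * min(1, 3 * (1 - step / cfg$steps) + 1e-3)
      up1 <- adam_step(net, bw$grads, opt_net, lr = lr_s)
      net <- up1$net; opt_net <- up1$state
      up2 <- adam_step_list(par, gpar, opt_par, lr = lr_s)
      par <- up2$params; opt_par <- up2$state
      if (dec > 0) {
        for (l in seq_along(net$layers)) for (pn in c("W", "b"))
          ema_net$layers[[l]][[pn]] <- dec * ema_net$layers[[l]][[pn]] +
            (1 - dec) * net$layers[[l]][[pn]]
        for (pn in names(par))
          ema_par[[pn]] <- dec * ema_par[[pn]] + (1 - dec) * par[[pn]]
      } else {
        ema_net <- net; ema_par <- par
      }
    }
  })
  structure(list(net = ema_net, params = ema_par, raw_net = net,
                 cfg = cfg, schedule = schedule,
                 m = m, d = d, center = center, scale = scale_,
                 clip_lo = clip_lo, clip_hi = clip_hi,
                 loss_trace = trace),
            class = "rg_diffusion")
}

#' Sample latent representations conditionally on a label
#'
#' Ancestral reverse loop `t = T..1`. At each step the guided clean-sample
#' prediction is `r̂0_g = (1 + w) f(r_t, t, y) - w f(r_t, t, null)`,
#' clamped, and `r_{t-1}` is drawn from the forward posterior
#' `q(r_{t-1} | r_t, r̂0_g)`. `w = 0` reduces to conditional-only
#' sampling.
#'
#' @param model trained `rg_diffusion`.
#' @param y length-d condition vector.
#' @param n number of samples.
#' @param guidance_weight overrides the bundle's guidance weight if given.
#' @param seed optional seed (same seed + y gives identical output).
#' @return n-by-m matrix of sampled representations (original scale).
#' @export
sample_representation <- function(model, y, n = 1L, guidance_weight = NULL,
                                  seed = NULL) {
  stopifnot(inherits(model, "rg_diffusion"))
  w <- if (is.null(guidance_weight)) model$cfg$guidance$guidance_weight
  else guidance_weight
  sch <- model$schedule
  m <- model$m
  Y <- matrix(y, n, model$d, byrow = TRUE)
  with_seed(seed, {
    r_t <- matrix(stats::rnorm(n * m), n, m)
    for (t in sch$T:1) {
      tv <- rep(t, n)
      ab_t <- sched_ab(sch, t)
      pred_c <- denoiser_forward(model$params, model$net, r_t, tv, Y,
                                 rep(FALSE, n), model$cfg$time_dim, ab_t)$out
      x0 <- if (w > 0) {
        pred_u <- denoiser_forward(model$params, model$net, r_t, tv, Y,
                                   rep(TRUE, n), model$cfg$time_dim, ab_t)$out
        (1 + w) * pred_c - w * pred_u
      } else pred_c
      x0 <- t(pmin(pmax(t(x0), model$clip_lo), model$clip_hi))
      if (t == 1L) {
        r_t <- x0
      } else {
        ab_prev <- sched_ab(sch, t - 1L)
        alpha_t <- ab_t / ab_prev
        beta_t <- 1 - alpha_t
        mean_ <- (sqrt(ab_prev) * beta_t / (1 - ab_t)) * x0 +
          (sqrt(alpha_t) * (1 - ab_prev) / (1 - ab_t)) * r_t
        var_ <- beta_t * (1 - ab_prev) / (1 - ab_t)
        r_t <- mean_ + sqrt(pmax(var_, 0)) *
          matrix(stats::rnorm(n * m), n, m)
      }
    }
    sweep(sweep(r_t, 2L, model$scale, "*"), 2L, model$center, "+")
  })
}
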