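## Module 3: conditional Wasserstein GAN with gradient penalty, generating
## one-hot sequences from (noise z, latent representation r, label y), plus
## an auxiliary discriminative classifier (ADC) over 2C mutually exclusive
## (real, class) / (fake, class) targets whose terms enter the generator
## objective with weight beta. The gradient penalty's parameter gradients
## are computed exactly by a forward-over-reverse pass through the critic
## (masks held fixed), not by a finite-difference surrogate.

#' Configure the sequence GAN
#'
#' @param z_dim noise dimension.
#' @param g_hidden,d_hidden,c_hidden hidden widths of generator, critic and
#'   classifier.
#' @param lambda gradient-penalty coefficient (> 0).
#' @param beta auxiliary-classifier weight (>= 0). The default 175 is the
#'   best-performing setting reported for this architecture family; values
#'   above 300 degrade performance, so a warning is issued there.
#' @param n_critic critic (and classifier) steps per generator step.
#' @param batch_size,steps,lr_g,lr_d,adam_beta1,adam_beta2 training budget
#'   and optimiser settings (the usual WGAN-GP choices).
#' @param log_every record the three loss values every this many generator
#'   steps (the final step is always logged). Logging runs under its own
#'   derived seed, so its frequency never perturbs the training stream.
#' @param use_r condition the generator/critic on the latent representation
#'   r? `FALSE` gives the one-stage label-only baseline.
#' @param mask_pad replace critic/classifier input rows beyond a sequence's
#'   true length by the canonical pad one-hot, making scores invariant to
#'   pad-region content?
#' @param seed integer seed.
#' @return `rg_gan_config` list.
#' @export
gan_config <- function(z_dim = 16L, g_hidden = c(128L, 128L),
                       d_hidden = c(128L, 128L), c_hidden = c(128L, 128L),
                       lambda = 10, beta = 175, n_critic = 5L,
                       batch_size = 64L, steps = 2000L,
                       lr_g = 1e-4, lr_d = 1e-4,
                       adam_beta1 = 0.5, adam_beta2 = 0.9, log_every = 10L,
                       use_r = TRUE, mask_pad = FALSE, seed = 1L) {
  stopifnot(lambda > 0, beta >= 0, n_critic >= 1)
  if (beta > 300)
    warning("beta = ", beta, " exceeds 300; performance typically ",
            "declines beyond that threshold")
  structure(list(z_dim = as.integer(z_dim), g_hidden = as.integer(g_hidden),
                 d_hidden = as.integer(d_hidden),
                 c_hidden = as.integer(c_hidden),
                 lambda = lambda, beta = beta, n_critic = as.integer(n_critic),
                 batch_size = as.integer(batch_size),
                 steps = as.integer(steps), lr_g = lr_g, lr_d = lr_d,
                 adam_beta1 = adam_beta1, adam_beta2 = adam_beta2,
                 log_every = as.integer(log_every),
                 use_r = isTRUE(use_r), mask_pad = isTRUE(mask_pad),
                 seed = as.integer(seed)),
            class = "rg_gan_config")
}

## row layout helpers: batch matrix n x (L*A), position-major per row
#' @keywords internal
to_pos_rows <- function(X, A) matrix(as.vector(t(X)), ncol = A, byrow = TRUE)
#' @keywords internal
from_pos_rows <- function(M, n) matrix(as.vector(t(M)), nrow = n, byrow = TRUE)

#' Initialise an untrained GAN bundle
#'
#' @param cfg an [gan_config()].
#' @param spec an [encoding_spec()].
#' @param m latent representation dimension (ignored when `use_r = FALSE`).
#' @param d label dimension.
#' @param C number of exclusive classes for the ADC head.
#' @return `rg_gan` bundle (generator, critic, classifier nets + config).
#' @export
init_gan <- function(cfg, spec, m, d, C) {
  LA <- spec$max_length * spec$A
  rm_ <- if (cfg$use_r) m else 0L
  gen <- nn_mlp(c(cfg$z_dim + rm_ + d, cfg$g_hidden, LA), seed = cfg$seed)
  cri <- nn_mlp(c(LA + rm_ + d, cfg$d_hidden, 1L), seed = cfg$seed + 1L)
  clf <- nn_mlp(c(LA, cfg$c_hidden, 2L * C), seed = cfg$seed + 2L)
  structure(list(gen = gen, critic = cri, clf = clf, cfg = cfg, spec = spec,
                 m = as.integer(rm_), d = as.integer(d), C = as.integer(C),
                 trained = FALSE),
            class = "rg_gan")
}

#' @keywords internal
gen_forward_batch <- function(gan, Z, R, Y, cache = FALSE) {
  inp <- cbind(Z, R, Y)
  fw <- nn_forward(gan$gen, inp, cache = cache)
  A <- gan$spec$A
  P <- row_softmax(to_pos_rows(fw$out, A))
  X <- from_pos_rows(P, nrow(inp))
  list(X = X, P = P, cache = fw$cache)
}

#' Generator forward pass (single example)
#'
#' Maps (noise, representation, label) to a relaxed one-hot sequence: an
#' L-by-A matrix of per-position amino-acid probabilities (each row sums to
#' 1). A hard sequence is obtained by per-row argmax at sampling time.
#'
#' @param gan an `rg_gan`.
#' @param z noise vector (`z_dim`).
#' @param r representation vector (`m`), or `NULL` when `use_r = FALSE`.
#' @param y label vector (`d`).
#' @return L-by-A probability matrix.
#' @export
generator_forward <- function(gan, z, r, y) {
  r <- if (gan$m > 0) r else numeric(0)
  if (length(r) != gan$m)
    stop("representation has length ", length(r), ", expected ", gan$m)
  X <- gen_forward_batch(gan, rbind(z), rbind(r)[, seq_len(gan$m), drop = FALSE],
                         rbind(y))$X
  matrix(X[1, ], gan$spec$max_length, gan$spec$A, byrow = TRUE,
         dimnames = list(NULL, gan$spec$alphabet))
}

#' @keywords internal
mask_pad_rows <- function(gan, X, true_length) {
  if (is.null(true_length)) return(X)
  A <- gan$spec$A; L <- gan$spec$max_length
  pad <- numeric(A); pad[gan$spec$pad_index] <- 1
  for (i in seq_len(nrow(X))) {
    tl <- true_length[min(i, length(true_length))]
    if (tl < L) {
      block <- matrix(X[i, ], L, A, byrow = TRUE)
      block[(tl + 1L):L, ] <- matrix(pad, L - tl, A, byrow = TRUE)
      X[i, ] <- as.vector(t(block))
    }
  }
  X
}

#' Critic (discriminator) forward pass
#'
#' @param gan an `rg_gan`.
#' @param x L-by-A matrix (relaxed or hard one-hot), or a flattened
#'   batch matrix n-by-(L*A).
#' @param r representation vector/matrix (or `NULL`).
#' @param y label vector/matrix.
#' @param true_length optional true sequence length(s); with
#'   `mask_pad = TRUE` in the config, content beyond it cannot affect the
#'   score.
#' @return Scalar score (or n-vector).
#' @export
critic_forward <- function(gan, x, r, y, true_length = NULL) {
  single <- is.matrix(x) && ncol(x) == gan$spec$A
  X <- if (single) rbind(as.vector(t(unclass(x)))) else rbind(x)
  if (ncol(X) != gan$spec$max_length * gan$spec$A)
    stop("x has ", ncol(X), " columns, expected L*A = ",
         gan$spec$max_length * gan$spec$A)
  if (gan$cfg$mask_pad) X <- mask_pad_rows(gan, X, true_length)
  R <- if (gan$m > 0) rbind(r)[, seq_len(gan$m), drop = FALSE]
  else matrix(0, nrow(X), 0)
  out <- nn_forward(gan$critic, cbind(X, R, rbind(y)))$out
  if (single) out[1, 1] else drop(out)
}

#' Auxiliary discriminative classifier forward pass
#'
#' Log-probabilities over the 2C mutually exclusive ADC targets: columns
#' `1..C` are (real, c), columns `C+1..2C` are (fake, c).
#'
#' @param gan an `rg_gan`.
#' @param x as in [critic_forward()].
#' @param true_length optional, see [critic_forward()].
#' @return Length-2C log-probability vector (or n-by-2C matrix).
#' @export
adc_classifier_forward <- function(gan, x, true_length = NULL) {
  single <- is.matrix(x) && ncol(x) == gan$spec$A
  X <- if (single) rbind(as.vector(t(unclass(x)))) else rbind(x)
  if (ncol(X) != gan$spec$max_length * gan$spec$A)
    stop("x has ", ncol(X), " columns, expected L*A = ",
         gan$spec$max_length * gan$spec$A)
  if (gan$cfg$mask_pad) X <- mask_pad_rows(gan, X, true_length)
  out <- row_log_softmax(nn_forward(gan$clf, X)$out)
  if (single) drop(out) else out
}

## Critic forward with cached ReLU masks + exact input gradient.
## Returns score, input gradient g (n x in), and the per-layer backward
## vectors v (v[[l]] = dscore/dz_l with masks applied) and activations.
#' @keywords internal
critic_grad_pass <- function(net, Xin) {
  fw <- nn_forward(net, Xin, cache = TRUE)
  L <- length(net$layers)
  v <- vector("list", L)
  v[[L]] <- matrix(1, nrow(Xin), 1L)
  dA <- v[[L]]
  for (l in rev(seq_len(L))) {
    if (l < L) {
      v[[l]] <- dA * (fw$cache[[l + 1L]] > 0)
    }
    dA <- tcrossprod(if (l < L) v[[l]] else v[[L]], net$layers[[l]]$W)
  }
  list(score = fw$out, g = dA, v = v, cache = fw$cache)
}

#' WGAN-GP gradient penalty
#'
#' `lambda * E[(||grad_x critic(x_hat, r, y)||_2 - 1)^2]` where `x_hat` is a
#' per-pair uniform interpolate between real and fake sequences. The
#' gradient is taken with respect to the sequence block of the critic input
#' only (r and y are conditioning, not transport variables).
#'
#' @param gan an `rg_gan` (or any object with `$critic` an `rg_mlp` plus
#'   `$m`, `$spec`).
#' @param real_batch,fake_batch n-by-(L*A) matrices.
#' @param r n-by-m matrix (or `NULL`).
#' @param y n-by-d matrix.
#' @param lambda penalty coefficient; defaults to the config value.
#' @param seed optional seed for the interpolation draws.
#' @param want_grads also return exact critic parameter gradients of the
#'   penalty (used by the training loop)?
#' @return Scalar penalty; with `want_grads = TRUE`, attribute `grads`
#'   carries the per-layer parameter gradients.
#' @export
gradient_penalty <- function(gan, real_batch, fake_batch, r, y,
                             lambda = NULL, seed = NULL, want_grads = FALSE) {
  if (is.null(lambda)) lambda <- gan$cfg$lambda
  real_batch <- rbind(real_batch); fake_batch <- rbind(fake_batch)
  stopifnot(nrow(real_batch) == nrow(fake_batch))
  n <- nrow(real_batch)
  LA <- ncol(real_batch)
  u <- with_seed(seed, stats::runif(n))
  Xhat <- u * real_batch + (1 - u) * fake_batch
  R <- if (!is.null(r) && gan$m > 0) rbind(r) else matrix(0, n, 0)
  Xin <- cbind(Xhat, R, rbind(y))
  gp <- critic_grad_pass(gan$critic, Xin)
  gx <- gp$g[, seq_len(LA), drop = FALSE]
  S <- sqrt(rowSums(gx^2))
  penalty <- lambda * mean((S - 1)^2)
  if (!want_grads) return(penalty)
  ## forward-over-reverse: d penalty / d W_l = (lambda/n) t(t_{l-1}) v_l
  ## where t is the JVP stream seeded with u_i = 2(S_i - 1) g_i / S_i.
  U <- (2 * (S - 1) / pmax(S, 1e-12)) * gx
  Tl <- cbind(U, matrix(0, n, ncol(Xin) - LA))
  net <- gan$critic
  Ln <- length(net$layers)
  grads <- vector("list", Ln)
  for (l in seq_len(Ln)) {
    grads[[l]] <- list(W = (lambda / n) * crossprod(Tl, gp$v[[l]]),
                       b = net$layers[[l]]$b * 0)
    if (l < Ln)
      Tl <- (Tl %*% net$layers[[l]]$W) * (gp$cache[[l + 1L]] > 0)
  }
  structure(penalty, grads = grads)
}

#' GAN objective values for one batch
#'
#' Forward-only computation of the three losses (used for logging, tests
#' and the convergence trace; the training loop computes gradients
#' directly):
#' \itemize{
#'   \item critic: `E[D(fake)] - E[D(real)] + gradient penalty`;
#'   \item classifier: `-E[log p(real, c | x_real)] - E[log p(fake, c | x_fake)]`;
#'   \item generator: `-E[D(fake)] + beta * E[log p(fake, c | x_fake) -
#'     log p(real, c | x_fake)]` (pushed towards (real, c), away from
#'     (fake, c)); with `beta = 0` this is the plain Wasserstein generator
#'     loss.
#' }
#'
#' @param gan an `rg_gan`.
#' @param batch list with `x_real` (n-by-LA), `r` (n-by-m or `NULL`), `y`
#'   (n-by-d), `cls` (integer class index in `1..C`), optional `x_fake`
#'   (generated if absent, using `seed`).
#' @param classifier optional override: a function `f(x_batch)` returning
#'   an n-by-2C log-probability matrix (for oracle-classifier checks).
#' @param seed optional seed for z and the interpolates.
#' @return List `loss_G`, `loss_D`, `loss_C` plus the named components.
#' @export
gan_losses <- function(gan, batch, classifier = NULL, seed = NULL) {
  n <- nrow(batch$x_real)
  with_seed(seed, {
    if (is.null(batch$x_fake)) {
      Z <- matrix(stats::rnorm(n * gan$cfg$z_dim), n, gan$cfg$z_dim)
      R <- if (gan$m > 0) batch$r else matrix(0, n, 0)
      batch$x_fake <- gen_forward_batch(gan, Z, R, batch$y)$X
    }
    d_real <- critic_forward(gan, batch$x_real, batch$r, batch$y)
    d_fake <- critic_forward(gan, batch$x_fake, batch$r, batch$y)
    gp <- gradient_penalty(gan, batch$x_real, batch$x_fake, batch$r, batch$y)
    clf_fun <- if (is.null(classifier)) {
      function(x) adc_classifier_forward(gan, x)
    } else classifier
    lp_real <- rbind(clf_fun(batch$x_real))
    lp_fake <- rbind(clf_fun(batch$x_fake))
    i <- seq_len(n)
    loss_C <- -mean(lp_real[cbind(i, batch$cls)]) -
      mean(lp_fake[cbind(i, gan$C + batch$cls)])
    clf_term <- mean(lp_fake[cbind(i, gan$C + batch$cls)] -
                     lp_fake[cbind(i, batch$cls)])
    w_gap <- mean(d_fake) - mean(d_real)
    list(loss_G = -mean(d_fake) + gan$cfg$beta * clf_term,
         loss_D = w_gap + gp,
         loss_C = loss_C,
         wasserstein_gap = w_gap,
         gradient_penalty = as.numeric(gp),
         classifier_term = clf_term)
  })
}

## backward of the row softmax: P, dP are (n*L) x A
#' @keywords internal
softmax_rows_backward <- function(P, dP) P * (dP - rowSums(dP * P))

#' Train the conditional sequence GAN
#'
#' Standard WGAN-GP loop: `n_critic` critic+classifier updates per
#' generator update, Adam throughout. Real sequences are encoded to one-hot
#' and conditioned on their embedder representation r (unless
#' `use_r = FALSE`) and label y; the ADC class index is the index of each
#' record's distinct label pattern.
#'
#' @param records labelled `rg_record` list.
#' @param embedder an `rg_embedder` (may be `NULL` when `use_r = FALSE`).
#' @param cfg an [gan_config()].
#' @param spec an [encoding_spec()].
#' @param resume optional previously returned `rg_gan` bundle to continue
#'   training from (bit-reproducibly: RNG and optimiser state are part of
#'   the bundle).
#' @param steps overrides `cfg$steps` (number of *additional* generator
#'   steps when resuming).
#' @param patterns optional matrix of expected label patterns (one row per
#'   ADC class); a pattern with no training records raises an error naming
#'   the class. By default the patterns observed in the data are used.
#' @return Trained `rg_gan` bundle with `log` (per-generator-step data
#'   frame of the three losses) and `label_patterns`.
#' @export
train_cwgan <- function(records, embedder, cfg, spec, resume = NULL,
                        steps = NULL, patterns = NULL) {
  labs <- do.call(rbind, lapply(records, `[[`, "label"))
  if (is.null(labs)) stop("records must be labelled")
  if (is.null(patterns))
    patterns <- if (!is.null(resume)) resume$label_patterns else unique(labs)
  cls <- apply(labs, 1L, function(v) {
    hit <- which(apply(patterns, 1L, function(p) all(p == v)))
    if (!length(hit)) stop("record label ", paste(v, collapse = ""),
                           " matches no expected pattern")
    hit
  })
  empty <- setdiff(seq_len(nrow(patterns)), unique(cls))
  if (length(empty))
    stop("empty class(es): ",
         paste(apply(patterns[empty, , drop = FALSE], 1L, paste,
                     collapse = ""), collapse = ", "))
  C <- nrow(patterns)
  d <- ncol(labs)
  n <- length(records)
  LA <- spec$max_length * spec$A

  Xreal <- t(vapply(records, function(rec)
    as.vector(t(unclass(one_hot_encode(rec, spec)))), numeric(LA)))
  R <- if (cfg$use_r) {
    stopifnot(!is.null(embedder))
    as.matrix(extract_representation(embedder, records))
  } else matrix(0, n, 0)
  m <- ncol(R)

  if (is.null(resume)) {
    gan <- init_gan(cfg, spec, m, d, C)
    gan$label_patterns <- patterns
    opt <- list(gen = adam_init(gan$gen), critic = adam_init(gan$critic),
                clf = adam_init(gan$clf))
    gan$log <- data.frame(step = integer(0), loss_G = numeric(0),
                          loss_D = numeric(0), loss_C = numeric(0),
                          wasserstein_gap = numeric(0))
    rng_state <- NULL
    set.seed(cfg$seed + 10L)
  } else {
    gan <- resume
    opt <- gan$opt
    assign(".Random.seed", gan$rng_state, envir = globalenv())
  }
  if (is.null(steps)) steps <- cfg$steps
  step0 <- if (nrow(gan$log)) max(gan$log$step) else 0L
  bs <- min(cfg$batch_size, n)
  b1 <- cfg$adam_beta1; b2 <- cfg$adam_beta2
  A <- spec$A

  new_log <- matrix(0, steps, 5L)
  for (s in seq_len(steps)) {
    ## --- critic + classifier updates -----------------------------------
    for (j in seq_len(cfg$n_critic)) {
      idx <- sample.int(n, bs)
      xr <- Xreal[idx, , drop = FALSE]
      rb <- R[idx, , drop = FALSE]
      yb <- labs[idx, , drop = FALSE]
      cb <- cls[idx]
      Z <- matrix(stats::rnorm(bs * cfg$z_dim), bs, cfg$z_dim)
      xf <- gen_forward_batch(gan, Z, rb, yb)$X

      ## critic: d/dtheta [ mean D(fake) - mean D(real) + GP ]
      fw_f <- nn_forward(gan$critic, cbind(xf, rb, yb), cache = TRUE)
      fw_r <- nn_forward(gan$critic, cbind(xr, rb, yb), cache = TRUE)
      g_f <- nn_backward(gan$critic, fw_f$cache,
                         matrix(1 / bs, bs, 1L))$grads
      g_r <- nn_backward(gan$critic, fw_r$cache,
                         matrix(-1 / bs, bs, 1L))$grads
      gp <- gradient_penalty(gan, xr, xf, rb, yb, want_grads = TRUE)
      g_gp <- attr(gp, "grads")
      gd <- lapply(seq_along(g_f), function(l)
        list(W = g_f[[l]]$W + g_r[[l]]$W + g_gp[[l]]$W,
             b = g_f[[l]]$b + g_r[[l]]$b + g_gp[[l]]$b))
      up <- adam_step(gan$critic, gd, opt$critic, lr = cfg$lr_d,
                      beta1 = b1, beta2 = b2)
      gan$critic <- up$net; opt$critic <- up$state

      ## classifier: CE towards (real,c) on reals and (fake,c) on fakes
      fwc_r <- nn_forward(gan$clf, xr, cache = TRUE)
      fwc_f <- nn_forward(gan$clf, xf, cache = TRUE)
      P_r <- row_softmax(fwc_r$out); P_f <- row_softmax(fwc_f$out)
      T_r <- matrix(0, bs, 2L * C); T_r[cbind(seq_len(bs), cb)] <- 1
      T_f <- matrix(0, bs, 2L * C); T_f[cbind(seq_len(bs), C + cb)] <- 1
      gc_r <- nn_backward(gan$clf, fwc_r$cache, (P_r - T_r) / bs)$grads
      gc_f <- nn_backward(gan$clf, fwc_f$cache, (P_f - T_f) / bs)$grads
      gc <- lapply(seq_along(gc_r), function(l)
        list(W = gc_r[[l]]$W + gc_f[[l]]$W,
             b = gc_r[[l]]$b + gc_f[[l]]$b))
      up <- adam_step(gan$clf, gc, opt$clf, lr = cfg$lr_d,
                      beta1 = b1, beta2 = b2)
      gan$clf <- up$net; opt$clf <- up$state
    }

    ## --- generator update ----------------------------------------------
    idx <- sample.int(n, bs)
    rb <- R[idx, , drop = FALSE]
    yb <- labs[idx, , drop = FALSE]
    cb <- cls[idx]
    Z <- matrix(stats::rnorm(bs * cfg$z_dim), bs, cfg$z_dim)
    gfw <- gen_forward_batch(gan, Z, rb, yb, cache = TRUE)
    xf <- gfw$X

    ## dLoss/dx from the critic: -(1/bs) * grad_x D
    cgp <- critic_grad_pass(gan$critic, cbind(xf, rb, yb))
    dx <- -cgp$g[, seq_len(LA), drop = FALSE] / bs
    ## dLoss/dx from the classifier term: beta/bs * (e_fake_c - e_real_c)
    if (cfg$beta > 0) {
      fwc <- nn_forward(gan$clf, xf, cache = TRUE)
      dlogits <- matrix(0, bs, 2L * C)
      dlogits[cbind(seq_len(bs), C + cb)] <- cfg$beta / bs
      dlogits[cbind(seq_len(bs), cb)] <- -cfg$beta / bs
      ## through log-softmax: dZ = dlp - rowSums(dlp) * softmax
      Pc <- row_softmax(fwc$out)
      dZc <- dlogits - rowSums(dlogits) * Pc
      dx <- dx + nn_backward(gan$clf, fwc$cache, dZc)$dX
    }
    dP <- to_pos_rows(dx, A)
    dlog <- softmax_rows_backward(gfw$P, dP)
    dgen_out <- from_pos_rows(dlog, bs)
    gg <- nn_backward(gan$gen, gfw$cache, dgen_out)$grads
    up <- adam_step(gan$gen, gg, opt$gen, lr = cfg$lr_g,
                    beta1 = b1, beta2 = b2)
    gan$gen <- up$net; opt$gen <- up$state

    ## --- log (seeded independently of the training stream) --------------
    if (s %% cfg$log_every == 0L || s == steps) {
      ls <- gan_losses(gan, list(x_real = Xreal[idx, , drop = FALSE],
                                 r = rb, y = yb, cls = cb, x_fake = xf),
                       seed = (cfg$seed + step0 + s) %% .Machine$integer.max)
      if (!all(is.finite(c(ls$loss_G, ls$loss_D, ls$loss_C))))
        stop("GAN training produced a non-finite loss at step ", step0 + s,
             " (G=", ls$loss_G, " D=", ls$loss_D, " C=", ls$loss_C, ")")
      new_log[s, ] <- c(step0 + s, ls$loss_G, ls$loss_D, ls$loss_C,
                        ls$wasserstein_gap)
    }
  }
  new_log <- new_log[new_log[, 1] > 0, , drop = FALSE]
  gan$log <- rbind(gan$log,
                   stats::setNames(as.data.frame(new_log), names(gan$log)))
  gan$opt <- opt
  gan$rng_state <- get(".Random.seed", envir = globalenv())
  gan$trained <- TRUE
  gan
}

#' Generate sequences by two-stage sampling
#'
#' For each draw: sample a latent representation from the diffusion model
#' given the label, then decode `argmax(G(z, r, y))` to residues. Records
#' carry the label and seed in their header tags when written to FASTA.
#'
#' @param gan trained `rg_gan`.
#' @param diffusion trained `rg_diffusion` (or `NULL` for a label-only
#'   GAN).
#' @param y length-d label vector.
#' @param n number of sequences.
#' @param seed integer seed; same seed and y give identical output.
#' @param prefix record-ID prefix.
#' @return List of `rg_record`s with labels set to `y`.
#' @export
generate_sequences <- function(gan, diffusion, y, n, seed = NULL,
                               prefix = "gen") {
  if (!isTRUE(gan$trained)) stop("generator is untrained; train_cwgan first")
  if (gan$m > 0 && is.null(diffusion))
    stop("this GAN conditions on r: a trained diffusion model is required")
  with_seed(seed, {
    R <- if (gan$m > 0) sample_representation(diffusion, y, n)
    else matrix(0, n, 0)
    Z <- matrix(stats::rnorm(n * gan$cfg$z_dim), n, gan$cfg$z_dim)
    Y <- matrix(y, n, gan$d, byrow = TRUE)
    X <- gen_forward_batch(gan, Z, R, Y)$X
    lapply(seq_len(n), function(i) {
      M <- matrix(X[i, ], gan$spec$max_length, gan$spec$A, byrow = TRUE)
      rec <- one_hot_decode(M, gan$spec, id = sprintf("%s_%03d", prefix, i))
      rec$label <- y
      rec
    })
  })
}

#' Save / load a GAN checkpoint
#'
#' The bundle is self-contained (parameters, optimiser state, RNG state,
#' config, log), so training resumed from a checkpoint reproduces the next
#' step's losses bit-identically.
#'
#' @param gan an `rg_gan`.
#' @param path file path.
#' @return `path` / the restored bundle.
#' @export
save_gan <- function(gan, path) { saveRDS(gan, path); invisible(path) }

#' @rdname save_gan
#' @export
load_gan <- function(path) readRDS(path)
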