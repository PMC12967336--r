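tiny_gan <- function(seed = 1, C = 2, mask_pad = FALSE, beta = 175) {
  spec <- encoding_spec(6)
  cfg <- gan_config(z_dim = 4, g_hidden = c(16, 16), d_hidden = c(16, 16),
                    c_hidden = c(16, 16), beta = beta, mask_pad = mask_pad,
                    seed = seed)
  init_gan(cfg, spec, m = 3, d = 2, C = C)
}

test_that("generator output rows are probabilities and seed-deterministic", {
  gan <- tiny_gan()
  set.seed(4)
  z <- rnorm(4); r <- rnorm(3); y <- c(1, 0)
  P <- generator_forward(gan, z, r, y)
  expect_equal(dim(P), c(6, 21))
  expect_equal(unname(rowSums(P)), rep(1, 6), tolerance = 1e-6)
  expect_true(all(P >= 0))
  expect_identical(P, generator_forward(gan, z, r, y))
  expect_error(generator_forward(gan, z, rnorm(5), y), "length 5")
})

test_that("critic and classifier forwards are finite and shape-checked", {
  gan <- tiny_gan()
  set.seed(5)
  x <- matrix(runif(6 * 21), 6, 21)
  x <- x / rowSums(x)
  s <- critic_forward(gan, x, rnorm(3), c(0, 1))
  expect_length(s, 1L)
  expect_true(is.finite(s))
  expect_error(critic_forward(gan, matrix(1, 2, 5), rnorm(3), c(0, 1)),
               "expected L\\*A")
  lp <- adc_classifier_forward(gan, x)
  expect_length(lp, 4L)               # 2C log-probabilities
  expect_equal(sum(exp(lp)), 1, tolerance = 1e-6)
})

test_that("pad masking makes scores invariant to pad-region content", {
  gan <- tiny_gan(mask_pad = TRUE)
  spec <- gan$spec
  rec <- sequence_record("s", "MKW")   # true length 3 of L = 6
  x1 <- unclass(one_hot_encode(rec, spec))
  x2 <- x1
  x2[4:6, ] <- matrix(runif(3 * 21), 3)  # garbage beyond true length
  r <- rnorm(3); y <- c(1, 0)
  expect_equal(critic_forward(gan, x1, r, y, true_length = 3),
               critic_forward(gan, x2, r, y, true_length = 3))
  expect_equal(adc_classifier_forward(gan, x1, true_length = 3),
               adc_classifier_forward(gan, x2, true_length = 3))
  ## without masking the scores differ
  gan0 <- tiny_gan(mask_pad = FALSE)
  expect_false(isTRUE(all.equal(critic_forward(gan0, x1, r, y),
                                critic_forward(gan0, x2, r, y))))
})

test_that("gradient penalty attains its closed forms exactly", {
  gan <- tiny_gan()
  LA <- 6 * 21
  lin <- function(w_first) {
    net <- list(layers = list(list(W = matrix(0, LA + 3 + 2, 1), b = 0)),
                sizes = c(LA + 3 + 2, 1L))
    net$layers[[1]]$W[1, 1] <- w_first
    structure(net, class = "rg_mlp")
  }
  set.seed(6)
  real <- matrix(runif(8 * LA), 8)
  fake <- matrix(runif(8 * LA), 8)
  r <- matrix(rnorm(8 * 3), 8); y <- matrix(rnorm(8 * 2), 8)
  ## critic(x) = x1 has unit input gradient everywhere -> penalty 0
  g1 <- gan; g1$critic <- lin(1)
  expect_equal(gradient_penalty(g1, real, fake, r, y, lambda = 10, seed = 2),
               0)
  ## critic(x) = 2 x1 -> penalty = lambda (2 - 1)^2 = lambda
  g2 <- gan; g2$critic <- lin(2)
  expect_equal(gradient_penalty(g2, real, fake, r, y, lambda = 10, seed = 2),
               10)
  expect_equal(gradient_penalty(g2, real, fake, r, y, lambda = 3, seed = 2),
               3)
  ## nonnegative for the real MLP critic
  expect_gte(gradient_penalty(gan, real, fake, r, y, seed = 2), 0)
})

test_that("penalty parameter gradients match finite differences", {
  gan <- tiny_gan(seed = 3)
  LA <- 6 * 21
  set.seed(7)
  real <- matrix(runif(5 * LA), 5); fake <- matrix(runif(5 * LA), 5)
  r <- matrix(rnorm(15), 5); y <- matrix(rnorm(10), 5)
  pen <- function(g) as.numeric(
    gradient_penalty(g, real, fake, r, y, lambda = 10, seed = 11))
  gp <- gradient_penalty(gan, real, fake, r, y, lambda = 10, seed = 11,
                         want_grads = TRUE)
  grads <- attr(gp, "grads")
  set.seed(8)
  for (trial in 1:6) {
    l <- sample(length(gan$critic$layers), 1)
    i <- sample(nrow(gan$critic$layers[[l]]$W), 1)
    j <- sample(ncol(gan$critic$layers[[l]]$W), 1)
    eps <- 1e-6
    gp_ <- gan; gp_$critic$layers[[l]]$W[i, j] <-
      gp_$critic$layers[[l]]$W[i, j] + eps
    gm_ <- gan; gm_$critic$layers[[l]]$W[i, j] <-
      gm_$critic$layers[[l]]$W[i, j] - eps
    fd <- (pen(gp_) - pen(gm_)) / (2 * eps)
    expect_equal(grads[[l]]$W[i, j], fd, tolerance = 1e-4)
  }
})

test_that("gan losses decompose as documented", {
  gan <- tiny_gan(C = 2, beta = 175)
  LA <- 6 * 21
  set.seed(9)
  n <- 6
  batch <- list(x_real = matrix(runif(n * LA), n),
                r = matrix(rnorm(n * 3), n),
                y = cbind(rep(1, n), 0),
                cls = rep(1:2, 3))
  ls <- gan_losses(gan, batch, seed = 21)
  expect_true(all(is.finite(unlist(ls))))
  ## beta = 0 collapses loss_G to the pure Wasserstein generator loss
  gan0 <- gan; gan0$cfg$beta <- 0
  ls0 <- gan_losses(gan0, batch, seed = 21)
  expect_equal(ls0$loss_G,
               ls0$loss_G - gan0$cfg$beta * ls0$classifier_term)
  ## the critic loss decomposes into gap + penalty on the logged components
  expect_equal(ls$loss_D, ls$wasserstein_gap + ls$gradient_penalty)

  ## an oracle classifier certain of (real, c) makes the generator's
  ## classifier term log p(fake,c) - log p(real,c) strongly negative
  oracle <- function(x) {
    n <- nrow(rbind(x))
    lp <- matrix(log(1e-12), n, 4)
    lp[, 1] <- log(1 - 3e-12)
    lp
  }
  batch1 <- batch; batch1$cls <- rep(1L, n)
  lso <- gan_losses(gan, batch1, classifier = oracle, seed = 21)
  expect_lt(lso$classifier_term, 0)
})

test_that("beta above the documented threshold warns", {
  expect_warning(gan_config(beta = 301), "exceeds 300")
  expect_silent(gan_config(beta = 175))
})

test_that("short training run is stable, logged, and resumable", {
  recs <- motif_records(n = 15, seed = 44)
  spec <- spec40()
  emb <- trained_embedder()
  cfg <- gan_config(z_dim = 8, g_hidden = c(32, 32), d_hidden = c(32, 32),
                    c_hidden = c(32, 32), batch_size = 16, n_critic = 2,
                    steps = 12, log_every = 1, seed = 5)
  gan <- train_cwgan(recs, emb, cfg, spec)
  expect_true(gan$trained)
  expect_equal(nrow(gan$log), 12L)
  expect_true(all(is.finite(as.matrix(gan$log))))

  ## resume-from-checkpoint reproduces the continued run bit-identically
  gan8 <- train_cwgan(recs, emb, cfg, spec, steps = 8)
  f <- withr::local_tempfile(fileext = ".rds")
  save_gan(gan8, f)
  resumed <- train_cwgan(recs, emb, cfg, spec, resume = load_gan(f),
                         steps = 4)
  expect_equal(resumed$log$loss_G, gan$log$loss_G, tolerance = 1e-12)
  expect_equal(resumed$log$loss_D, gan$log$loss_D, tolerance = 1e-12)

  ## a declared class with no training records is refused by name
  only_two <- Filter(function(r) r$label[3] != 1, recs)
  expect_error(train_cwgan(only_two, emb, cfg, spec,
                           patterns = diag(3)), "empty class.*001")
})

test_that("generation requires trained stages and is seed-deterministic", {
  gan <- tiny_gan()
  expect_error(generate_sequences(gan, NULL, c(1, 0), 3), "untrained")
})
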