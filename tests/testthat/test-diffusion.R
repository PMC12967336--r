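test_that("cosine time embedding is bounded, injective, and smooth", {
  e1 <- cosine_time_embedding(1, 32)
  e2 <- cosine_time_embedding(2, 32)
  expect_length(e1, 32)
  expect_true(all(abs(c(e1, e2)) <= 1))
  expect_gt(sum(abs(e1 - e2)), 0)
  expect_error(cosine_time_embedding(0, 32), ">= 1")
  expect_error(cosine_time_embedding(1, 31))
  ## at a fixed low-frequency band, cosine similarity decays with |t - t'|
  band <- 25:32   # slowest frequencies of a 32-dim embedding
  base <- cosine_time_embedding(100, 32)[band]
  sims <- vapply(c(101, 110, 140, 200), function(t2) {
    v <- cosine_time_embedding(t2, 32)[band]
    sum(base * v) / sqrt(sum(base^2) * sum(v^2))
  }, numeric(1))
  expect_true(all(diff(sims) < 0))
})

test_that("the cosine schedule has the documented shape", {
  sch <- build_schedule(10)
  expect_length(sch$alpha_bar, 11)
  expect_equal(sch$alpha_bar[1], 1.0)
  expect_true(all(diff(sch$alpha_bar) < 0))
  expect_true(all(sch$alpha_bar > 0 & sch$alpha_bar <= 1))
  ## doubling T refines but preserves endpoint behaviour
  for (T_ in c(10, 20, 200)) {
    expect_lt(build_schedule(T_)$alpha_bar[T_ + 1], 0.01)
  }
  expect_error(build_schedule(10, name = "linear"), "unknown")
  expect_error(build_schedule(1), "T_steps")
})

test_that("forward diffusion is exact in the zero-noise limit and seeded", {
  sch <- build_schedule(50)
  ## custom schedule with an exact-1 entry exercises the identity limit
  sch1 <- sch; sch1$alpha_bar[2] <- 1.0
  r0 <- matrix(rnorm(20), 4, 5)
  fd <- forward_diffuse(r0, 1, sch1, seed = 3)
  expect_identical(fd$r_t, r0)
  a <- forward_diffuse(r0, 25, sch, seed = 11)
  b <- forward_diffuse(r0, 25, sch, seed = 11)
  expect_identical(a$r_t, b$r_t)
  expect_error(forward_diffuse(r0, 51, sch), "out of range")
})

test_that("forward marginals match their moments at several timesteps", {
  sch <- build_schedule(200)
  r0 <- matrix(2, 1, 1)
  n <- 10000
  for (t in c(5, 50, 100, 150, 199)) {
    ab <- sch$alpha_bar[t + 1]
    draws <- forward_diffuse(matrix(r0, n, 1), t, sch, seed = t)$r_t
    resid <- draws - sqrt(ab) * 2
    v <- var(as.vector(resid))
    ## sample variance of n draws has sd ~ sqrt(2/n) * true variance
    expect_lt(abs(v - (1 - ab)), 5 * sqrt(2 / n) * (1 - ab) + 1e-8)
    expect_lt(abs(mean(resid)), 5 * sqrt((1 - ab) / n))
  }
})

test_that("diffusion loss has its closed forms and drop-rate contract", {
  sch <- build_schedule(100)
  set.seed(8)
  r <- matrix(rnorm(40 * 3), 40, 3)
  y <- diag(4)[sample(4, 40, TRUE), ]
  ## oracle denoiser returning the true r attains loss 0
  oracle <- local({
    r_true <- r
    i <- 0
    function(r_t, t, y) { i <<- i + 1; r_true[i, ] }
  })
  expect_equal(as.numeric(diffusion_loss(oracle, r, y, sch, seed = 1)), 0)
  ## denoiser returning zero scores mean ||r||^2
  zero_fn <- function(r_t, t, y) numeric(3)
  expect_equal(as.numeric(diffusion_loss(zero_fn, r, y, sch, seed = 1)),
               mean(r^2))
  ## condition-dropout frequency: binomial around 10%
  g <- guidance_config(drop_probability = 0.1)
  n_tot <- 0L; n_drop <- 0L
  for (i in 1:100) {
    l <- diffusion_loss(zero_fn, r, y, sch, guidance = g, seed = 1000 + i)
    n_drop <- n_drop + attr(l, "n_dropped")
    n_tot <- n_tot + nrow(r)
  }
  p_hat <- n_drop / n_tot
  expect_lt(abs(p_hat - 0.1), 3 * sqrt(0.1 * 0.9 / n_tot))
  expect_error(diffusion_loss(zero_fn, r[0, , drop = FALSE],
                              y[0, , drop = FALSE], sch), "empty")
})

test_that("training on the Gaussian-mixture fixture learns the conditional", {
  dm <- trained_diffusion()
  ld <- latent_fixture()
  ## final training loss sits well below the prior predictor's floor
  ## (predicting the global mean scores ~ the marginal variance)
  expect_lt(mean(utils::tail(dm$loss_trace, 200)),
            0.5 * mean(utils::head(dm$loss_trace, 10)))
  ## class-conditional parameter recovery, conditional-only sampling
  mu <- latent_means()
  for (c in 1:4) {
    y <- numeric(4); y[c] <- 1
    s <- sample_representation(dm, y, n = 500, guidance_weight = 0,
                               seed = 100 + c)
    expect_lt(max(abs(colMeans(s) - mu[c, ])), 0.1)
  }
})

test_that("sampling is seed-deterministic and guidance paths are finite", {
  dm <- trained_diffusion()
  y <- c(0, 1, 0, 0)
  a <- sample_representation(dm, y, n = 5, seed = 77)
  b <- sample_representation(dm, y, n = 5, seed = 77)
  expect_identical(a, b)
  expect_false(identical(a, sample_representation(dm, y, n = 5, seed = 78)))
  ## the null-condition path (trained via 10% dropout) samples finitely
  u <- sample_representation(dm, y, n = 5, guidance_weight = 5, seed = 9)
  expect_true(all(is.finite(u)))
})
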