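## Minimal dense-network toolkit: vectorized forward/backward passes and an
## Adam optimiser. All model code in this package (embedder, diffusion
## denoiser, GAN generator/critic/classifier) is built from these pieces so
## that input gradients (needed analytically by the WGAN gradient penalty)
## are exact, not numerical.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the RNG to `seed`, evaluates `expr`, and restores the previous RNG
#' state, so seeded internals never disturb the caller's random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

#' Construct a fully connected network
#'
#' He-normal initialisation; hidden layers use ReLU, the output layer is
#' linear (losses apply softmax / sigmoid themselves where needed).
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param seed optional integer seed for reproducible initialisation.
#' @return An object of class `rg_mlp`: a list of layers, each `list(W, b)`.
#' @keywords internal
nn_mlp <- function(sizes, seed = NULL) {
  stopifnot(length(sizes) >= 2, all(sizes >= 1))
  with_seed(seed, {
    layers <- vector("list", length(sizes) - 1L)
    for (l in seq_along(layers)) {
      fan_in <- sizes[l]
      layers[[l]] <- list(
        W = matrix(stats::rnorm(fan_in * sizes[l + 1], sd = sqrt(2 / fan_in)),
                   fan_in, sizes[l + 1]),
        b = numeric(sizes[l + 1])
      )
    }
    structure(list(layers = layers, sizes = sizes), class = "rg_mlp")
  })
}

#' Forward pass through an `rg_mlp`
#'
#' @param net an `rg_mlp`.
#' @param X numeric matrix, one row per example.
#' @param cache keep intermediate activations for a later backward pass?
#' @return `list(out, cache)`; `out` is an n-by-output matrix.
#' @keywords internal
nn_forward <- function(net, X, cache = FALSE) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == net$sizes[1])
  L <- length(net$layers)
  acts <- if (cache) vector("list", L + 1L) else NULL
  A <- X
  if (cache) acts[[1L]] <- A
  for (l in seq_len(L)) {
    Z <- A %*% net$layers[[l]]$W
    Z <- sweep(Z, 2L, net$layers[[l]]$b, "+")
    A <- if (l < L) pmax(Z, 0) else Z
    if (cache) acts[[l + 1L]] <- A
  }
  list(out = A, cache = acts)
}

#' Backward pass through an `rg_mlp`
#'
#' @param net an `rg_mlp`.
#' @param cache activation list from `nn_forward(..., cache = TRUE)`.
#' @param dout gradient of the loss w.r.t. the network output.
#' @return `list(grads, dX)`: parameter gradients (same shape as layers) and
#'   the gradient w.r.t. the input matrix.
#' @keywords internal
nn_backward <- function(net, cache, dout) {
  L <- length(net$layers)
  grads <- vector("list", L)
  dA <- as.matrix(dout)
  for (l in rev(seq_len(L))) {
    A_in <- cache[[l]]
    A_out <- cache[[l + 1L]]
    dZ <- if (l < L) dA * (A_out > 0) else dA
    grads[[l]] <- list(W = crossprod(A_in, dZ), b = colSums(dZ))
    dA <- tcrossprod(dZ, net$layers[[l]]$W)
  }
  list(grads = grads, dX = dA)
}

## --- Adam ---------------------------------------------------------------

#' @keywords internal
adam_init <- function(net) {
  zeros <- lapply(net$layers, function(ly)
    list(W = ly$W * 0, b = ly$b * 0))
  list(m = zeros, v = zeros, t = 0L)
}

#' One Adam update over all layers of an `rg_mlp`
#'
#' @param net,grads network and matching gradient structure.
#' @param state optimiser state from [adam_init()].
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @return `list(net, state)` with updated parameters and moments.
#' @keywords internal
adam_step <- function(net, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (l in seq_along(net$layers)) {
    for (p in c("W", "b")) {
      g <- grads[[l]][[p]]
      state$m[[l]][[p]] <- beta1 * state$m[[l]][[p]] + (1 - beta1) * g
      state$v[[l]][[p]] <- beta2 * state$v[[l]][[p]] + (1 - beta2) * g^2
      mhat <- state$m[[l]][[p]] / bc1
      vhat <- state$v[[l]][[p]] / bc2
      net$layers[[l]][[p]] <- net$layers[[l]][[p]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(net = net, state = state)
}

## Generic Adam over an arbitrary named list of numeric arrays (used for
## parameters living outside an rg_mlp, e.g. condition-embedding maps).
#' @keywords internal
adam_init_list <- function(params) {
  zeros <- lapply(params, function(p) p * 0)
  list(m = zeros, v = zeros, t = 0L)
}

#' @keywords internal
adam_step_list <- function(params, grads, state, lr = 1e-3,
                           beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## Numerically stable row-wise softmax / log-softmax.
#' @keywords internal
row_softmax <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  E <- exp(Z - mx)
  E / rowSums(E)
}

#' @keywords internal
row_log_softmax <- function(Z) {
  mx <- Z[cbind(seq_len(nrow(Z)), max.col(Z, ties.method = "first"))]
  Z <- Z - mx
  Z - log(rowSums(exp(Z)))
}
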