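## Module 1: supervised representation learning. A compact 1-D
## convolutional encoder over the one-hot matrix (the trainable desk-scale
## backbone) feeds a residual block and a fully connected classifier head
## trained with cross entropy on the GO labels. The latent representation
## R(X) is read from the residual block's post-activation output (dimension
## m), before the classifier head. An adapter accepts externally computed
## protein-language-model embeddings instead, in which case no training
## happens here and unannotated records are embeddable too.

#' Configure the embedder
#'
#' @param mode `"standin"` (train the small conv encoder) or `"external"`
#'   (use a supplied embedding table).
#' @param m latent dimension; defaults to 64 in stand-in mode. External
#'   mode takes m from the table (480 for a typical protein-language-model
#'   layer).
#' @param conv_filters,conv_width backbone 1-D convolution layout.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param freeze_backbone keep the convolutional backbone fixed during
#'   training (the analogue of freezing a pretrained trunk)?
#' @param seed integer seed for initialisation and batching.
#' @return An `rg_embedder_config` list.
#' @export
embedder_config <- function(mode = c("standin", "external"), m = 64L,
                            conv_filters = 48L, conv_width = 5L,
                            epochs = 30L, batch_size = 32L, lr = 1e-3,
                            freeze_backbone = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(m > 0, conv_filters > 0, conv_width >= 1, epochs >= 1, lr > 0)
  structure(list(mode = mode, m = as.integer(m),
                 conv_filters = as.integer(conv_filters),
                 conv_width = as.integer(conv_width),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 freeze_backbone = isTRUE(freeze_backbone),
                 seed = as.integer(seed)),
            class = "rg_embedder_config")
}

## im2col: one sequence's one-hot matrix -> (L-w+1) x (w*A) window matrix.
#' @keywords internal
im2col_onehot <- function(X, w) {
  L <- nrow(X); A <- ncol(X)
  npos <- L - w + 1L
  out <- matrix(0, npos, w * A)
  for (k in seq_len(w))
    out[, ((k - 1L) * A + 1L):(k * A)] <- X[k:(k + npos - 1L), , drop = FALSE]
  out
}

#' @keywords internal
embedder_params_init <- function(cfg, spec, d, seed) {
  with_seed(seed, {
    fin_c <- cfg$conv_width * spec$A
    f <- cfg$conv_filters; m <- cfg$m
    list(
      Wc = matrix(stats::rnorm(fin_c * f, sd = sqrt(2 / fin_c)), fin_c, f),
      bc = numeric(f),
      Wp = matrix(stats::rnorm(f * m, sd = sqrt(2 / f)), f, m),
      bp = numeric(m),
      W1 = matrix(stats::rnorm(m * m, sd = sqrt(2 / m)), m, m),
      b1 = numeric(m),
      W2 = matrix(stats::rnorm(m * m, sd = sqrt(2 / m)), m, m),
      b2 = numeric(m),
      Wh = matrix(stats::rnorm(m * d, sd = sqrt(2 / m)), m, d),
      bh = numeric(d)
    )
  })
}

## Forward through backbone + residual block (+ optionally head).
## Xcol: stacked im2col rows; grp: sequence index per row; npos: rows/seq.
#' @keywords internal
embedder_forward <- function(par, Xcol, grp, npos, head = TRUE,
                             cache = FALSE) {
  Hpre <- sweep(Xcol %*% par$Wc, 2L, par$bc, "+")
  H <- pmax(Hpre, 0)
  P <- rowsum(H, grp, reorder = TRUE) / npos        # mean pool per sequence
  Z0 <- sweep(P %*% par$Wp, 2L, par$bp, "+")
  A0 <- pmax(Z0, 0)
  Z1 <- sweep(A0 %*% par$W1, 2L, par$b1, "+")
  A1 <- pmax(Z1, 0)
  Z2 <- sweep(A1 %*% par$W2, 2L, par$b2, "+")
  R <- pmax(A0 + Z2, 0)                             # the representation
  logits <- if (head) sweep(R %*% par$Wh, 2L, par$bh, "+") else NULL
  out <- list(R = R, logits = logits)
  if (cache) out$cache <- list(Xcol = Xcol, grp = grp, H = H, P = P,
                               A0 = A0, A1 = A1, Z2 = Z2)
  out
}

#' @keywords internal
embedder_backward <- function(par, fw, dlogits, npos, freeze_backbone) {
  cc <- fw$cache
  R <- fw$R
  g <- list()
  g$Wh <- crossprod(R, dlogits); g$bh <- colSums(dlogits)
  dR <- tcrossprod(dlogits, par$Wh)
  dRes <- dR * (R > 0)                 # through final ReLU of A0 + Z2
  dZ2 <- dRes
  g$W2 <- crossprod(cc$A1, dZ2); g$b2 <- colSums(dZ2)
  dA1 <- tcrossprod(dZ2, par$W2)
  dZ1 <- dA1 * (cc$A1 > 0)
  g$W1 <- crossprod(cc$A0, dZ1); g$b1 <- colSums(dZ1)
  dA0 <- tcrossprod(dZ1, par$W1) + dRes     # skip connection
  dZ0 <- dA0 * (cc$A0 > 0)
  g$Wp <- crossprod(cc$P, dZ0); g$bp <- colSums(dZ0)
  if (freeze_backbone) {
    g$Wc <- par$Wc * 0; g$bc <- par$bc * 0
  } else {
    dP <- tcrossprod(dZ0, par$Wp)
    dH <- dP[cc$grp, , drop = FALSE] / npos
    dHpre <- dH * (cc$H > 0)
    g$Wc <- crossprod(cc$Xcol, dHpre); g$bc <- colSums(dHpre)
  }
  g
}

#' Train the stand-in embedder on labelled records
#'
#' Minimises cross entropy on the classification task: softmax cross
#' entropy when every record carries exactly one label, element-wise binary
#' cross entropy summed over the d label terms otherwise (GO annotations
#' are multi-label in general). Requires at least two distinct label
#' patterns. Training is mini-batch Adam; the loss trace is kept so callers
#' can verify improvement.
#'
#' @param records labelled `rg_record` list (every record annotated).
#' @param cfg an [embedder_config()] with `mode = "standin"`.
#' @param spec an [encoding_spec()].
#' @return An `rg_embedder` with fields `params`, `cfg`, `spec`, `d`,
#'   `loss_trace` (per-epoch mean CE, element 1 = untrained loss).
#' @export
train_embedder <- function(records, cfg, spec) {
  stopifnot(inherits(cfg, "rg_embedder_config"), cfg$mode == "standin")
  labs <- lapply(records, `[[`, "label")
  if (any(vapply(labs, is.null, logical(1))))
    stop("all records must be annotated for embedder training")
  Y <- do.call(rbind, labs)
  if (nrow(unique(Y)) < 2L)
    stop("embedder training needs >= 2 distinct label patterns; got 1")
  exclusive <- all(rowSums(Y) == 1)
  d <- ncol(Y)
  n <- length(records)
  w <- cfg$conv_width
  npos <- spec$max_length - w + 1L

  cols <- lapply(records, function(r)
    im2col_onehot(unclass(one_hot_encode(r, spec)), w))
  Xcol_all <- do.call(rbind, cols)
  grp_all <- rep(seq_len(n), each = npos)

  par <- embedder_params_init(cfg, spec, d, cfg$seed)
  opt <- adam_init_list(par)
  loss_of <- function(logits, Yb) {
    if (exclusive) {
      lp <- row_log_softmax(logits)
      -mean(lp[cbind(seq_len(nrow(Yb)), max.col(Yb))])
    } else {
      p <- 1 / (1 + exp(-logits))
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      mean(rowSums(-Yb * log(p) - (1 - Yb) * log(1 - p)))
    }
  }
  grad_of <- function(logits, Yb) {
    nb <- nrow(Yb)
    if (exclusive) (row_softmax(logits) - Yb) / nb
    else (1 / (1 + exp(-logits)) - Yb) / nb
  }

  trace <- numeric(cfg$epochs + 1L)
  fw0 <- embedder_forward(par, Xcol_all, grp_all, npos)
  trace[1L] <- loss_of(fw0$logits, Y)

  with_seed(cfg$seed + 1L, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
      for (idx in batches) {
        rows <- which(grp_all %in% idx)
        Xb <- Xcol_all[rows, , drop = FALSE]
        grp_b <- match(grp_all[rows], sort(idx))
        Yb <- Y[sort(idx), , drop = FALSE]
        fw <- embedder_forward(par, Xb, grp_b, npos, cache = TRUE)
        dlogits <- grad_of(fw$logits, Yb)
        g <- embedder_backward(par, fw, dlogits, npos, cfg$freeze_backbone)
        st <- adam_step_list(par, g, opt, lr = cfg$lr)
        par <- st$params; opt <- st$state
      }
      fw <- embedder_forward(par, Xcol_all, grp_all, npos)
      trace[ep + 1L] <- loss_of(fw$logits, Y)
      if (!is.finite(trace[ep + 1L]))
        stop("embedder training diverged: loss is not finite at epoch ", ep,
             " (last finite loss ", signif(trace[ep], 4), ")")
    }
  })
  structure(list(mode = "standin", params = par, cfg = cfg, spec = spec,
                 d = d, exclusive = exclusive, loss_trace = trace),
            class = "rg_embedder")
}

#' Wrap an external embedding table as an embedder
#'
#' For workflows where per-sequence embeddings come from a separately run
#' protein language model. Works for unannotated records (semi-supervised
#' use): lookup is by record ID only.
#'
#' @param embeddings named list or matrix from
#'   [load_external_embeddings()].
#' @return An `rg_embedder` with `mode = "external"`.
#' @export
external_embedder <- function(embeddings) {
  if (is.matrix(embeddings))
    embeddings <- stats::setNames(
      lapply(seq_len(nrow(embeddings)), function(i) embeddings[i, ]),
      rownames(embeddings))
  m <- unique(lengths(embeddings))
  stopifnot(length(m) == 1L)
  structure(list(mode = "external", table = embeddings, m = as.integer(m)),
            class = "rg_embedder")
}

#' Extract the latent representation of a record
#'
#' Deterministic given (embedder, record). In stand-in mode this is the
#' residual block's post-activation output; in external mode, the table row
#' for the record's ID.
#'
#' @param embedder an `rg_embedder`.
#' @param record an `rg_record` (or a list of them).
#' @return Numeric vector of length m (or an n-by-m matrix for a list).
#' @export
extract_representation <- function(embedder, record) {
  stopifnot(inherits(embedder, "rg_embedder"))
  recs <- if (inherits(record, "rg_record")) list(record) else record
  if (embedder$mode == "external") {
    ids <- vapply(recs, `[[`, character(1), "id")
    miss <- setdiff(ids, names(embedder$table))
    if (length(miss))
      stop("no external embedding for ID(s): ", paste(miss, collapse = ", "))
    R <- do.call(rbind, embedder$table[ids])
  } else {
    spec <- embedder$spec
    w <- embedder$cfg$conv_width
    npos <- spec$max_length - w + 1L
    for (r in recs) if (nchar(r$residues) > spec$max_length)
      stop("record '", r$id, "' is longer than the embedder's max_length ",
           spec$max_length)
    cols <- lapply(recs, function(r)
      im2col_onehot(unclass(one_hot_encode(r, spec)), w))
    Xcol <- do.call(rbind, cols)
    grp <- rep(seq_along(recs), each = npos)
    R <- embedder_forward(embedder$params, Xcol, grp, npos, head = FALSE)$R
  }
  if (inherits(record, "rg_record")) drop(R) else R
}

#' Predict labels with a trained stand-in embedder
#'
#' @param object trained `rg_embedder` (stand-in mode).
#' @param records list of `rg_record`s.
#' @param ... unused.
#' @return Matrix of predicted 0/1 labels (argmax for exclusive labels,
#'   0.5-thresholded sigmoids otherwise).
#' @export
predict.rg_embedder <- function(object, records, ...) {
  stopifnot(object$mode == "standin")
  spec <- object$spec
  w <- object$cfg$conv_width
  npos <- spec$max_length - w + 1L
  cols <- lapply(records, function(r)
    im2col_onehot(unclass(one_hot_encode(r, spec)), w))
  Xcol <- do.call(rbind, cols)
  grp <- rep(seq_along(records), each = npos)
  logits <- embedder_forward(object$params, Xcol, grp, npos)$logits
  if (object$exclusive) {
    P <- matrix(0, nrow(logits), ncol(logits))
    P[cbind(seq_len(nrow(P)), max.col(logits, ties.method = "first"))] <- 1
    P
  } else (logits > 0) + 0
}

## --- external embedding files -------------------------------------------

#' Load externally computed embeddings
#'
#' Expects a TSV whose first column is the sequence ID and whose remaining
#' columns are the embedding coordinates (consistent width).
#'
#' @param path TSV file.
#' @param ids IDs that must all be present.
#' @return Named list id -> numeric vector (consistent length m).
#' @export
load_external_embeddings <- function(path, ids = NULL) {
  if (!file.exists(path)) stop("embedding file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(parts)
  if (length(unique(widths)) != 1L)
    stop("ragged embedding file: rows have ",
         paste(sort(unique(widths)), collapse = "/"), " fields")
  tab <- lapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p[-1]))
    if (anyNA(v)) stop("non-numeric embedding value in row starting '",
                       p[1], "'")
    v
  })
  names(tab) <- vapply(parts, `[`, character(1), 1L)
  if (!is.null(ids)) {
    miss <- setdiff(ids, names(tab))
    if (length(miss))
      stop("embedding file is missing ID(s): ", paste(miss, collapse = ", "))
    tab <- tab[ids]
  }
  tab
}

#' Write embeddings in the format read by [load_external_embeddings()]
#'
#' Full precision (`%.17g`), so a write/read round trip is exact.
#'
#' @param embeddings named list id -> numeric vector.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  lines <- vapply(names(embeddings), function(id) {
    paste(c(id, sprintf("%.17g", embeddings[[id]])), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
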