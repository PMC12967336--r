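## Metric suite for (real, generated) sequence-set pairs: spectrum k-mer
## features embedded in a Gaussian RKHS, maximum mean discrepancy (MMD),
## label-wise mean reciprocal rank (MRR), alignment column entropy and
## average entropy difference (AED), mean pairwise RKHS distance, and
## global / sliding-window percent identity.

#' Gaussian kernel specification
#'
#' @param sigma positive bandwidth, or `"median_heuristic"` to set it to
#'   the median pooled pairwise Euclidean distance at evaluation time.
#' @return `rg_kernel` list.
#' @export
kernel_spec <- function(sigma = "median_heuristic") {
  if (is.numeric(sigma)) stopifnot(sigma > 0)
  structure(list(family = "gaussian", sigma = sigma), class = "rg_kernel")
}

#' @keywords internal
resolve_sigma <- function(kernel, pooled) {
  if (is.numeric(kernel$sigma)) return(kernel$sigma)
  D <- as.matrix(stats::dist(pooled))
  s <- stats::median(D[upper.tri(D)])
  if (!is.finite(s) || s <= 0) 1 else s
}

#' @keywords internal
gauss_kernel <- function(X, Y, sigma) {
  D2 <- outer(rowSums(X^2), rowSums(Y^2), "+") - 2 * tcrossprod(X, Y)
  exp(-pmax(D2, 0) / (2 * sigma^2))
}

#' Normalised k-mer spectrum features
#'
#' Counts of overlapping k-mers over the 20-letter core alphabet,
#' L1-normalised per sequence. Pad/unknown symbols are stripped first. A
#' sequence shorter than k yields a zero row and a warning (flagged in the
#' `short` attribute).
#'
#' @param seqs character vector of residue strings (or `rg_record` list).
#' @param k k-mer length (spectrum order); default 3.
#' @return n-by-20^k matrix; attribute `short` marks too-short sequences.
#' @export
spectrum_features <- function(seqs, k = 3L) {
  stopifnot(k >= 1)
  if (is.list(seqs)) seqs <- vapply(seqs, `[[`, character(1), "residues")
  seqs <- gsub(sprintf("[^%s]", paste(AA20, collapse = "")), "",
               toupper(seqs))
  V <- 20L^k
  out <- matrix(0, length(seqs), V)
  short <- nchar(seqs) < k
  if (any(short))
    warning(sum(short), " sequence(s) shorter than k = ", k,
            " produce zero feature vectors")
  pow <- 20L^((k - 1L):0L)
  for (i in which(!short)) {
    codes <- match(strsplit(seqs[i], "", fixed = TRUE)[[1]], AA20) - 1L
    n_kmer <- length(codes) - k + 1L
    idx <- numeric(n_kmer)
    for (j in seq_len(k)) idx <- idx + codes[j:(j + n_kmer - 1L)] * pow[j]
    tab <- tabulate(idx + 1L, nbins = V)
    out[i, ] <- tab / n_kmer
  }
  structure(out, short = short)
}

#' @keywords internal
as_features <- function(x, k) {
  if (is.matrix(x)) x else spectrum_features(x, k)
}

#' Maximum mean discrepancy between two feature sets
#'
#' RKHS distance between the kernel mean embeddings of the two samples.
#' The default biased V-statistic is
#' `MMD^2 = mean(K_PP) + mean(K_QQ) - 2 mean(K_PQ)` (non-negative); the
#' square root is returned. The unbiased U-statistic (diagonal terms of
#' the within-set sums removed) is also available; its square can be
#' negative, in which case 0 is returned.
#'
#' @param feats_P,feats_Q feature matrices (rows = sequences), or character
#'   vectors of sequences (featurised with [spectrum_features()] at `k`).
#' @param kernel an [kernel_spec()].
#' @param k spectrum order used when raw sequences are passed.
#' @param unbiased use the unbiased estimator?
#' @return Non-negative scalar MMD.
#' @export
mmd <- function(feats_P, feats_Q, kernel = kernel_spec(), k = 3L,
                unbiased = FALSE) {
  P <- as_features(feats_P, k); Q <- as_features(feats_Q, k)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop("empty feature set")
  sigma <- resolve_sigma(kernel, rbind(P, Q))
  Kpp <- gauss_kernel(P, P, sigma)
  Kqq <- gauss_kernel(Q, Q, sigma)
  Kpq <- gauss_kernel(P, Q, sigma)
  m2 <- if (unbiased) {
    np <- nrow(P); nq <- nrow(Q)
    if (np < 2L || nq < 2L) stop("unbiased estimator needs >= 2 per set")
    (sum(Kpp) - sum(diag(Kpp))) / (np * (np - 1)) +
      (sum(Kqq) - sum(diag(Kqq))) / (nq * (nq - 1)) - 2 * mean(Kpq)
  } else {
    mean(Kpp) + mean(Kqq) - 2 * mean(Kpq)
  }
  sqrt(max(m2, 0))
}

#' Label-wise mean reciprocal rank
#'
#' For each target label c, the MMD between the generated set for c and
#' every real labelled set is computed (one shared bandwidth, resolved on
#' the pooled features, so distances are comparable); the real set with the
#' target label ideally ranks first. MRR is the mean over labels of the
#' reciprocal rank of the target (ties get the mean rank), so it lies in
#' (0, 1] and equals 1 for perfect conditional consistency.
#'
#' @param generated_by_label,real_by_label named lists (same names) of
#'   sequence vectors / record lists / feature matrices.
#' @param kernel an [kernel_spec()].
#' @param k spectrum order for raw sequences.
#' @return Scalar MRR; attribute `ranks` gives the per-label target rank.
#' @export
mrr <- function(generated_by_label, real_by_label, kernel = kernel_spec(),
                k = 3L) {
  labs <- names(generated_by_label)
  if (is.null(labs) || !setequal(labs, names(real_by_label)))
    stop("generated and real label sets differ")
  gen <- lapply(generated_by_label[labs], as_features, k = k)
  real <- lapply(real_by_label[labs], as_features, k = k)
  if (any(vapply(c(gen, real), nrow, 1L) == 0L))
    stop("every label must have a nonempty set on both sides")
  sigma <- resolve_sigma(kernel, do.call(rbind, c(gen, real)))
  kern <- kernel_spec(sigma)
  C <- length(labs)
  ranks <- numeric(C)
  for (i in seq_len(C)) {
    d <- vapply(seq_len(C), function(j)
      mmd(gen[[i]], real[[j]], kern), numeric(1))
    ranks[i] <- rank(d, ties.method = "average")[i]
  }
  structure(mean(1 / ranks), ranks = stats::setNames(ranks, labs))
}

#' Per-column Shannon entropy of a multiple sequence alignment
#'
#' `H_j = -sum_s p_js log2 p_js` over the symbols observed in column j
#' (the gap character counts as a symbol), in bits.
#'
#' @param alignment aligned FASTA path, or a character vector of equal
#'   length aligned rows.
#' @return Numeric vector of length = alignment width.
#' @export
msa_column_entropy <- function(alignment) {
  if (length(alignment) == 1L && file.exists(alignment)) {
    ss <- Biostrings::readAAStringSet(alignment)
    alignment <- as.character(ss)
  }
  lens <- nchar(alignment)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment: row lengths ",
         paste(sort(unique(lens)), collapse = "/"))
  M <- do.call(rbind, strsplit(toupper(alignment), "", fixed = TRUE))
  apply(M, 2L, function(col) {
    p <- table(col) / length(col)
    -sum(p * log2(p))
  })
}

#' Per-position entropy profile of an (unaligned, equal-frame) sequence set
#'
#' Entropy at position j over the residues of all sequences long enough to
#' reach j. Suitable when sequences share a common frame (e.g. fixture
#' sets); for real families, compute an MSA externally and use
#' [msa_column_entropy()].
#'
#' @param seqs character vector / record list.
#' @return Numeric entropy vector of length `max(nchar)`.
#' @export
position_entropy <- function(seqs) {
  if (is.list(seqs)) seqs <- vapply(seqs, `[[`, character(1), "residues")
  Lmax <- max(nchar(seqs))
  vapply(seq_len(Lmax), function(j) {
    col <- substr(seqs[nchar(seqs) >= j], j, j)
    p <- table(col) / length(col)
    -sum(p * log2(p))
  }, numeric(1))
}

#' Average entropy difference (generated minus real)
#'
#' Mean over positions of `H_generated - H_real`: negative values mean the
#' generated set is less diverse than the real one, positive values more
#' diverse. Antisymmetric by construction.
#'
#' @param real_profile,generated_profile entropy vectors.
#' @param rule what to do on length mismatch: `"error"` (default) or
#'   `"truncate"` to the common prefix.
#' @return Scalar AED.
#' @export
aed <- function(real_profile, generated_profile,
                rule = c("error", "truncate")) {
  rule <- match.arg(rule)
  if (length(real_profile) != length(generated_profile)) {
    if (rule == "error")
      stop("profiles have lengths ", length(real_profile), " and ",
           length(generated_profile), "; pass rule = \"truncate\"")
    n <- min(length(real_profile), length(generated_profile))
    real_profile <- real_profile[seq_len(n)]
    generated_profile <- generated_profile[seq_len(n)]
  }
  mean(generated_profile - real_profile)
}

#' AED across feature dimensions
#'
#' Alternative diversity score: per spectrum-feature dimension, the Shannon
#' entropy (bits) of each set's values histogrammed on shared equal-width
#' bins; AED is the mean over dimensions of (generated - real). Only
#' dimensions with any variation in the pooled data contribute.
#'
#' @param feats_real,feats_gen feature matrices with equal column counts.
#' @param bins histogram bin count.
#' @return Scalar AED.
#' @export
aed_features <- function(feats_real, feats_gen, bins = 10L) {
  stopifnot(ncol(feats_real) == ncol(feats_gen))
  hent <- function(v, brk) {
    p <- tabulate(findInterval(v, brk, all.inside = TRUE), length(brk) - 1L)
    p <- p / sum(p); p <- p[p > 0]
    -sum(p * log2(p))
  }
  diffs <- vapply(seq_len(ncol(feats_real)), function(j) {
    pooled <- c(feats_real[, j], feats_gen[, j])
    if (max(pooled) == min(pooled)) return(NA_real_)
    brk <- seq(min(pooled), max(pooled), length.out = bins + 1L)
    hent(feats_gen[, j], brk) - hent(feats_real[, j], brk)
  }, numeric(1))
  mean(diffs, na.rm = TRUE)
}

#' Mean pairwise RKHS distance between two sets
#'
#' Mean over pairs (p in P, q in Q) of the kernel-induced distance
#' `sqrt(k(p,p) + k(q,q) - 2 k(p,q))`. When the two sets are the identical
#' matrix, self-pairs (the diagonal) are excluded. For a Gaussian kernel
#' every pair distance is bounded by `sqrt(2)`.
#'
#' @param feats_P,feats_Q feature matrices or sequence vectors.
#' @param kernel an [kernel_spec()].
#' @param k spectrum order for raw sequences.
#' @return Scalar mean distance.
#' @export
mean_pairwise_rkhs_distance <- function(feats_P, feats_Q,
                                        kernel = kernel_spec(), k = 3L) {
  P <- as_features(feats_P, k); Q <- as_features(feats_Q, k)
  if (nrow(P) == 0L || nrow(Q) == 0L) stop("empty feature set")
  sigma <- resolve_sigma(kernel, rbind(P, Q))
  Kpq <- gauss_kernel(P, Q, sigma)
  D <- sqrt(pmax(2 - 2 * Kpq, 0))   # k(p,p) = k(q,q) = 1 for gaussian
  same <- nrow(P) == nrow(Q) && isTRUE(all.equal(P, Q, check.attributes = FALSE))
  if (!same) return(mean(D))
  if (nrow(P) == 1L) return(0)  # a point is at distance 0 from itself
  mean(D[row(D) != col(D)])
}

## --- identity metrics ---------------------------------------------------

#' @keywords internal
identity_alignment <- function(a, b, match = 1, mismatch = 0, gap = 1) {
  letters_ <- sort(unique(c(strsplit(a, "")[[1]], strsplit(b, "")[[1]])))
  sm <- matrix(mismatch, length(letters_), length(letters_),
               dimnames = list(letters_, letters_))
  diag(sm) <- match
  Biostrings::pairwiseAlignment(a, b, type = "global",
                                substitutionMatrix = sm,
                                gapOpening = 0, gapExtension = gap)
}

#' Global percent identity (Needleman-Wunsch)
#'
#' Global alignment with match +1, mismatch 0, gap -1 by default
#' (score-exposed); identity = matches / alignment length * 100. Symmetric
#' in its arguments.
#'
#' @param seq_a,seq_b residue strings (or `rg_record`s).
#' @param match,mismatch,gap alignment scores (gap is the per-position
#'   cost, applied as a negative score).
#' @return Percent identity in `[0, 100]`.
#' @export
global_identity <- function(seq_a, seq_b, match = 1, mismatch = 0, gap = 1) {
  if (inherits(seq_a, "rg_record")) seq_a <- seq_a$residues
  if (inherits(seq_b, "rg_record")) seq_b <- seq_b$residues
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty input sequence")
  al <- identity_alignment(seq_a, seq_b, match, mismatch, gap)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  100 * sum(pa == sa & pa != "-") / length(pa)
}

#' Sliding-window percent identity to the nearest training sequence
#'
#' Local-novelty profile: the query is globally aligned to each training
#' sequence (anchor alignment); for every window of `w` consecutive query
#' residues, the ungapped within-window identity against that alignment is
#' computed, and the maximum over training sequences is reported. Window
#' start positions are 1-based query coordinates.
#'
#' @param query residue string (or record).
#' @param training_set character vector / record list.
#' @param w window width (>= 1); `w = nchar(query)` reduces to one global
#'   ungapped identity value.
#' @return Numeric vector of length `nchar(query) - w + 1` in `[0, 100]`.
#' @export
sliding_window_identity <- function(query, training_set, w = 3L) {
  if (inherits(query, "rg_record")) query <- query$residues
  if (is.list(training_set))
    training_set <- vapply(training_set, `[[`, character(1), "residues")
  if (length(training_set) == 0L) stop("training set is empty")
  stopifnot(w >= 1, nchar(query) >= w)
  nq <- nchar(query)
  nwin <- nq - w + 1L
  best <- rep(0, nwin)
  for (tr in training_set) {
    al <- identity_alignment(query, tr)
    pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    qpos <- cumsum(pa != "-")
    hit <- logical(nq)
    ok <- pa != "-" & pa == sa
    hit[qpos[ok]] <- TRUE
    wid <- vapply(seq_len(nwin), function(i)
      100 * mean(hit[i:(i + w - 1L)]), numeric(1))
    best <- pmax(best, wid)
    if (all(best == 100)) break
  }
  best
}

## --- report -------------------------------------------------------------

#' Evaluate a (real, generated) labelled sequence-set pair
#'
#' Computes the full metric report: pooled MMD, label-wise MRR, entropy
#' profiles and AED (position mode by default; feature mode optional),
#' mean pairwise RKHS distance, and (optionally, on a subsample) global
#' identity of generated sequences to their nearest real neighbour.
#'
#' @param real_by_label,generated_by_label named lists of `rg_record` lists
#'   (or character vectors), same label names.
#' @param k spectrum order.
#' @param kernel an [kernel_spec()].
#' @param alignment optional aligned FASTA path; when given, entropy
#'   profiles come from [msa_column_entropy()] on it instead of the
#'   positional profiles.
#' @param aed_mode `"position"` (default) or `"feature"`.
#' @param identity_sample number of generated sequences (per label) to
#'   score for nearest-real global identity; 0 disables.
#' @return `rg_eval_report` list with fields `mmd`, `mrr`, `aed`,
#'   `mean_pairwise_rkhs_distance`, `entropy_real`, `entropy_generated`,
#'   `identity` (summary or NULL), `per_label_mmd`.
#' @export
evaluate_sets <- function(real_by_label, generated_by_label, k = 3L,
                          kernel = kernel_spec(), alignment = NULL,
                          aed_mode = c("position", "feature"),
                          identity_sample = 0L) {
  aed_mode <- match.arg(aed_mode)
  labs <- names(real_by_label)
  stopifnot(!is.null(labs), setequal(labs, names(generated_by_label)))
  as_chr <- function(x) if (is.list(x))
    vapply(x, `[[`, character(1), "residues") else x
  real_s <- lapply(real_by_label[labs], as_chr)
  gen_s <- lapply(generated_by_label[labs], as_chr)
  real_f <- lapply(real_s, spectrum_features, k = k)
  gen_f <- lapply(gen_s, spectrum_features, k = k)
  sigma <- resolve_sigma(kernel, do.call(rbind, c(real_f, gen_f)))
  kern <- kernel_spec(sigma)

  pooled_real <- do.call(rbind, real_f)
  pooled_gen <- do.call(rbind, gen_f)
  mmd_all <- mmd(pooled_gen, pooled_real, kern)
  per_label <- vapply(labs, function(l)
    mmd(gen_f[[l]], real_f[[l]], kern), numeric(1))
  mrr_val <- mrr(gen_f, real_f, kern)

  if (!is.null(alignment)) {
    ## one joint MSA; per-set column entropies over its shared width.
    ## generated rows are identified by the `gen` ID prefix used by
    ## generate_sequences().
    ss <- Biostrings::readAAStringSet(alignment)
    ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
    rows <- as.character(ss)
    gen_rows <- grepl("^gen", ids)
    if (!any(gen_rows) || all(gen_rows))
      stop("alignment must contain both generated ('gen...' IDs) and ",
           "real rows")
    ent_real <- msa_column_entropy(rows[!gen_rows])
    ent_gen <- msa_column_entropy(rows[gen_rows])
  } else {
    ent_real <- position_entropy(unlist(real_s, use.names = FALSE))
    ent_gen <- position_entropy(unlist(gen_s, use.names = FALSE))
  }
  aed_val <- if (aed_mode == "position")
    aed(ent_real, ent_gen, rule = "truncate")
  else aed_features(pooled_real, pooled_gen)

  dist_val <- mean_pairwise_rkhs_distance(pooled_gen, pooled_real, kern)

  identity <- NULL
  if (identity_sample > 0L) {
    ids <- unlist(lapply(labs, function(l)
      utils::head(gen_s[[l]], identity_sample)), use.names = FALSE)
    pool <- unlist(real_s, use.names = FALSE)
    nearest <- vapply(ids, function(g)
      max(vapply(pool, function(r) global_identity(g, r), numeric(1))),
      numeric(1))
    identity <- list(mean = mean(nearest), max = max(nearest),
                     values = unname(nearest))
  }
  structure(list(mmd = mmd_all, mrr = as.numeric(mrr_val), aed = aed_val,
                 mean_pairwise_rkhs_distance = dist_val,
                 entropy_real = ent_real, entropy_generated = ent_gen,
                 per_label_mmd = per_label,
                 mrr_ranks = attr(mrr_val, "ranks"),
                 identity = identity, sigma = sigma),
            class = "rg_eval_report")
}

#' @export
print.rg_eval_report <- function(x, ...) {
  cat("Sequence-set evaluation report\n")
  cat(sprintf("  MMD (similarity):          %.4f\n", x$mmd))
  cat(sprintf("  MRR (cond. consistency):   %.4f\n", x$mrr))
  cat(sprintf("  AED (diversity, gen-real): %+.4f\n", x$aed))
  cat(sprintf("  Mean pairwise RKHS dist.:  %.4f\n",
              x$mean_pairwise_rkhs_distance))
  if (!is.null(x$identity))
    cat(sprintf("  Nearest-real identity:     mean %.1f%%, max %.1f%%\n",
                x$identity$mean, x$identity$max))
  invisible(x)
}
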