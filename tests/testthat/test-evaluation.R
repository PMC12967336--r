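test_that("spectrum features are normalised overlapping k-mer counts", {
  f <- spectrum_features("AAA", k = 2)
  expect_equal(sum(f != 0), 1L)
  expect_equal(max(f), 1.0)
  f1 <- spectrum_features("ARN", k = 1)
  expect_equal(sort(f1[f1 != 0]), rep(1 / 3, 3), ignore_attr = TRUE)
  ## normalisation sweep over random sequences
  F <- spectrum_features(random_seqs(100, 10:40, seed = 5), k = 3)
  expect_equal(unname(rowSums(F)), rep(1, 100))
  ## too-short sequences are zero rows with a warning
  expect_warning(fs <- spectrum_features(c("AR", "ARNDC"), k = 3),
                 "shorter than k")
  expect_equal(sum(fs[1, ]), 0)
  expect_true(attr(fs, "short")[1])
})

test_that("mmd matches the brute-force kernel-sum oracle to 1e-10", {
  set.seed(31)
  P <- matrix(rnorm(20 * 5), 20, 5)
  Q <- matrix(rnorm(20 * 5, mean = 0.5), 20, 5)
  sigma <- 1.3
  expect_equal(mmd(P, Q, kernel_spec(sigma)), brute_mmd(P, Q, sigma),
               tolerance = 1e-10)
  ## identical multisets give zero
  expect_lt(mmd(P, P, kernel_spec(sigma)), 1e-10)
  ## symmetry
  expect_equal(mmd(P, Q, kernel_spec(sigma)), mmd(Q, P, kernel_spec(sigma)))
  ## singleton closed form: MMD^2 = 2 - 2 exp(-||x-y||^2 / (2 sigma^2))
  x <- matrix(c(1, 2), 1); y <- matrix(c(2, 0), 1)
  expect_equal(mmd(x, y, kernel_spec(sigma)),
               sqrt(2 - 2 * exp(-sum((x - y)^2) / (2 * sigma^2))),
               tolerance = 1e-12)
  expect_error(mmd(P[0, , drop = FALSE], Q), "empty")
})

test_that("mmd is monotone in mean shift for Gaussian samples", {
  set.seed(7)
  base <- matrix(rnorm(40 * 3), 40, 3)
  vals <- vapply(c(0, 0.5, 1, 2, 4), function(sh)
    mmd(base, base + sh, kernel_spec(1)), numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("mean pairwise RKHS distance matches its oracle and bounds", {
  set.seed(13)
  P <- matrix(rnorm(10 * 4), 10, 4)
  Q <- matrix(rnorm(10 * 4), 10, 4)
  expect_equal(mean_pairwise_rkhs_distance(P, Q, kernel_spec(0.8)),
               brute_pairwise_dist(P, Q, 0.8), tolerance = 1e-10)
  ## gaussian kernel bounds every pair distance by sqrt(2)
  expect_lte(mean_pairwise_rkhs_distance(P, Q * 100, kernel_spec(0.1)),
             sqrt(2))
  ## identical singleton pair -> 0; identical sets exclude self-pairs
  s <- matrix(1:3, 1)
  expect_equal(mean_pairwise_rkhs_distance(s, s, kernel_spec(1)), 0)
  expect_gt(mean_pairwise_rkhs_distance(P, P, kernel_spec(1)), 0)
})

test_that("mrr is exact in the separated limit and bounded", {
  set.seed(5)
  mk <- function(mu) matrix(rnorm(15 * 3, sd = 0.05), 15, 3) +
    matrix(mu, 15, 3, byrow = TRUE)
  mus <- list(a = c(0, 0, 0), b = c(10, 0, 0), c = c(0, 10, 0),
              d = c(0, 0, 10), e = c(10, 10, 10))
  real <- lapply(mus, mk)
  gen <- lapply(mus, mk)
  m <- mrr(gen, real, kernel_spec(1))
  expect_equal(as.numeric(m), 1.0)
  expect_equal(unname(attr(m, "ranks")), rep(1, 5))
  ## adversarial: every generated set closest to one fixed wrong label
  gen_bad <- lapply(mus, function(...) mk(mus$a))
  m_bad <- as.numeric(mrr(gen_bad, real, kernel_spec(1)))
  expect_lte(m_bad, 0.5 + 1e-9)
  expect_error(mrr(gen[1:3], real), "differ")
})

test_that("random label assignment calibrates to the analytic expectation", {
  ## 5 equidistant classes (simplex vertices); generated sets get a random
  ## permutation of labels, making the target's rank uniform on 1..5, so
  ## E[MRR] = (1/5) * sum(1/i) ~ 0.4567. Modest reps here; the acceptance
  ## suite runs the full calibration.
  set.seed(17)
  expected <- mean(1 / (1:5))
  C <- 5
  reps <- 200
  vals <- vapply(seq_len(reps), function(rep) {
    mk <- function(c) {
      mu <- numeric(C); mu[c] <- 3
      matrix(rnorm(10 * C, sd = 0.5), 10, C) +
        matrix(mu, 10, C, byrow = TRUE)
    }
    real <- lapply(1:C, mk)
    names(real) <- paste0("c", 1:C)
    perm <- sample(C)
    gen <- lapply(perm, mk)
    names(gen) <- paste0("c", 1:C)
    as.numeric(mrr(gen, real, kernel_spec(1)))
  }, numeric(1))
  se <- sd(vals) / sqrt(reps)
  expect_lt(abs(mean(vals) - expected), max(3 * se, 0.02))
})

test_that("MSA column entropy matches hand-computed closed forms", {
  expect_equal(msa_column_entropy(c("A", "A", "A", "A")), 0)
  expect_equal(msa_column_entropy(c("A", "C", "G", "T")), 2.0)
  expect_equal(msa_column_entropy(c("A", "A", "G", "T")), 1.5)
  ## gap counts as a symbol; per-column over a real alignment shape
  H <- msa_column_entropy(c("AC-A", "ACCA", "AC-A", "ACCT"))
  expect_equal(H[1], 0)
  expect_equal(H[2], 0)
  expect_equal(H[3], 1.0)      # '-' x2, 'C' x2
  expect_equal(H[4], -sum(c(.75, .25) * log2(c(.75, .25))))
  expect_error(msa_column_entropy(c("AC", "A")), "ragged")
})

test_that("aed follows the generated-minus-real sign convention", {
  expect_equal(aed(c(1, 2, 3), c(1, 2, 3)), 0)
  ## constant generated columns vs varied real -> strictly negative
  expect_lt(aed(c(2, 2, 2), c(0, 0, 0)), 0)
  ## hand-computed 5-column toy pair
  real <- c(1.0, 0.5, 2.0, 0.0, 1.5)
  gen <- c(1.2, 0.4, 2.0, 0.5, 1.4)
  expect_equal(aed(real, gen), mean(gen - real))
  ## antisymmetry
  expect_equal(aed(real, gen), -aed(gen, real))
  expect_error(aed(1:3, 1:4), "truncate")
  expect_equal(aed(1:3, c(1:3 + 1, 9), rule = "truncate"), 1)
})

test_that("global identity is the NW match fraction", {
  expect_equal(global_identity("MKWVT", "MKWVT"), 100)
  expect_equal(global_identity("AAAA", "AATA"), 75)
  expect_equal(global_identity("MKWVT", "MKVT"),
               global_identity("MKVT", "MKWVT"))
  expect_error(global_identity("", "MK"), "empty")
})

test_that("sliding-window identity profiles local novelty", {
  train <- random_seqs(5, 30, seed = 9)
  ## query in the training set -> 100% everywhere
  expect_equal(sliding_window_identity(train[1], train, w = 3),
               rep(100, 28))
  ## a planted 3-residue novel patch drops the windows covering it
  q <- train[1]
  ## replace positions 11..13 with residues differing from every training
  ## sequence at those positions
  pick <- function(j) {
    used <- unique(substr(train, j, j))
    setdiff(regenseq:::AA20, used)[1]
  }
  substr(q, 11, 11) <- pick(11)
  substr(q, 12, 12) <- pick(12)
  substr(q, 13, 13) <- pick(13)
  wid <- sliding_window_identity(q, train, w = 3)
  expect_true(all(wid[9:13] < 100))
  expect_equal(wid[1:8], rep(100, 8))
  ## w = query length reduces to one global ungapped identity value
  expect_length(sliding_window_identity(q, train, w = nchar(q)), 1L)
  expect_error(sliding_window_identity(q, list()), "empty")
})

test_that("evaluate_sets returns a coherent report on the motif fixture", {
  recs <- motif_records()
  by_lab <- records_by_label(recs)
  half <- lapply(by_lab, function(g) g[seq(1, length(g), by = 2)])
  other <- lapply(by_lab, function(g) g[seq(2, length(g), by = 2)])
  rep_ <- evaluate_sets(half, other, identity_sample = 2)
  expect_s3_class(rep_, "rg_eval_report")
  expect_gte(rep_$mmd, 0)
  expect_equal(rep_$mrr, 1.0)   # same-distribution halves, separated motifs
  expect_true(is.finite(rep_$aed))
  expect_true(all(rep_$entropy_real >= 0))
  expect_true(all(rep_$entropy_real <= log2(21)))
  expect_lte(rep_$mean_pairwise_rkhs_distance, sqrt(2))
  expect_true(rep_$identity$max <= 100)
  expect_output(print(rep_), "MRR")
})
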