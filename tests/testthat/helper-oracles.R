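## Brute-force oracles, independent of the package's vectorised
## implementations: explicit double loops over scalar kernel evaluations.

brute_mmd <- function(P, Q, sigma) {
  kf <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  acc <- function(X, Y) {
    s <- 0
    for (i in seq_len(nrow(X))) for (j in seq_len(nrow(Y)))
      s <- s + kf(X[i, ], Y[j, ])
    s / (nrow(X) * nrow(Y))
  }
  sqrt(max(acc(P, P) + acc(Q, Q) - 2 * acc(P, Q), 0))
}

brute_pairwise_dist <- function(P, Q, sigma) {
  kf <- function(a, b) exp(-sum((a - b)^2) / (2 * sigma^2))
  tot <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(nrow(Q)))
    tot <- tot + sqrt(kf(P[i, ], P[i, ]) + kf(Q[j, ], Q[j, ]) -
                        2 * kf(P[i, ], Q[j, ]))
  tot / (nrow(P) * nrow(Q))
}

## Desk-scale end-to-end run on the 3-class motif fixture (300 records,
## L = 40), trained once per test session and shared.
pipeline_fixture_spec <- function() fixture_spec(C = 3, n = 100, L = 40,
                                                 seed = 101)

pipeline_config <- function(seed = 7) {
  run_config(max_length = 40, seed = seed,
             embedder = embedder_config(m = 32, epochs = 25),
             diffusion = diffusion_config(steps = 6000L, batch_size = 256L),
             gan = gan_config(steps = 1500L),
             n_generate = 100L, holdout = 0.25)
}

trained_pipeline <- function() {
  cached("pipeline", function() {
    recs <- generate_labeled_sequences(pipeline_fixture_spec())
    run_full_pipeline(pipeline_config(), records = recs)
  })
}

## label-only one-stage baseline at the same generator-step budget
one_stage_baseline <- function() {
  cached("one_stage", function() {
    recs <- generate_labeled_sequences(pipeline_fixture_spec())
    cfg <- pipeline_config()
    gcfg <- cfg$gan
    gcfg$use_r <- FALSE
    gcfg$seed <- regenseq:::seed_offsets(cfg$seed)$gan
    spec <- encoding_spec(40)
    so <- regenseq:::seed_offsets(cfg$seed)
    sp <- regenseq:::split_by_pattern(recs)
    idx_hold <- regenseq:::with_seed(so$split, {
      unlist(lapply(unique(sp$cls), function(c) {
        ix <- which(sp$cls == c)
        sample(ix, max(1L, round(cfg$holdout * length(ix))))
      }))
    })
    gan <- train_cwgan(recs[-idx_hold], NULL, gcfg, spec)
    pat_names <- apply(sp$patterns, 1L, paste, collapse = "")
    gen <- stats::setNames(
      lapply(seq_len(nrow(sp$patterns)), function(c)
        generate_sequences(gan, NULL, sp$patterns[c, ], n = cfg$n_generate,
                           seed = so$generate + c,
                           prefix = sprintf("gen_c%d", c))),
      pat_names)
    list(gan = gan, generated = gen)
  })
}
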