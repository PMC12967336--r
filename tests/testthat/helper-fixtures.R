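## Shared fixtures. Expensive trained objects are built once per test run
## and cached in this environment so several test files can reuse them.

.rg_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .rg_cache)) assign(key, builder(), envir = .rg_cache)
  get(key, envir = .rg_cache)
}

spec40 <- function() encoding_spec(40)

## 3-class motif fixture used across modules
motif_records <- function(n = 60, seed = 11) {
  cached(sprintf("motif_%d_%d", n, seed), function()
    generate_labeled_sequences(fixture_spec(C = 3, n = n, L = 40,
                                            seed = seed)))
}

## small trained embedder on the motif fixture
trained_embedder <- function() {
  cached("embedder", function()
    train_embedder(motif_records(),
                   embedder_config(m = 32, epochs = 20, seed = 7),
                   spec40()))
}

## trained diffusion on a 4-class Gaussian-mixture latent fixture
latent_fixture <- function() {
  cached("latent", function()
    generate_latent_dataset(C = 4, n = 200, m = 4, noise_sd = 0.1,
                            seed = 3))
}

latent_means <- function() {
  mu <- matrix(0, 4, 4)
  for (c in 1:4) mu[c, c] <- 5
  mu
}

trained_diffusion <- function() {
  cached("diffusion", function() {
    ld <- latent_fixture()
    train_diffusion(ld$r, ld$y,
                    diffusion_config(steps = 12000L, batch_size = 256L,
                                     seed = 4))
  })
}

## records grouped into per-label lists keyed by the label bit-pattern
records_by_label <- function(records) {
  keys <- vapply(records, function(r) paste(r$label, collapse = ""),
                 character(1))
  split(records, keys)
}

## random residue strings over the core alphabet
random_seqs <- function(n, len, seed = 1) {
  with_seed <- regenseq:::with_seed
  with_seed(seed, vapply(seq_len(n), function(i) {
    li <- len[(i - 1L) %% length(len) + 1L]
    paste(sample(regenseq:::AA20, li, replace = TRUE), collapse = "")
  }, character(1)))
}
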