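# regenseq

Conditional generation of functional protein sequences from small labelled
datasets, for computational protein designers and methods researchers who
need a fully inspectable, CPU-scale implementation of the two-stage
("regeneration") approach together with its evaluation suite.

## The model

Let `X` be an amino-acid sequence, one-hot encoded as an `L x A` matrix
(`A = 21`: 20 canonical residues plus a combined unknown/pad symbol), and
`Y` a d-dimensional multi-hot Gene Ontology annotation vector. Direct
modelling of `P(X | Y)` is brittle when the labelled family is small and
`X` is high-dimensional (`L = 2048` gives a 43,008-dimensional space).
`regenseq` factorises through a compact deterministic representation
`R = R(X)`, `m << L x A`:

```
P(X | Y) = P(X | R, Y) · P(R | Y)
```

and models the factors separately:

1. **`train_embedder()`** — a supervised classification network
   (convolutional encoder, residual block, fully connected head; cross
   entropy on the GO labels). The representation is the residual block's
   post-activation output. Externally computed protein-language-model
   embeddings can be used instead (`load_external_embeddings()`).
2. **`train_diffusion()`** — a conditional denoising diffusion model over
   `R`: cosine schedule, x0-prediction, classifier-free guidance via 10%
   condition dropout; sampling is the guided ancestral reverse chain.
3. **`train_cwgan()`** — a conditional Wasserstein GAN with gradient
   penalty (`lambda = 10`, 5 critic steps per generator step) decoding
   `(z, r, y)` to sequences, plus an auxiliary discriminative classifier
   over 2C mutually exclusive (real, class)/(fake, class) targets with
   weight `beta = 175`.

Generation is two-step: `r ~ P(R | Y = y)`, then `x ~ P(X | R = r, Y = y)`
(`generate_sequences()`). Evaluation (`evaluate_sets()`) compares real and
generated sets in an RKHS over 3-mer spectrum features: MMD (similarity),
label-wise MRR (conditional consistency), average entropy difference
(diversity), mean pairwise RKHS distance, and global / sliding-window
percent identity.

## Worked example

A complete desk-scale run on the built-in synthetic fixture — three
classes of 100 length-40 sequences, each class carrying a planted
5-residue motif — trains all three stages and evaluates generated
sequences against a held-out quarter of the data:

```r
library(regenseq)

fs   <- fixture_spec(C = 3, n = 100, L = 40, seed = 101)
recs <- generate_labeled_sequences(fs)

cfg <- run_config(max_length = 40, seed = 7,
                  embedder  = embedder_config(m = 32, epochs = 25),
                  diffusion = diffusion_config(steps = 6000, batch_size = 256),
                  gan       = gan_config(steps = 1500),
                  n_generate = 100, holdout = 0.25)

res <- run_full_pipeline(cfg, records = recs)
print(res$report)
#> Sequence-set evaluation report
#>   MMD (similarity):          0.1130
#>   MRR (cond. consistency):   1.0000
#>   AED (diversity, gen-real): -1.1399
#>   Mean pairwise RKHS dist.:  0.8772
```

Reading the numbers: MRR = 1.0 means every generated set is
distributionally closest to the real set bearing its own label — perfect
conditional consistency on this fixture (chance would be ~0.46). The MMD
of 0.11 is the residual distributional gap to the held-out reals, and the
negative AED says the generated sets are less position-diverse than the
real ones, the expected behaviour of a GAN trained on a few hundred
sequences. In the same run, 99–100% of generated sequences per class
contain their class's planted motif. About six minutes on one CPU.

The same machinery is scriptable from the shell via
`inst/cli/regenseq.R` (`make-fixture`, `train-*`, `generate`, `evaluate`,
`ablate`, `run-all`; every subcommand accepts `--config`, `--seed`,
`--dry-run`), and `run_ablation()` reproduces the architecture ablations
(one-stage label-only baseline, `beta = 0`, beta sweep) with step-indexed
MMD/MRR traces.

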