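test_that("embedder training reduces cross entropy on the fixture task", {
  emb <- trained_embedder()
  expect_lt(utils::tail(emb$loss_trace, 1), emb$loss_trace[1])
  ## and the trend is a genuine decrease, not a lucky endpoint
  n <- length(emb$loss_trace)
  expect_lt(mean(emb$loss_trace[(n - 4):n]), mean(emb$loss_trace[1:5]))
})

test_that("trained embedder beats the majority-class rate on held-out data", {
  recs <- motif_records()
  ## train on two thirds, evaluate on the rest (per class, interleaved)
  idx_te <- seq(1, length(recs), by = 3)
  emb <- train_embedder(recs[-idx_te],
                        embedder_config(m = 32, epochs = 20, seed = 7),
                        spec40())
  pred <- predict(emb, recs[idx_te])
  truth <- do.call(rbind, lapply(recs[idx_te], `[[`, "label"))
  acc <- mean(apply(pred == truth, 1L, all))
  expect_gt(acc, max(colMeans(truth)))   # majority-class rate = 1/3
})

test_that("shuffled labels give chance-level held-out accuracy", {
  recs <- motif_records()
  shuffled <- regenseq:::with_seed(99, {
    perm <- sample(length(recs))
    mapply(function(r, j) { r$label <- recs[[j]]$label; r },
           recs, perm, SIMPLIFY = FALSE)
  })
  idx_te <- seq(1, length(recs), by = 3)
  emb <- train_embedder(shuffled[-idx_te],
                        embedder_config(m = 32, epochs = 10, seed = 5),
                        spec40())
  pred <- predict(emb, shuffled[idx_te])
  truth <- do.call(rbind, lapply(shuffled[idx_te], `[[`, "label"))
  acc <- mean(apply(pred == truth, 1L, all))
  n_te <- length(idx_te)
  ## within a generous binomial envelope of 1/3 (labels carry no signal)
  expect_lt(abs(acc - 1 / 3), 4 * sqrt((1 / 3) * (2 / 3) / n_te))
})

test_that("freezing the backbone keeps its weights bit-identical", {
  recs <- motif_records(n = 20, seed = 15)
  cfg <- embedder_config(m = 16, epochs = 3, seed = 2,
                         freeze_backbone = TRUE)
  init <- regenseq:::embedder_params_init(cfg, spec40(),
                                          d = length(recs[[1]]$label),
                                          seed = cfg$seed)
  emb <- train_embedder(recs, cfg, spec40())
  expect_identical(emb$params$Wc, init$Wc)
  expect_identical(emb$params$bc, init$bc)
  ## the head did train
  expect_false(identical(emb$params$Wh, init$Wh))
})

test_that("embedder refuses degenerate inputs", {
  recs <- motif_records(n = 10, seed = 3)
  one_class <- lapply(recs, function(r) { r$label <- c(1, 0, 0); r })
  expect_error(train_embedder(one_class,
                              embedder_config(epochs = 1), spec40()),
               "2 distinct label patterns")
  unlab <- recs; unlab[[1]]$label <- NULL
  expect_error(train_embedder(unlab, embedder_config(epochs = 1), spec40()),
               "annotated")
})

test_that("representations are deterministic, sized m, and class-separated", {
  emb <- trained_embedder()
  recs <- motif_records()
  r1 <- extract_representation(emb, recs[[1]])
  r2 <- extract_representation(emb, recs[[1]])
  expect_identical(r1, r2)
  expect_length(r1, emb$cfg$m)
  ## between-class mean distance exceeds within-class mean distance
  R <- extract_representation(emb, recs)
  cls <- attr(recs, "classes")
  D <- as.matrix(dist(R))
  same <- outer(cls, cls, "==") & upper.tri(D)
  diff_ <- outer(cls, cls, "!=") & upper.tri(D)
  expect_gt(mean(D[diff_]), mean(D[same]))
  ## over-long records are refused
  long <- sequence_record("long", strrep("M", 41))
  expect_error(extract_representation(emb, long), "longer")
})

test_that("external embeddings load, validate, and round-trip exactly", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(10)
  emb_tab <- setNames(lapply(1:3, function(i) rnorm(8)),
                      c("p1", "p2", "p3"))
  write_embeddings(emb_tab, f)
  back <- load_external_embeddings(f, ids = c("p1", "p2", "p3"))
  expect_identical(back, emb_tab)        # full precision round trip
  expect_error(load_external_embeddings(f, ids = c("p1", "zz")), "zz")
  writeLines(c("a\t1\t2", "b\t1"), f)
  expect_error(load_external_embeddings(f), "ragged")

  ## external mode embeds unannotated records by ID (semi-supervised use)
  ext <- external_embedder(emb_tab)
  rec <- sequence_record("p2", "MKWVT")   # no label
  expect_identical(extract_representation(ext, rec), emb_tab$p2)
  expect_length(extract_representation(ext, rec), 8L)
})

test_that("a 480-column external table yields m = 480", {
  f <- withr::local_tempfile(fileext = ".tsv")
  set.seed(2)
  write_embeddings(list(q1 = rnorm(480)), f)
  ext <- external_embedder(load_external_embeddings(f))
  expect_equal(ext$m, 480L)
})
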