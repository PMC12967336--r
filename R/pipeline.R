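## End-to-end orchestration of the two-step generating procedure
## (sample r given y, then x given (r, y)), configuration handling, the
## ablation runner (no-representation baseline, no-classifier, beta sweep)
## and a thin command-line surface.

#' Assemble a run configuration
#'
#' One document holding every tunable of the pipeline, with the package's
#' documented defaults filled in, so deviations are visible in the run
#' manifest. Can be written to / read from YAML.
#'
#' @param fasta,labels input paths (FASTA + label TSV). Either these or
#'   `records` must be supplied at run time.
#' @param out_dir output directory (`NULL` = return results only).
#' @param max_length,vocabulary encoding: L and the GO vocabulary (needed
#'   when reading labels from TSV).
#' @param embedder an [embedder_config()].
#' @param diffusion an [diffusion_config()].
#' @param gan an [gan_config()].
#' @param eval_k spectrum order for evaluation.
#' @param n_generate generated sequences per label pattern at evaluation.
#' @param holdout fraction of records (per class) held out for evaluation.
#' @param seed global seed; propagated to every stochastic component.
#' @return `rg_run_config` list.
#' @export
run_config <- function(fasta = NULL, labels = NULL, out_dir = NULL,
                       max_length = 40L, vocabulary = NULL,
                       embedder = embedder_config(),
                       diffusion = diffusion_config(),
                       gan = gan_config(),
                       eval_k = 3L, n_generate = 100L, holdout = 0.25,
                       seed = 1L) {
  stopifnot(holdout > 0, holdout < 1)
  structure(list(fasta = fasta, labels = labels, out_dir = out_dir,
                 max_length = as.integer(max_length),
                 vocabulary = vocabulary, embedder = embedder,
                 diffusion = diffusion, gan = gan,
                 eval_k = as.integer(eval_k),
                 n_generate = as.integer(n_generate), holdout = holdout,
                 seed = as.integer(seed)),
            class = "rg_run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file.
#' @return An `rg_run_config` / `path` invisibly.
#' @export
load_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  cfg <- run_config()
  sub_ctors <- list(embedder = embedder_config, diffusion = diffusion_config,
                    gan = gan_config)
  for (nm in names(y)) {
    if (nm %in% names(sub_ctors)) {
      args <- y[[nm]]
      if (nm == "diffusion" && !is.null(args$guidance))
        args$guidance <- do.call(guidance_config, args$guidance)
      cfg[[nm]] <- do.call(sub_ctors[[nm]], args)
    } else if (nm %in% names(cfg)) {
      cfg[[nm]] <- if (nm %in% c("max_length", "eval_k", "n_generate",
                                 "seed")) as.integer(y[[nm]]) else y[[nm]]
    } else {
      stop("unknown config field: ", nm)
    }
  }
  cfg
}

#' @rdname load_run_config
#' @param cfg an `rg_run_config`.
#' @export
save_run_config <- function(cfg, path) {
  strip <- function(x) {
    if (is.list(x)) lapply(unclass(x), strip) else x
  }
  yaml::write_yaml(strip(cfg), path)
  invisible(path)
}

#' @keywords internal
seed_offsets <- function(seed) {
  ## distinct, stable sub-seeds per stage, kept well inside 32-bit range
  base <- (as.integer(seed) %% 1000000L) * 101L
  list(fixture = base + 1L, embedder = base + 2L, diffusion = base + 3L,
       gan = base + 4L, generate = base + 5L, split = base + 6L)
}

#' @keywords internal
load_labeled_records <- function(cfg) {
  spec <- encoding_spec(cfg$max_length)
  if (is.null(cfg$fasta) || is.null(cfg$labels))
    stop("config must name a FASTA and a label table")
  if (!file.exists(cfg$labels))
    stop("label file not found: ", cfg$labels)
  records <- read_fasta(cfg$fasta, spec)
  vocab <- cfg$vocabulary
  if (is.null(vocab)) {
    fields <- utils::read.delim(cfg$labels, header = FALSE,
                                colClasses = "character")[[2]]
    vocab <- sort(unique(trimws(unlist(strsplit(fields, ";")))))
    vocab <- vocab[nzchar(vocab)]
  }
  labels <- read_label_table(cfg$labels, vocab)
  list(records = join_labels(records, labels), spec = spec, vocab = vocab)
}

#' @keywords internal
split_by_pattern <- function(records) {
  labs <- do.call(rbind, lapply(records, `[[`, "label"))
  patterns <- unique(labs)
  key <- apply(labs, 1L, paste, collapse = "")
  pat_key <- apply(patterns, 1L, paste, collapse = "")
  list(patterns = patterns, cls = match(key, pat_key))
}

#' Run the full two-stage pipeline on a labelled dataset
#'
#' Trains embedder, then latent diffusion on the embedder representations,
#' then the sequence GAN; generates `n_generate` sequences per label
#' pattern; evaluates them against held-out real sequences. Any stage
#' failure aborts with the stage name. With `dry_run = TRUE` the inputs and
#' configuration are validated and the function returns before any
#' training.
#'
#' @param cfg an [run_config()] (or path to its YAML).
#' @param records optional pre-loaded labelled `rg_record` list (bypasses
#'   the FASTA/label paths).
#' @param dry_run validate only?
#' @return List with `report` (an `rg_eval_report`), `generated`
#'   (records by label), `embedder`, `diffusion`, `gan`, `config`; writes
#'   artifacts (generated FASTA, report JSON, loss logs, manifest) under
#'   `cfg$out_dir` when set.
#' @export
run_full_pipeline <- function(cfg, records = NULL, dry_run = FALSE) {
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  stopifnot(inherits(cfg, "rg_run_config"))
  so <- seed_offsets(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  if (is.null(records)) {
    loaded <- stage("load", load_labeled_records(cfg))
    records <- loaded$records
    spec <- loaded$spec
  } else {
    spec <- encoding_spec(cfg$max_length)
    stage("load", {
      if (any(vapply(records, function(r) is.null(r$label), logical(1))))
        stop("unlabelled record present")
    })
  }
  if (dry_run) {
    sp <- split_by_pattern(records)
    return(invisible(list(ok = TRUE, n_records = length(records),
                          n_patterns = nrow(sp$patterns), config = cfg)))
  }

  sp <- split_by_pattern(records)
  idx_hold <- stage("split", with_seed(so$split, {
    unlist(lapply(unique(sp$cls), function(c) {
      ix <- which(sp$cls == c)
      sample(ix, max(1L, round(cfg$holdout * length(ix))))
    }))
  }))
  train_recs <- records[-idx_hold]
  hold_recs <- records[idx_hold]

  emb_cfg <- cfg$embedder; emb_cfg$seed <- so$embedder
  embedder <- stage("embedder", train_embedder(train_recs, emb_cfg, spec))

  Rtr <- stage("representation",
               extract_representation(embedder, train_recs))
  Ytr <- do.call(rbind, lapply(train_recs, `[[`, "label"))
  dif_cfg <- cfg$diffusion; dif_cfg$seed <- so$diffusion
  diffusion <- stage("diffusion", train_diffusion(Rtr, Ytr, dif_cfg))

  gan_cfg <- cfg$gan; gan_cfg$seed <- so$gan
  gan <- stage("gan", train_cwgan(train_recs, embedder, gan_cfg, spec))

  pat_names <- apply(sp$patterns, 1L, paste, collapse = "")
  generated <- stage("generate", {
    out <- lapply(seq_len(nrow(sp$patterns)), function(c)
      generate_sequences(gan, diffusion, sp$patterns[c, ],
                         n = cfg$n_generate, seed = so$generate + c,
                         prefix = sprintf("gen_c%d", c)))
    stats::setNames(out, pat_names)
  })
  hold_cls <- split_by_pattern(hold_recs)
  real_by_label <- stats::setNames(
    lapply(seq_len(nrow(sp$patterns)), function(c) {
      key <- paste(sp$patterns[c, ], collapse = "")
      hold_recs[apply(do.call(rbind, lapply(hold_recs, `[[`, "label")),
                      1L, paste, collapse = "") == key]
    }), pat_names)

  report <- stage("evaluate",
                  evaluate_sets(real_by_label, generated, k = cfg$eval_k))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    all_gen <- unlist(generated, recursive = FALSE)
    write_fasta(all_gen, file.path(cfg$out_dir, "generated.fasta"),
                tags = c(seed = as.character(cfg$seed)))
    jsonlite::write_json(
      list(mmd = report$mmd, mrr = report$mrr, aed = report$aed,
           mean_pairwise_rkhs_distance = report$mean_pairwise_rkhs_distance,
           per_label_mmd = as.list(report$per_label_mmd)),
      file.path(cfg$out_dir, "report.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(gan$log, file.path(cfg$out_dir, "gan_losses.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(
      data.frame(step = seq_along(diffusion$loss_trace),
                 loss = diffusion$loss_trace),
      file.path(cfg$out_dir, "diffusion_losses.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    save_run_config(cfg, file.path(cfg$out_dir, "manifest.yaml"))
  }
  list(report = report, generated = generated, embedder = embedder,
       diffusion = diffusion, gan = gan, config = cfg,
       holdout = real_by_label)
}

#' Ablation runner
#'
#' Mirrors the architecture ablations at reduced scale:
#' \itemize{
#'   \item `no_representation`: one-stage label-only CWGAN-GP baseline
#'     (maps directly from function to sequence) vs the two-stage model,
#'     at equal training budget;
#'   \item `no_classifier`: `beta = 0` vs the configured beta;
#'   \item `beta_sweep`: one run per value in `betas`.
#' }
#' Each variant is trained in segments; after each segment the MMD and MRR
#' of freshly generated sets against held-out reals are recorded, giving
#' step-indexed metric traces.
#'
#' @param cfg an [run_config()].
#' @param mode one of `"no_representation"`, `"no_classifier"`,
#'   `"beta_sweep"`.
#' @param records optional pre-loaded labelled records.
#' @param betas beta values for `beta_sweep`.
#' @param checkpoints number of evaluation checkpoints across the budget.
#' @param n_eval generated sequences per label at each checkpoint.
#' @return Data frame with columns `variant`, `step`, `mmd`, `mrr`; also
#'   written as TSV under `cfg$out_dir` when set.
#' @export
run_ablation <- function(cfg, mode = c("no_representation", "no_classifier",
                                       "beta_sweep"),
                         records = NULL, betas = c(0, 17.5, 175),
                         checkpoints = 4L, n_eval = 50L) {
  mode <- match.arg(mode)
  if (is.character(cfg)) cfg <- load_run_config(cfg)
  so <- seed_offsets(cfg$seed)
  if (is.null(records)) records <- load_labeled_records(cfg)$records
  spec <- encoding_spec(cfg$max_length)
  sp <- split_by_pattern(records)
  idx_hold <- with_seed(so$split, {
    unlist(lapply(unique(sp$cls), function(c) {
      ix <- which(sp$cls == c)
      sample(ix, max(1L, round(cfg$holdout * length(ix))))
    }))
  })
  train_recs <- records[-idx_hold]
  hold_recs <- records[idx_hold]
  pat_names <- apply(sp$patterns, 1L, paste, collapse = "")
  real_by_label <- stats::setNames(
    lapply(seq_len(nrow(sp$patterns)), function(c) {
      key <- pat_names[c]
      hold_recs[vapply(hold_recs, function(r)
        paste(r$label, collapse = "") == key, logical(1))]
    }), pat_names)

  emb_cfg <- cfg$embedder; emb_cfg$seed <- so$embedder
  embedder <- train_embedder(train_recs, emb_cfg, spec)
  Rtr <- extract_representation(embedder, train_recs)
  Ytr <- do.call(rbind, lapply(train_recs, `[[`, "label"))
  dif_cfg <- cfg$diffusion; dif_cfg$seed <- so$diffusion
  diffusion <- train_diffusion(Rtr, Ytr, dif_cfg)

  variants <- switch(mode,
    no_representation = list(two_stage = list(use_r = TRUE),
                             one_stage = list(use_r = FALSE)),
    no_classifier = list(with_classifier = list(beta = cfg$gan$beta),
                         no_classifier = list(beta = 0)),
    beta_sweep = stats::setNames(
      lapply(betas, function(b) list(beta = b)),
      sprintf("beta_%g", betas)))

  seg <- max(1L, cfg$gan$steps %/% checkpoints)
  rows <- list()
  for (vn in names(variants)) {
    gcfg <- cfg$gan
    for (f in names(variants[[vn]])) gcfg[[f]] <- variants[[vn]][[f]]
    gcfg$seed <- so$gan
    gan <- NULL
    done <- 0L
    while (done < cfg$gan$steps) {
      take <- min(seg, cfg$gan$steps - done)
      gan <- train_cwgan(train_recs, embedder, gcfg, spec,
                         resume = gan, steps = take)
      done <- done + take
      gen <- stats::setNames(
        lapply(seq_len(nrow(sp$patterns)), function(c)
          generate_sequences(gan, if (gcfg$use_r) diffusion else NULL,
                             sp$patterns[c, ], n = n_eval,
                             seed = so$generate + c,
                             prefix = sprintf("gen_c%d", c))),
        pat_names)
      gen_f <- lapply(gen, spectrum_features, k = cfg$eval_k)
      real_f <- lapply(real_by_label, spectrum_features, k = cfg$eval_k)
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vn, step = done,
        mmd = mmd(do.call(rbind, gen_f), do.call(rbind, real_f)),
        mrr = as.numeric(mrr(gen_f, real_f)))
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(out,
                       file.path(cfg$out_dir, sprintf("ablation_%s.tsv", mode)),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}
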