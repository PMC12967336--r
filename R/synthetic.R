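## Fixture generator: labelled sequence datasets with planted class motifs
## and per-position conservation, plus Gaussian-mixture latent datasets.
## These emulate the statistical structure of small curated enzyme-family
## datasets (a handful of GO classes, class-specific conserved motifs,
## class-conditional length variation) so every model stage is testable
## offline with known ground truth.

#' Specify a synthetic labelled-sequence fixture
#'
#' Each class plants one motif on an i.i.d. background. Motifs must be
#' pairwise non-substring so class membership is unambiguous. Motif
#' positions default to a fixed, evenly spread per-class offset
#' (conserved-site convention); set `position = "uniform"` for random
#' placement.
#'
#' @param C number of classes.
#' @param n sequences per class.
#' @param L sequence length cap (and default length).
#' @param motifs character vector of `C` motifs over the 20-letter alphabet;
#'   defaults to deterministic distinct 5-mers.
#' @param position `"fixed"` (default) or `"uniform"`.
#' @param background probability vector over the 20 canonical amino acids;
#'   default uniform.
#' @param conservation numeric vector of length `L` in `[0, 1)`: per
#'   position, the probability that the background residue is replaced by
#'   that position's consensus residue (shared across classes), creating
#'   low-entropy columns. Default all 0.
#' @param length_range integer `c(min, max)` sequence lengths drawn
#'   uniformly per record (motif always fits); default `c(L, L)`.
#' @param seed integer seed.
#' @return An `rg_fixture_spec` list.
#' @export
fixture_spec <- function(C = 3, n = 100, L = 40,
                         motifs = NULL, position = c("fixed", "uniform"),
                         background = NULL, conservation = NULL,
                         length_range = NULL, seed = 1L) {
  position <- match.arg(position)
  if (is.null(motifs)) {
    pool <- c("WHKDE", "CMNPQ", "FYTGI", "RLSVA", "DHWEC", "NQFYM",
              "GIKLP", "STVAR", "EWCHD", "MPQCN")
    if (C > length(pool)) stop("supply motifs explicitly for C > 10")
    motifs <- pool[seq_len(C)]
  }
  stopifnot(length(motifs) == C)
  if (any(!grepl(sprintf("^[%s]+$", paste(AA20, collapse = "")), motifs)))
    stop("motifs must use the 20 canonical amino acids")
  if (any(nchar(motifs) >= L)) stop("motif length must be < L")
  for (i in seq_len(C)) for (j in seq_len(C))
    if (i != j && grepl(motifs[i], motifs[j], fixed = TRUE))
      stop("motifs must be pairwise non-substring: '", motifs[i],
           "' occurs in '", motifs[j], "'")
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20, all(background >= 0))
  background <- background / sum(background)
  if (is.null(conservation)) conservation <- rep(0, L)
  stopifnot(length(conservation) == L,
            all(conservation >= 0), all(conservation < 1))
  if (is.null(length_range)) length_range <- c(L, L)
  stopifnot(length(length_range) == 2, length_range[1] >= max(nchar(motifs)),
            length_range[2] <= L, length_range[1] <= length_range[2])
  structure(list(C = as.integer(C), n = as.integer(n), L = as.integer(L),
                 motifs = motifs, position = position,
                 background = background, conservation = conservation,
                 length_range = as.integer(length_range),
                 seed = as.integer(seed)),
            class = "rg_fixture_spec")
}

#' @keywords internal
fixed_motif_positions <- function(spec) {
  ## spread class motifs across the usable span, 1-based start positions
  usable <- spec$length_range[1] - nchar(spec$motifs)
  starts <- round(seq(1, pmax(1, min(usable) + 1), length.out = spec$C + 2))
  pmax(1L, as.integer(starts[2:(spec$C + 1)]))
}

#' Generate a labelled synthetic sequence dataset
#'
#' Background residues are drawn i.i.d. from the background distribution
#' (optionally pulled towards a per-position consensus by the conservation
#' weights), the class motif is planted, and the label is the class one-hot.
#' Generation-time assertions re-check every property other tests rely on:
#' each record contains exactly its class motif, and motifs are absent from
#' off-class backgrounds by anything but chance.
#'
#' @param spec an [fixture_spec()].
#' @return List of `rg_record`s (length `C * n`) with class one-hot labels;
#'   attribute `classes` gives each record's class index and attribute
#'   `motif_starts` the 1-based planted positions.
#' @export
generate_labeled_sequences <- function(spec) {
  stopifnot(inherits(spec, "rg_fixture_spec"))
  with_seed(spec$seed, {
    consensus <- sample(AA20, spec$L, replace = TRUE)
    fixed_pos <- fixed_motif_positions(spec)
    records <- vector("list", spec$C * spec$n)
    classes <- integer(spec$C * spec$n)
    starts <- integer(spec$C * spec$n)
    k <- 0L
    for (c in seq_len(spec$C)) {
      motif <- spec$motifs[c]
      mlen <- nchar(motif)
      for (i in seq_len(spec$n)) {
        k <- k + 1L
        len <- if (spec$length_range[1] == spec$length_range[2])
          spec$length_range[1]
        else sample(spec$length_range[1]:spec$length_range[2], 1L)
        bg <- sample(AA20, len, replace = TRUE, prob = spec$background)
        cons_hit <- stats::runif(len) < spec$conservation[seq_len(len)]
        bg[cons_hit] <- consensus[seq_len(len)][cons_hit]
        pos <- if (spec$position == "fixed") min(fixed_pos[c], len - mlen + 1L)
        else sample.int(len - mlen + 1L, 1L)
        bg[pos:(pos + mlen - 1L)] <- strsplit(motif, "")[[1]]
        res <- paste(bg, collapse = "")
        ## re-plant if a chance copy of another class motif appeared
        tries <- 0L
        while (any(vapply(spec$motifs[-c], grepl, logical(1), x = res,
                          fixed = TRUE)) && tries < 20L) {
          bg <- sample(AA20, len, replace = TRUE, prob = spec$background)
          cons_hit <- stats::runif(len) < spec$conservation[seq_len(len)]
          bg[cons_hit] <- consensus[seq_len(len)][cons_hit]
          bg[pos:(pos + mlen - 1L)] <- strsplit(motif, "")[[1]]
          res <- paste(bg, collapse = "")
          tries <- tries + 1L
        }
        label <- numeric(spec$C); label[c] <- 1
        records[[k]] <- sequence_record(sprintf("class%d_seq%03d", c, i),
                                        res, label)
        classes[k] <- c
        starts[k] <- pos
        stopifnot(grepl(motif, res, fixed = TRUE))
      }
    }
    attr(records, "classes") <- classes
    attr(records, "motif_starts") <- starts
    attr(records, "spec") <- spec
    records
  })
}

#' Generate a Gaussian-mixture latent dataset
#'
#' Unit-test bed for the latent diffusion stage: representations are drawn
#' from `Normal(mean_c, noise_sd^2 I)` with class one-hot labels. Class
#' means should be pairwise separated by more than `4 * noise_sd` for
#' parameter-recovery tests to be meaningful; this is asserted.
#'
#' @param C classes; @param n draws per class; @param m latent dimension.
#' @param class_means C-by-m matrix (default: `sep * I`-style spread).
#' @param noise_sd isotropic noise standard deviation.
#' @param seed integer seed.
#' @return `list(r, y, class)`: n*C-by-m latent matrix, n*C-by-C one-hot
#'   label matrix, integer class index.
#' @export
generate_latent_dataset <- function(C = 4, n = 200, m = 4,
                                    class_means = NULL, noise_sd = 0.1,
                                    seed = 1L) {
  if (is.null(class_means)) {
    class_means <- matrix(0, C, m)
    for (c in seq_len(C)) class_means[c, ((c - 1L) %% m) + 1L] <- 5 * ((c - 1L) %/% m + 1L)
  }
  stopifnot(nrow(class_means) == C, ncol(class_means) == m)
  if (C > 1) {
    dmin <- min(stats::dist(class_means))
    if (dmin <= 4 * noise_sd)
      stop("class means must be separated by > 4 * noise_sd (min distance ",
           signif(dmin, 3), ")")
  }
  with_seed(seed, {
    if (n == 0L)
      return(list(r = matrix(0, 0, m), y = matrix(0, 0, C),
                  class = integer(0)))
    cls <- rep(seq_len(C), each = n)
    r <- class_means[cls, , drop = FALSE] +
      matrix(stats::rnorm(length(cls) * m, sd = noise_sd), length(cls), m)
    y <- matrix(0, length(cls), C)
    y[cbind(seq_along(cls), cls)] <- 1
    list(r = r, y = y, class = cls)
  })
}

#' Write a fixture to FASTA + label TSV
#'
#' Emits the standard on-disk form so fixtures flow through the public
#' interface unchanged. The label vocabulary is synthetic GO-style IDs, one
#' per class.
#'
#' @param records output of [generate_labeled_sequences()].
#' @param fasta,labels output paths.
#' @return Character vector of the synthetic GO vocabulary, invisibly.
#' @export
write_fixture <- function(records, fasta, labels) {
  C <- length(records[[1]]$label)
  vocab <- sprintf("GO:%07d", seq_len(C))
  write_fasta(records, fasta)
  lines <- vapply(records, function(r) {
    paste(r$id, paste(vocab[r$label == 1], collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(lines, labels)
  invisible(vocab)
}
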