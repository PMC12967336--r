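## Shared data layer: alphabet/encoding definitions, FASTA and label-table
## I/O, one-hot padding. Positions are 0-based internally where arithmetic
## needs them; every user-facing report is 1-based.

#' The 20 canonical amino acids
#' @keywords internal
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Create an encoding specification
#'
#' Defines the model's sequence space: an ordered alphabet of `A` symbols, a
#' maximum length `L` (sequences are padded up to it), and which symbol is
#' the pad. The default alphabet is the 20 canonical amino acids plus `"X"`,
#' which doubles as the unknown-residue symbol and the pad, giving A = 21.
#'
#' @param max_length maximum sequence length L in residues.
#' @param alphabet ordered character vector of unique single-character
#'   symbols.
#' @param pad_symbol one member of `alphabet` used for padding.
#' @return An object of class `rg_encoding`: list with `alphabet`, `A`,
#'   `max_length`, `pad_symbol`, `pad_index`.
#' @examples
#' spec <- encoding_spec(max_length = 2048)
#' spec$A * spec$max_length  # flattened one-hot dimension: 43008
#' @export
encoding_spec <- function(max_length, alphabet = c(AA20, "X"),
                          pad_symbol = "X") {
  alphabet <- as.character(alphabet)
  if (anyDuplicated(alphabet))
    stop("alphabet symbols must be unique")
  if (any(nchar(alphabet) != 1L))
    stop("alphabet symbols must be single characters")
  if (!pad_symbol %in% alphabet)
    stop("pad_symbol must be a member of the alphabet")
  stopifnot(is.numeric(max_length), max_length >= 1)
  structure(list(
    alphabet = alphabet,
    A = length(alphabet),
    max_length = as.integer(max_length),
    pad_symbol = pad_symbol,
    pad_index = match(pad_symbol, alphabet)
  ), class = "rg_encoding")
}

#' Create a sequence record
#'
#' @param id record identifier (FASTA header token).
#' @param residues residue string (non-pad alphabet symbols).
#' @param label optional numeric 0/1 annotation vector.
#' @return An `rg_record` list.
#' @export
sequence_record <- function(id, residues, label = NULL) {
  structure(list(id = as.character(id), residues = as.character(residues),
                 label = label), class = "rg_record")
}

#' @keywords internal
check_record <- function(record, spec, truncate = FALSE) {
  res <- record$residues
  n <- nchar(res)
  if (n < 1L) stop("record '", record$id, "' has an empty residue string")
  if (n > spec$max_length) {
    if (!truncate)
      stop("record '", record$id, "' has length ", n,
           " > max_length ", spec$max_length,
           " (set truncate = TRUE to cut it)")
    record$residues <- substr(res, 1L, spec$max_length)
  }
  record
}

#' One-hot encode a sequence record
#'
#' Row i of the result is the indicator of residue i; rows past the true
#' sequence length carry the pad indicator, so every row sums to exactly 1
#' and the flattened dimension is `L * A`.
#'
#' @param record an [sequence_record()] (or a bare residue string).
#' @param spec an [encoding_spec()].
#' @param truncate cut sequences longer than `L` instead of erroring?
#' @return L-by-A 0/1 matrix of class `rg_onehot` with attribute
#'   `true_length`.
#' @export
one_hot_encode <- function(record, spec, truncate = FALSE) {
  if (is.character(record)) record <- sequence_record("seq", record)
  record <- check_record(record, spec, truncate)
  chars <- strsplit(record$residues, "", fixed = TRUE)[[1]]
  idx <- match(chars, spec$alphabet)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop("cannot encode record '", record$id, "': residue '", chars[bad],
         "' at position ", bad, " is not in the alphabet")
  }
  n <- length(idx)
  M <- matrix(0, spec$max_length, spec$A,
              dimnames = list(NULL, spec$alphabet))
  M[cbind(seq_len(n), idx)] <- 1
  if (n < spec$max_length)
    M[(n + 1L):spec$max_length, spec$pad_index] <- 1
  structure(M, true_length = n, class = c("rg_onehot", "matrix", "array"))
}

#' Decode a one-hot (or relaxed probability) matrix back to residues
#'
#' Takes the per-row argmax symbol; ties are broken towards the lowest
#' alphabet index. Decoding stops at the first pad row; trailing pads are
#' stripped. An all-pad matrix decodes to an empty residue string and is
#' flagged degenerate.
#'
#' @param x L-by-A numeric matrix.
#' @param spec an [encoding_spec()].
#' @param id identifier for the returned record.
#' @return An `rg_record`; attribute `degenerate` is `TRUE` when the decoded
#'   string is empty.
#' @export
one_hot_decode <- function(x, spec, id = "decoded") {
  x <- unclass(x)
  stopifnot(is.matrix(x), ncol(x) == spec$A)
  if (any(rowSums(abs(x)) == 0))
    stop("cannot decode: row ", which(rowSums(abs(x)) == 0)[1],
         " is all zeros")
  idx <- max.col(x, ties.method = "first")
  first_pad <- which(idx == spec$pad_index)[1]
  keep <- if (is.na(first_pad)) seq_along(idx) else seq_len(first_pad - 1L)
  residues <- paste(spec$alphabet[idx[keep]], collapse = "")
  rec <- sequence_record(id, residues)
  attr(rec, "degenerate") <- nchar(residues) == 0L
  rec
}

## --- FASTA --------------------------------------------------------------

#' Read amino-acid sequences from a FASTA file
#'
#' Wraps [Biostrings::readAAStringSet()]. The first whitespace-delimited
#' header token becomes the record ID. Lowercase residues are uppercased;
#' characters outside the encoding alphabet (e.g. ambiguity codes B, Z) are
#' mapped to the unknown symbol with a warning. Gzip input is accepted.
#'
#' @param path FASTA file.
#' @param spec an [encoding_spec()]; used for alphabet normalisation.
#' @return List of `rg_record`s (labels absent).
#' @export
read_fasta <- function(path, spec = encoding_spec(2048)) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("FASTA file is empty: ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(ss))
  core <- setdiff(spec$alphabet, spec$pad_symbol)
  ok <- paste0(c(core, spec$pad_symbol), collapse = "")
  n_bad <- 0L
  seqs <- vapply(seqs, function(s) {
    bad <- gsub(sprintf("[%s]", ok), "", s)
    if (nchar(bad) > 0L) {
      n_bad <<- n_bad + nchar(bad)
      s <- gsub(sprintf("[^%s]", ok), spec$pad_symbol, s)
    }
    s
  }, character(1), USE.NAMES = FALSE)
  if (n_bad > 0L)
    warning(n_bad, " residue(s) outside the alphabet were mapped to '",
            spec$pad_symbol, "'")
  recs <- mapply(sequence_record, ids, seqs, SIMPLIFY = FALSE,
                 USE.NAMES = FALSE)
  for (i in seq_along(recs)) recs[[i]]$desc <- names(ss)[i]
  recs
}

#' Write sequence records to FASTA
#'
#' 60-column wrapping; labels (if any) are appended to the header as a
#' `label=` tag so generated sets round-trip through standard tools.
#'
#' @param records list of `rg_record`s.
#' @param path output file.
#' @param tags optional named character vector of extra `key=value` header
#'   tags applied to every record.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, tags = NULL) {
  headers <- vapply(records, function(r) {
    h <- r$id
    if (!is.null(r$label))
      h <- paste0(h, " label=", paste(as.integer(r$label), collapse = ""))
    if (length(tags))
      h <- paste0(h, " ", paste(names(tags), tags, sep = "=", collapse = " "))
    h
  }, character(1))
  ss <- Biostrings::AAStringSet(vapply(records, `[[`, character(1), "residues"))
  names(ss) <- headers
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

## --- label table --------------------------------------------------------

#' Read a GO-annotation label table
#'
#' Expects a two-column TSV (`id<TAB>GO:...;GO:...`; header optional with
#' columns named `id` and `go`). Each row becomes a multi-hot vector over
#' `vocabulary`; GO IDs outside the vocabulary are dropped with one warning
#' giving the dropped count. An empty GO field yields a zero vector
#' (unannotated).
#'
#' @param path TSV file.
#' @param vocabulary ordered character vector of GO-term IDs defining the
#'   label dimension d.
#' @return Named list mapping id to numeric 0/1 vector of length
#'   `length(vocabulary)`.
#' @export
read_label_table <- function(path, vocabulary) {
  if (!file.exists(path)) stop("label table not found: ", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          colClasses = "character", quote = "",
                          blank.lines.skip = TRUE)
  if (ncol(df) < 2L) stop("label table must have two tab-separated columns")
  if (tolower(df[1, 1]) == "id") df <- df[-1, , drop = FALSE]
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate IDs in label table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  dropped <- 0L
  out <- lapply(df[[2]], function(field) {
    v <- numeric(length(vocabulary))
    terms <- strsplit(field, ";", fixed = TRUE)[[1]]
    terms <- trimws(terms[nzchar(trimws(terms))])
    hit <- match(terms, vocabulary)
    dropped <<- dropped + sum(is.na(hit))
    v[hit[!is.na(hit)]] <- 1
    v
  })
  if (dropped > 0L)
    warning(dropped, " GO ID(s) not in the vocabulary were dropped")
  names(out) <- ids
  out
}

#' Attach labels to sequence records
#'
#' @param records list of `rg_record`s.
#' @param labels named list from [read_label_table()].
#' @return The records with `label` filled in. IDs present in the records
#'   but absent from the table raise an error listing the orphans.
#' @export
join_labels <- function(records, labels) {
  ids <- vapply(records, `[[`, character(1), "id")
  orphans <- setdiff(ids, names(labels))
  if (length(orphans))
    stop("records with no label-table entry: ",
         paste(orphans, collapse = ", "))
  lapply(records, function(r) { r$label <- labels[[r$id]]; r })
}
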