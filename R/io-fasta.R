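#' Parse FASTA text into sequence records
#'
#' Accepts wrapped or unwrapped sequence lines. The header token before the
#' first whitespace becomes the record id. Sequences are upper-cased on read
#' and validated against the declared alphabet; in DNA, `U` is mapped to `T`
#' with a warning. Parsing round-trips through [write_fasta()] bit-identically
#' modulo line wrapping.
#'
#' @param text FASTA-formatted character scalar (or vector of lines).
#' @param alphabet One of `"dna"`, `"protein"`, `"binary"`.
#' @return List of `seq_record` objects, one per header.
#' @export
parse_fasta <- function(text, alphabet = "dna") {
  alphabet <- match.arg(alphabet, names(.alphabets))
  if (length(text) == 1L) text <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  tf <- tempfile(fileext = ".fasta")
  on.exit(unlink(tf))
  writeLines(text, tf)
  read_fasta(tf, alphabet)
}

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @inheritParams parse_fasta
#' @return List of `seq_record` objects.
#' @export
read_fasta <- function(path, alphabet = "dna") {
  alphabet <- match.arg(alphabet, names(.alphabets))
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("failed to parse FASTA: ",
                                           conditionMessage(e)))
  if (!length(set)) stop("FASTA input contains no records")
  ids <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  Map(function(id, s) seq_record(id, s, alphabet), ids, unname(seqs))
}

#' Write sequence records or an alignment to FASTA
#'
#' @param x List of `seq_record` objects or an `alignment`.
#' @param path Output path.
#' @param width Line-wrap width (default 60 characters).
#' @return Invisibly, the path.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (inherits(x, "alignment")) {
    ids <- x$ids
    seqs <- apply(x$mat, 1L, paste, collapse = "")
  } else {
    ids <- vapply(x, `[[`, "", "id")
    seqs <- vapply(x, `[[`, "", "seq")
  }
  set <- Biostrings::BStringSet(seqs)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Convert FASTA records to an alignment
#'
#' @param records List of `seq_record` objects of equal length.
#' @param alphabet Alphabet tag; taken from records if omitted.
#' @return An `alignment`.
#' @export
records_to_alignment <- function(records, alphabet = NULL) {
  new_alignment(records, alphabet)
}
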