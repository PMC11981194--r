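# Alphabet definitions shared by parsers and the alignment container.
# DNA allows N (ambiguous) and '-' (gap); protein allows X and '-';
# binary is the presence/absence recoding used for indel reconstruction.
.alphabets <- list(
  dna     = c("A", "C", "G", "T", "N", "-"),
  protein = c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
              "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y", "X", "-"),
  binary  = c("0", "1")
)

#' Alphabet symbol set
#'
#' Returns the allowed symbols for one of the three sequence alphabets used
#' throughout the package.
#'
#' @param alphabet One of `"dna"`, `"protein"`, `"binary"`.
#' @return Character vector of allowed single-character symbols.
#' @export
alphabet_symbols <- function(alphabet) {
  alphabet <- match.arg(alphabet, names(.alphabets))
  .alphabets[[alphabet]]
}

#' Create a sequence record
#'
#' A sequence record is the atomic unit handled by the I/O layer: a unique
#' identifier plus a sequence string over a declared alphabet. Sequences are
#' case-normalized to upper case; in DNA, `U` is mapped to `T` with a warning.
#'
#' @param id Non-empty identifier without whitespace.
#' @param seq Non-empty sequence string.
#' @param alphabet One of `"dna"`, `"protein"`, `"binary"`.
#' @return A list with class `seq_record` and elements `id`, `seq`,
#'   `alphabet`.
#' @export
seq_record <- function(id, seq, alphabet = "dna") {
  alphabet <- match.arg(alphabet, names(.alphabets))
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("record id must be a single non-empty string")
  if (grepl("[[:space:]]", id))
    stop("record id must not contain whitespace: ", sQuote(id))
  if (!is.character(seq) || length(seq) != 1L || !nzchar(seq))
    stop("sequence for ", sQuote(id), " must be a non-empty string")
  seq <- toupper(seq)
  if (alphabet == "dna" && grepl("U", seq, fixed = TRUE)) {
    warning("sequence ", sQuote(id), ": 'U' mapped to 'T'")
    seq <- gsub("U", "T", seq, fixed = TRUE)
  }
  .check_alphabet(seq, alphabet, id)
  structure(list(id = id, seq = seq, alphabet = alphabet),
            class = "seq_record")
}

.check_alphabet <- function(seq, alphabet, id) {
  allowed <- .alphabets[[alphabet]]
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% allowed))
  if (length(bad)) {
    stop("sequence ", sQuote(id), ": character ", sQuote(chars[bad[1L]]),
         " at position ", bad[1L], " is not in the ", alphabet, " alphabet")
  }
  invisible(TRUE)
}

#' Build an alignment from sequence records
#'
#' An alignment is an ordered set of equal-length sequence records over one
#' alphabet, stored internally as a character matrix (rows = sequences,
#' columns = alignment columns) for fast column-wise operations.
#'
#' @param records List of `seq_record` objects (or a named character vector
#'   of sequences).
#' @param alphabet Alphabet tag; taken from the records if omitted.
#' @return An object of class `alignment` with fields `ids`, `mat` (character
#'   matrix) and `alphabet`.
#' @export
new_alignment <- function(records, alphabet = NULL) {
  if (is.character(records)) {
    if (is.null(names(records)) || anyNA(names(records)))
      stop("a character vector of sequences must be named by id")
    records <- Map(function(id, s) seq_record(id, s, alphabet %||% "dna"),
                   names(records), unname(records))
  }
  if (!length(records)) stop("alignment must contain at least one sequence")
  ids <- vapply(records, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate sequence ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (is.null(alphabet)) alphabet <- records[[1L]]$alphabet
  seqs <- vapply(records, `[[`, "", "seq")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("aligned sequences must have equal length (found lengths ",
         paste(unique(lens), collapse = ", "), ")")
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  structure(list(ids = ids, mat = mat, alphabet = alphabet),
            class = "alignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.alignment <- function(x, ...) {
  cat("<alignment> ", length(x$ids), " sequences x ", ncol(x$mat),
      " columns (", x$alphabet, ")\n", sep = "")
  invisible(x)
}

#' Number of alignment columns
#' @param aln An `alignment`.
#' @return Integer column count.
#' @export
n_columns <- function(aln) ncol(aln$mat)

#' Extract one row of an alignment as a string
#' @param aln An `alignment`.
#' @param id Sequence identifier.
#' @return Single sequence string (with gaps).
#' @export
aln_sequence <- function(aln, id) {
  i <- match(id, aln$ids)
  if (is.na(i)) stop("id ", sQuote(id), " not present in alignment")
  paste(aln$mat[i, ], collapse = "")
}

#' Remove gap characters from a sequence string
#' @param seq Sequence string.
#' @return The string with all `-` removed.
#' @export
ungap <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Mark an alignment as a codon alignment
#'
#' A codon alignment is a DNA alignment whose column count is divisible by
#' three and in which every gap run within a row covers whole codons (length
#' divisible by three, starting at a codon boundary). Ungapping any row must
#' reproduce its source coding sequence exactly.
#'
#' @param aln A DNA `alignment`.
#' @param col_map Optional integer vector mapping current columns back to the
#'   original (untrimmed) column indices; defaults to `1:n_columns`.
#' @return The alignment with class `c("codon_alignment", "alignment")` and
#'   a `col_map` field.
#' @export
as_codon_alignment <- function(aln, col_map = NULL) {
  stopifnot(inherits(aln, "alignment"))
  if (aln$alphabet != "dna") stop("codon alignment must use the dna alphabet")
  L <- ncol(aln$mat)
  if (L %% 3L != 0L)
    stop("codon alignment length must be divisible by 3 (got ", L, ")")
  if (is.null(col_map)) col_map <- seq_len(L)
  if (length(col_map) != L) stop("col_map length must equal column count")
  for (i in seq_along(aln$ids)) {
    .check_codon_gaps(aln$mat[i, ], aln$ids[i])
  }
  aln$col_map <- col_map
  class(aln) <- c("codon_alignment", "alignment")
  aln
}

.check_codon_gaps <- function(chars, id) {
  isgap <- chars == "-"
  if (!any(isgap)) return(invisible(TRUE))
  r <- rle(isgap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  bad <- r$values & (r$lengths %% 3L != 0L | (starts - 1L) %% 3L != 0L)
  if (any(bad))
    stop("row ", sQuote(id), ": gap run at column ", starts[which(bad)[1L]],
         " does not cover whole codons")
  invisible(TRUE)
}
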