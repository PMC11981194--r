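#' Per-column information matrix for sequence logos
#'
#' For each alignment column, symbol frequencies `f` are computed over
#' non-gap (and non-ambiguous) characters; the column information content
#' is `IC = log2(|alphabet|) - H` with `H = -sum(f * log2(f))`, and each
#' symbol's entry is `f * IC` bits. No pseudocount or small-sample
#' correction is applied. Columns with no countable characters are emitted
#' as zeros with a warning.
#'
#' @param aln An `alignment` (protein or DNA).
#' @param alphabet Symbols counted per column; defaults to the 20 residues
#'   (protein) or 4 nucleotides (DNA), i.e. gaps, `X` and `N` are excluded
#'   from the frequencies.
#' @return Numeric matrix (columns x symbols) of information contributions
#'   in bits, with per-column totals in attribute `column_ic`.
#' @export
information_matrix <- function(aln, alphabet = NULL) {
  stopifnot(inherits(aln, "alignment"))
  if (is.null(alphabet)) {
    alphabet <- switch(aln$alphabet,
                       protein = setdiff(.alphabets$protein, c("X", "-")),
                       dna = c("A", "C", "G", "T"),
                       stop("supply the alphabet for ", aln$alphabet,
                            " alignments"))
  }
  L <- ncol(aln$mat)
  k <- length(alphabet)
  M <- matrix(0, L, k, dimnames = list(as.character(seq_len(L)), alphabet))
  ic <- numeric(L)
  empty <- logical(L)
  for (j in seq_len(L)) {
    chars <- aln$mat[, j]
    chars <- chars[chars %in% alphabet]
    if (!length(chars)) {
      empty[j] <- TRUE
      next
    }
    f <- table(factor(chars, levels = alphabet)) / length(chars)
    f <- as.numeric(f)
    H <- -sum(ifelse(f > 0, f * log2(f), 0))
    ic[j] <- log2(k) - H
    M[j, ] <- f * ic[j]
  }
  if (any(empty))
    warning(sum(empty), " column(s) with no countable characters ",
            "emitted as zeros")
  structure(M, column_ic = ic)
}
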