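.stop_codons <- c("TAA", "TAG", "TGA")

split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Filter coding sequences before ancestral reconstruction
#'
#' Applies the pre-reconstruction quality filters in a fixed order:
#' (1) drop records whose length is not a multiple of three; (2) drop records
#' with an internal stop codon; (3) strip one terminal stop codon if present;
#' (4) keep records whose post-stripping length lies in
#' `[min_len, max_len]` inclusive. Nothing raises an error: every problem
#' becomes a rejection recorded in the report.
#'
#' @param records List of DNA `seq_record` objects.
#' @param min_len,max_len Inclusive length bounds applied after stop
#'   stripping (defaults 2400 and 2800 nucleotides, the full-length helper
#'   NLR window).
#' @return List with `records` (kept, possibly stop-stripped) and `report`,
#'   a `filter_report`: `kept` ids, `rejected` data frame (id, reason with
#'   reason in internal_stop / not_multiple_of_three / length_out_of_range),
#'   and `trimmed_terminal_stop` ids.
#' @export
filter_cds <- function(records, min_len = 2400L, max_len = 2800L) {
  stopifnot(min_len <= max_len)
  kept <- list()
  rejected_id <- character()
  rejected_reason <- character()
  trimmed <- character()
  for (rec in records) {
    if (rec$alphabet != "dna") stop("filter_cds expects DNA records")
    n <- nchar(rec$seq)
    if (n %% 3L != 0L) {
      rejected_id <- c(rejected_id, rec$id)
      rejected_reason <- c(rejected_reason, "not_multiple_of_three")
      next
    }
    codons <- split_codons(rec$seq)
    internal <- codons[-length(codons)] %in% .stop_codons
    if (any(internal)) {
      rejected_id <- c(rejected_id, rec$id)
      rejected_reason <- c(rejected_reason, "internal_stop")
      next
    }
    if (codons[length(codons)] %in% .stop_codons) {
      rec$seq <- substr(rec$seq, 1L, n - 3L)
      trimmed <- c(trimmed, rec$id)
      if (!nzchar(rec$seq)) {
        # a lone stop codon strips to nothing: too short by construction
        rejected_id <- c(rejected_id, rec$id)
        rejected_reason <- c(rejected_reason, "length_out_of_range")
        next
      }
    }
    L <- nchar(rec$seq)
    if (L < min_len || L > max_len) {
      rejected_id <- c(rejected_id, rec$id)
      rejected_reason <- c(rejected_reason, "length_out_of_range")
      next
    }
    kept <- c(kept, list(rec))
  }
  report <- structure(
    list(kept = vapply(kept, `[[`, "", "id"),
         rejected = data.frame(id = rejected_id, reason = rejected_reason,
                               stringsAsFactors = FALSE),
         trimmed_terminal_stop = trimmed),
    class = "filter_report")
  list(records = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> kept ", length(x$kept), ", rejected ",
      nrow(x$rejected), ", terminal stops stripped ",
      length(x$trimmed_terminal_stop), "\n", sep = "")
  invisible(x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' Codons containing `N` translate to `X`. A stop codon anywhere signals
#' that [filter_cds()] was skipped and raises an error.
#'
#' @param record A DNA `seq_record` with length a multiple of three.
#' @return A protein `seq_record` with the same id.
#' @export
translate_cds <- function(record) {
  stopifnot(inherits(record, "seq_record"))
  if (record$alphabet != "dna") stop("translate_cds expects a DNA record")
  if (nchar(record$seq) %% 3L != 0L)
    stop("sequence ", sQuote(record$id), " length is not a multiple of 3")
  codons <- split_codons(record$seq)
  if (any(codons %in% .stop_codons)) {
    i <- which(codons %in% .stop_codons)[1L]
    stop("sequence ", sQuote(record$id), " has a stop codon at codon ", i,
         "; run filter_cds first")
  }
  code <- Biostrings::GENETIC_CODE
  aa <- code[codons]
  aa[is.na(aa)] <- "X"   # any codon with N (or other ambiguity)
  seq_record(record$id, paste(aa, collapse = ""), "protein")
}

#' Thread coding sequences onto a protein alignment
#'
#' Replaces each aligned residue with its source codon and each protein gap
#' with `---`, producing a frame-preserving codon alignment. For every row,
#' the translation of the CDS must equal the degapped protein row (with `X`
#' matching any residue).
#'
#' @param protein_aln Protein `alignment`.
#' @param cds List of DNA `seq_record` objects covering every aligned id.
#' @return A `codon_alignment`; ungapping any row reproduces its CDS exactly.
#' @export
thread_codons <- function(protein_aln, cds) {
  stopifnot(inherits(protein_aln, "alignment"))
  if (protein_aln$alphabet != "protein")
    stop("thread_codons expects a protein alignment")
  cds_ids <- vapply(cds, `[[`, "", "id")
  rows <- character(length(protein_aln$ids))
  for (i in seq_along(protein_aln$ids)) {
    id <- protein_aln$ids[i]
    j <- match(id, cds_ids)
    if (is.na(j)) stop("no CDS provided for aligned id ", sQuote(id))
    prot_chars <- protein_aln$mat[i, ]
    residues <- prot_chars[prot_chars != "-"]
    codons <- split_codons(cds[[j]]$seq)
    if (length(codons) != length(residues))
      stop("CDS ", sQuote(id), " encodes ", length(codons),
           " codons but the aligned row has ", length(residues), " residues")
    trans <- translate_cds(cds[[j]])
    trans_chars <- strsplit(trans$seq, "", fixed = TRUE)[[1L]]
    mism <- which(trans_chars != residues & trans_chars != "X" &
                    residues != "X")
    if (length(mism))
      stop("translation mismatch for ", sQuote(id), " at residue ", mism[1L],
           ": CDS encodes ", trans_chars[mism[1L]], ", alignment has ",
           residues[mism[1L]])
    out <- rep("---", length(prot_chars))
    out[prot_chars != "-"] <- codons
    rows[i] <- paste(out, collapse = "")
  }
  names(rows) <- protein_aln$ids
  aln <- new_alignment(rows, "dna")
  as_codon_alignment(aln)
}

#' Remove gappy alignment columns
#'
#' A column is removed iff its gap fraction is strictly greater than `g`.
#' For codon alignments the unit of removal is the codon triple, removed iff
#' the pooled gap fraction over its three columns exceeds `g`, so the
#' reading frame stays intact.
#'
#' @param aln An `alignment` or `codon_alignment`.
#' @param g Gap-fraction threshold in `[0, 1]` (default 0.9).
#' @return List with `alignment` (same class as the input) and `col_map`,
#'   the retained original column indices.
#' @export
trim_gappy_columns <- function(aln, g = 0.9) {
  stopifnot(inherits(aln, "alignment"), g >= 0, g <= 1)
  gapfrac <- colMeans(aln$mat == "-")
  if (inherits(aln, "codon_alignment")) {
    L <- ncol(aln$mat)
    triple <- rep(seq_len(L / 3L), each = 3L)
    pooled <- tapply(gapfrac, triple, mean)
    keep_triple <- pooled <= g
    keep <- keep_triple[triple]
  } else {
    keep <- gapfrac <= g
  }
  keep <- as.logical(keep)
  if (!any(keep)) stop("trimming at g = ", g, " removes every column")
  old_map <- if (!is.null(aln$col_map)) aln$col_map else seq_len(ncol(aln$mat))
  out <- aln
  out$mat <- aln$mat[, keep, drop = FALSE]
  col_map <- old_map[keep]
  if (inherits(aln, "codon_alignment")) {
    out$col_map <- col_map
    out <- as_codon_alignment(unclass_alignment(out), col_map)
  }
  list(alignment = out, col_map = col_map)
}

unclass_alignment <- function(aln) {
  structure(list(ids = aln$ids, mat = aln$mat, alphabet = aln$alphabet),
            class = "alignment")
}

#' Remove duplicate sequences
#'
#' Exact full-length string equality (after upper-casing) defines
#' duplicates; the first occurrence in input order is the retained
#' representative. Reverse-complement matching is not performed.
#'
#' @param x An `alignment` or list of `seq_record` objects.
#' @return List with `records` (or `alignment`) of representatives in input
#'   order and `clusters`, a named list mapping representative id to all
#'   member ids.
#' @export
deduplicate <- function(x) {
  if (inherits(x, "alignment")) {
    seqs <- apply(x$mat, 1L, paste, collapse = "")
    ids <- x$ids
  } else {
    seqs <- toupper(vapply(x, `[[`, "", "seq"))
    ids <- vapply(x, `[[`, "", "id")
  }
  first <- !duplicated(seqs)
  rep_of <- ids[first][match(seqs, seqs[first])]
  clusters <- split(ids, factor(rep_of, levels = ids[first]))
  if (inherits(x, "alignment")) {
    out <- x
    out$ids <- ids[first]
    out$mat <- x$mat[first, , drop = FALSE]
    if (inherits(x, "codon_alignment"))
      out <- as_codon_alignment(unclass_alignment(out), x$col_map)
    list(alignment = out, clusters = clusters)
  } else {
    list(records = x[first], clusters = clusters)
  }
}

#' Apply manual alignment patches
#'
#' Generic representation of curated single-position edits: each patch is a
#' row (id, position, replacement), with `position` the alignment column,
#' applied before codon threading.
#'
#' @param aln An `alignment`.
#' @param patches Data frame with columns `id`, `position`, `replacement`.
#' @return The patched alignment.
#' @export
apply_patches <- function(aln, patches) {
  stopifnot(inherits(aln, "alignment"),
            all(c("id", "position", "replacement") %in% names(patches)))
  for (k in seq_len(nrow(patches))) {
    i <- match(patches$id[k], aln$ids)
    if (is.na(i)) stop("patch id ", sQuote(patches$id[k]), " not in alignment")
    p <- patches$position[k]
    if (p < 1L || p > ncol(aln$mat))
      stop("patch position ", p, " outside alignment columns")
    repl <- toupper(patches$replacement[k])
    if (nchar(repl) != 1L || !(repl %in% .alphabets[[aln$alphabet]]))
      stop("patch replacement must be one symbol of the ", aln$alphabet,
           " alphabet")
    aln$mat[i, p] <- repl
  }
  aln
}
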