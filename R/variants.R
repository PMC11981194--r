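#' Map reference residue positions to alignment columns
#'
#' The k-th non-gap residue of the reference row corresponds to one
#' alignment column; requested 1-based residue positions are translated to
#' those columns. This is how interface positions numbered on a reference
#' receptor are located in the alignment.
#'
#' @param aln An `alignment` containing the reference sequence.
#' @param reference_id Id of the reference row.
#' @param positions 1-based residue indices on the ungapped reference.
#' @return Integer alignment columns, named by position.
#' @export
map_reference_positions <- function(aln, reference_id, positions) {
  stopifnot(inherits(aln, "alignment"))
  i <- match(reference_id, aln$ids)
  if (is.na(i)) stop("reference id ", sQuote(reference_id),
                     " not in alignment")
  nongap <- which(aln$mat[i, ] != "-")
  positions <- as.integer(positions)
  bad <- positions < 1L | positions > length(nongap)
  if (any(bad))
    stop("position ", positions[which(bad)[1L]], " outside the ",
         length(nongap), "-residue reference ", sQuote(reference_id))
  stats::setNames(nongap[positions], positions)
}

#' Residue positions spanned by interface regions
#'
#' @param regions Data frame with columns `label`, `start`, `end` (1-based
#'   inclusive reference residue indices), as produced by
#'   [cluster_regions()].
#' @return Integer vector of all residue positions covered.
#' @export
region_positions <- function(regions) {
  stopifnot(all(c("start", "end") %in% names(regions)))
  unlist(Map(seq.int, regions$start, regions$end), use.names = FALSE)
}

#' Enumerate alternative ancestral variants at selected positions
#'
#' At each selected position, candidate states are all states with
#' posterior probability strictly greater than `threshold`; where no state
#' exceeds it, the single maximum-a-posteriori state is taken with a
#' warning. Variants are the Cartesian product of candidates across
#' positions, ordered by joint probability (product of the chosen state
#' probabilities) descending, truncated at `max_variants` with a warning,
#' and labelled `anc<node>.<k>` by rank.
#'
#' @param residues A `posterior_table` over residues (e.g. from
#'   [residue_posteriors()]).
#' @param columns Sites of the table to use (e.g. mapped interface
#'   columns), in reporting order.
#' @param nodes Node ids to enumerate (default: all nodes in the table).
#' @param threshold Ambiguity threshold on the posterior (default 0.3).
#' @param max_variants Cap on enumerated variants per node (default 16).
#' @return Object of class `ancestral_variants`: a data frame with columns
#'   `node`, `label`, `sequence`, `probability`, plus attribute `states`
#'   (per-node list of per-position candidate state/probability tables).
#' @export
call_variants <- function(residues, columns, nodes = NULL, threshold = 0.3,
                          max_variants = 16L) {
  stopifnot(inherits(residues, "posterior_table"),
            threshold > 0, threshold < 1)
  if (!length(columns)) stop("no positions selected")
  if (is.null(nodes)) nodes <- pt_nodes(residues)
  sites <- dimnames(residues)[[2L]]
  cols <- match(as.character(columns), sites)
  if (anyNA(cols))
    stop("columns not present in the posterior table: ",
         paste(columns[is.na(cols)], collapse = ", "))
  states <- pt_states(residues)
  out <- list()
  cand_info <- list()
  for (nd in nodes) {
    cand <- lapply(cols, function(j) {
      p <- residues[nd, j, ]
      keep <- which(p > threshold)
      if (!length(keep)) {
        warning("node ", nd, ", site ", sites[j],
                ": no state exceeds threshold ", threshold,
                "; using the MAP state")
        keep <- which.max(p)
      }
      data.frame(state = states[keep], prob = unname(p[keep]),
                 stringsAsFactors = FALSE)
    })
    names(cand) <- sites[cols]
    cand_info[[nd]] <- cand
    grid <- expand.grid(lapply(cand, function(d) seq_len(nrow(d))),
                        KEEP.OUT.ATTRS = FALSE)
    seqs <- apply(grid, 1L, function(ix)
      paste(vapply(seq_along(ix),
                   function(q) cand[[q]]$state[ix[q]], ""), collapse = ""))
    probs <- apply(grid, 1L, function(ix)
      prod(vapply(seq_along(ix),
                  function(q) cand[[q]]$prob[ix[q]], 0)))
    ord <- order(-probs, seqs)
    seqs <- seqs[ord]
    probs <- probs[ord]
    if (length(seqs) > max_variants) {
      warning("node ", nd, ": ", length(seqs),
              " candidate variants truncated to ", max_variants)
      seqs <- seqs[seq_len(max_variants)]
      probs <- probs[seq_len(max_variants)]
    }
    out[[nd]] <- data.frame(
      node = nd,
      label = paste0("anc", nd, ".", seq_along(seqs)),
      sequence = seqs,
      probability = probs,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, states = cand_info, threshold = threshold,
            class = c("ancestral_variants", "data.frame"))
}
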