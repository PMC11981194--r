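#' Parse a Newick tree
#'
#' Wraps the ape parser with the validation the downstream reconstruction
#' steps rely on: a single statement terminated by `;`, balanced parentheses,
#' unique leaf labels, and finite non-negative branch lengths. Branch lengths
#' absent from the input default to 0 with a warning. Internal-node support
#' values, when present, are stored as node labels, never as lengths.
#' Re-serialization through [write_newick()] preserves topology and lengths.
#'
#' @param text Newick string (single statement ending in `;`).
#' @return An [ape::read.tree()] `phylo` object.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  if (!nzchar(text) || !endsWith(text, ";"))
    stop("Newick input must be a single statement ending in ';'")
  n_open <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  n_close <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (n_open != n_close)
    stop("unbalanced parentheses in Newick input (", n_open, " '(' vs ",
         n_close, " ')')")
  tree <- tryCatch(ape::read.tree(text = text),
                   warning = function(w) stop("Newick parse failed: ",
                                              conditionMessage(w)),
                   error = function(e) stop("Newick parse failed: ",
                                            conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failed")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  if (is.null(tree$edge.length)) {
    warning("Newick input has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    warning("missing branch lengths defaulted to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(!is.finite(tree$edge.length)) || any(tree$edge.length < 0))
    stop("branch lengths must be finite and non-negative")
  tree
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; if `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (default 15, enough
#'   for a lossless double round-trip in practice).
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL, digits = 15L) {
  stopifnot(inherits(tree, "phylo"))
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

# Stable node identifiers: tips keep their labels; internal nodes use their
# own labels when present and non-empty, otherwise "Node<k>" by ape number.
node_ids <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  internal <- paste0("Node", ntip + seq_len(nnode))
  if (!is.null(tree$node.label)) {
    has <- !is.na(tree$node.label) & nzchar(tree$node.label)
    internal[has] <- tree$node.label[has]
  }
  c(tree$tip.label, internal)
}

#' Root a tree on a declared outgroup
#'
#' @param tree A `phylo` object.
#' @param outgroup Tip label (or labels) of the outgroup.
#' @return A rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  missing_tips <- setdiff(outgroup, tree$tip.label)
  if (length(missing_tips))
    stop("outgroup tip(s) not in tree: ", paste(missing_tips, collapse = ", "))
  if (ape::is.rooted(tree) && identical(sort(outgroup), sort(tree$tip.label)))
    return(tree)
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}
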