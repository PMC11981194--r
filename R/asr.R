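# Down-pass (outside) partial likelihoods for one rate category.
# For a child w of v: down[w](y) = sum_x P_xy(t_w) * down[v](x) *
# prod_{siblings s} msg_s(x).  Products are rescaled per site; only the
# normalized per-site posterior up * down is consumed, so the scale drops
# out.
.down_category <- function(tree, cat, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L <- ncol(cat$up[[cat$root]])
  s <- length(model$states)
  down <- vector("list", nn)
  down[[cat$root]] <- matrix(model$freqs, s, L)
  edges_by_parent <- .children_list(tree)
  # preorder over nodes: parents before children
  ro <- ape::reorder.phylo(tree, "postorder")
  node_order <- rev(unique(ro$edge[, 1L]))
  for (v in node_order) {
    edges <- edges_by_parent[[v]]
    for (e in edges) {
      w <- tree$edge[e, 2L]
      prod_other <- down[[v]]
      for (e2 in setdiff(edges, e)) prod_other <- prod_other * cat$msg[[e2]]
      P <- transition_matrix(model, tree$edge.length[e],
                             attr(cat, "rate"))
      dw <- crossprod(P, prod_other)
      m <- .col_max(dw)
      m[m == 0] <- 1
      down[[w]] <- sweep(dw, 2L, m, "/")
    }
  }
  down
}

.marginal_engine <- function(tree, aln, model) {
  leavesE <- .encode_leaves(tree, aln, model$states)
  cats <- lapply(model$rates, function(r) {
    out <- .prune_category(tree, leavesE, model, r)
    attr(out, "rate") <- r
    out
  })
  invC <- .invariant_compat(leavesE, model$freqs)
  mix <- .site_mixture(cats, model, invC)
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  ids <- node_ids(tree)[internal]
  L <- ncol(aln$mat)
  s <- length(model$states)
  arr <- array(0, dim = c(length(internal), L, s),
               dimnames = list(ids, as.character(seq_len(L)), model$states))
  # invariant-class posterior is the same at every node
  inv_post <- invC$comp * model$freqs
  Csafe <- ifelse(invC$C > 0, invC$C, 1)
  inv_post <- sweep(inv_post, 2L, Csafe, "/")
  per_cat_post <- lapply(cats, function(cat) {
    down <- .down_category(tree, cat, model)
    lapply(seq_along(internal), function(k) {
      v <- internal[k]
      F <- cat$up[[v]] * down[[v]]
      sweep(F, 2L, colSums(F), "/")
    })
  })
  for (k in seq_along(internal)) {
    post <- sweep(inv_post, 2L, mix$w_inv, "*")
    for (c_i in seq_along(cats))
      post <- post + sweep(per_cat_post[[c_i]][[k]], 2L, mix$w_cat[c_i, ], "*")
    post <- sweep(post, 2L, colSums(post), "/")
    arr[k, , ] <- t(post)
  }
  structure(posterior_table(arr),
            log_likelihood = sum(mix$site_log), tree = tree)
}

#' Empirical-Bayes marginal ancestral state reconstruction
#'
#' For every internal node of the rooted tree and every alignment site,
#' computes the marginal posterior probability of each state given the leaf
#' data, with model parameters held fixed (empirical Bayes). Rate-category
#' mixtures are combined with per-site category posteriors, and the
#' invariant-site class contributes its (constant-site) posterior mass.
#' Gaps and `N` are missing data; the indel signal is reconstructed
#' separately by [indel_asr()].
#'
#' @param tree A rooted `phylo`, or an unrooted tree plus `outgroup`.
#' @param aln An `alignment` over the model states.
#' @param model A `subst_model`.
#' @param outgroup Optional tip label(s) used to root an unrooted tree.
#' @return A `posterior_table` (internal nodes x sites x states) with
#'   attributes `log_likelihood` and `tree` (the rooted tree used; node ids
#'   in the table follow its labels).
#' @export
marginal_asr <- function(tree, aln, model, outgroup = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "alignment"))
  if (!ape::is.rooted(tree)) {
    if (is.null(outgroup))
      stop("tree is unrooted: supply an outgroup to root on")
    tree <- root_on_outgroup(tree, outgroup)
  }
  .marginal_engine(tree, aln, model)
}

#' Binary indel (gap presence/absence) reconstruction
#'
#' Recodes the alignment column-wise to a two-state presence/absence
#' alignment (non-gap and gap) and runs marginal reconstruction under the
#' two-state Jukes-Cantor-type model (JC2) with the branch lengths of the
#' supplied tree taken as-is, never re-optimized.
#'
#' @inheritParams marginal_asr
#' @param model A `subst_model` built with `build_model("JC2")` (default).
#' @return A `posterior_table` over states `present` and `gap`.
#' @export
indel_asr <- function(tree, aln, model = build_model("JC2"),
                      outgroup = NULL) {
  stopifnot(inherits(aln, "alignment"))
  if (!identical(model$states, c("0", "1")))
    stop("indel reconstruction requires a two-state model")
  rec <- aln
  m <- matrix("0", nrow(aln$mat), ncol(aln$mat),
              dimnames = dimnames(aln$mat))
  m[aln$mat == "-"] <- "1"
  rec$mat <- m
  rec$alphabet <- "binary"
  class(rec) <- "alignment"
  pt <- marginal_asr(tree, rec, model, outgroup = outgroup)
  dimnames(pt)[[3L]] <- c("present", "gap")
  pt
}
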