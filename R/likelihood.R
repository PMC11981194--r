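# Shared pruning machinery for likelihoods and marginal reconstruction.
#
# Partial likelihoods are kept as (state x site) matrices per node, scaled
# per site by the running maximum with the log scale accumulated, so deep
# trees do not underflow. Gaps and ambiguity codes are missing data: their
# leaf partial vector is all ones.

.encode_leaves <- function(tree, aln, states) {
  miss <- setdiff(tree$tip.label, aln$ids)
  if (length(miss))
    stop("tree leaves missing from alignment: ", paste(miss, collapse = ", "))
  extra <- setdiff(aln$ids, tree$tip.label)
  if (length(extra))
    stop("alignment ids missing from tree: ", paste(extra, collapse = ", "))
  L <- ncol(aln$mat)
  s <- length(states)
  lapply(tree$tip.label, function(id) {
    chars <- aln$mat[match(id, aln$ids), ]
    E <- matrix(0, s, L)
    for (k in seq_len(s)) E[k, ] <- as.numeric(chars == states[k])
    observed <- chars %in% states
    E[, !observed] <- 1
    E
  })
}

.children_list <- function(tree) {
  nn <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    ch[[tree$edge[e, 1L]]] <- c(ch[[tree$edge[e, 1L]]], e)
  ch   # edge indices grouped by parent node
}

.col_max <- function(M) {
  m <- M[1L, ]
  for (k in seq_len(nrow(M))[-1L]) m <- pmax(m, M[k, ])
  m
}

# One full pruning pass for a single rate category.
# Returns up partials, per-edge child messages M_e = P_e %*% up[child],
# per-node cumulative log scale, and per-site log-likelihood.
.prune_category <- function(tree, leavesE, model, rate) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  L <- ncol(leavesE[[1L]])
  up <- vector("list", nn)
  msg <- vector("list", nrow(tree$edge))
  logscale <- matrix(0, nn, L)
  for (i in seq_len(ntip)) up[[i]] <- leavesE[[i]]
  po <- ape::reorder.phylo(tree, "postorder")
  ord <- match(paste(po$edge[, 1L], po$edge[, 2L]),
               paste(tree$edge[, 1L], tree$edge[, 2L]))
  for (e in ord) {
    child <- tree$edge[e, 2L]
    parent <- tree$edge[e, 1L]
    P <- transition_matrix(model, tree$edge.length[e], rate)
    msg[[e]] <- P %*% up[[child]]
    if (is.null(up[[parent]])) {
      up[[parent]] <- msg[[e]]
      logscale[parent, ] <- logscale[child, ]
    } else {
      up[[parent]] <- up[[parent]] * msg[[e]]
      logscale[parent, ] <- logscale[parent, ] + logscale[child, ]
    }
    m <- .col_max(up[[parent]])
    m[m == 0] <- 1
    up[[parent]] <- sweep(up[[parent]], 2L, m, "/")
    logscale[parent, ] <- logscale[parent, ] + log(m)
  }
  root <- setdiff(tree$edge[, 1L], tree$edge[, 2L])[1L]
  site_log <- log(colSums(model$freqs * up[[root]])) + logscale[root, ]
  list(up = up, msg = msg, logscale = logscale, site_log = site_log,
       root = root)
}

# Invariant-class bookkeeping: comp[x, site] = 1 iff every observed leaf
# equals state x; C_site = sum_x pi_x comp[x, site].
.invariant_compat <- function(leavesE, freqs) {
  comp <- leavesE[[1L]]
  for (i in seq_along(leavesE)[-1L]) comp <- comp * leavesE[[i]]
  list(comp = comp, C = colSums(freqs * comp))
}

.site_mixture <- function(cats, model, invC) {
  # per-site log-likelihood of the full mixture and per-component posterior
  # weights: weight_inv (invariant class) and weight_c (each rate category)
  logs <- do.call(rbind, lapply(cats, `[[`, "site_log"))
  m <- apply(logs, 2L, max)
  rel <- exp(sweep(logs, 2L, m, "-")) * model$weights
  sum_rel <- colSums(rel)
  log_noninv <- m + log1p(-model$p_inv) + log(sum_rel)
  if (model$p_inv > 0) {
    log_inv <- ifelse(invC$C > 0, log(model$p_inv) + log(invC$C), -Inf)
    hi <- pmax(log_noninv, log_inv)
    site_log <- hi + log(exp(log_noninv - hi) + exp(log_inv - hi))
    w_inv <- exp(log_inv - site_log)
  } else {
    site_log <- log_noninv
    w_inv <- rep(0, length(site_log))
  }
  w_cat <- sweep(rel, 2L, sum_rel, "/") * rep(1 - w_inv, each = nrow(rel))
  list(site_log = site_log, w_inv = w_inv, w_cat = w_cat)
}

#' Per-site pruning log-likelihoods
#'
#' Felsenstein pruning over the tree, with gaps and ambiguity characters
#' treated as missing data, mixed over the model's rate categories and
#' invariant-site class:
#' `L_site = p_inv * C_site + (1 - p_inv) * sum_i w_i * L_site(r_i)`,
#' where `C_site` is the stationary mass of states compatible with a
#' constant site. For reversible models the total is invariant to root
#' placement.
#'
#' @param tree A `phylo` whose leaves match the alignment ids.
#' @param aln An `alignment` over the model's alphabet.
#' @param model A `subst_model`.
#' @return List with `site_log_likelihoods` and `log_likelihood` (their
#'   sum).
#' @export
site_likelihoods <- function(tree, aln, model) {
  stopifnot(inherits(tree, "phylo"), inherits(aln, "alignment"),
            inherits(model, "subst_model"))
  leavesE <- .encode_leaves(tree, aln, model$states)
  cats <- lapply(model$rates,
                 function(r) .prune_category(tree, leavesE, model, r))
  invC <- .invariant_compat(leavesE, model$freqs)
  mix <- .site_mixture(cats, model, invC)
  list(site_log_likelihoods = mix$site_log,
       log_likelihood = sum(mix$site_log))
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate ascent, one branch at a time, each by bounded scalar search on
#' `[1e-8, 10]`; a sweep visits every branch and the loop terminates when
#' the total log-likelihood improves by less than `tol` over a full sweep.
#' The log-likelihood is monotone non-decreasing across sweeps.
#'
#' @inheritParams site_likelihoods
#' @param tol Convergence tolerance on the total log-likelihood.
#' @param max_sweeps Sweep cap; non-convergence warns and returns the best
#'   tree so far.
#' @return The tree with optimized `edge.length`.
#' @export
optimize_branch_lengths <- function(tree, aln, model, tol = 1e-6,
                                    max_sweeps = 100L) {
  stopifnot(tol > 0)
  cur <- site_likelihoods(tree, aln, model)$log_likelihood
  for (sweep_i in seq_len(max_sweeps)) {
    for (e in seq_len(nrow(tree$edge))) {
      f <- function(t) {
        tree$edge.length[e] <- t
        site_likelihoods(tree, aln, model)$log_likelihood
      }
      opt <- stats::optimize(f, interval = c(1e-8, 10), maximum = TRUE,
                             tol = 1e-8)
      if (opt$objective >= f(tree$edge.length[e]))
        tree$edge.length[e] <- opt$maximum
    }
    new <- site_likelihoods(tree, aln, model)$log_likelihood
    if (new - cur < tol) return(tree)
    cur <- new
  }
  warning("branch-length optimization did not converge in ", max_sweeps,
          " sweeps; returning best tree so far")
  tree
}
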