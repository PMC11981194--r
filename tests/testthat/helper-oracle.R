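# Independent brute-force oracle for pruning likelihoods and marginal
# posteriors: enumerates every joint assignment of internal-node states and
# sums path probabilities, using Matrix::expm for the transition kernels so
# the oracle shares no code path with the package's eigendecomposition.

oracle_transition <- function(model, t, r) {
  as.matrix(Matrix::expm(model$Q * r * t))
}

oracle_leaf_encoding <- function(tree, aln, model) {
  s <- length(model$states)
  L <- ncol(aln$mat)
  lapply(tree$tip.label, function(id) {
    chars <- aln$mat[match(id, aln$ids), ]
    E <- matrix(0, s, L)
    for (k in seq_len(s)) E[k, ] <- as.numeric(chars == model$states[k])
    E[, !(chars %in% model$states)] <- 1
    E
  })
}

# returns list(post = array(internal x site x state), loglik)
oracle_marginal <- function(tree, aln, model) {
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  s <- length(model$states)
  L <- ncol(aln$mat)
  leaves <- oracle_leaf_encoding(tree, aln, model)
  internal <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(seq_len(s)), length(internal))))
  post <- array(0, c(length(internal), L, s))
  tot <- rep(0, L)
  comp <- Reduce(`*`, leaves)
  for (ci in seq_along(model$rates)) {
    r <- model$rates[ci]
    w <- model$weights[ci]
    Ps <- lapply(seq_len(nrow(tree$edge)),
                 function(e) oracle_transition(model, tree$edge.length[e], r))
    for (g in seq_len(nrow(grid))) {
      asg <- grid[g, ]
      pr <- rep(model$freqs[asg[root - ntip]], L)
      for (e in seq_len(nrow(tree$edge))) {
        par <- tree$edge[e, 1]
        chi <- tree$edge[e, 2]
        ps <- asg[par - ntip]
        if (chi <= ntip) {
          pr <- pr * as.numeric(Ps[[e]][ps, ] %*% leaves[[chi]])
        } else {
          pr <- pr * Ps[[e]][ps, asg[chi - ntip]]
        }
      }
      pr <- (1 - model$p_inv) * w * pr
      tot <- tot + pr
      for (k in seq_along(internal))
        post[k, , asg[k]] <- post[k, , asg[k]] + pr
    }
  }
  if (model$p_inv > 0) {
    for (x in seq_len(s)) {
      pr <- model$p_inv * model$freqs[x] * comp[x, ]
      tot <- tot + pr
      for (k in seq_along(internal)) post[k, , x] <- post[k, , x] + pr
    }
  }
  for (k in seq_along(internal)) post[k, , ] <- post[k, , ] / tot
  list(post = post, loglik = sum(log(tot)))
}

random_simplex <- function(k, floor_p = 0.05) {
  x <- stats::rexp(k) + floor_p
  x / sum(x)
}

random_alignment <- function(tree, L, states, alphabet, gap_prob = 0.1) {
  pool <- states
  if (alphabet == "dna") pool <- c(states, "-")
  seqs <- vapply(tree$tip.label, function(i) {
    chars <- sample(pool, L, replace = TRUE,
                    prob = c(rep((1 - gap_prob) / length(states),
                                 length(states)),
                             if (alphabet == "dna") gap_prob))
    paste(chars, collapse = "")
  }, "")
  new_alignment(seqs, alphabet)
}
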