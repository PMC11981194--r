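#' Simulate a random bifurcating tree
#'
#' Topology by uniform coalescent-style joins: starting from the taxa,
#' two lineages chosen uniformly at random are joined until one remains.
#' Every branch length is drawn i.i.d. exponential with the given mean.
#' Deterministic for a seed.
#'
#' @param n_taxa Number of leaves (>= 2), labelled `t1..tn`.
#' @param mean_branch_length Mean of the exponential branch lengths in
#'   substitutions/site (default 0.05).
#' @param seed Optional integer seed.
#' @return A rooted `phylo`.
#' @export
simulate_tree <- function(n_taxa, mean_branch_length = 0.05, seed = NULL) {
  if (n_taxa < 2L) stop("n_taxa must be at least 2")
  stopifnot(mean_branch_length > 0)
  if (!is.null(seed)) set.seed(seed)
  nodes <- paste0("t", seq_len(n_taxa))
  while (length(nodes) > 1L) {
    pick <- sample.int(length(nodes), 2L)
    bl <- stats::rexp(2L, rate = 1 / mean_branch_length)
    joined <- sprintf("(%s:%.17g,%s:%.17g)",
                      nodes[pick[1L]], bl[1L], nodes[pick[2L]], bl[2L])
    nodes <- c(nodes[-pick], joined)
  }
  parse_newick(paste0(nodes, ";"))
}

# closed-form 2-state transition matrix for the presence/absence chain
# states: 1 = present, 2 = absent; loss = present->absent rate, gain the
# reverse
.presence_kernel <- function(loss, gain, t) {
  if (loss + gain == 0 || t == 0) return(diag(2))
  e <- exp(-(loss + gain) * t)
  s <- loss + gain
  matrix(c((gain + loss * e) / s, (loss - loss * e) / s,
           (gain - gain * e) / s, (loss + gain * e) / s),
         2L, 2L, byrow = TRUE)
}

.default_sim_model <- function() {
  build_model("HKY85", frequencies = c(0.3, 0.2, 0.2, 0.3), kappa = 2,
              rates = c(0.25, 0.75, 1.5, 2.5), weights = rep(0.25, 4L))
}

#' Simulate codon sequence evolution with whole-codon indels
#'
#' Evolves nucleotide sequences along the tree under a reversible model
#' with per-site rate categories, together with an independent two-state
#' presence/absence process per codon (whole-codon indel units). The root
#' sequence is drawn from the stationary frequencies avoiding stop codons;
#' codon columns in which any present leaf carries a stop codon are
#' resampled wholesale (ancestors included) so the emitted leaves always
#' pass [filter_cds()]; the resample count is recorded. Child states are
#' drawn from the exact transition kernel `P(Q r t)` of each branch, which
#' has the same law as event-level simulation of the chain.
#'
#' @param tree Rooted `phylo` (e.g. from [simulate_tree()]).
#' @param n_codons Number of codons per sequence.
#' @param model A nucleotide `subst_model`; default HKY85 (kappa 2, uneven
#'   base composition) with a 4-category free-rate mixture.
#' @param indel List with `gain`, `loss` (rates of the presence/absence
#'   chain, same time units as branch lengths) and `root_present`
#'   (probability a codon is present at the root). Defaults
#'   `gain = loss = 0.1`, `root_present = 0.9`.
#' @param seed Optional integer seed.
#' @return List of class `sim_evolution` with `alignment` (leaf
#'   `codon_alignment`) and `truth`: `tree`, `node_sequences` (every node,
#'   gaps included), `presence` (node x codon logical matrix), `site_rates`,
#'   `model`, `indel`, `seed`, `n_resampled_columns`.
#' @export
simulate_evolution <- function(tree, n_codons,
                               model = .default_sim_model(),
                               indel = list(gain = 0.1, loss = 0.1,
                                            root_present = 0.9),
                               seed = NULL) {
  stopifnot(inherits(tree, "phylo"), n_codons >= 1L)
  if (!ape::is.rooted(tree)) stop("simulation requires a rooted tree")
  if (!identical(model$states, .nuc_states))
    stop("simulation requires a nucleotide model")
  stopifnot(indel$gain >= 0, indel$loss >= 0,
            indel$root_present >= 0, indel$root_present <= 1)
  if (!is.null(seed)) set.seed(seed)

  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  root <- ntip + 1L
  L <- 3L * n_codons
  ids <- node_ids(tree)
  # edges parents-first
  po <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(po$edge)))
  edges <- po$edge[edge_order, , drop = FALSE]
  elens <- po$edge.length[edge_order]

  draw_rates <- function(n) {
    r <- numeric(n)
    inv <- stats::runif(n) < model$p_inv
    cat_i <- sample.int(length(model$rates), n, replace = TRUE,
                        prob = model$weights)
    r[!inv] <- model$rates[cat_i[!inv]]
    r  # 0 marks an invariant site
  }

  sim_columns <- function(cols) {
    # simulate nucleotide states and presence for the given codon columns
    ncod <- length(cols)
    l <- 3L * ncod
    rates <- draw_rates(l)
    S <- matrix(0L, nn, l)
    # stop-free root codons by rejection from pi
    for (k in seq_len(ncod)) {
      repeat {
        cand <- sample.int(4L, 3L, replace = TRUE, prob = model$freqs)
        if (!(paste(.nuc_states[cand], collapse = "") %in% .stop_codons))
          break
      }
      S[root, (3L * k - 2L):(3L * k)] <- cand
    }
    pres <- matrix(NA, nn, ncod)
    pres[root, ] <- stats::runif(ncod) < indel$root_present
    for (e in seq_len(nrow(edges))) {
      par <- edges[e, 1L]; chi <- edges[e, 2L]; t_e <- elens[e]
      child <- integer(l)
      inv <- rates == 0
      child[inv] <- S[par, inv]
      for (rv in unique(rates[rates > 0])) {
        P <- transition_matrix(model, t_e, rv)
        sel <- which(rates == rv)
        for (s in 1:4) {
          ss <- sel[S[par, sel] == s]
          if (length(ss))
            child[ss] <- sample.int(4L, length(ss), replace = TRUE,
                                    prob = P[s, ])
        }
      }
      S[chi, ] <- child
      P2 <- .presence_kernel(indel$loss, indel$gain, t_e)
      pp <- pres[par, ]
      u <- stats::runif(ncod)
      pres[chi, ] <- ifelse(pp, u < P2[1L, 1L], u < P2[2L, 1L])
    }
    list(S = S, pres = pres, rates = rates)
  }

  full <- sim_columns(seq_len(n_codons))
  S <- full$S; pres <- full$pres; rates <- full$rates
  # resample codon columns where a present leaf carries a stop codon
  n_resampled <- 0L
  repeat {
    bad <- logical(n_codons)
    for (k in seq_len(n_codons)) {
      cols <- (3L * k - 2L):(3L * k)
      for (i in seq_len(ntip)) {
        if (pres[i, k] &&
            paste(.nuc_states[S[i, cols]], collapse = "") %in% .stop_codons) {
          bad[k] <- TRUE
          break
        }
      }
    }
    if (!any(bad)) break
    n_resampled <- n_resampled + sum(bad)
    redo <- sim_columns(which(bad))
    for (j in seq_along(which(bad))) {
      k <- which(bad)[j]
      cols <- (3L * k - 2L):(3L * k)
      S[, cols] <- redo$S[, (3L * j - 2L):(3L * j)]
      pres[, k] <- redo$pres[, j]
      rates[cols] <- redo$rates[(3L * j - 2L):(3L * j)]
    }
  }

  seq_of_node <- function(v) {
    chars <- .nuc_states[S[v, ]]
    for (k in seq_len(n_codons)) {
      if (!pres[v, k]) chars[(3L * k - 2L):(3L * k)] <- "-"
    }
    paste(chars, collapse = "")
  }
  node_sequences <- vapply(seq_len(nn), seq_of_node, "")
  names(node_sequences) <- ids
  leaf_seqs <- node_sequences[seq_len(ntip)]
  aln <- as_codon_alignment(new_alignment(leaf_seqs, "dna"))
  rownames(pres) <- ids
  truth <- list(tree = tree, node_sequences = node_sequences,
                presence = pres, site_rates = rates, model = model,
                indel = indel, seed = seed,
                n_resampled_columns = n_resampled)
  structure(list(alignment = aln, truth = truth), class = "sim_evolution")
}

#' Simulate HR score datasets
#'
#' Draws i.i.d. ordinal scores on the 0..7 hypersensitive-response scale
#' for each treatment group.
#'
#' @param groups Named list; each element a list with `n` (spot count) and
#'   `probs` (length-8 probability vector over scores 0..7).
#' @param seed Optional integer seed.
#' @return Data frame with columns `treatment`, `replicate`, `score`.
#' @export
simulate_hr_scores <- function(groups, seed = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(names(groups), function(g) {
    sp <- groups[[g]]
    if (length(sp$probs) != 8L || any(sp$probs < 0) ||
        abs(sum(sp$probs) - 1) > 1e-8)
      stop("group ", g, ": probs must be a length-8 simplex over scores 0..7")
    if (sp$n < 1L) stop("group ", g, ": n must be positive")
    data.frame(treatment = g, replicate = seq_len(sp$n),
               score = sample(0:7, sp$n, replace = TRUE, prob = sp$probs),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Build a toy two-chain complex with known contacts
#'
#' Places one heavy atom per chain-A residue and an opposing chain-B atom
#' at a specified distance, with consecutive residues spaced far enough
#' apart that only the designed pairs can fall in a contact window. The
#' expected contact pairs and clustered regions are known by construction.
#'
#' @param residues Chain-A residue numbers (author numbering).
#' @param distances Designed A-B atom distances in angstroms (recycled).
#' @param spacing Spacing between consecutive residues along x (default 10,
#'   larger than any contact cutoff).
#' @param chain_a,chain_b Chain identifiers.
#' @return Atom table compatible with [find_contacts()].
#' @export
make_toy_complex <- function(residues, distances = 3.0, spacing = 10,
                             chain_a = "A", chain_b = "B") {
  if (!length(residues))
    return(data.frame(chain = character(), resno = integer(),
                      resid = character(), atom = character(),
                      element = character(), x = numeric(), y = numeric(),
                      z = numeric(), stringsAsFactors = FALSE))
  n <- length(residues)
  distances <- rep_len(distances, n)
  xs <- spacing * seq_len(n)
  a <- data.frame(chain = chain_a, resno = as.integer(residues),
                  resid = "ALA", atom = "CB", element = "C",
                  x = xs, y = 0, z = 0, stringsAsFactors = FALSE)
  b <- data.frame(chain = chain_b, resno = seq_len(n), resid = "GLY",
                  atom = "CA", element = "C",
                  x = xs, y = distances, z = 0, stringsAsFactors = FALSE)
  rbind(a, b)
}

#' Write an atom table as a minimal PDB file
#'
#' Fixed-width ATOM records sufficient for round-tripping toy complexes
#' through [read_structure()].
#'
#' @param atoms Atom table (as from [make_toy_complex()]).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_toy_pdb <- function(atoms, path) {
  lines <- sprintf(
    "ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(atoms)), atoms$atom, atoms$resid, atoms$chain,
    atoms$resno, atoms$x, atoms$y, atoms$z, 1, 0, atoms$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
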