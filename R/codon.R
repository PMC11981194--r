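.codon_names <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))  # varies fastest on left
}

#' Combine nucleotide and indel posteriors into codon posteriors
#'
#' For each internal node and codon site, the probability of each of the 64
#' codons is the product of the three per-position nucleotide posteriors.
#' A codon site is called a gap at a node iff the mean gap posterior over
#' its three columns exceeds `gap_threshold`, in which case the gap state
#' supersedes the codon states. Both the raw products (which need not sum
#' to 1) and the renormalized distributions (with the gap state) are
#' retained.
#'
#' @param nuc `posterior_table` over `A, C, G, T` with sites in codon frame.
#' @param indel `posterior_table` over `present, gap` on the same columns.
#' @param gap_threshold Gap-call threshold on the mean gap posterior
#'   (default 0.5, the MAP decision on the binary state).
#' @return An object of class `codon_posterior`: `raw` (node x codon_site x
#'   64), `renorm` (node x codon_site x 65, codons plus `---`),
#'   `gap_posterior` (node x codon_site), `gap_threshold`.
#' @export
combine_codon <- function(nuc, indel, gap_threshold = 0.5) {
  stopifnot(inherits(nuc, "posterior_table"), inherits(indel, "posterior_table"))
  if (!identical(pt_states(nuc), c("A", "C", "G", "T")))
    stop("nucleotide posterior table must be over A, C, G, T")
  if (!("gap" %in% pt_states(indel)))
    stop("indel posterior table must carry a 'gap' state")
  if (!identical(pt_nodes(nuc), pt_nodes(indel)))
    stop("nucleotide and indel tables cover different node sets")
  L <- dim(nuc)[2L]
  if (L %% 3L != 0L)
    stop("nucleotide sites (", L, ") are not in codon frame")
  if (dim(indel)[2L] != L)
    stop("indel table has ", dim(indel)[2L], " sites; expected ", L)
  nodes <- pt_nodes(nuc)
  n_codon <- L / 3L
  codons <- .codon_names()
  raw <- array(0, dim = c(length(nodes), n_codon, 64L),
               dimnames = list(nodes, as.character(seq_len(n_codon)), codons))
  renorm <- array(0, dim = c(length(nodes), n_codon, 65L),
                  dimnames = list(nodes, as.character(seq_len(n_codon)),
                                  c(codons, "---")))
  gapP <- matrix(0, length(nodes), n_codon,
                 dimnames = list(nodes, as.character(seq_len(n_codon))))
  # codon index decomposition matching .codon_names(): first base varies
  # fastest in position 1
  i1 <- rep(1:4, times = 16L)
  i2 <- rep(rep(1:4, each = 4L), times = 4L)
  i3 <- rep(1:4, each = 16L)
  for (v in seq_along(nodes)) {
    for (k in seq_len(n_codon)) {
      c1 <- nuc[v, 3L * k - 2L, ]
      c2 <- nuc[v, 3L * k - 1L, ]
      c3 <- nuc[v, 3L * k, ]
      p <- c1[i1] * c2[i2] * c3[i3]
      raw[v, k, ] <- p
      g <- mean(indel[v, (3L * k - 2L):(3L * k), "gap"])
      gapP[v, k] <- g
      if (g > gap_threshold) {
        renorm[v, k, 65L] <- 1
      } else {
        renorm[v, k, 1:64] <- p / sum(p)
      }
    }
  }
  structure(list(raw = raw, renorm = renorm, gap_posterior = gapP,
                 gap_threshold = gap_threshold),
            class = "codon_posterior")
}

#' @export
print.codon_posterior <- function(x, ...) {
  d <- dim(x$raw)
  cat("<codon_posterior> ", d[1L], " nodes x ", d[2L], " codon sites",
      " (gap threshold ", x$gap_threshold, ")\n", sep = "")
  invisible(x)
}

#' Residue posteriors from codon posteriors
#'
#' Sums the renormalized codon posteriors over synonymous codons. Mass on
#' stop codons is reported separately (attribute `stop_mass`) and warned
#' about; rows of the returned table therefore sum to 1 minus the stop
#' mass.
#'
#' @param codons A `codon_posterior`.
#' @param code Named genetic code (codon -> single-letter residue, `*` for
#'   stop); default [Biostrings::GENETIC_CODE].
#' @return A `posterior_table` over the 20 residues plus `-`, with
#'   attribute `stop_mass` (node x codon_site matrix).
#' @export
residue_posteriors <- function(codons, code = Biostrings::GENETIC_CODE) {
  stopifnot(inherits(codons, "codon_posterior"))
  cn <- .codon_names()
  aa_of <- unname(code[cn])
  aas <- sort(setdiff(unique(aa_of), "*"))
  states <- c(aas, "-")
  dn <- dimnames(codons$renorm)
  arr <- array(0, dim = c(dim(codons$renorm)[1:2], length(states)),
               dimnames = list(dn[[1L]], dn[[2L]], states))
  for (a in aas) {
    sel <- which(aa_of == a)
    sub <- codons$renorm[, , sel, drop = FALSE]
    arr[, , a] <- apply(sub, c(1L, 2L), sum)
  }
  arr[, , "-"] <- codons$renorm[, , 65L]
  stop_sel <- which(aa_of == "*")
  stop_mass <- apply(codons$renorm[, , stop_sel, drop = FALSE],
                     c(1L, 2L), sum)
  if (any(stop_mass > 1e-6))
    warning("posterior mass on stop codons detected (max ",
            format(max(stop_mass), digits = 3), "); reported separately")
  structure(posterior_table(arr, partial = TRUE), stop_mass = stop_mass)
}
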