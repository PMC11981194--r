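---
title: "Methods: codon-aware ancestral reconstruction of helper NLR interfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-aware ancestral reconstruction of helper NLR interfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonasr)
```

## The scientific problem

Helper NLR immune receptors of the NRC family execute cell death downstream
of sensor NLRs in Solanaceae. Some parasite effectors, such as the cyst
nematode protein SS15, bind the NB-ARC module of particular NRCs and block
their activation. Whether an extant receptor is inhibited can hinge on a
handful of residues at the receptor-effector interface, so a natural
question is what the *ancestral* receptor looked like at those positions and
when escape polymorphisms arose. `codonasr` implements the computational
pipeline for that question: prepare a codon-level alignment from coding
sequences, reconstruct ancestral states at internal nodes of a phylogeny,
reconstruct gap (indel) states separately, combine both into codon and
residue posteriors, and enumerate the alternative ancestral interface
sequences implied by posterior ambiguity, together with the contact-based
definition of the interface itself and the permutation statistics used on
cell-death scores.

## Sequence preparation

Coding sequences pass four filters, applied in a fixed order so that each
test is well defined: reading frame (length divisible by three), internal
stop codons, removal of one terminal stop codon, and an inclusive length
window applied to the stop-stripped sequence (defaults 2,400-2,800 nt, a
full-length helper NLR window). The order matters: "internal stop" is only
meaningful once the frame is known, and the length filter sees the sequence
the downstream steps will see. The filter is idempotent and never throws:
every exclusion is recorded with a reason.

Protein alignments are threaded back to nucleotides codon-by-codon
(each aligned residue replaced by its source codon, each residue gap by
`---`), which preserves frame by construction and guarantees that ungapping
a threaded row reproduces the input CDS byte for byte. Gappy-column
trimming removes columns whose gap fraction strictly exceeds `g` (default
0.9); on codon alignments the unit of removal is the codon triple, judged
by its pooled gap fraction, because removing single nucleotide columns
would destroy the frame that the codon posterior product rule later relies
on. Deduplication is exact string identity on the full sequence, keeping
the first occurrence; curated single-position edits are expressed as a
generic patch table applied before threading rather than as ad hoc code.

## Substitution models and likelihood

Models are reversible rate matrices `Q` with `q_ij = s_ij * pi_j`, covering
JC69, K80, HKY85, TIM3 (a GTR restriction with the ties AC = CG and
AT = GT), full GTR, and the two-state JC2 used for gap presence/absence.
`Q` is normalized so one unit of branch length is one expected substitution
per site after averaging over the rate-category mixture and the
invariant-site class: the matrix satisfies `-sum(pi_i q_ii) = 1` and the
free category rates are rescaled so `(1 - p_inv) * sum(w_i r_i) = 1`.
Transition probabilities come from the symmetric eigendecomposition of
`D^{1/2} Q D^{-1/2}` (`D = diag(pi)`), which reversibility guarantees has a
real spectrum; this is exact, stable, and makes `P(0) = I` and
Chapman-Kolmogorov hold to machine precision.

Site likelihoods use Felsenstein pruning with per-site rescaling of partial
likelihoods (running column maxima with accumulated logs), so deep or long
trees do not underflow. Gaps and `N` are missing data - a deliberate
separation of concerns, since the indel signal is handled by the dedicated
binary reconstruction. The mixture likelihood is
`L = p_inv * C + (1 - p_inv) * sum_i w_i L(r_i)`, where `C` is the
stationary mass of states compatible with a constant site (zero if two
different residues are observed, the full simplex mass if the column is
entirely missing). Branch-length fitting, needed only when no externally
estimated tree is supplied, is coordinate ascent with a bounded scalar
search per branch on `[1e-8, 10]`, terminating when a full sweep improves
the log-likelihood by less than `tol`; the trajectory is monotone by
construction.

## Marginal ancestral reconstruction

Reconstruction is empirical Bayes and *marginal*: for each internal node,
site and state we report `P(state | data)` with model parameters held
fixed, computed from inside (post-order) and outside (pre-order) partial
likelihoods. Rate categories are combined with per-site category
posteriors, `P(x | site) = sum_c P(c | site) P(x | site, c)`, the standard
treatment when the mixture is part of the model; the invariant class
contributes its constant-site posterior in the same way. Trees must be
rooted; an unrooted input is rooted on a user-declared outgroup, and
posteriors are reported for the internal nodes of that rooted tree.

Indel states are reconstructed on the same alignment recoded column-wise to
two states (non-gap/gap) under JC2, with branch lengths taken exactly as
given and never re-optimized - the binary recoding carries far less signal
than the nucleotides, so re-fitting lengths on it would only degrade them.

## Codon and residue posteriors, ambiguity, variants

Codon posteriors are the product of the three per-position nucleotide
posteriors - deliberately ignoring within-codon correlation, which is the
price of reconstructing on a nucleotide model; both the raw products and
the renormalized distributions are retained so the approximation is
auditable. A codon site is called a gap at a node when the mean gap
posterior over its three columns exceeds 0.5, the MAP decision on the
binary state; the gap call supersedes the codon states. Residue posteriors
sum synonymous codons; mass landing on stop codons is reported separately
and warned about rather than silently renormalized away.

Ambiguity is thresholded at the *residue* level: a position is ambiguous
when more than one residue has posterior probability above 0.3. The
codon-level tables are still emitted, because the thresholding level is a
genuine modelling choice and the codon numbers let a user re-derive either
convention. Variant enumeration takes the Cartesian product of per-position
candidate states, orders variants by joint probability (product of chosen
state probabilities) descending with a lexicographic tie-break, truncates
at `max_variants` (default 16) with a warning, and labels them
`anc<node>.<k>` by rank. Note the labelling convention: sub-numbering is by
descending probability, so the top-ranked variant is always `.1`; any
externally published sub-numbering of the same node may order its variants
differently, and the mapping should be made by the reported probabilities,
not the labels. Positions are specified in reference-sequence numbering and
mapped through the alignment via the reference row's non-gap columns.

## Interface definition from a complex structure

The receptor-effector interface is defined from a two-chain structure by
inter-chain heavy-atom contacts with an inclusive distance window of
2.5-3.6 angstroms (a polar-contact window; hydrogens are excluded, waters
optional, alternate locations other than 'A'/blank dropped). Contacting
receptor residues are merged into regions while consecutive author-numbered
residues differ by at most `gap_tol` (default 15, chosen so that contact
sets with loop-scale gaps coalesce into a small number of contiguous
interface regions; the clustering rule is exposed because no single
tolerance is canonical). A cell-list accelerator and an all-pairs search
give identical results; the package tests enforce that equivalence.

## Permutation statistics on HR scores

Cell-death scores are ordinal 0-7. The test statistic is the difference of
group means; labels are permuted without replacement, and the two-sided
Monte-Carlo p-value uses the +1 small-sample correction,
`p = (#{|T*| >= |T_obs| - 1e-12} + 1)/(B + 1)`, so p is never exactly 0 and
the test is valid at any `B`. An exact enumeration over all
`choose(n, n_a)` assignments (no +1 correction) serves as the oracle.
Because ordinal scores tie heavily, null p-values are *conservative* -
stochastically larger than uniform - rather than exactly uniform; the
calibration study in the test suite therefore checks one-sided dominance at
every level plus the achieved size at `alpha = 0.05` (measured 0.0415 over
2,000 null datasets of 24 + 24 uniform scores at `B = 599`), which sits
inside the binomial 99% band around 0.05.

## The synthetic-data generator

The generator exists so the full pipeline is testable end to end with the
ancestral truth known. Defaults were chosen once, as plausible conditions
for a plant NLR coding-sequence family, and are not tuned per test:

* trees: uniform random joins, exponential branch lengths with mean 0.05
  substitutions/site (32 taxa and 300 codons in the pipeline regression);
* nucleotides: HKY85 with `kappa = 2` and base frequencies
  (0.3, 0.2, 0.2, 0.3), with a 4-category free-rate mixture
  (0.25, 0.75, 1.5, 2.5 before normalization, equal weights) standing in
  for the rate heterogeneity real alignments show;
* indels: whole-codon presence/absence evolving at gain = loss = 0.1 per
  unit branch length, root presence probability 0.9 - indels rarer than
  substitutions, mostly-present columns, matching what a trimmed codon
  alignment looks like;
* HR scores: i.i.d. draws from per-group distributions over 0-7.

Child states are drawn from the exact transition kernel `P(Q r t)` per
branch, which has the same marginal law as simulating exponential waiting
times; the recorded truth is the state at every node, not the event path.
Codon columns where any *present* leaf ends up with a stop codon are
resampled wholesale (ancestors included, count recorded) so fixtures always
pass the CDS filter while leaf and ancestor truth stay mutually consistent.

What the generator does **not** emulate: domain architecture, selection
(dN/dS), alignment error, non-codon indels, recombination, and duplicated
splice variants. Passing the recovery regressions therefore shows the
inference machinery is correct under its own model assumptions - not that
real helper NLR data meet those assumptions.

## Numerical choices and problem sizes

Tolerances follow the quantity: enumeration-oracle equivalence and
Chapman-Kolmogorov at 1e-10, closed forms at 1e-12, re-rooting invariance
at 1e-8, the two-taxon branch MLE against the closed-form JC distance at
1e-4. The oracle suite runs 200 random instances on trees of 3-5 leaves
with 20 sites; the pipeline regression uses one 32-taxon, 300-codon dataset
per branch scaling (x1, x4, x16), sizes at which the whole suite completes
in well under a minute per stage while still exercising every code path.
The root-recovery floor of 90% at the x1 scale is a regression guard for
this configuration, not a claim about real data.

## Known limitations

* The codon posterior product rule ignores within-codon dependence; a codon
  model would capture it at far higher cost.
* Reconstruction quality is conditional on the supplied tree and model
  parameters; neither topology search nor model selection is in scope.
* Gap calling via the 0.5 MAP rule on the mean gap posterior is a
  convention; near 0.5 the codon/gap decision is genuinely uncertain and
  both tables should be consulted.
* The exact permutation oracle is limited to `choose(n, n_a) <= 1e6`
  assignments.
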