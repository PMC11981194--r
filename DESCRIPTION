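Package: codonasr
Title: Codon-Aware Ancestral Sequence Reconstruction with Indel Handling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to reconstruct ancestral coding sequences at
    protein-protein interface positions of plant helper NLR immune
    receptors. Covers coding-sequence quality filtering, codon threading of
    a protein alignment, gappy-column trimming and deduplication; reversible
    nucleotide and two-state substitution models with rate-category
    mixtures and an invariant-site class; Felsenstein pruning likelihoods
    and empirical-Bayes marginal ancestral state reconstruction; a separate
    binary presence/absence reconstruction of whole-codon indels; codon and
    residue posterior combination with ambiguity-aware enumeration of
    alternative ancestral variants; inter-chain heavy-atom contact mapping
    from a receptor-effector complex structure; two-sided permutation tests
    on ordinal hypersensitive-response scores; per-column information
    matrices for sequence logos; and synthetic-data generators (trees,
    codon sequences with recorded ancestral truth, score datasets, toy
    complexes) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    Matrix,
    jsonlite
Config/testthat/edition: 3
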