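test_that("near-zero branches make the root state certain", {
  tree <- parse_newick("(a:1e-6,b:1e-6,c:1e-6);")
  tree <- root_on_outgroup(tree, "a")
  aln <- new_alignment(c(a = "A", b = "A", c = "A"), "dna")
  pt <- marginal_asr(tree, aln, build_model("JC69"))
  root_id <- dimnames(pt)[[1]][1]
  expect_gt(pt[root_id, "1", "A"], 0.9999)
})

test_that("star tree with A, C, G leaves leaves T strictly least likely", {
  tree <- root_on_outgroup(parse_newick("(a:0.3,b:0.3,c:0.3);"), "a")
  aln <- new_alignment(c(a = "A", b = "C", c = "G"), "dna")
  pt <- marginal_asr(tree, aln, build_model("JC69"))
  root_id <- dimnames(pt)[[1]][1]
  p <- pt[root_id, "1", ]
  expect_true(all(p["T"] < p[c("A", "C", "G")]))
  or <- oracle_marginal(attr(pt, "tree"), aln, build_model("JC69"))
  expect_equal(unname(p), or$post[1, 1, ], tolerance = 1e-10)
})

test_that("marginal posteriors equal exhaustive Bayes on small trees", {
  set.seed(81)
  for (i in 1:12) {
    tree <- simulate_tree(sample(3:5, 1), 0.4)
    model <- switch(i %% 3 + 1,
                    build_model("JC69", rates = c(0.4, 1.6),
                                weights = c(0.5, 0.5), p_inv = 0.2),
                    build_model("HKY85", frequencies = c(.15, .35, .3, .2),
                                kappa = 2.5),
                    build_model("JC69"))
    aln <- random_alignment(tree, 8, model$states, "dna")
    pt <- marginal_asr(tree, aln, model)
    or <- oracle_marginal(tree, aln, model)
    expect_equal(max(abs(unclass(pt)[, , ] - or$post)), 0,
                 tolerance = 1e-10)
    # normalization at every (node, site)
    expect_equal(max(abs(apply(unclass(pt), c(1, 2), sum) - 1)), 0,
                 tolerance = 1e-9)
  }
})

test_that("an unrooted tree requires an outgroup", {
  tree <- ape::unroot(simulate_tree(4, 0.2, seed = 82))
  aln <- random_alignment(tree, 5, c("A", "C", "G", "T"), "dna")
  expect_error(marginal_asr(tree, aln, build_model("JC69")), "outgroup")
  pt <- marginal_asr(tree, aln, build_model("JC69"), outgroup = "t1")
  expect_s3_class(pt, "posterior_table")
})

test_that("indel reconstruction recodes gaps and matches the oracle", {
  # two-leaf symmetric case: one gap, one present -> (0.5, 0.5) at the root
  tree <- parse_newick("(a:0.2,b:0.2);")
  aln <- new_alignment(c(a = "A", b = "-"), "dna")
  pt <- indel_asr(tree, aln)
  root_id <- dimnames(pt)[[1]][1]
  expect_equal(unname(pt[root_id, "1", ]), c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(dimnames(pt)[[3]], c("present", "gap"))

  # all leaves present on short branches -> ancestral presence near 1
  tree2 <- simulate_tree(6, 0.02, seed = 83)
  aln2 <- new_alignment(stats::setNames(rep("AAA", 6), tree2$tip.label),
                        "dna")
  pt2 <- indel_asr(tree2, aln2)
  expect_true(all(pt2[, , "present"] > 0.99))

  # oracle equivalence on the recoded data
  set.seed(84)
  for (i in 1:5) {
    tree3 <- simulate_tree(sample(3:5, 1), 0.5)
    aln3 <- random_alignment(tree3, 8, c("A", "C", "G", "T"), "dna",
                             gap_prob = 0.4)
    pt3 <- indel_asr(tree3, aln3)
    rec <- aln3
    m <- matrix("0", nrow(aln3$mat), ncol(aln3$mat))
    m[aln3$mat == "-"] <- "1"
    rec$mat <- m
    rec$alphabet <- "binary"
    or <- oracle_marginal(tree3, rec, build_model("JC2"))
    expect_equal(max(abs(unclass(pt3)[, , ] - or$post)), 0,
                 tolerance = 1e-10)
  }
})

test_that("codon combination multiplies nucleotide posteriors", {
  nodes <- "n1"
  mk <- function(p_per_site, states) {
    arr <- array(0, c(1, nrow(p_per_site), length(states)),
                 dimnames = list(nodes,
                                 as.character(seq_len(nrow(p_per_site))),
                                 states))
    arr[1, , ] <- p_per_site
    posterior_table(arr)
  }
  nuc <- mk(rbind(c(0.9, 0.1, 0, 0),     # A: 0.9
                  c(0, 0.8, 0.2, 0),     # C: 0.8
                  c(0, 0, 1, 0)),        # G: 1.0
            c("A", "C", "G", "T"))
  ind <- mk(rbind(c(1, 0), c(1, 0), c(1, 0)), c("present", "gap"))
  cp <- combine_codon(nuc, ind)
  expect_equal(cp$raw["n1", "1", "ACG"], 0.72, tolerance = 1e-12)
  expect_equal(sum(cp$renorm["n1", "1", ]), 1, tolerance = 1e-12)
  expect_equal(cp$renorm["n1", "1", "---"], 0)

  # certain codon
  nuc2 <- mk(rbind(c(1, 0, 0, 0), c(0, 0, 0, 1), c(0, 0, 1, 0)),
             c("A", "C", "G", "T"))
  cp2 <- combine_codon(nuc2, ind)
  expect_equal(cp2$raw["n1", "1", "ATG"], 1, tolerance = 1e-12)
  expect_equal(sum(cp2$raw["n1", "1", ] > 0), 1L)

  # full gap posterior supersedes the codon states
  ind3 <- mk(rbind(c(0, 1), c(0, 1), c(0, 1)), c("present", "gap"))
  cp3 <- combine_codon(nuc, ind3)
  expect_equal(cp3$renorm["n1", "1", "---"], 1)
  expect_equal(sum(cp3$renorm["n1", "1", 1:64]), 0)
})

test_that("residue posteriors sum synonymous codons and conserve mass", {
  nodes <- "n1"
  arr <- array(0, c(1, 3, 4),
               dimnames = list(nodes, c("1", "2", "3"),
                               c("A", "C", "G", "T")))
  # nucleotide mix at position 3 splits the codon mass between AAA and
  # AAG; both are Lys, so the residue posterior re-collects it
  p3 <- rbind(c(1, 0, 0, 0),            # A
              c(1, 0, 0, 0),            # A
              c(0.3 / 0.55, 0, 0.25 / 0.55, 0))  # A vs G mix
  pt_arr <- array(0, c(1, 3, 4),
                  dimnames = list(nodes, c("1", "2", "3"),
                                  c("A", "C", "G", "T")))
  pt_arr[1, , ] <- p3
  nucpt <- posterior_table(pt_arr)
  ind <- posterior_table(array(rep(c(1, 0), each = 3), c(1, 3, 2),
                               dimnames = list(nodes, c("1", "2", "3"),
                                               c("present", "gap"))))
  cp <- combine_codon(nucpt, ind)
  res <- residue_posteriors(cp)
  expect_equal(res["n1", "1", "K"], 1, tolerance = 1e-12)  # AAA+AAG both Lys

  # random tables conserve residue + gap + stop mass
  set.seed(85)
  tree <- simulate_tree(6, 0.6)
  sim <- simulate_evolution(tree, 10, seed = 86)
  nucp <- marginal_asr(tree, sim$alignment, sim$truth$model)
  indp <- indel_asr(tree, sim$alignment)
  cpp <- combine_codon(nucp, indp)
  resp <- suppressWarnings(residue_posteriors(cpp))
  tot <- apply(unclass(resp), c(1, 2), sum) + attr(resp, "stop_mass")
  expect_equal(max(abs(tot - 1)), 0, tolerance = 1e-9)
})

test_that("single certain codon gives a certain residue", {
  nuc_arr <- array(0, c(1, 3, 4),
                   dimnames = list("n1", c("1", "2", "3"),
                                   c("A", "C", "G", "T")))
  nuc_arr[1, 1, "A"] <- 1; nuc_arr[1, 2, "T"] <- 1; nuc_arr[1, 3, "G"] <- 1
  nuc <- posterior_table(nuc_arr)
  ind <- posterior_table(array(rep(c(1, 0), each = 3), c(1, 3, 2),
                               dimnames = list("n1", c("1", "2", "3"),
                                               c("present", "gap"))))
  res <- residue_posteriors(combine_codon(nuc, ind))
  expect_equal(res["n1", "1", "M"], 1, tolerance = 1e-12)
})

test_that("reference position mapping translates residue indices", {
  aln <- new_alignment(c(ref = "M-AC", other = "MKAC"), "protein")
  expect_equal(unname(map_reference_positions(aln, "ref", 2)), 3L)
  expect_equal(unname(map_reference_positions(aln, "ref", 1)), 1L)
  expect_error(map_reference_positions(aln, "ref", 5), "outside")
  expect_error(map_reference_positions(aln, "nope", 1), "not in alignment")
})

test_that("variant enumeration follows the ambiguity threshold", {
  states <- c("D", "E", "K", "N")
  arr <- array(0, c(1, 3, 4),
               dimnames = list("node1", c("10", "11", "12"), states))
  arr[1, 1, ] <- c(0, 1, 0, 0)            # certain E
  arr[1, 2, ] <- c(0.55, 0, 0, 0.45)      # ambiguous D/N
  arr[1, 3, ] <- c(0, 0, 1, 0)            # certain K
  pt <- posterior_table(arr)
  v <- call_variants(pt, columns = c(10, 11, 12), threshold = 0.3)
  expect_equal(nrow(v), 2L)
  expect_equal(v$label, c("ancnode1.1", "ancnode1.2"))
  expect_equal(v$sequence[1], "EDK")       # higher joint probability first
  expect_equal(v$sequence[2], "ENK")
  expect_equal(v$probability, c(0.55, 0.45), tolerance = 1e-12)

  # all unambiguous -> exactly one variant
  arr1 <- arr; arr1[1, 2, ] <- c(1, 0, 0, 0)
  v1 <- call_variants(posterior_table(arr1), columns = c(10, 11, 12))
  expect_equal(nrow(v1), 1L)

  # two ambiguous positions -> Cartesian product in descending order
  arr2 <- arr; arr2[1, 1, ] <- c(0, 0.6, 0.4, 0)
  v2 <- call_variants(posterior_table(arr2), columns = c(10, 11, 12))
  expect_equal(nrow(v2), 4L)
  expect_equal(v2$probability, sort(v2$probability, decreasing = TRUE))
  expect_equal(v2$probability[1], 0.6 * 0.55, tolerance = 1e-12)

  # candidate count product respected below the cap
  expect_equal(nrow(v2), 2L * 2L * 1L)
})

test_that("variant enumeration warns and truncates at the cap", {
  states <- c("A", "C", "D", "E")
  arr <- array(1 / 3, c(1, 3, 4),
               dimnames = list("n", c("1", "2", "3"), states))
  arr[, , 4] <- 0
  pt <- posterior_table(arr)
  expect_warning(v <- call_variants(pt, columns = 1:3, threshold = 0.3,
                                    max_variants = 5L), "truncated")
  expect_equal(nrow(v), 5L)

  # no state above threshold -> MAP with warning
  arr2 <- array(c(0.28, 0.26, 0.24, 0.22), c(1, 1, 4),
                dimnames = list("n", "1", states))
  expect_warning(v2 <- call_variants(posterior_table(arr2), columns = 1,
                                     threshold = 0.3), "MAP")
  expect_equal(v2$sequence, "A")
})
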