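test_that("progressive_align returns a consistent alignment in input order", {
  seqs <- c(s1 = "MKVLAWDYCHEKK", s2 = "MKVLWDYCHEKK", s3 = "MKVLAWDYAHEKK",
            s4 = "GGGMKVLAWDYCH")
  msa <- progressive_align(seqs)
  expect_s3_class(msa, "mca_msa")
  expect_identical(msa$labels, names(seqs))
  expect_equal(length(unique(nchar(msa$rows))), 1)
  # ungapping each row recovers the input sequence exactly
  for (nm in names(seqs)) {
    expect_identical(gsub("-", "", msa$rows[[nm]]), seqs[[nm]])
  }
  # single- and two-sequence cases
  expect_identical(progressive_align(seqs[1])$rows[[1]], seqs[[1]])
  m2 <- progressive_align(seqs[1:2])
  expect_identical(gsub("-", "", m2$rows[[2]]), seqs[[2]])
  expect_error(progressive_align(unname(seqs)), "names")
})

test_that("distances computes p-distance and Poisson correction", {
  msa <- new_msa(c(a = "AAAA", b = "AAAT", c = "A-TT"))
  dp <- distances(msa, model = "p-distance")
  expect_equal(dp$matrix["a", "b"], 1 / 4)
  expect_equal(dp$matrix["a", "c"], 2 / 3)  # pairwise deletion: 3 sites
  expect_equal(diag(dp$matrix), rep(0, 3), ignore_attr = TRUE)
  po <- distances(msa, model = "poisson")
  expect_equal(po$matrix["a", "b"], -log(1 - 1 / 4))
  dc <- distances(msa, model = "p-distance", deletion = "complete")
  expect_equal(dc$matrix["a", "b"], 1 / 3)  # gapped column dropped for all
  # saturation and empty-overlap errors name the pair
  expect_error(distances(new_msa(c(a = "AA", b = "TT"))),
               "undefined-distance.*'a' and 'b'")
  expect_error(distances(new_msa(c(a = "A-", b = "-A"))),
               "undefined-distance")
})

test_that("nj_tree solves a hand-computable four-taxon case", {
  # tree ((a:1, b:2):5, c:3, d:4) with internal edge 5
  D <- matrix(c(0, 3, 9, 10,
                3, 0, 10, 11,
                9, 10, 0, 7,
                10, 11, 7, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- nj_tree(D)
  expect_equal(ape::cophenetic.phylo(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
  # a+b vs c+d is the internal split
  expect_true(cbmca:::.is_split(tr, c("a", "b")))
  expect_false(cbmca:::.is_split(tr, c("a", "c")))
  expect_error(nj_tree(D[1:2, 1:2]), "3 labels")
  D2 <- D; D2[1, 2] <- D2[2, 1] <- NA
  expect_error(nj_tree(D2), "non-finite")
})

test_that("nj_tree recovers random additive trees (light property check)", {
  set.seed(17)
  for (i in 1:50) {
    tr <- random_additive_tree(sample(4:12, 1))
    D <- ape::cophenetic.phylo(tr)
    est <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ape::cophenetic.phylo(est)[rownames(D), colnames(D)] -
                        D)), 1e-9)
  }
})

test_that("negative NJ edges are clamped without breaking the topology", {
  # a non-additive matrix known to produce a negative NJ edge estimate
  D <- matrix(c(0, 2, 2, 10,
                2, 0, 3, 2,
                2, 3, 0, 2,
                10, 2, 2, 0), 4, 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length >= 0))
})

test_that("bootstrap_support reports supports and respects its seed", {
  set.seed(41)
  seqs <- c(stats::setNames(varied_cassettes("alpha", 3), paste0("a", 1:3)),
            stats::setNames(varied_cassettes("beta", 3), paste0("b", 1:3)))
  msa <- progressive_align(seqs)
  t1 <- bootstrap_support(msa, n_replicates = 50, seed = 2)
  t2 <- bootstrap_support(msa, n_replicates = 50, seed = 2)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(stats::na.omit(as.numeric(t1$node.label)) >= 0))
  expect_true(all(stats::na.omit(as.numeric(t1$node.label)) <= 100))
  expect_equal(attr(t1, "n_replicates") + attr(t1, "n_skipped"), 50)
  sup <- clade_support(t1, paste0("a", 1:3))
  expect_false(is.na(sup))
  expect_true(is.na(clade_support(t1, c("a1", "b1"))))
  # zero replicates: point tree, no supports
  t0 <- bootstrap_support(msa, n_replicates = 0)
  expect_null(t0$node.label)
  expect_equal(attr(t0, "n_replicates"), 0)
})

test_that("outgroup rooting preserves supports and rejects non-splits", {
  set.seed(43)
  seqs <- c(stats::setNames(varied_cassettes("alpha", 3), paste0("a", 1:3)),
            stats::setNames(varied_cassettes("beta", 2), paste0("b", 1:2)))
  tr <- bootstrap_support(progressive_align(seqs), n_replicates = 30,
                          seed = 1)
  rooted <- root_with_outgroup(tr, c("b1", "b2"))
  expect_true(ape::is.rooted(rooted))
  expect_setequal(rooted$tip.label, tr$tip.label)
  expect_error(root_with_outgroup(tr, c("zz")), "not in tree")
})

test_that("newick serialization round-trips topology, lengths and labels", {
  set.seed(44)
  tr <- random_additive_tree(8)
  tr$node.label <- as.character(seq_len(tr$Nnode) * 10)
  txt <- to_newick(tr)
  back <- from_newick(txt)
  expect_equal(ape::dist.topo(tr, back), 0, ignore_attr = TRUE)
  expect_equal(sort(back$edge.length), sort(tr$edge.length),
               tolerance = 1e-6)
  expect_identical(sort(back$node.label), sort(tr$node.label))
  expect_error(from_newick("((a,b),(c,d);"), "parse error")
  expect_error(from_newick("(a,b))c;"), "position")
})
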