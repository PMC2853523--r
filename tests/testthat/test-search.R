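# Helper proteins for transitivity tests: three 120-residue sequences where
# B shares its first half with A and its second half with C, while A and C
# share nothing.
.make_chain <- function() {
  set.seed(55)
  part <- function() paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G",
                                    "H", "I", "L", "K", "M", "F", "P", "S",
                                    "T", "W", "Y", "V"), 60, replace = TRUE),
                           collapse = "")
  pa <- part(); pb <- part(); pc <- part(); pd <- part()
  list(A = paste0(pa, pb), B = paste0(pb, pc), C = paste0(pc, pd))
}

test_that("iterative_search finds transitive hits through query expansion", {
  ch <- .make_chain()
  db <- c(geneB = ch$B, geneC = ch$C)
  res <- iterative_search(c(q = ch$A), db)
  expect_setequal(res$hits, c("geneB", "geneC"))
  expect_true(res$converged)
  # geneC is reachable only through geneB, so it must arrive in round 2
  lg <- res$log
  expect_equal(lg$round[lg$gene_id == "geneB"], 1)
  expect_equal(lg$round[lg$gene_id == "geneC"], 2)
  expect_equal(lg$added_by_query[lg$gene_id == "geneC"], "geneB")
})

test_that("round thresholds are applied per round and logged", {
  ch <- .make_chain()
  db <- c(geneB = ch$B, geneC = ch$C)
  res <- iterative_search(c(q = ch$A), db,
                          config = search_config(c(1e-10, 1e-10, 2e-20)))
  expect_equal(res$log$threshold[res$log$round == 1], rep(1e-10, 1))
  # an absurdly strict first-round threshold blocks everything
  res2 <- iterative_search(c(q = ch$A), db,
                           config = search_config(1e-300, max_rounds = 5))
  expect_length(res2$hits, 0)
  expect_true(res2$converged)
})

test_that("rejected candidates are never revisited", {
  ch <- .make_chain()
  db <- c(geneB = ch$B, geneC = ch$C)
  calls <- character(0)
  res <- iterative_search(c(q = ch$A), db, validate = function(gid, s) {
    calls <<- c(calls, gid)
    FALSE
  })
  expect_length(res$hits, 0)
  expect_true(res$converged)
  expect_false(anyDuplicated(calls) > 0)
})

test_that("search converges when a round adds nothing and flags truncation", {
  ch <- .make_chain()
  db <- c(geneB = ch$B, geneC = ch$C)
  res <- iterative_search(c(q = ch$A), db,
                          config = search_config(1e-10, max_rounds = 1))
  expect_identical(res$hits, "geneB")
  expect_false(res$converged)  # stopped by max_rounds with work pending
  expect_equal(res$rounds, 1)
})

test_that("search input contracts are enforced", {
  expect_error(iterative_search(character(0), c(a = "AAA")), "empty query")
  expect_error(iterative_search(c(q = "AAA"), "AAA"), "named")
  expect_error(iterative_search(c("AAA"), c(a = "AAA")), "named")
  expect_error(iterative_search(c(q = "AAA"), c(a = "A1A")),
               "invalid-alphabet")
})

test_that("E-values in the log use query length times database residues", {
  ch <- .make_chain()
  db <- c(geneB = ch$B, geneC = ch$C)
  res <- iterative_search(c(q = ch$A), db)
  s <- scoring_scheme()
  rowB <- res$log[res$log$gene_id == "geneB", ]
  expect_equal(rowB$best_evalue,
               evalue(rowB$best_score, m = nchar(ch$A),
                      n = sum(nchar(db)), scheme = s))
})
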