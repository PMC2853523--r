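test_that("scan_profile finds a planted consensus at the right position", {
  m <- builtin_models()$singles$GUN4
  set.seed(3)
  flank1 <- rand_seq(37, alphabet = c("A", "E", "K", "L"))
  flank2 <- rand_seq(50, alphabet = c("A", "E", "K", "L"))
  seq <- paste0(flank1, m$consensus, flank2)
  h <- scan_profile(seq, m)
  expect_equal(nrow(h), 1)
  expect_equal(h$start, 38)
  expect_equal(h$end, 38 + nchar(m$consensus) - 1)
  expect_equal(h$score, m$max_score)
  # window score equals the manual column-sum at the hit offset
  cols <- strsplit(m$consensus, "")[[1]]
  manual <- sum(vapply(seq_along(cols),
                       function(j) m$scores[cols[j], j], numeric(1)))
  expect_equal(h$score, manual)
})

test_that("scan_profile hits are non-overlapping and greedy by score", {
  m <- builtin_models()$repeats$WD40
  seq <- strrep(m$consensus, 4)
  h <- scan_profile(seq, m)
  expect_equal(nrow(h), 4)
  o <- order(h$start)
  expect_true(all(h$start[o][-1] > h$end[o][-nrow(h)]))
})

test_that("detect_repeats collapses tandem units with a copy count", {
  m <- builtin_models()$repeats$Pentapeptide
  seq <- paste0("AEK", strrep(m$consensus, 4), "LLE")
  h <- detect_repeats(seq, m)
  expect_equal(nrow(h), 1)
  expect_equal(h$copies, 4)
  expect_equal(h$domain_type, "Pentapeptide")
  expect_equal(h$start, 4)
  expect_equal(h$end, 3 + 4 * nchar(m$consensus))
  # below min_copies nothing is reported
  expect_equal(nrow(detect_repeats(strrep(m$consensus, 2), m)), 0)
})

test_that("detect_tm matches the window-mean oracle", {
  seqs <- c(
    paste0(strrep("D", 30), strrep("I", 25), strrep("D", 30)),
    paste0(strrep("L", 22), strrep("K", 40)),
    strrep("D", 60),
    "AK")  # shorter than the window
  for (s in seqs) {
    hits <- detect_tm(s)
    hot <- oracle_tm_windows(s)
    expect_equal(nrow(hits) > 0, length(hot) > 0, info = substr(s, 1, 10))
    if (nrow(hits)) {
      expect_equal(min(hits$start), min(hot))
      expect_equal(max(hits$end), max(hot) + 19 - 1)
    }
  }
  set.seed(9)
  for (i in 1:25) {
    s <- rand_seq(80, alphabet = c("I", "L", "V", "D", "K", "G"))
    expect_equal(nrow(detect_tm(s)) > 0, length(oracle_tm_windows(s)) > 0)
  }
})

test_that("architecture strings parse and render round-trip", {
  d <- parse_architecture("NACHT, WD40(13)")
  expect_equal(d$domain_type, c("NACHT", "WD40"))
  expect_equal(d$copies, c(1L, 13L))
  expect_identical(render_architecture(d), "NACHT, WD40(13)")
  expect_equal(nrow(parse_architecture("")), 0)
  expect_identical(render_architecture(parse_architecture("")), "")
  expect_error(parse_architecture("WD40(3), Kinase"), "unknown-domain")
  expect_error(parse_architecture("Kinase"), "Kinase")
  # case-insensitive type matching normalizes to the canonical name
  expect_identical(parse_architecture("wd40(2)")$domain_type, "WD40")
})

test_that("all fixture architecture strings round-trip", {
  rec <- load_table2_fixture()
  for (txt in rec$domains) {
    d <- parse_architecture(txt)
    expect_identical(render_architecture(d), txt)
  }
  total <- sum(vapply(rec$domains,
                      function(t) sum(parse_architecture(t)$copies),
                      numeric(1)))
  expect_equal(total, 276)
})

test_that("annotate assembles CASc, accessory domains and TM", {
  set.seed(11)
  p <- cbmca:::.plant_protein("beta", sim_config(dyad_mutation_rate = 0))
  arch <- annotate(p$sequence)
  expect_s3_class(arch, "domain_architecture")
  expect_true("CASc" %in% arch$hits$domain_type)
  got <- cbmca:::.additional_hits(arch)
  expect_identical(
    render_architecture(got[order(got$start), c("domain_type", "copies")]),
    p$domains)
  ptm <- cbmca:::.plant_protein("alpha-TM", sim_config(dyad_mutation_rate = 0))
  atm <- annotate(ptm$sequence)
  expect_true(atm$has_tm)
  expect_identical(atm$casc_position, "N-terminal")
  pc <- cbmca:::.plant_protein("alpha-C", sim_config(dyad_mutation_rate = 0))
  expect_identical(annotate(pc$sequence)$casc_position, "C-terminal")
})

test_that("annotate reports no CASc on background decoys (specificity)", {
  set.seed(21)
  cfg <- sim_config()
  for (i in 1:100) {
    s <- cbmca:::.clean_segment(400, cfg$background, forbid_tm = FALSE,
                                forbid_any_context = FALSE)
    arch <- annotate(s)
    expect_false("CASc" %in% arch$hits$domain_type)
    expect_equal(nrow(cbmca:::.additional_hits(arch)), 0)
  }
})
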