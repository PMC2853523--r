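test_that("validate_metacaspase applies the acceptance rules", {
  cfg <- sim_config(dyad_mutation_rate = 0)
  set.seed(31)
  p <- cbmca:::.plant_protein("alpha-other", cfg)
  arch <- annotate(p$sequence)
  dyad <- scan_dyad(p$sequence)
  expect_identical(validate_metacaspase(arch, dyad),
                   list(accepted = TRUE, reason = "none"))
  # substituted dyad: accepted unless strict
  ps <- cbmca:::.plant_protein("alpha-other",
                               sim_config(dyad_mutation_rate = 1))
  archs <- annotate(ps$sequence)
  dyads <- scan_dyad(ps$sequence)
  expect_true(validate_metacaspase(archs, dyads)$accepted)
  strict <- validate_metacaspase(archs, dyads, strict = TRUE)
  expect_false(strict$accepted)
  expect_identical(strict$reason, "dyad-substituted-strict")
  # no P20 hit
  decoy <- annotate(cbmca:::.clean_segment(200, cfg$background))
  expect_identical(validate_metacaspase(decoy, scan_dyad(strrep("A", 30)))$reason,
                   "no-P20")
})

test_that("assign_family follows the precedence rules", {
  cfg <- sim_config(dyad_mutation_rate = 0)
  set.seed(32)
  for (sf in c("alpha-I", "alpha-TM", "alpha-other", "alpha-C")) {
    p <- cbmca:::.plant_protein(sf, cfg)
    fam <- assign_family(annotate(p$sequence))
    expect_identical(fam$family, "alpha", info = sf)
    expect_identical(fam$subfamily, sf)
  }
  pb <- cbmca:::.plant_protein("beta", cfg)
  famb <- assign_family(annotate(pb$sequence))
  expect_identical(famb$family, "beta")
  expect_true(is.na(famb$subfamily))
  # extension_min moves the alpha-other/alpha-I boundary
  pi <- cbmca:::.plant_protein("alpha-I", cfg)
  archi <- annotate(pi$sequence)
  expect_identical(assign_family(archi, extension_min = 1L)$subfamily,
                   "alpha-other")
  decoy <- annotate(cbmca:::.clean_segment(200, cfg$background))
  expect_error(assign_family(decoy), "not-a-metacaspase")
})

test_that("classify_protein matches the generator truth (seeds 1-3)", {
  for (seed in 1:3) {
    sim <- generate_proteome(sim_config(seed = seed, n_strains = 1,
                                        proteins_per_strain = 8,
                                        mca_per_strain = 6))
    tr <- sim$truth[sim$truth$is_mca, ]
    for (k in seq_len(nrow(tr))) {
      s <- sim$proteomes[[tr$strain[k]]][[tr$gene_id[k]]]
      r <- classify_protein(s, gene_id = tr$gene_id[k],
                            strain = tr$strain[k])
      expect_true(r$accepted, info = tr$gene_id[k])
      got <- if (r$family == "beta") "beta" else r$subfamily
      expect_identical(got, tr$family[k], info = tr$gene_id[k])
      expect_identical(r$his_state, tr$his_state[k])
      expect_identical(r$cys_state, tr$cys_state[k])
      expect_identical(r$domains, tr$domains[k])
      expect_equal(r$p20_start, tr$p20_start[k])
      expect_equal(r$p20_end, tr$p20_end[k])
    }
  }
})

test_that("summarize_mca reconstructs the published per-strain table", {
  rec <- load_table2_fixture()
  st <- load_strain_table()
  s <- summarize_mca(rec, st)
  m <- merge(s$per_strain, st, by = "strain",
             suffixes = c(".calc", ".pub"))
  expect_equal(nrow(m), 33)
  expect_equal(m$n_mca.calc, m$n_mca.pub)
  expect_equal(m$pct_mca.calc, m$pct_mca.pub)
  expect_equal(m$n_mutated.calc, m$n_mutated.pub)
  expect_equal(m$n_additional_domains.calc, m$n_additional_domains.pub)
  # partition invariant: per-strain counts sum to the global census
  expect_equal(sum(s$per_strain$n_mca), s$totals$n_total)
  expect_equal(s$totals$n_alpha + s$totals$n_beta, s$totals$n_total)
  expect_equal(s$totals$n_alpha_I + s$totals$n_alpha_TM +
                 s$totals$n_alpha_other + s$totals$n_alpha_C,
               s$totals$n_alpha)
  expect_equal(sum(s$per_strain$n_additional_domains),
               s$totals$n_additional_domains)
  expect_error(summarize_mca(rec, st[-22, ]), "missing-strain")
})

test_that("round_half_up rounds halves away from zero", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(0.135, 2), 0.14)
  expect_equal(round_half_up(2.5), 3)
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(53.448275862, 1), 53.4)
})
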