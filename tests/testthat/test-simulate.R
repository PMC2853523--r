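test_that("sim_config validates its invariants", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(mca_per_strain = 50, proteins_per_strain = 40),
               "invalid-config")
  expect_error(sim_config(family_mix = c("alpha-I" = 0.5)), "invalid-config")
  expect_error(sim_config(family_mix = c(nope = 1)), "invalid-config")
  expect_error(sim_config(dyad_mutation_rate = 1.2), "invalid-config")
  expect_error(sim_config(wd40_copy_range = c(0, 5)), "invalid-config")
  expect_error(sim_config(background = rep(0.05, 19)), "invalid-config")
})

test_that("plant_p20_cassette is deterministic and validates states", {
  c1 <- plant_p20_cassette("Tyr", "Ser")
  c2 <- plant_p20_cassette("Tyr", "Ser")
  expect_identical(c1, c2)
  expect_equal(nchar(c1$segment), 340)
  expect_identical(substr(c1$segment, c1$his_position, c1$his_position), "Y")
  expect_identical(substr(c1$segment, c1$cys_position, c1$cys_position), "S")
  expect_error(plant_p20_cassette("His", "intact"), "invalid-spec")
  expect_error(plant_p20_cassette("intact", "Ala"), "invalid-spec")
  # the two lineage variants differ outside the catalytic machinery
  expect_false(identical(plant_p20_cassette(variant = "alpha")$segment,
                         plant_p20_cassette(variant = "beta")$segment))
})

test_that("generate_proteome is deterministic per seed", {
  s1 <- generate_proteome(sim_config(seed = 7))
  s2 <- generate_proteome(sim_config(seed = 7))
  expect_identical(s1$proteomes, s2$proteomes)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_proteome(sim_config(seed = 8))
  expect_false(identical(s1$proteomes, s3$proteomes))
  # and it restores the caller's RNG state
  set.seed(123); before <- .Random.seed
  invisible(generate_proteome(sim_config(seed = 7, n_strains = 1,
                                         proteins_per_strain = 4,
                                         mca_per_strain = 1)))
  expect_identical(.Random.seed, before)
})

test_that("the truth table matches the planted sequences", {
  sim <- generate_proteome(sim_config(seed = 4))
  cfg <- sim$config
  expect_equal(nrow(sim$truth), cfg$n_strains * cfg$proteins_per_strain)
  expect_equal(sum(sim$truth$is_mca), cfg$n_strains * cfg$mca_per_strain)
  tr <- sim$truth[sim$truth$is_mca, ]
  for (k in seq_len(nrow(tr))) {
    s <- sim$proteomes[[tr$strain[k]]][[tr$gene_id[k]]]
    d <- scan_dyad(s, span = c(tr$p20_start[k], tr$p20_end[k]))
    expect_identical(d$his_state, tr$his_state[k], info = tr$gene_id[k])
    expect_identical(d$cys_state, tr$cys_state[k], info = tr$gene_id[k])
  }
  expect_equal(sim$n_mutated_planted,
               sum(tr$his_state != "intact" | tr$cys_state != "intact"))
  # decoys never carry a full dyad pair within a catalytic-domain span
  dec <- sim$truth[!sim$truth$is_mca, ]
  for (k in seq_len(nrow(dec))) {
    s <- sim$proteomes[[dec$strain[k]]][[dec$gene_id[k]]]
    expect_false(cbmca:::.has_dyad_pair(s), info = dec$gene_id[k])
  }
})

test_that("dyad_mutation_rate 0 and 1 are respected", {
  s0 <- generate_proteome(sim_config(seed = 5, dyad_mutation_rate = 0))
  expect_equal(s0$n_mutated_planted, 0)
  t0 <- s0$truth[s0$truth$is_mca, ]
  expect_true(all(t0$his_state == "intact" & t0$cys_state == "intact"))
  s1 <- generate_proteome(sim_config(seed = 5, dyad_mutation_rate = 1))
  t1 <- s1$truth[s1$truth$is_mca, ]
  expect_true(all(t1$cys_state != "intact"))
  expect_equal(s1$n_mutated_planted, nrow(t1))
})

test_that("write_proteome / read_proteome_fasta round-trip", {
  sim <- generate_proteome(sim_config(seed = 6, n_strains = 2,
                                      proteins_per_strain = 5,
                                      mca_per_strain = 2))
  d <- withr::local_tempdir()
  paths <- write_proteome(sim, d)
  expect_true(all(file.exists(paths)))
  back <- read_proteome_fasta(d)
  expect_identical(back, sim$proteomes)
  expect_error(read_proteome_fasta(withr::local_tempdir()), "no .fasta")
})

test_that("seed_query_set is deterministic with intact dyads", {
  q1 <- seed_query_set()
  q2 <- seed_query_set()
  expect_identical(q1, q2)
  expect_named(q1, c("query_alpha", "query_beta"))
  for (q in q1) {
    d <- scan_dyad(q)
    expect_identical(d$his_state, "intact")
    expect_identical(d$cys_state, "intact")
  }
})
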