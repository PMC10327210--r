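test_that("locus generation is deterministic and matches its truth", {
  sim1 <- simulateRpnLocus(seed = 7L)
  sim2 <- simulateRpnLocus(seed = 7L)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  writeFasta(sequences(sim1$bundle), f1)
  writeFasta(sequences(sim2$bundle), f2)
  expect_identical(readLines(f1), readLines(f2))
  g1 <- withr::local_tempfile(); g2 <- withr::local_tempfile()
  writeGff3(annotations(sim1$bundle), g1)
  writeGff3(annotations(sim2$bundle), g2)
  expect_identical(readLines(g1), readLines(g2))

  # generator/scorer cross-check: planted SD scores exactly as configured
  cds <- as.character(extractCds(sim1$bundle, "parent1"))
  p <- 3L * (sim1$truth$itis_codon_index - 1L) + 1L
  sc <- scoreRbs(substr(cds, p - 19L, p - 1L))
  expect_equal(sc$match_len, 6L)
  expect_equal(sc$spacer_nt, 7L)
})

test_that("a zero-match locus has no SD-like hexamer in the RBS window", {
  for (seed in 1:10) {
    sim <- simulateRpnLocus(seed = seed, rbs_match_len = 0L)
    cds <- as.character(extractCds(sim$bundle, "parent1"))
    p <- 3L * (sim$truth$itis_codon_index - 1L) + 1L
    w <- substr(cds, p - 19L, p - 1L)
    expect_lt(oracle_score_rbs(w)$match_len, 4L)
  }
})

test_that("locus generation rejects incompatible geometry", {
  expect_error(simulateRpnLocus(itis_codon_index = 200L,
                                parent_len_codons = 120L),
               "incompatible")
  expect_error(simulateRpnLocus(itis_codon_index = 4L, rbs_spacer_nt = 7L),
               "too close")
})

test_that("profiling tracks carry the configured initiation peaks", {
  sim <- simulateRpnLocus(seed = 8L)
  trk <- simulateRiboseqTracks(sim$bundle, sim$truth,
                               peak_enrichment = 50, background_depth = 2,
                               seed = 9L)
  tv <- trackValues(trk$initiation_trapped)$locus1
  pos <- sim$truth$itis_genome_pos
  peak_max <- max(tv[(pos - 9L):(pos + 9L)])
  local_med <- median(tv[(pos - 100L):(pos + 100L)])
  expect_gte(peak_max, 50 * local_med)

  # zero-depth configuration yields all-zero tracks
  z <- simulateRiboseqTracks(sim$bundle, sim$truth, peak_enrichment = 50,
                             background_depth = 0, seed = 9L)
  expect_true(all(trackValues(z$untreated)$locus1 == 0))
  expect_true(all(trackValues(z$initiation_trapped)$locus1 == 0))
})

test_that("unit peak enrichment makes the tracks indistinguishable", {
  sim <- simulateRpnLocus(seed = 10L)
  trk <- simulateRiboseqTracks(sim$bundle, sim$truth, peak_enrichment = 1,
                               background_depth = 5, seed = 11L)
  ann <- annotations(sim$bundle)
  cds_rng <- ann[ann$feature_type == "CDS"]
  idx <- BiocGenerics::start(cds_rng):BiocGenerics::end(cds_rng)
  p <- mannWhitneyU(trackValues(trk$initiation_trapped)$locus1[idx],
                    trackValues(trk$untreated)$locus1[idx],
                    "two_sided")$p_value
  expect_gt(p, 0.01)
})

test_that("strain panels vary only by whole repeat units", {
  pan <- simulateStrainPanel(c(2L, 3L), repeat_unit = "KGIE", seed = 13L)
  rep23 <- compareRepeatCounts(pan)
  expect_equal(unname(rep23$copies), c(2L, 3L))
  expect_equal(rep23$deltas, 1L)
  expect_true(rep23$indel_consistent)

  # single-member truths: the caller reports the configured copy number
  for (k in c(2L, 5L)) {
    pank <- simulateStrainPanel(k, seed = 14L)
    reg <- findTandemRepeats(as.character(pank[[1]]))
    expect_equal(reg$copies, k)
    expect_equal(reg$start_aa - 1L, 12L)   # configured insertion offset
  }

  # zero copies returns the base protein unchanged
  pan0 <- simulateStrainPanel(c(0L, 3L), seed = 15L)
  truth <- attr(pan0, "truth")
  expect_equal(as.character(pan0[[1]]), truth$base_protein)
  expect_error(simulateStrainPanel(-1L), ">= 0")
})

test_that("defense context generator produces the configured clustering", {
  ctx <- simulateDefenseContext(n_genes = 400L, n_focal = 10L,
                                window_genes = 5L, p_near = 1, p_bg = 0,
                                seed = 16L)
  fr <- vapply(ctx$focal_ids, function(g)
    neighborhoodFraction(ctx$annotations, g, 5L)$fraction, numeric(1))
  expect_true(all(fr == 1))

  ctx2 <- simulateDefenseContext(seed = 17L)
  ctx3 <- simulateDefenseContext(seed = 17L)
  expect_identical(ctx2$annotations$defense_flag,
                   ctx3$annotations$defense_flag)
  expect_error(simulateDefenseContext(p_near = 0.1, p_bg = 0.5),
               "p_near")
})

test_that("toy structure coordinates are deterministic", {
  a <- generateToyStructure("helix_bundle_dimer", seed = 3L,
                            jitter_sd = 0.05)
  b <- generateToyStructure("helix_bundle_dimer", seed = 3L,
                            jitter_sd = 0.05)
  expect_identical(atoms(a), atoms(b))
  c <- generateToyStructure("helix_bundle_dimer", seed = 4L,
                            jitter_sd = 0.05)
  expect_false(identical(atoms(a)$x, atoms(c)$x))
})
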