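test_that("RBS scoring recovers a perfect consensus and a null window", {
  w <- paste0(strrep("C", 6), "AGGAGG", strrep("C", 7))
  sc <- scoreRbs(w)
  expect_equal(sc$match_len, 6L)
  expect_equal(sc$spacer_nt, 7L)

  null <- scoreRbs(strrep("C", 19))
  expect_equal(null$match_len, 0L)

  expect_error(scoreRbs("ACGT"), "shorter than")
})

test_that("RBS scoring equals exhaustive enumeration on random windows", {
  set.seed(201)
  for (i in 1:300) {
    w <- rand_dna(sample(10:30, 1L))
    got <- scoreRbs(w)
    want <- oracle_score_rbs(w)
    expect_equal(got$match_len, want$match_len, info = w)
    if (want$match_len > 0L)
      expect_equal(got$spacer_nt, want$spacer_nt, info = w)
  }
})

test_that("internal ORF scan counts codons and protein lengths correctly", {
  # 32-codon CDS (96 nt), single internal ATG at codon 13
  codons <- c("ATG", rep("GCA", 30L), "TAA")
  codons[13L] <- "ATG"
  cds <- paste(codons, collapse = "")
  got <- findInternalOrfs(cds, min_offset_codons = 5L, min_len_aa = 5L)
  expect_equal(nrow(got), 1L)
  expect_equal(got$codon_index, 13L)
  expect_equal(got$small_protein_len_aa, 19L)   # 31 - 13 + 1

  none <- findInternalOrfs(paste(c("ATG", rep("GCA", 30L), "TAA"),
                                 collapse = ""), 5L, 5L)
  expect_equal(nrow(none), 0L)

  expect_error(findInternalOrfs("ATGGC"), "divisible by 3")
  expect_error(findInternalOrfs("ATGGCAGCA"), "stop codon")
})

test_that("internal ORF scan equals brute-force codon scan on random CDSs", {
  set.seed(202)
  for (i in 1:50) {
    cds <- rand_cds(sample(40:120, 1L))
    mo <- sample(c(5L, 20L, 30L), 1L)
    ml <- sample(c(5L, 10L, 20L), 1L)
    got <- findInternalOrfs(cds, mo, ml)
    want <- oracle_internal_orfs(cds, mo, ml)
    expect_equal(got$codon_index, want$codon_index)
    expect_equal(got$start_codon, want$start_codon)
    expect_equal(got$small_protein_len_aa, want$small_protein_len_aa)
  }
})

test_that("initiation peak calling computes enrichment against local median", {
  L <- 500L
  tv <- rep(2, L); tv[248:252] <- 100
  uv <- rep(2, L)
  treated <- CoverageTrack(list(c1 = tv), "initiation_trapped")
  untreated <- CoverageTrack(list(c1 = uv), "untreated")
  pk <- callInitiationPeaks(treated, untreated, "c1", 250L)
  expect_equal(pk$peak_enrichment, 50)
  expect_true(pk$peak)

  # treated identical to a uniform untreated track: no peak
  flat <- CoverageTrack(list(c1 = rep(5, L)), "initiation_trapped")
  flatu <- CoverageTrack(list(c1 = rep(5, L)), "untreated")
  pk2 <- callInitiationPeaks(flat, flatu, "c1", 250L)
  expect_false(pk2$peak)

  expect_error(callInitiationPeaks(treated, untreated, "c1", 600L),
               "outside contig")
})

test_that("evidence classification equals direct rule evaluation", {
  expect_equal(classifyItis(S4Vectors::DataFrame(
    rbs_match = 6L, peak = TRUE))$evidence_class, "sequence_and_profiling")
  expect_equal(classifyItis(S4Vectors::DataFrame(
    rbs_match = 6L, peak = NA))$evidence_class, "sequence_only")

  set.seed(203)
  cand <- S4Vectors::DataFrame(
    rbs_match = sample(0:6, 1000L, replace = TRUE),
    peak = sample(c(TRUE, FALSE, NA), 1000L, replace = TRUE))
  got <- classifyItis(cand, min_rbs = 4L)
  seq_ev <- cand$rbs_match >= 4L
  peak_ev <- !is.na(cand$peak) & cand$peak
  want <- ifelse(seq_ev & peak_ev, "sequence_and_profiling",
          ifelse(seq_ev, "sequence_only",
          ifelse(peak_ev, "profiling_only", NA)))
  expect_equal(got$evidence_class, want[!is.na(want)])
  expect_equal(nrow(got), sum(!is.na(want)))
})

test_that("full discovery pipeline classifies a simulated locus", {
  sim <- simulateRpnLocus(seed = 11L)
  trk <- simulateRiboseqTracks(sim$bundle, sim$truth, seed = 12L)
  b <- GenomeBundle(sequences(sim$bundle), annotations(sim$bundle),
                    unname(trk))
  calls <- discoverItis(b)
  hit <- calls[calls$codon_index == sim$truth$itis_codon_index, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$evidence_class, "sequence_and_profiling")
  expect_equal(hit$rbs_match, 6L)
  expect_equal(hit$small_protein_len_aa, sim$truth$small_protein_len_aa)
  expect_equal(hit$genome_pos, sim$truth$itis_genome_pos)

  # without tracks the same candidate is sequence evidence only
  calls2 <- discoverItis(sim$bundle)
  hit2 <- calls2[calls2$codon_index == sim$truth$itis_codon_index, ]
  expect_equal(hit2$evidence_class, "sequence_only")
})
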