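test_that("the KGIE worked example and degenerate inputs behave", {
  got <- findTandemRepeats("MNTKGIEKGIEKGIEWQ")
  expect_equal(nrow(got), 1L)
  expect_equal(got$copies, 3L)
  expect_equal(got$unit_as_found, "KGIE")
  expect_equal(got$unit, "EKGI")            # lexicographic rotation
  expect_equal(got$start_aa, 4L)
  expect_true(got$composition_ok)

  # homopolymer runs are period-1, never reported as period-4 arrays
  expect_equal(nrow(findTandemRepeats("MAAAAAAAA")), 0L)
  # short input: empty, no error
  expect_equal(nrow(findTandemRepeats("MKGIE")), 0L)
})

test_that("unit composition rule: one hydrophobic plus three charged/Gly", {
  expect_true(classifyUnitComposition("KGIE"))
  expect_false(classifyUnitComposition("LLKE"))   # two hydrophobic
  expect_false(classifyUnitComposition("KRED"))   # no hydrophobic
  expect_true(classifyUnitComposition("TAEL") == FALSE)  # T not charged
  expect_error(classifyUnitComposition("KG1E"), "non-amino-acid")
})

test_that("repeat caller equals brute-force enumeration on random strings", {
  set.seed(301)
  for (i in 1:1000) {
    # reduced alphabet so period-4 arrays actually occur by chance
    s <- rand_protein(sample(16:32, 1L), alphabet = c("K", "G", "I", "E"))
    got <- findTandemRepeats(s)
    want <- oracle_tandem_repeats(s)
    expect_equal(got$start_aa, want$start_aa, info = s)
    expect_equal(got$copies, want$copies, info = s)
  }
})

test_that("inserting one unit increments copies and preserves the unit", {
  set.seed(302)
  for (i in 1:25) {
    k <- sample(2:6, 1L)
    pan <- simulateStrainPanel(k, seed = i)
    s <- as.character(pan[[1]])
    reg <- findTandemRepeats(s)
    s2 <- insertRepeatUnits(s, reg$unit_as_found, 1L, reg$start_aa - 1L)
    reg2 <- findTandemRepeats(s2)
    expect_equal(reg2$copies, reg$copies + 1L)
    expect_equal(reg2$unit, reg$unit)
  }
})

test_that("reported regions reconstruct the underlying sequence", {
  set.seed(303)
  for (i in 1:50) {
    s <- rand_protein(sample(20:40, 1L), alphabet = c("K", "G", "I", "E"))
    regs <- findTandemRepeats(s)
    for (r in seq_len(nrow(regs))) {
      span <- substr(s, regs$start_aa[r],
                     regs$start_aa[r] + 4L * regs$copies[r] - 1L)
      expect_equal(span, strrep(regs$unit_as_found[r], regs$copies[r]))
    }
  }
})

test_that("repeat calling is invariant to flanking sequence content", {
  core <- strrep("KGIE", 4L)
  for (i in 1:10) {
    set.seed(400 + i)
    s <- paste0("M", rand_protein(sample(5:15, 1L), c("P", "S", "T", "W")),
                core,
                rand_protein(sample(5:15, 1L), c("P", "S", "T", "W")))
    got <- findTandemRepeats(s)
    kgie <- got[got$unit_as_found == "KGIE", , drop = FALSE]
    expect_equal(kgie$copies, 4L)
  }
})

test_that("cross-strain comparison detects unit-consistent indels", {
  pan <- simulateStrainPanel(c(3L, 4L), seed = 21L)
  cmp <- compareRepeatCounts(pan)
  expect_equal(cmp$deltas, 1L)
  expect_true(cmp$indel_consistent)

  # identical sequences: delta 0, consistent
  pan2 <- Biostrings::AAStringSet(c(a = as.character(pan[[1]]),
                                    b = as.character(pan[[1]])))
  cmp2 <- compareRepeatCounts(pan2)
  expect_equal(cmp2$deltas, 0L)
  expect_true(cmp2$indel_consistent)

  # a 3-residue (non-multiple-of-4) insertion inside the repeat region
  s <- as.character(pan[[1]])
  reg <- findTandemRepeats(s)
  s3 <- paste0(substr(s, 1L, reg$start_aa + 3L), "PQP",
               substr(s, reg$start_aa + 4L, nchar(s)))
  cmp3 <- compareRepeatCounts(Biostrings::AAStringSet(c(a = s, b = s3)))
  expect_false(cmp3$indel_consistent)

  expect_error(compareRepeatCounts(c(a = "MKGIEKGIE", b = "")), "empty")
})

test_that("repeat offsets relative to Met are computed and flagged", {
  reg <- data.frame(start_aa = 13L)
  off <- locateRepeatOffset(reg)
  expect_equal(off$offset, 12L)
  expect_false(off$flagged)
  off2 <- locateRepeatOffset(data.frame(start_aa = 3L))
  expect_equal(off2$offset, 2L)
  expect_true(off2$flagged)

  pan <- simulateStrainPanel(3L, insert_after_aa = 12L, seed = 22L)
  reg3 <- findTandemRepeats(as.character(pan[[1]]))
  expect_equal(locateRepeatOffset(reg3)$offset, 12L)
})
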