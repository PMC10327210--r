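.mk_genes <- function(flags, contig = "c1") {
  n <- length(flags)
  gr <- GenomicRanges::GRanges(contig,
    IRanges::IRanges(start = seq_len(n) * 1000L, width = 900L),
    strand = "+")
  gr$gene_id <- sprintf("g%02d", seq_len(n))
  gr$feature_type <- "gene"
  gr$defense_flag <- flags
  gr
}

test_that("neighborhood fractions count flags over the shrunken window", {
  # 11 genes, focal at index 6 (1-based), window 3: neighbors 3..9 minus
  # the focal gene; defense flags on two of the six neighbors
  flags <- rep(FALSE, 11L)
  flags[c(4L, 8L)] <- TRUE
  gr <- .mk_genes(flags)
  obs <- neighborhoodFraction(gr, "g06", window_genes = 3L)
  expect_equal(obs$n_neighbors, 6L)
  expect_equal(obs$n_defense, 2L)
  expect_equal(obs$fraction, 2 / 6)

  expect_equal(neighborhoodFraction(.mk_genes(rep(FALSE, 11L)), "g06",
                                    3L)$fraction, 0)
  # focal gene's own flag is excluded, so all-neighbors-flagged gives 1
  allf <- rep(TRUE, 11L)
  expect_equal(neighborhoodFraction(.mk_genes(allf), "g06", 3L)$fraction, 1)
  # contig edge shrinks the window
  edge <- neighborhoodFraction(gr, "g01", window_genes = 3L)
  expect_equal(edge$n_neighbors, 3L)
  expect_error(neighborhoodFraction(gr, "nope"), "absent")
})

test_that("random focal sampling is seeded, disjoint and uniform", {
  gr <- .mk_genes(rep(FALSE, 40L))
  a <- sampleRandomFocals(gr, 10L, seed = 1L, exclude = c("g01", "g02"))
  b <- sampleRandomFocals(gr, 10L, seed = 1L, exclude = c("g01", "g02"))
  expect_identical(a, b)
  expect_length(intersect(a, c("g01", "g02")), 0L)
  expect_error(sampleRandomFocals(gr, 39L, 1L, exclude = c("g01", "g02")),
               "eligible")

  # inclusion frequencies uniform within binomial 99% bounds
  draws <- 10000L
  counts <- table(unlist(lapply(seq_len(draws), function(i)
    sampleRandomFocals(gr, 2L, seed = i))))
  p <- 2 / 40
  bound <- 2.58 * sqrt(draws * p * (1 - p))
  expect_true(all(abs(counts - draws * p) < bound))
})

test_that("Mann-Whitney exact p-values match the worked enumerations", {
  r <- mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "less")
  expect_equal(r$U, 0)
  expect_equal(r$p_value, 1 / 20)
  expect_equal(r$method, "exact")
  expect_equal(mannWhitneyU(c(1, 2, 3), c(4, 5, 6), "two_sided")$p_value,
               0.10)
  r2 <- mannWhitneyU(c(1, 3), c(2, 4), "two_sided")
  expect_equal(r2$U, 1)
  expect_equal(r2$p_value, 2 / 3)
  # identical samples: no effect, approximate path because of ties
  r3 <- mannWhitneyU(c(1, 2, 3), c(1, 2, 3), "two_sided")
  expect_equal(r3$p_value, 1)
  expect_equal(r3$method, "normal_approx")
  expect_error(mannWhitneyU(numeric(0), 1), "empty")
})

test_that("tie-corrected normal approximation matches the reference", {
  set.seed(601)
  for (i in 1:25) {
    x <- sample(0:5, 30L, replace = TRUE) / 10
    y <- sample(0:5, 25L, replace = TRUE) / 10
    for (alt in c("two_sided", "greater", "less")) {
      got <- mannWhitneyU(x, y, alt, method = "normal_approx")$p_value
      ref <- suppressWarnings(stats::wilcox.test(
        x, y, alternative = sub("two_sided", "two.sided", alt),
        exact = FALSE, correct = TRUE)$p.value)
      expect_equal(got, ref, tolerance = 1e-9)
    }
  }
})

test_that("U statistics of the two directions sum to n*m", {
  set.seed(602)
  for (i in 1:30) {
    n <- sample(2:12, 1L); m <- sample(2:12, 1L)
    x <- sample(0:8, n, replace = TRUE)
    y <- sample(0:8, m, replace = TRUE)
    expect_equal(mannWhitneyU(x, y)$U + mannWhitneyU(y, x)$U, n * m)
    # shift invariance of the p-value
    expect_equal(mannWhitneyU(x, y)$p_value,
                 mannWhitneyU(x + 7, y + 7)$p_value)
  }
})

test_that("exact and normal p-values agree for n = m = 25", {
  set.seed(603)
  x <- sample(1:1000, 25L); y <- sample(setdiff(1:1000, x), 25L)
  for (alt in c("two_sided", "greater", "less")) {
    pe <- mannWhitneyU(x, y, alt, method = "exact")$p_value
    pn <- mannWhitneyU(x, y, alt, method = "normal_approx")$p_value
    expect_lt(abs(pe - pn), 0.01)
  }
})

test_that("the enrichment test detects planted clustering", {
  ctx <- simulateDefenseContext(p_near = 0.4, p_bg = 0.02, seed = 41L)
  rep <- enrichmentTest(ctx$annotations, ctx$focal_ids, window_genes = 10L,
                        n_random = 50L, seed = 42L)
  expect_lt(rep@p_value, 1e-4)
  expect_gt(median(rep@focal_fractions), median(rep@random_fractions))
  expect_lte(rep@U, length(rep@focal_fractions) *
               length(rep@random_fractions))
  expect_error(enrichmentTest(ctx$annotations, ctx$focal_ids[1L]),
               "two focal")
})
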