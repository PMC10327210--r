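# Defense-gene neighborhood enrichment: anti-phage defense systems cluster
# in "defense islands", so genes that participate in defense tend to have
# defense-flagged neighbors.  The test compares per-gene neighborhood
# defense fractions between focal genes and randomly sampled genes with a
# from-scratch Mann-Whitney U test.

#' Defense fraction in a gene's neighborhood
#'
#' Neighbors are up to \code{window_genes} genes on each side of the focal
#' gene on the same contig, ordered by start coordinate, excluding the
#' focal gene itself; contig edges shrink the window and the fraction is
#' computed over the actual neighbor count.
#'
#' @param annotations \link[GenomicRanges]{GRanges} of genes with
#'   \code{gene_id} and logical \code{defense_flag} metadata columns.
#' @param focal_gene gene id of the focal gene.
#' @param window_genes genes per side (default 10).
#' @return list with \code{focal_gene_id}, \code{window_genes},
#'   \code{n_neighbors}, \code{n_defense}, \code{fraction}.
#' @export
neighborhoodFraction <- function(annotations, focal_gene,
                                 window_genes = 10L) {
  idx <- match(focal_gene, annotations$gene_id)
  .assert(!is.na(idx), "focal gene '%s' absent from annotations",
          focal_gene)
  ctg <- as.character(GenomicRanges::seqnames(annotations))
  ord <- order(ctg, BiocGenerics::start(annotations))
  pos_in_ctg <- which(ord == idx)
  same <- which(ctg[ord] == ctg[idx])
  lo <- max(min(same), pos_in_ctg - window_genes)
  hi <- min(max(same), pos_in_ctg + window_genes)
  nb <- setdiff(lo:hi, pos_in_ctg)
  flags <- annotations$defense_flag[ord][nb]
  list(focal_gene_id = focal_gene, window_genes = as.integer(window_genes),
       n_neighbors = length(nb), n_defense = sum(flags),
       fraction = if (length(nb)) sum(flags) / length(nb) else NA_real_)
}

#' Sample random focal genes for the enrichment null
#'
#' Uniform sample without replacement from all genes, excluding a given
#' set (by default the focal genes and their window neighbors, so the null
#' is not contaminated by the focal neighborhoods).
#'
#' @param annotations \link[GenomicRanges]{GRanges} of genes.
#' @param n number of genes to draw.
#' @param seed RNG seed (integer); the draw is deterministic given the
#'   seed.
#' @param exclude character vector of gene ids to exclude.
#' @return character vector of sampled gene ids.
#' @export
sampleRandomFocals <- function(annotations, n, seed, exclude = character()) {
  pool <- setdiff(annotations$gene_id, exclude)
  .assert(n <= length(pool),
          "requested %d random genes but only %d eligible", n,
          length(pool))
  .with_seed(seed, sample(pool, n))
}

#' Mann-Whitney U test (from scratch)
#'
#' Computes \code{U = #\{(i,j): x_i > y_j\} + 0.5 * #\{ties\}} and its
#' p-value, by full enumeration of the exact null distribution (counting
#' recurrence over all arrangements) when \code{method = "auto"}, both
#' sample sizes are at most 25 and there are no ties; otherwise by normal
#' approximation with tie correction and continuity correction.
#'
#' @param x,y numeric samples (non-empty).
#' @param alternative \code{"two_sided"}, \code{"greater"} (x tends larger)
#'   or \code{"less"}.
#' @param method \code{"auto"}, \code{"exact"} or \code{"normal_approx"}.
#' @param exact_cutoff largest sample size for the automatic exact path.
#' @return list with \code{U}, \code{p_value} and \code{method} used.
#' @export
mannWhitneyU <- function(x, y,
                         alternative = c("two_sided", "greater", "less"),
                         method = c("auto", "exact", "normal_approx"),
                         exact_cutoff = 25L) {
  alternative <- match.arg(alternative)
  method <- match.arg(method)
  .assert(length(x) >= 1L && length(y) >= 1L, "empty sample")
  n <- length(x); m <- length(y)
  gt <- sum(outer(x, y, ">"))
  eq <- sum(outer(x, y, "=="))
  U <- gt + 0.5 * eq
  has_ties <- anyDuplicated(c(x, y)) > 0L
  if (method == "auto")
    method <- if (n <= exact_cutoff && m <= exact_cutoff && !has_ties)
      "exact" else "normal_approx"
  if (method == "exact") {
    .assert(!has_ties, "exact method requires tie-free samples")
    cdf <- .u_exact_cdf(n, m)               # P(U <= u) for u = 0..n*m
    p_le <- cdf[U + 1L]
    p_ge <- 1 - (if (U >= 1) cdf[U] else 0)
    p <- switch(alternative,
                greater = p_ge, less = p_le,
                two_sided = min(1, 2 * min(p_le, p_ge)))
  } else {
    mu <- n * m / 2
    tie_tab <- table(c(x, y))
    N <- n + m
    tie_term <- sum(tie_tab^3 - tie_tab) / (N * (N - 1))
    sig2 <- n * m / 12 * ((N + 1) - tie_term)
    if (sig2 <= 0) {
      p <- 1
    } else {
      # continuity correction is tail-specific: P(U >= u) uses u - 1/2,
      # P(U <= u) uses u + 1/2, two-sided shrinks |U - mu| by 1/2
      dev <- U - mu
      sig <- sqrt(sig2)
      p <- switch(alternative,
        greater = stats::pnorm((dev - 0.5) / sig, lower.tail = FALSE),
        less = stats::pnorm((dev + 0.5) / sig),
        two_sided = {
          z <- (dev - sign(dev) * 0.5) / sig
          min(1, 2 * min(stats::pnorm(z), stats::pnorm(z,
                                                       lower.tail = FALSE)))
        })
    }
  }
  list(U = U, p_value = p, method = method)
}

# exact CDF of the Mann-Whitney U statistic for tie-free samples, from the
# counting recurrence f(n, m, u) = f(n-1, m, u-m) + f(n, m-1, u):
# tab[[n'+1]][[m'+1]][u+1] = number of arrangements of n' x's and m' y's
# with statistic u
.u_exact_cdf <- function(n, m) {
  tab <- vector("list", n + 1L)
  for (i in 0:n) tab[[i + 1L]] <- vector("list", m + 1L)
  for (i in 0:n) tab[[i + 1L]][[1L]] <- 1
  for (j in 0:m) tab[[1L]][[j + 1L]] <- 1
  for (i in seq_len(n)) for (j in seq_len(m)) {
    a <- tab[[i]][[j + 1L]]          # one fewer x, shift by j
    b <- tab[[i + 1L]][[j]]          # one fewer y, no shift
    v <- numeric(i * j + 1L)
    v[seq_along(a) + j] <- a
    v[seq_along(b)] <- v[seq_along(b)] + b
    tab[[i + 1L]][[j + 1L]] <- v
  }
  counts <- tab[[n + 1L]][[m + 1L]]
  cumsum(counts) / sum(counts)
}

#' Defense-gene enrichment test
#'
#' Compares per-gene neighborhood defense fractions of focal genes against
#' an equally computed set of randomly sampled genes, with a one-sided
#' (greater) Mann-Whitney U test as the primary test (the enrichment
#' hypothesis); the two-sided p-value is reported alongside.
#'
#' @param annotations \link[GenomicRanges]{GRanges} of genes with
#'   \code{gene_id} and \code{defense_flag}.
#' @param focal_ids character vector of focal gene ids (>= 2).
#' @param window_genes neighborhood half-width in genes (default 10).
#' @param n_random number of random genes to sample (default 100).
#' @param seed RNG seed for the random draw.
#' @param exclude_focal_neighborhoods exclude focal genes and their window
#'   neighbors from the random pool (default TRUE).
#' @return An \linkS4class{EnrichmentReport}.
#' @export
enrichmentTest <- function(annotations, focal_ids, window_genes = 10L,
                           n_random = 100L, seed = 1L,
                           exclude_focal_neighborhoods = TRUE) {
  .assert(length(focal_ids) >= 2L, "need at least two focal genes")
  .log("INFO",
       "enrichmentTest: %d focal, window=%d, n_random=%d, seed=%d",
       length(focal_ids), window_genes, n_random, seed)
  # vectorized equivalent of neighborhoodFraction over many genes: order
  # once, then use prefix sums of the defense flags per contig
  ctg <- as.character(GenomicRanges::seqnames(annotations))
  ord <- order(ctg, BiocGenerics::start(annotations))
  ids_ord <- annotations$gene_id[ord]
  flags_ord <- annotations$defense_flag[ord]
  ctg_ord <- ctg[ord]
  first <- match(ctg_ord, ctg_ord)               # first index of own contig
  last <- length(ctg_ord) + 1L -
    match(ctg_ord, rev(ctg_ord))                 # last index of own contig
  prefix <- cumsum(flags_ord)
  frac_of <- function(ids) {
    pos <- match(ids, ids_ord)
    .assert(!anyNA(pos), "gene id(s) absent from annotations")
    lo <- pmax(first[pos], pos - window_genes)
    hi <- pmin(last[pos], pos + window_genes)
    ndef <- prefix[hi] - ifelse(lo > 1L, prefix[lo - 1L], 0) -
      flags_ord[pos]
    nnb <- hi - lo
    ifelse(nnb > 0L, ndef / nnb, NA_real_)
  }
  focal_fr <- frac_of(focal_ids)
  names(focal_fr) <- focal_ids
  excl <- focal_ids
  if (exclude_focal_neighborhoods) {
    for (g in focal_ids) {
      pidx <- match(g, ids_ord)
      nb <- max(first[pidx], pidx - window_genes):
            min(last[pidx], pidx + window_genes)
      excl <- union(excl, ids_ord[nb])
    }
  }
  rnd <- sampleRandomFocals(annotations, n_random, seed, exclude = excl)
  random_fr <- frac_of(rnd)
  ok <- !is.na(focal_fr); focal_fr <- focal_fr[ok]
  ok <- !is.na(random_fr); random_fr <- random_fr[ok]
  mw1 <- mannWhitneyU(focal_fr, random_fr, alternative = "greater")
  mw2 <- mannWhitneyU(focal_fr, random_fr, alternative = "two_sided")
  new("EnrichmentReport", focal_fractions = unname(focal_fr),
      random_fractions = unname(random_fr), U = mw1$U,
      p_value = mw1$p_value, p_two_sided = mw2$p_value,
      method = mw1$method, n_random_draws = as.integer(n_random),
      seed = as.integer(seed))
}
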