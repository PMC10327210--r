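# Independent brute-force oracles used by the property tests.  Each oracle
# is written as a direct enumeration of the definition, independent of the
# package's implementation path.

# exhaustive RBS scoring: try every window substring of every length and
# every alignment offset against the consensus, keep the best admissible
oracle_score_rbs <- function(window, min_spacer = 4L, max_spacer = 13L,
                             consensus = "AGGAGG") {
  W <- nchar(window)
  best_len <- 0L; best_spacer <- NA_integer_
  for (i in seq_len(W)) for (len in seq_len(min(6L, W - i + 1L))) {
    sub <- substr(window, i, i + len - 1L)
    spacer <- W - (i + len - 1L)
    if (spacer < min_spacer || spacer > max_spacer) next
    for (a in seq_len(6L - len + 1L)) {
      if (sub == substr(consensus, a, a + len - 1L)) {
        if (len > best_len ||
            (len == best_len && spacer < best_spacer)) {
          best_len <- len; best_spacer <- spacer
        }
        break
      }
    }
  }
  list(match_len = best_len, spacer_nt = best_spacer)
}

# brute-force internal ORF scan: check every codon index directly
oracle_internal_orfs <- function(cds, min_offset, min_len) {
  ncod <- nchar(cds) %/% 3L
  hits <- data.frame(codon_index = integer(), start_codon = character(),
                     small_protein_len_aa = integer())
  for (k in seq_len(ncod - 1L)) {
    codon <- substr(cds, 3L * k - 2L, 3L * k)
    len <- ncod - k
    if (codon %in% c("ATG", "GTG", "TTG") && k >= min_offset &&
        len >= min_len)
      hits <- rbind(hits, data.frame(codon_index = k, start_codon = codon,
                                     small_protein_len_aa = len))
  }
  hits
}

# exhaustive tandem-array enumeration: every (start, copies) exact array of
# the given period whose unit is primitive, then greedy left-to-right
# non-overlapping maximal selection (mirrors the declared reporting rule)
oracle_tandem_repeats <- function(protein, unit_len = 4L, min_copies = 2L) {
  n <- nchar(protein)
  prim <- function(u) {
    for (p in seq_len(nchar(u) - 1L))
      if (nchar(u) %% p == 0L &&
          strrep(substr(u, 1L, p), nchar(u) %/% p) == u) return(p)
    nchar(u)
  }
  arrays <- list()
  for (i in seq_len(n)) {
    u <- substr(protein, i, i + unit_len - 1L)
    if (nchar(u) < unit_len) next
    cp <- 1L
    while (substr(protein, i + cp * unit_len,
                  i + (cp + 1L) * unit_len - 1L) == u &&
           i + (cp + 1L) * unit_len - 1L <= n)
      cp <- cp + 1L
    if (cp >= min_copies && prim(u) == unit_len)
      arrays[[length(arrays) + 1L]] <- c(start = i, copies = cp)
  }
  if (!length(arrays)) return(data.frame(start_aa = integer(),
                                         copies = integer()))
  arr <- do.call(rbind, arrays)
  arr <- arr[order(arr[, "start"]), , drop = FALSE]
  out <- list(); busy_until <- 0L
  for (r in seq_len(nrow(arr))) {
    if (arr[r, "start"] <= busy_until) next
    out[[length(out) + 1L]] <- arr[r, ]
    busy_until <- arr[r, "start"] + unit_len * arr[r, "copies"] - 1L
  }
  out <- do.call(rbind, out)
  data.frame(start_aa = unname(out[, "start"]),
             copies = unname(out[, "copies"]))
}

# quadratic ITR oracle: every (left start, right start, length) triple
oracle_itr <- function(element, min_len = 12L, max_mismatch = 1L,
                       end_window = 50L) {
  n <- nchar(element)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ch <- strsplit(toupper(element), "")[[1L]]
  best <- NULL
  for (len in seq(min_len, end_window)) {
    for (i in seq_len(end_window - len + 1L)) {
      for (rs in seq(n - end_window + 1L, n - len + 1L)) {
        arm1 <- ch[i:(i + len - 1L)]
        arm2 <- ch[rs:(rs + len - 1L)]
        mm <- sum(arm1 != rev(unname(comp[arm2])))
        if (is.na(mm) || mm > max_mismatch) next
        prox <- (i - 1L) + (n - (rs + len - 1L))
        cand <- list(length = len, mismatches = mm, left_pos = i,
                     right_pos = rs, prox = prox)
        if (is.null(best) || cand$length > best$length ||
            (cand$length == best$length &&
             (cand$mismatches < best$mismatches ||
              (cand$mismatches == best$mismatches &&
               cand$prox < best$prox))))
          best <- cand
      }
    }
  }
  best
}

# TSD oracle: direct comparison of flank suffix vs flank prefix per length
oracle_tsd <- function(left_flank, right_flank, len_range = c(2L, 15L)) {
  best <- NULL
  for (len in seq(len_range[1L], min(len_range[2L], nchar(left_flank),
                                     nchar(right_flank)))) {
    a <- substr(left_flank, nchar(left_flank) - len + 1L, nchar(left_flank))
    if (a == substr(right_flank, 1L, len)) best <- list(length = len,
                                                        sequence = a)
  }
  best
}

# full permutation oracle for the Mann-Whitney test (tie-free samples):
# enumerate every assignment of the pooled values to the two groups
oracle_mwu_p <- function(x, y, alternative) {
  n <- length(x); m <- length(y)
  pool <- c(x, y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  u_obs <- u_of(x, y)
  combs <- combn(n + m, n)
  us <- apply(combs, 2L, function(idx) u_of(pool[idx], pool[-idx]))
  p_le <- mean(us <= u_obs); p_ge <- mean(us >= u_obs)
  switch(alternative, greater = p_ge, less = p_le,
         two_sided = min(1, 2 * min(p_le, p_ge)))
}

# quadratic tandem-duplication oracle: every (start, offset) block with the
# required length, gap and identity
oracle_tandem_dup_exists <- function(locus, min_block, min_identity) {
  ch <- strsplit(toupper(locus), "")[[1L]]
  n <- length(ch)
  for (d in seq(min_block, floor(1.1 * n / 2))) {
    max_b <- min(d, n - d)
    if (max_b < min_block) next
    for (start in seq_len(n - d - min_block + 1L)) {
      for (b in seq(min_block, min(max_b, n - d - start + 1L))) {
        if (d - b > 0.10 * b) next
        idx <- start:(start + b - 1L)
        if (mean(ch[idx] == ch[idx + d]) >= min_identity) return(TRUE)
      }
    }
  }
  FALSE
}

# random DNA / protein helpers for property tests
rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
rand_protein <- function(n, alphabet = Biostrings::AA_STANDARD)
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# random CDS: start codon, non-stop body, terminal stop
rand_cds <- function(n_codons) {
  body <- sample(setdiff(names(Biostrings::GENETIC_CODE),
                         c("TAA", "TAG", "TGA")), n_codons - 2L,
                 replace = TRUE)
  paste(c("ATG", body, "TAA"), collapse = "")
}
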