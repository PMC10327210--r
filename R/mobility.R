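# Transposition-signature scanning: autonomous mobile elements (insertion
# sequences) carry terminal inverted repeats and are flanked by target-site
# duplications; rpn gene arrays instead arise by tandem direct duplication.
# These scanners test an element for each signature.

.revcomp <- function(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

#' Scan an element for terminal inverted repeats
#'
#' Searches the first and last \code{end_window} bases of an element for
#' the best pair of substrings that are reverse complements within
#' \code{max_mismatch} mismatches (mismatch-tolerant because real ITR arms
#' diverge).  Pairs are ranked by length, then by fewest mismatches, then
#' by proximity to the element termini (biological ITRs abut element ends).
#' Nothing is reported when the best pair is shorter than \code{min_len}.
#'
#' @param element element sequence (character or DNAString), length
#'   >= 2 * end_window.
#' @param min_len minimum reportable arm length (default 12).
#' @param max_mismatch mismatches tolerated between the arms (default 1).
#' @param end_window terminal window searched at each end (default 50).
#' @return NULL, or list with \code{length}, \code{mismatches},
#'   \code{left_pos} and \code{right_pos} (1-based starts of the left and
#'   right arms within the element).
#' @export
scanTerminalInvertedRepeats <- function(element, min_len = 12L,
                                        max_mismatch = 1L,
                                        end_window = 50L) {
  s <- toupper(as.character(element))
  n <- nchar(s)
  .assert(n >= 2L * end_window,
          "element of %d bp shorter than 2*end_window (%d)", n,
          2L * end_window)
  if (min_len > end_window) return(NULL)
  left <- strsplit(substr(s, 1L, end_window), "")[[1L]]
  right <- strsplit(substr(s, n - end_window + 1L, n), "")[[1L]]
  right_rc <- rev(vapply(right, function(b) switch(b, A = "T", C = "G",
    G = "C", T = "A", "N"), character(1)))
  # right_rc[k] corresponds to element position n - k + 1
  best <- NULL
  for (len in end_window:min_len) {
    for (i in 1L:(end_window - len + 1L)) {       # left arm start
      la <- left[i:(i + len - 1L)]
      for (j in 1L:(end_window - len + 1L)) {     # start within right_rc
        mm <- sum(la != right_rc[j:(j + len - 1L)])
        if (mm > max_mismatch) next
        right_start <- n - (j + len - 1L) + 1L
        prox <- (i - 1L) + (n - (right_start + len - 1L))
        cand <- list(length = len, mismatches = mm, left_pos = i,
                     right_pos = right_start, .prox = prox)
        if (is.null(best) ||
            cand$length > best$length ||
            (cand$length == best$length &&
             (cand$mismatches < best$mismatches ||
              (cand$mismatches == best$mismatches &&
               cand$.prox < best$.prox))))
          best <- cand
      }
    }
    if (!is.null(best)) break   # longer lengths searched first
  }
  if (is.null(best)) return(NULL)
  best$.prox <- NULL
  best
}

#' Scan element flanks for a target-site duplication
#'
#' Target-site duplications arise by replication of a single site during
#' transposition, so the two copies are expected identical: the scan looks
#' for the longest exact direct repeat with one copy immediately left of
#' the element start and one immediately right of the element end.  The
#' reported length is capped at the top of \code{len_range}; nothing is
#' reported below its bottom.
#'
#' @param left_flank,right_flank flanking sequence immediately left/right
#'   of the element (characters; at least \code{len_range[2]} bases of
#'   flank are used when available).
#' @param len_range duplication length range searched (default c(2, 15)).
#' @return NULL, or list with \code{length} and \code{sequence}.
#' @export
scanTargetSiteDuplication <- function(left_flank, right_flank,
                                      len_range = c(2L, 15L)) {
  lf <- toupper(as.character(left_flank))
  rf <- toupper(as.character(right_flank))
  .assert(nzchar(lf) && nzchar(rf),
          "element at contig boundary: empty flank")
  maxlen <- min(len_range[2L], nchar(lf), nchar(rf))
  for (len in rev(seq(len_range[1L], maxlen))) {
    a <- substr(lf, nchar(lf) - len + 1L, nchar(lf))
    b <- substr(rf, 1L, len)
    if (a == b) return(list(length = len, sequence = a))
  }
  NULL
}

#' Detect tandem direct duplications within a locus
#'
#' Finds adjacent direct-repeat blocks by exact k-mer seeding followed by
#' ungapped extension.  Seeds are pairs of identical k-mers whose offset
#' could place two copies side by side; extension maximizes block length
#' while overall identity stays at or above \code{min_identity}.  Two
#' blocks count as tandem when the gap between the copies is at most 10%
#' of the block length.
#'
#' @param locus DNA sequence (character or DNAString), length >=
#'   2 * min_block.
#' @param min_block smallest reportable block (default 200 bp).
#' @param min_identity minimum identity of the two copies (default 0.9).
#' @param k seed k-mer length (default 16).
#' @return data.frame with columns \code{left_start}, \code{right_start},
#'   \code{block_len}, \code{identity}; zero rows when none found.
#' @export
detectTandemDuplications <- function(locus, min_block = 200L,
                                     min_identity = 0.9, k = 16L) {
  s <- toupper(as.character(locus))
  n <- nchar(s)
  .assert(n >= 2L * min_block, "locus of %d bp shorter than 2*min_block",
          n)
  empty <- data.frame(left_start = integer(), right_start = integer(),
                      block_len = integer(), identity = numeric())
  ch <- strsplit(s, "")[[1L]]
  kmers <- substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  grp <- split(seq_along(kmers), kmers)
  grp <- grp[lengths(grp) >= 2L]
  if (!length(grp)) return(empty)
  max_gap_frac <- 0.10
  # candidate offsets d = right_start - left_start; tandem blocks of length
  # B with gap g have d = B + g, g <= 0.1 B  =>  d in [B, 1.1 B]
  cands <- list()
  seen_offsets <- new.env()
  for (idx in grp) {
    prs <- utils::combn(idx, 2L)
    for (cidx in seq_len(ncol(prs))) {
      p1 <- prs[1L, cidx]; p2 <- prs[2L, cidx]
      d <- p2 - p1
      if (d < min_block || d > ceiling(1.2 * (n / 2))) next
      key <- as.character(d)
      anchors <- mget(key, envir = seen_offsets, ifnotfound = list(NULL))[[1]]
      if (!is.null(anchors) && any(abs(anchors - p1) <= k)) next
      assign(key, c(anchors, p1), envir = seen_offsets)
      # ungapped extension at fixed offset d, maximizing length while
      # identity >= min_identity (score-drop style extension)
      ext <- .extend_ungapped(ch, p1, d, n, min_identity)
      if (is.null(ext)) next
      if (ext$len > d) {   # extension ran past the copy boundary: trim
        ext$len <- d
      }
      # boundary mismatches are never part of an ungapped block: shrink
      # both ends to matching bases, then recompute identity
      lo <- ext$start; hi <- ext$start + ext$len - 1L
      while (lo <= hi && ch[lo] != ch[lo + d]) lo <- lo + 1L
      while (hi >= lo && ch[hi] != ch[hi + d]) hi <- hi - 1L
      if (hi < lo) next
      ext$start <- lo
      ext$len <- hi - lo + 1L
      idx <- lo:hi
      ext$identity <- mean(ch[idx] == ch[idx + d])
      if (ext$identity < min_identity) next
      B <- ext$len
      gap <- d - B
      if (B >= min_block && gap >= 0 && gap <= max_gap_frac * B)
        cands[[length(cands) + 1L]] <-
          data.frame(left_start = ext$start, right_start = ext$start + d,
                     block_len = B, identity = ext$identity)
    }
  }
  if (!length(cands)) return(empty)
  out <- unique(do.call(rbind, cands))
  # keep the best block per offset/overlap cluster (longest, then identity)
  out <- out[order(-out$block_len, -out$identity), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) for (j in (i + 1L):nrow(out)) {
      if (!keep[j]) next
      if (out$left_start[j] < out$left_start[i] + out$block_len[i] &&
          out$left_start[i] < out$left_start[j] + out$block_len[j])
        keep[j] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal-scoring ungapped extension of a match at offset d around anchor
# p1 (X-drop: match +1, mismatch -3, stop when the score falls 12 below
# the running maximum); score-maximal ends always sit on matches, so
# low-identity fringes are excluded by construction
.extend_ungapped <- function(ch, p1, d, n, min_identity,
                             mismatch_penalty = 3L, xdrop = 12L) {
  # right of the anchor (inclusive)
  sc <- 0L; best_sc <- 0L; best_hi <- p1 - 1L
  i <- p1
  while (i + d <= n) {
    sc <- sc + if (ch[i] == ch[i + d]) 1L else -mismatch_penalty
    if (sc > best_sc) { best_sc <- sc; best_hi <- i }
    if (sc < best_sc - xdrop) break
    i <- i + 1L
  }
  if (best_hi < p1) return(NULL)
  # left of the anchor
  sc <- 0L; best_sc <- 0L; best_lo <- p1
  i <- p1 - 1L
  while (i >= 1L) {
    sc <- sc + if (ch[i] == ch[i + d]) 1L else -mismatch_penalty
    if (sc > best_sc) { best_sc <- sc; best_lo <- i }
    if (sc < best_sc - xdrop) break
    i <- i - 1L
  }
  idx <- best_lo:best_hi
  ident <- mean(ch[idx] == ch[idx + d])
  if (ident < min_identity) return(NULL)
  list(start = best_lo, len = length(idx), identity = ident)
}

#' Transposase-like verdict for an element
#'
#' FALSE (no autonomous-element signature) iff neither a terminal inverted
#' repeat nor a target-site duplication was found -- the signature pattern
#' that distinguishes true insertion sequences from elements that spread by
#' other routes (recombination, hitchhiking, tandem duplication).
#'
#' @param itr result of \code{\link{scanTerminalInvertedRepeats}}.
#' @param tsd result of \code{\link{scanTargetSiteDuplication}}.
#' @return logical(1): TRUE when either signature is present.
#' @export
transposaseVerdict <- function(itr, tsd) {
  !is.null(itr) || !is.null(tsd)
}
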