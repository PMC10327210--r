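#' @importFrom S4Vectors DataFrame
NULL

.START_CODONS <- c("ATG", "GTG", "TTG")
.STOP_CODONS <- c("TAA", "TAG", "TGA")
.SD_CONSENSUS <- "AGGAGG"

#' Score a Shine-Dalgarno ribosome binding site
#'
#' Scores the window immediately upstream of a (candidate) start codon
#' against the Shine-Dalgarno consensus AGGAGG by maximum contiguous match.
#' Every placement of the consensus along the window (overhangs allowed) is
#' considered; within a placement, every contiguous run of matching bases is
#' a candidate whose spacer is the number of bases between the 3' end of the
#' run and the first base of the start codon.  The best run with spacer in
#' \code{[min_spacer, max_spacer]} is returned (ties go to the shorter
#' spacer).  Contiguous matching is used instead of a free-energy
#' hybridization model: it is transparent and directly checkable by
#' exhaustive enumeration.
#'
#' @param window character or \link[Biostrings]{DNAString}; the upstream
#'   sequence whose last base is immediately 5' of the start codon.  Must be
#'   at least \code{6 + min_spacer} bases long.
#' @param min_spacer,max_spacer allowed spacer range in nt (defaults 4, 13,
#'   the common bacterial range).
#' @param consensus Shine-Dalgarno consensus hexamer.
#' @return list with \code{match_len} (0--6; 0 when no run of length >= 1
#'   has an admissible spacer), \code{spacer_nt} (NA when match_len is 0)
#'   and \code{window_pos} (1-based start of the matched run within the
#'   window; NA when match_len is 0).
#' @export
scoreRbs <- function(window, min_spacer = 4L, max_spacer = 13L,
                     consensus = .SD_CONSENSUS) {
  w <- toupper(as.character(window))
  W <- nchar(w)
  L <- nchar(consensus)
  .assert(W >= L + min_spacer,
          "window of %d nt shorter than consensus + min_spacer (%d)",
          W, L + min_spacer)
  wv <- strsplit(w, "")[[1L]]
  cv <- strsplit(consensus, "")[[1L]]
  # runlen[a, j]: length of the contiguous consensus match ending at
  # window position j with consensus position a aligned to j
  # (runlen[a, j] = runlen[a-1, j-1] + 1 on a match, else 0); the best
  # run with an admissible spacer is the maximum over j in the spacer
  # range, scanning high j first so ties prefer the shorter spacer
  runlen <- matrix(0L, L, W)
  for (a in seq_len(L)) {
    m <- wv == cv[a]
    if (a == 1L) runlen[1L, ] <- as.integer(m)
    else {
      runlen[a, 1L] <- as.integer(m[1L])
      runlen[a, 2:W] <- ifelse(m[2:W], runlen[a - 1L, 1:(W - 1L)] + 1L, 0L)
    }
  }
  best <- list(match_len = 0L, spacer_nt = NA_integer_,
               window_pos = NA_integer_)
  for (j in seq(W - min_spacer, max(1L, W - max_spacer))) {
    len <- max(runlen[, j])
    if (len > best$match_len) {
      best <- list(match_len = len, spacer_nt = W - j,
                   window_pos = j - len + 1L)
    }
  }
  best
}

#' Enumerate in-frame internal ORF candidates within a CDS
#'
#' Scans a coding sequence for in-frame ATG/GTG/TTG codons at codon index
#' >= \code{min_offset_codons} that would direct synthesis of a small
#' protein sharing the parent's stop codon.  The small-protein length is
#' the number of codons from the internal start to the last sense codon
#' inclusive.
#'
#' @param cds coding-strand CDS (character or
#'   \link[Biostrings]{DNAString}); length divisible by 3, ending in a stop
#'   codon.
#' @param min_offset_codons smallest admissible internal start codon index
#'   (1-based; default 30).
#' @param min_len_aa smallest admissible small-protein length (default 20).
#' @return \link[S4Vectors]{DataFrame} with columns \code{codon_index},
#'   \code{start_codon}, \code{small_protein_len_aa}; zero rows when no
#'   candidate exists.
#' @export
findInternalOrfs <- function(cds, min_offset_codons = 30L,
                             min_len_aa = 20L) {
  s <- toupper(as.character(cds))
  n <- nchar(s)
  .assert(n %% 3L == 0L, "CDS length %d not divisible by 3", n)
  ncod <- n %/% 3L
  codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
  .assert(codons[ncod] %in% .STOP_CODONS,
          "CDS does not end with a stop codon (found %s)", codons[ncod])
  idx <- which(codons %in% .START_CODONS)
  idx <- idx[idx >= min_offset_codons & idx < ncod]
  len <- ncod - idx                 # codons up to (and incl.) last sense codon
  keep <- len >= min_len_aa
  DataFrame(codon_index = as.integer(idx[keep]),
            start_codon = codons[idx[keep]],
            small_protein_len_aa = as.integer(len[keep]))
}

#' Call initiation peaks from paired ribosome-profiling tracks
#'
#' For each queried genome position, computes the initiation-trapped
#' enrichment as the maximum treated coverage within \code{+/- window_nt}
#' divided by the local median of the treated track over \code{+/- 100} nt
#' (floored at 1 to avoid division by zero).  A peak is called when the
#' enrichment reaches \code{min_fold_local} and the treated/untreated ratio
#' at the maximum reaches \code{min_ratio_vs_untreated}.
#'
#' @param treated,untreated \linkS4class{CoverageTrack} objects
#'   (initiation-trapped and control libraries).
#' @param contig contig name the positions refer to.
#' @param positions integer vector of 1-based genome positions (first base
#'   of each candidate start codon).
#' @param window_nt half-width of the peak search window (default 9 nt,
#'   approximating the initiation-footprint spread).
#' @param min_fold_local minimum enrichment over local median (default 5).
#' @param min_ratio_vs_untreated minimum treated/untreated ratio at the
#'   maximum (default 3).
#' @return \link[S4Vectors]{DataFrame} with columns \code{position},
#'   \code{peak_enrichment}, \code{ratio_vs_untreated}, \code{peak}.
#' @export
callInitiationPeaks <- function(treated, untreated, contig, positions,
                                window_nt = 9L, min_fold_local = 5,
                                min_ratio_vs_untreated = 3) {
  .assert(contig %in% names(trackValues(treated)) &&
          contig %in% names(trackValues(untreated)),
          "contig '%s' not covered by both tracks", contig)
  tv <- trackValues(treated)[[contig]]
  uv <- trackValues(untreated)[[contig]]
  L <- length(tv)
  .assert(all(positions >= 1L & positions <= L),
          "position outside contig (length %d)", L)
  out <- lapply(positions, function(pos) {
    win <- max(1L, pos - window_nt):min(L, pos + window_nt)
    tmax <- max(tv[win])
    argmax <- win[which.max(tv[win])]
    bg <- max(1, stats::median(tv[max(1L, pos - 100L):min(L, pos + 100L)]))
    enr <- tmax / bg
    ratio <- tmax / max(1, uv[argmax])
    c(enr, ratio)
  })
  out <- do.call(rbind, out)
  DataFrame(position = as.integer(positions),
            peak_enrichment = out[, 1L],
            ratio_vs_untreated = out[, 2L],
            peak = out[, 1L] >= min_fold_local &
                   out[, 2L] >= min_ratio_vs_untreated)
}

#' Combine sequence and profiling evidence into iTIS calls
#'
#' Assigns each candidate an evidence class: RBS match of at least
#' \code{min_rbs} together with an initiation peak gives
#' \code{sequence_and_profiling}; exactly one line of evidence gives
#' \code{sequence_only} or \code{profiling_only}; candidates with neither
#' are dropped.  When no tracks were provided, \code{peak} should be NA and
#' sequence evidence alone is classified \code{sequence_only}.
#'
#' @param candidates \link[S4Vectors]{DataFrame} with at least
#'   \code{rbs_match} (integer) and \code{peak} (logical, NA when no
#'   profiling data exist).
#' @param min_rbs minimum RBS contiguous match for sequence evidence
#'   (default 4).
#' @return The input with an added \code{evidence_class} column, rows with
#'   neither line of evidence removed.
#' @export
classifyItis <- function(candidates, min_rbs = 4L) {
  seq_ev <- candidates$rbs_match >= min_rbs
  peak_ev <- !is.na(candidates$peak) & candidates$peak
  cls <- rep(NA_character_, nrow(candidates))
  cls[seq_ev & peak_ev] <- "sequence_and_profiling"
  cls[seq_ev & !peak_ev] <- "sequence_only"
  cls[!seq_ev & peak_ev] <- "profiling_only"
  out <- candidates[!is.na(cls), , drop = FALSE]
  out$evidence_class <- cls[!is.na(cls)]
  out
}

#' Discover internal translation initiation sites in a genome bundle
#'
#' Runs the full iTIS discovery pipeline over every annotated CDS:
#' in-frame start-codon scanning (\code{\link{findInternalOrfs}}),
#' Shine-Dalgarno scoring of each candidate's upstream window
#' (\code{\link{scoreRbs}}), initiation-peak calling on the profiling
#' tracks when present (\code{\link{callInitiationPeaks}}), and evidence
#' classification (\code{\link{classifyItis}}).
#'
#' @param bundle a \linkS4class{GenomeBundle}; if it carries both an
#'   untreated and an initiation-trapped track, profiling evidence is used.
#' @param min_offset_codons,min_len_aa candidate filters, see
#'   \code{\link{findInternalOrfs}}.
#' @param min_rbs minimum RBS match for sequence evidence.
#' @param min_spacer,max_spacer RBS spacer range (nt).
#' @param window_nt,min_fold_local,min_ratio_vs_untreated peak-calling
#'   parameters, see \code{\link{callInitiationPeaks}}.
#' @return \link[S4Vectors]{DataFrame} of classified iTIS calls with
#'   columns \code{parent_gene_id}, \code{codon_index}, \code{start_codon},
#'   \code{small_protein_len_aa}, \code{rbs_match}, \code{rbs_spacer},
#'   \code{genome_pos}, \code{peak_enrichment}, \code{peak},
#'   \code{evidence_class}.
#' @export
discoverItis <- function(bundle, min_offset_codons = 30L, min_len_aa = 20L,
                         min_rbs = 4L, min_spacer = 4L, max_spacer = 13L,
                         window_nt = 9L, min_fold_local = 5,
                         min_ratio_vs_untreated = 3) {
  ann <- annotations(bundle)
  cdss <- ann[ann$feature_type == "CDS"]
  labs <- vapply(tracks(bundle), trackLabel, character(1))
  have_tracks <- all(c("untreated", "initiation_trapped") %in% labs)
  treated <- if (have_tracks)
    tracks(bundle)[[match("initiation_trapped", labs)]] else NULL
  untreated <- if (have_tracks)
    tracks(bundle)[[match("untreated", labs)]] else NULL
  .log("INFO", "discoverItis: %d CDS, tracks=%s, min_rbs=%d, min_offset=%d",
       length(cdss), have_tracks, min_rbs, min_offset_codons)
  res <- list()
  wlen <- 6L + max_spacer
  for (i in seq_along(cdss)) {
    gid <- cdss$gene_id[i]
    cds <- as.character(extractCds(bundle, gid))
    cand <- findInternalOrfs(cds, min_offset_codons, min_len_aa)
    if (!nrow(cand)) next
    rbs <- lapply(cand$codon_index, function(k) {
      p <- 3L * (k - 1L) + 1L
      if (p - wlen < 1L)   # start too close to the CDS 5' end to score
        return(list(match_len = 0L, spacer_nt = NA_integer_))
      scoreRbs(substr(cds, p - wlen, p - 1L), min_spacer, max_spacer)
    })
    cand$rbs_match <- vapply(rbs, `[[`, integer(1), "match_len")
    cand$rbs_spacer <- vapply(rbs, `[[`, integer(1), "spacer_nt")
    minus <- as.character(BiocGenerics::strand(cdss[i])) == "-"
    cand$genome_pos <- if (minus)
      BiocGenerics::end(cdss[i]) - 3L * (cand$codon_index - 1L)
    else BiocGenerics::start(cdss[i]) + 3L * (cand$codon_index - 1L)
    cand$parent_gene_id <- gid
    if (have_tracks) {
      pk <- callInitiationPeaks(treated, untreated,
                                as.character(GenomicRanges::seqnames(cdss[i])),
                                cand$genome_pos, window_nt, min_fold_local,
                                min_ratio_vs_untreated)
      cand$peak_enrichment <- pk$peak_enrichment
      cand$peak <- pk$peak
    } else {
      cand$peak_enrichment <- NA_real_
      cand$peak <- NA
    }
    res[[length(res) + 1L]] <- cand
  }
  if (!length(res))
    return(DataFrame(parent_gene_id = character(), codon_index = integer(),
                     start_codon = character(),
                     small_protein_len_aa = integer(),
                     rbs_match = integer(), rbs_spacer = integer(),
                     genome_pos = integer(), peak_enrichment = numeric(),
                     peak = logical(), evidence_class = character()))
  out <- do.call(rbind, res)
  out <- classifyItis(out, min_rbs)
  cols <- c("parent_gene_id", "codon_index", "start_codon",
            "small_protein_len_aa", "rbs_match", "rbs_spacer", "genome_pos",
            "peak_enrichment", "peak", "evidence_class")
  out[, cols]
}
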