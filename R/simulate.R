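# Seeded synthetic-data generators with known ground truth.  Every
# generator is a pure function of its arguments and seed, and the returned
# truth is sufficient to compute every downstream stage's expected output
# without re-deriving it from the data.

.NON_STOP_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                            c("TAA", "TAG", "TGA"))

#' Simulate a bacterial locus carrying an intragenic small-protein gene
#'
#' Emits a contig with one parent CDS whose internal region holds an
#' in-frame start codon (the iTIS) preceded by a Shine-Dalgarno-like
#' hexamer with a configured contiguous match length and spacer -- the
#' genes-within-genes arrangement of rpn loci.  The parent gene has its
#' own consensus RBS upstream of its annotated start.  Mismatching bases
#' are repaired to cytosine (which can never form part of a start, stop,
#' or the purine SD consensus), so the construction is deterministic:
#' \code{scoreRbs} at the iTIS returns exactly \code{rbs_match_len} when
#' it is >= 4, and no window run of 4+ matches exists when it is < 4.
#'
#' @param seed RNG seed.
#' @param parent_len_codons parent CDS length in codons including the stop
#'   (default 120).
#' @param itis_codon_index 1-based codon index of the internal start
#'   (default places a ~50-aa small protein, mid-range for Rpn C-terminal
#'   tails).
#' @param start_codon internal start codon (default "ATG").
#' @param rbs_match_len planted contiguous SD match, 0-6 (default 6).
#' @param rbs_spacer_nt spacer between SD 3' end and the start codon
#'   (default 7).
#' @param flank flanking sequence length on each side (default 100).
#' @return list with \code{bundle} (a \linkS4class{GenomeBundle}) and
#'   \code{truth} (list: gene_id, contig, itis_codon_index,
#'   itis_genome_pos, start_codon, rbs_match_len, rbs_spacer_nt,
#'   small_protein_len_aa, parent_len_codons).
#' @export
simulateRpnLocus <- function(seed = 1L, parent_len_codons = 120L,
                             itis_codon_index = parent_len_codons - 50L,
                             start_codon = "ATG", rbs_match_len = 6L,
                             rbs_spacer_nt = 7L, flank = 100L) {
  k <- as.integer(itis_codon_index)
  ncod <- as.integer(parent_len_codons)
  .assert(k >= 3L && k < ncod,
          "small-protein length incompatible with parent length")
  .assert(start_codon %in% .START_CODONS, "invalid start codon '%s'",
          start_codon)
  .assert(rbs_match_len >= 0L && rbs_match_len <= 6L,
          "rbs_match_len must be 0-6")
  p <- 3L * (k - 1L) + 1L
  .assert(p - rbs_spacer_nt - 6L >= 1L,
          "iTIS too close to the parent start for the configured RBS")
  .with_seed(seed, {
    codons <- c("ATG", sample(.NON_STOP_CODONS, ncod - 2L, replace = TRUE),
                "TAA")
    s <- paste(codons, collapse = "")
    # plant the internal start codon
    substr(s, p, p + 2L) <- start_codon
    # plant the SD hexamer: the 3'-most rbs_match_len bases match the
    # AGGAGG consensus, the rest are C (guaranteed mismatches)
    hex_start <- p - rbs_spacer_nt - 6L
    planted <- strsplit(.SD_CONSENSUS, "")[[1L]]
    if (rbs_match_len < 6L)
      planted[seq_len(6L - rbs_match_len)] <- "C"
    substr(s, hex_start, hex_start + 5L) <- paste(planted, collapse = "")
    s <- .repair_locus(s, ncod, k, p, rbs_match_len, rbs_spacer_nt)
    # contig: flank + parent RBS already inside the upstream flank
    up <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                collapse = "")
    substr(up, flank - 12L, flank - 7L) <- .SD_CONSENSUS  # parent RBS
    dn <- paste(sample(c("A", "C", "G", "T"), flank, replace = TRUE),
                collapse = "")
    contig <- paste0(up, s, dn)
    gene_start <- flank + 1L
    gene_end <- flank + nchar(s)
    ann <- GenomicRanges::GRanges("locus1",
      IRanges::IRanges(start = c(gene_start, gene_start),
                       end = c(gene_end, gene_end)),
      strand = "+")
    ann$gene_id <- c("parent1", "parent1")
    ann$feature_type <- c("gene", "CDS")
    ann$defense_flag <- FALSE
    seqs <- Biostrings::DNAStringSet(contig)
    names(seqs) <- "locus1"
    truth <- list(gene_id = "parent1", contig = "locus1",
                  itis_codon_index = k,
                  itis_genome_pos = gene_start + p - 1L,
                  start_codon = start_codon,
                  rbs_match_len = as.integer(rbs_match_len),
                  rbs_spacer_nt = as.integer(rbs_spacer_nt),
                  small_protein_len_aa = ncod - k,
                  parent_len_codons = ncod)
    list(bundle = GenomeBundle(seqs, ann), truth = truth)
  })
}

# deterministic repair: remove internal stops and enforce the configured
# RBS score at the iTIS window; all repairs write 'C', which never forms
# part of a stop codon, a start codon, or the SD consensus
.repair_locus <- function(s, ncod, k, p, rbs_match_len, rbs_spacer_nt) {
  wlen <- 6L + 13L
  hex_start <- p - rbs_spacer_nt - 6L
  pinned <- c(1:3, p:(p + 2L), hex_start:(hex_start + 5L),
              (3L * ncod - 2L):(3L * ncod))
  target <- as.integer(rbs_match_len)
  for (iter in 1:100) {
    changed <- FALSE
    # (a) no internal in-frame stop codons
    codons <- substring(s, 3L * seq_len(ncod) - 2L, 3L * seq_len(ncod))
    bad <- which(codons %in% .STOP_CODONS & seq_len(ncod) < ncod)
    for (j in bad) {
      base_pos <- (3L * j - 2L):(3L * j)
      free <- setdiff(base_pos, pinned)
      .assert(length(free) > 0L, "cannot repair stop codon at codon %d", j)
      substr(s, free[1L], free[1L]) <- "C"
      changed <- TRUE
    }
    # (a2) the planted iTIS is the only in-frame start codon within 5
    # codons, so its initiation peak cannot be attributed to a neighbor
    near <- setdiff(max(2L, k - 5L):min(ncod - 1L, k + 5L), k)
    bad2 <- near[codons[near] %in% .START_CODONS]
    for (j in bad2) {
      free <- setdiff((3L * j - 2L):(3L * j), pinned)
      .assert(length(free) > 0L, "cannot repair start codon at codon %d", j)
      substr(s, free[1L], free[1L]) <- "C"
      changed <- TRUE
    }
    # (b) RBS window score must be exactly the target (>= 4) or below 4
    win_start <- p - wlen
    if (win_start >= 1L) {
      sc <- scoreRbs(substr(s, win_start, p - 1L))
      ok <- if (target >= 4L)
        sc$match_len == target && sc$spacer_nt == rbs_spacer_nt
      else sc$match_len < 4L
      if (!ok) {
        run <- (win_start + sc$window_pos - 1L):
               (win_start + sc$window_pos + sc$match_len - 2L)
        free <- setdiff(run, pinned)
        .assert(length(free) > 0L,
                "cannot repair RBS window (planted run interferes)")
        substr(s, free[1L], free[1L]) <- "C"
        changed <- TRUE
      }
    }
    if (!changed) return(s)
  }
  stop("locus repair did not converge", call. = FALSE)
}

#' Simulate paired ribosome-profiling coverage tracks
#'
#' The untreated track is uniform elongation coverage over each annotated
#' CDS (per-base Poisson counts at \code{background_depth}).  The
#' initiation-trapped track is the same background plus peaks at every
#' annotated CDS start and every truth iTIS: a 5-nt plateau of
#' deterministic height \code{(peak_enrichment - 1) * background_depth}
#' added to the Poisson background, so the expected peak maximum is
#' \code{peak_enrichment * background_depth}.  With
#' \code{peak_enrichment = 1} the two tracks are identically distributed;
#' with \code{background_depth = 0} both tracks are all zero.
#'
#' @param bundle a \linkS4class{GenomeBundle} with CDS annotations.
#' @param truths list of truth records from \code{\link{simulateRpnLocus}}
#'   (or a single truth record).
#' @param peak_enrichment fold enrichment of initiation peaks over
#'   background (>= 1, default 50).
#' @param background_depth mean per-base background coverage (default 2).
#' @param seed RNG seed.
#' @return list of two \linkS4class{CoverageTrack}s named
#'   \code{untreated} and \code{initiation_trapped}.
#' @export
simulateRiboseqTracks <- function(bundle, truths, peak_enrichment = 50,
                                  background_depth = 2, seed = 1L) {
  .assert(peak_enrichment >= 1, "peak_enrichment must be >= 1")
  .assert(background_depth >= 0, "background_depth must be >= 0")
  if (!is.null(truths$itis_genome_pos)) truths <- list(truths)
  ann <- annotations(bundle)
  cdss <- ann[ann$feature_type == "CDS"]
  lens <- Biostrings::width(sequences(bundle))
  names(lens) <- names(sequences(bundle))
  .with_seed(seed, {
    mk <- function() lapply(lens, function(L) numeric(L))
    unt <- mk(); trt <- mk()
    for (i in seq_along(cdss)) {
      ctg <- as.character(GenomicRanges::seqnames(cdss[i]))
      idx <- BiocGenerics::start(cdss[i]):BiocGenerics::end(cdss[i])
      unt[[ctg]][idx] <- unt[[ctg]][idx] +
        stats::rpois(length(idx), background_depth)
      trt[[ctg]][idx] <- trt[[ctg]][idx] +
        stats::rpois(length(idx), background_depth)
    }
    h <- (peak_enrichment - 1) * background_depth
    add_peak <- function(ctg, pos) {
      idx <- max(1L, pos - 2L):min(lens[[ctg]], pos + 2L)
      trt[[ctg]][idx] <<- trt[[ctg]][idx] + h
    }
    for (i in seq_along(cdss)) {
      ctg <- as.character(GenomicRanges::seqnames(cdss[i]))
      pos <- if (as.character(BiocGenerics::strand(cdss[i])) == "-")
        BiocGenerics::end(cdss[i]) else BiocGenerics::start(cdss[i])
      add_peak(ctg, pos)
    }
    for (tr in truths) add_peak(tr$contig, tr$itis_genome_pos)
    list(untreated = CoverageTrack(unt, "untreated"),
         initiation_trapped = CoverageTrack(trt, "initiation_trapped"))
  })
}

#' Simulate a strain panel of homologs varying in repeat copy number
#'
#' One protein per requested copy number: a shared base protein with
#' \code{copies} adjacent copies of the four-residue unit inserted at a
#' fixed point (default 12 residues after the initiating Met, the middle
#' of the 8-20 range observed for Rpn small proteins).  The base protein
#' is sampled from residues not occurring in the unit, so the inserted
#' array can never be extended by flanking sequence and the truth copy
#' number is exact.  Sequences are identical outside the repeat block.
#'
#' @param copies_list integer vector of repeat copy numbers (>= 0).
#' @param repeat_unit the repeated unit (default "KGIE").
#' @param base_len length of the base protein (default 60).
#' @param insert_after_aa insertion point, residues after Met (default 12).
#' @param seed RNG seed.
#' @return named \link[Biostrings]{AAStringSet} (names strain1, strain2,
#'   ...), with attribute \code{truth} carrying the generator parameters.
#' @export
simulateStrainPanel <- function(copies_list, repeat_unit = "KGIE",
                                base_len = 60L, insert_after_aa = 12L,
                                seed = 1L) {
  .assert(all(copies_list >= 0L), "copies must be >= 0")
  .assert(nchar(repeat_unit) == 4L, "repeat unit must be 4 residues")
  pool <- setdiff(Biostrings::AA_STANDARD,
                  c(strsplit(repeat_unit, "")[[1L]], "M", "C"))
  .with_seed(seed, {
    base <- paste0("M", paste(sample(pool, base_len - 1L, replace = TRUE),
                              collapse = ""))
    seqs <- vapply(copies_list, function(cp)
      insertRepeatUnits(base, repeat_unit, cp, insert_after_aa),
      character(1))
    out <- Biostrings::AAStringSet(seqs)
    names(out) <- paste0("strain", seq_along(copies_list))
    attr(out, "truth") <- list(base_protein = base,
                               repeat_unit = repeat_unit,
                               copies_list = as.integer(copies_list),
                               insert_after_aa = as.integer(insert_after_aa))
    out
  })
}

#' Simulate a gene table with defense genes clustered near focal genes
#'
#' Lays \code{n_genes} genes along one contig and flags each as a defense
#' gene with probability \code{p_near} when it lies within
#' \code{window_genes} genes of a focal gene and \code{p_bg} otherwise
#' (focal genes themselves are never flagged).  Focal genes are evenly
#' spaced so their windows do not overlap.  With \code{p_near = p_bg} the
#' focal neighborhoods are exchangeable with the background (the null of
#' the enrichment test).
#'
#' @param n_genes total number of genes (default 4000, a typical
#'   bacterial genome scale, so focal loci are sparse).
#' @param n_focal number of focal genes (default 50).
#' @param window_genes neighborhood half-width in genes (default 10).
#' @param p_near defense probability near focal genes.
#' @param p_bg background defense probability.
#' @param seed RNG seed.
#' @return list with \code{annotations} (\link[GenomicRanges]{GRanges}
#'   with gene_id, feature_type, defense_flag) and \code{focal_ids}.
#' @export
simulateDefenseContext <- function(n_genes = 4000L, n_focal = 50L,
                                   window_genes = 10L, p_near = 0.3,
                                   p_bg = 0.05, seed = 1L) {
  .assert(p_near >= p_bg, "p_near must be >= p_bg")
  .assert(p_near >= 0 && p_near <= 1 && p_bg >= 0 && p_bg <= 1,
          "probabilities must lie in [0,1]")
  spacing <- n_genes %/% n_focal
  .assert(spacing >= 2L * window_genes + 2L,
          "focal windows overlap: increase n_genes or reduce n_focal")
  focal_idx <- spacing %/% 2L + spacing * (seq_len(n_focal) - 1L)
  near <- unique(unlist(lapply(focal_idx, function(i)
    max(1L, i - window_genes):min(n_genes, i + window_genes))))
  near <- setdiff(near, focal_idx)
  .with_seed(seed, {
    flags <- logical(n_genes)
    flags[near] <- stats::runif(length(near)) < p_near
    bg <- setdiff(seq_len(n_genes), c(near, focal_idx))
    flags[bg] <- stats::runif(length(bg)) < p_bg
    width <- 900L; gap <- 100L
    starts <- (seq_len(n_genes) - 1L) * (width + gap) + 1L
    ann <- GenomicRanges::GRanges("ctx1",
      IRanges::IRanges(start = starts, width = width), strand = "+")
    ann$gene_id <- sprintf("g%04d", seq_len(n_genes))
    ann$feature_type <- "gene"
    ann$defense_flag <- flags
    list(annotations = ann, focal_ids = ann$gene_id[focal_idx])
  })
}
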