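#' Read a FASTA file
#'
#' Parses FASTA records in file order.  Multi-line sequence bodies are
#' concatenated; the header token up to the first whitespace is used as the
#' record id.  Input case is folded to uppercase and validated against the
#' declared alphabet (ACGTN for DNA; the 20 amino acids plus X and * for
#' protein).  Malformed input is rejected with an error naming the offending
#' line, never silently repaired.
#'
#' @param path path to a FASTA file.
#' @param moltype \code{"dna"} or \code{"protein"}.
#' @return A \link[Biostrings]{DNAStringSet} or
#'   \link[Biostrings]{AAStringSet}; empty set for an empty file.
#' @export
readFasta <- function(path, moltype = c("dna", "protein")) {
  moltype <- match.arg(moltype)
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  ids <- character(); seqs <- character()
  cur <- NULL; buf <- character(); header_line <- NA_integer_
  flush <- function() {
    if (!is.null(cur)) {
      s <- paste(buf, collapse = "")
      .assert(nzchar(s), "line %d: record '%s' has an empty sequence body",
              header_line, cur)
      ids[[length(ids) + 1L]] <<- cur
      seqs[[length(seqs) + 1L]] <<- s
    }
  }
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (startsWith(ln, ">")) {
      id <- sub("\\s.*$", "", substring(ln, 2L))
      .assert(nzchar(id), "line %d: malformed FASTA header (empty id)", i)
      flush(); cur <- id; buf <- character(); header_line <- i
    } else if (nzchar(trimws(ln))) {
      .assert(!is.null(cur),
              "line %d: sequence data before any FASTA header", i)
      buf[[length(buf) + 1L]] <- trimws(ln)
    }
  }
  flush()
  seqs <- toupper(seqs)
  alph <- if (moltype == "dna") "ACGTN" else "ACDEFGHIKLMNPQRSTVWYX*"
  bad <- grepl(sprintf("[^%s]", alph), seqs)
  .assert(!any(bad), "record '%s' contains characters outside alphabet [%s]",
          if (any(bad)) ids[which(bad)[1L]] else "", alph)
  out <- if (moltype == "dna") Biostrings::DNAStringSet(seqs)
         else Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write sequences to FASTA
#'
#' Writes 60-column-wrapped records; \code{writeFasta(readFasta(f))}
#' reproduces a 60-column-wrapped input byte-identically.
#'
#' @param x a named \link[Biostrings]{XStringSet} (or character vector).
#' @param path output path.
#' @param width line-wrap width in characters.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(x, path, width = 60L) {
  con <- file(path, "w"); on.exit(close(con))
  nm <- names(x)
  .assert(!is.null(nm), "sequences must be named")
  for (i in seq_along(x)) {
    s <- as.character(x[[i]])
    writeLines(paste0(">", nm[[i]]), con)
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con)
  }
  invisible(path)
}

#' Read gene annotations from GFF3
#'
#' Loads a GFF3 file (1-based inclusive coordinates) into a
#' \link[GenomicRanges]{GRanges}.  The \code{ID} attribute becomes the
#' \code{gene_id} metadata column, the feature type column becomes
#' \code{feature_type}, and a \code{defense=true/false} attribute becomes
#' the logical \code{defense_flag} column (FALSE when absent).  Comment and
#' directive lines are skipped.  Structural errors (end < start, unknown
#' strand) are rejected with the offending line number.
#'
#' @param path path to a GFF3 file.
#' @return A \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{gene_id}, \code{feature_type}, \code{defense_flag}, plus
#'   \code{source} and any remaining attributes.
#' @export
readGff3 <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    .assert(length(f) >= 9L, "line %d: expected 9 tab-separated columns", i)
    st <- suppressWarnings(as.integer(f[[4L]]))
    en <- suppressWarnings(as.integer(f[[5L]]))
    .assert(!is.na(st) && !is.na(en), "line %d: non-numeric coordinates", i)
    .assert(en >= st, "line %d: end (%d) < start (%d)", i, en, st)
    .assert(f[[7L]] %in% c("+", "-", "."),
            "line %d: unknown strand character '%s'", i, f[[7L]])
  }
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- S4Vectors::mcols(gr)
  gene_id <- if (!is.null(mc$ID)) as.character(mc$ID)
             else rep(NA_character_, length(gr))
  defense <- if (!is.null(mc$defense))
    tolower(as.character(mc$defense)) %in% "true" else rep(FALSE, length(gr))
  out <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(gr), IRanges::ranges(gr),
    strand = BiocGenerics::strand(gr))
  out$gene_id <- gene_id
  out$feature_type <- as.character(mc$type)
  out$defense_flag <- defense
  out$source <- as.character(mc$source)
  out
}

#' Write gene annotations to GFF3
#'
#' Inverse of \code{\link{readGff3}}: \code{gene_id} is written as the
#' \code{ID} attribute and \code{defense_flag} as \code{defense=true/false}.
#'
#' @param gr a \link[GenomicRanges]{GRanges} with \code{gene_id},
#'   \code{feature_type} and optional \code{defense_flag} columns.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGff3 <- function(gr, path) {
  src <- if (!is.null(gr$source)) gr$source else rep("rpntools", length(gr))
  ft <- if (!is.null(gr$feature_type)) gr$feature_type
        else rep("gene", length(gr))
  def <- if (!is.null(gr$defense_flag)) gr$defense_flag
         else rep(FALSE, length(gr))
  attrs <- sprintf("ID=%s;defense=%s", gr$gene_id,
                   ifelse(def, "true", "false"))
  lines <- c("##gff-version 3", sprintf(
    "%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
    as.character(GenomicRanges::seqnames(gr)), src, ft,
    BiocGenerics::start(gr), BiocGenerics::end(gr),
    as.character(BiocGenerics::strand(gr)), attrs))
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedGraph coverage file into a CoverageTrack
#'
#' Intervals (0-based half-open in the file) are expanded to per-base
#' coverage; uncovered bases are 0.  Overlapping intervals are an error,
#' never summed, so ambiguity is surfaced rather than repaired.  Intervals
#' extending beyond the declared contig length are rejected naming the
#' interval.
#'
#' @param path path to a bedGraph file.
#' @param contig_lengths named integer vector of contig lengths.
#' @param label track label, \code{"untreated"} or
#'   \code{"initiation_trapped"}.
#' @return A \linkS4class{CoverageTrack}.
#' @export
readBedGraph <- function(path, contig_lengths,
                         label = c("untreated", "initiation_trapped")) {
  label <- match.arg(label)
  .assert(file.exists(path), "file not found: %s", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  vals <- lapply(contig_lengths, function(n) numeric(n))
  names(vals) <- names(contig_lengths)
  if (length(gr)) {
    hits <- GenomicRanges::findOverlaps(gr, drop.self = TRUE,
                                        drop.redundant = TRUE)
    .assert(length(hits) == 0L,
            "overlapping bedGraph intervals (first pair: records %d and %d)",
            if (length(hits)) S4Vectors::queryHits(hits)[1L] else 0L,
            if (length(hits)) S4Vectors::subjectHits(hits)[1L] else 0L)
    ctg <- as.character(GenomicRanges::seqnames(gr))
    for (i in seq_along(gr)) {
      .assert(ctg[[i]] %in% names(vals),
              "bedGraph contig '%s' not among declared contigs", ctg[[i]])
      s <- BiocGenerics::start(gr)[i]; e <- BiocGenerics::end(gr)[i]
      .assert(e <= contig_lengths[[ctg[[i]]]],
              "interval %s:%d-%d beyond contig length %d",
              ctg[[i]], s - 1L, e, contig_lengths[[ctg[[i]]]])
      vals[[ctg[[i]]]][s:e] <- gr$score[[i]]
    }
  }
  CoverageTrack(vals, label)
}

#' Write a CoverageTrack to bedGraph
#'
#' Runs of equal non-zero coverage are written as 0-based half-open
#' intervals; zero-coverage bases are omitted.
#'
#' @param track a \linkS4class{CoverageTrack}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (ctg in names(trackValues(track))) {
    v <- trackValues(track)[[ctg]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    keep <- r$values != 0
    if (any(keep))
      writeLines(sprintf("%s\t%d\t%d\t%g", ctg, starts[keep] - 1L,
                         ends[keep], r$values[keep]), con)
  }
  invisible(path)
}

#' Extract the coding sequence of an annotated gene
#'
#' Returns the CDS on the coding strand: minus-strand genes are
#' reverse-complemented before any CDS-level analysis, so an annotated CDS
#' beginning ATG always translates to a protein beginning M.
#'
#' @param bundle a \linkS4class{GenomeBundle}.
#' @param gene_id gene identifier to extract.
#' @param feature_type annotation feature type to use (default "CDS",
#'   falling back to "gene" if no CDS feature exists for the gene).
#' @return A \link[Biostrings]{DNAString} of the coding-strand sequence.
#' @export
extractCds <- function(bundle, gene_id, feature_type = "CDS") {
  ann <- annotations(bundle)
  sel <- ann[ann$gene_id == gene_id & ann$feature_type == feature_type]
  if (!length(sel)) sel <- ann[ann$gene_id == gene_id]
  .assert(length(sel) >= 1L, "gene '%s' not found in annotations", gene_id)
  sel <- sel[1L]
  ctg <- as.character(GenomicRanges::seqnames(sel))
  s <- Biostrings::subseq(sequences(bundle)[[ctg]],
                          BiocGenerics::start(sel), BiocGenerics::end(sel))
  if (as.character(BiocGenerics::strand(sel)) == "-")
    s <- Biostrings::reverseComplement(s)
  s
}

#' Translate a coding sequence
#'
#' @param cds a \link[Biostrings]{DNAString} or character CDS (coding
#'   strand, length divisible by 3).
#' @param drop_stop drop the trailing stop symbol if present.
#' @return An \link[Biostrings]{AAString} protein sequence.
#' @export
translateCds <- function(cds, drop_stop = TRUE) {
  cds <- Biostrings::DNAString(as.character(cds))
  .assert(length(cds) %% 3L == 0L, "CDS length %d not divisible by 3",
          length(cds))
  aa <- Biostrings::translate(cds, if.fuzzy.codon = "X")
  if (drop_stop && length(aa) &&
      as.character(Biostrings::subseq(aa, length(aa))) == "*")
    aa <- Biostrings::subseq(aa, 1L, length(aa) - 1L)
  aa
}
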