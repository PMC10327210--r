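#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom BiocGenerics width start end strand
#' @importClassesFrom Biostrings DNAStringSet
#' @importClassesFrom GenomicRanges GRanges
#' @importFrom stats median rpois runif rnorm pnorm
#' @importFrom utils combn data
NULL

#' CoverageTrack: per-base ribosome-profiling coverage
#'
#' Holds one per-base, non-negative coverage vector per contig, plus a label
#' identifying the library type.  Ribosome-profiling experiments with
#' initiation-trapping antibiotics (e.g. Onc112, retapamulin) produce sharp
#' coverage peaks at translation initiation sites; the matched untreated
#' library shows elongation coverage over the whole coding sequence.
#'
#' @slot values named list of numeric vectors, one per contig; element i is
#'   coverage at base i (1-based).
#' @slot label character(1), one of \code{"untreated"} or
#'   \code{"initiation_trapped"}.
#' @exportClass CoverageTrack
setClass("CoverageTrack",
  representation(values = "list", label = "character"))

setValidity("CoverageTrack", function(object) {
  msg <- character()
  if (length(object@label) != 1L ||
      !object@label %in% c("untreated", "initiation_trapped"))
    msg <- c(msg, "label must be 'untreated' or 'initiation_trapped'")
  if (is.null(names(object@values)) || any(names(object@values) == ""))
    msg <- c(msg, "values must be a named list (names are contigs)")
  for (v in object@values) {
    if (!is.numeric(v)) { msg <- c(msg, "coverage must be numeric"); break }
    if (any(!is.finite(v)) || any(v < 0)) {
      msg <- c(msg, "coverage values must be finite and >= 0"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CoverageTrack
#'
#' @param values named list of per-base numeric vectors (one per contig).
#' @param label \code{"untreated"} or \code{"initiation_trapped"}.
#' @return A \linkS4class{CoverageTrack}.
#' @export
CoverageTrack <- function(values, label) {
  new("CoverageTrack", values = values, label = label)
}

#' GenomeBundle: genome + annotation + optional profiling tracks
#'
#' The unit that all discovery stages consume: one or more contig sequences,
#' gene/CDS annotations, and up to two ribosome-profiling coverage tracks
#' (untreated and initiation-trapped).
#'
#' @slot sequences a \link[Biostrings]{DNAStringSet}, one entry per contig.
#' @slot annotations a \link[GenomicRanges]{GRanges} with metadata columns
#'   \code{gene_id}, \code{feature_type} and (optionally)
#'   \code{defense_flag}.
#' @slot tracks list of 0--2 \linkS4class{CoverageTrack} objects.
#' @exportClass GenomeBundle
setClass("GenomeBundle",
  representation(sequences = "DNAStringSet", annotations = "GRanges",
                 tracks = "list"))

setValidity("GenomeBundle", function(object) {
  msg <- character()
  ctgs <- names(object@sequences)
  if (is.null(ctgs) || any(ctgs == ""))
    msg <- c(msg, "all sequences must be named")
  ann <- object@annotations
  if (length(ann)) {
    if (is.null(ann$gene_id))
      msg <- c(msg, "annotations need a gene_id metadata column")
    bad <- !as.character(GenomicRanges::seqnames(ann)) %in% ctgs
    if (any(bad))
      msg <- c(msg, sprintf("annotation contig(s) not in sequences: %s",
                            paste(unique(as.character(
                              GenomicRanges::seqnames(ann))[bad]),
                              collapse = ", ")))
    else {
      lens <- Biostrings::width(object@sequences)[
        match(as.character(GenomicRanges::seqnames(ann)), ctgs)]
      if (any(BiocGenerics::start(ann) < 1L) ||
          any(BiocGenerics::end(ann) > lens))
        msg <- c(msg, "annotation coordinates outside contig bounds")
    }
  }
  if (length(object@tracks) > 2L)
    msg <- c(msg, "at most two coverage tracks (untreated, trapped)")
  for (tr in object@tracks) {
    if (!is(tr, "CoverageTrack")) {
      msg <- c(msg, "tracks must be CoverageTrack objects"); break
    }
    for (ctg in names(tr@values)) {
      if (!ctg %in% ctgs) {
        msg <- c(msg, sprintf("track contig '%s' not in sequences", ctg))
      } else if (length(tr@values[[ctg]]) !=
                 Biostrings::width(object@sequences)[match(ctg, ctgs)]) {
        msg <- c(msg, sprintf("track length mismatch on contig '%s'", ctg))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenomeBundle
#'
#' @param sequences named \link[Biostrings]{DNAStringSet} (or named character
#'   vector) of contig sequences.
#' @param annotations \link[GenomicRanges]{GRanges} with \code{gene_id} and
#'   \code{feature_type} metadata columns; may be empty.
#' @param tracks list of 0--2 \linkS4class{CoverageTrack} objects.
#' @return A \linkS4class{GenomeBundle}.
#' @export
GenomeBundle <- function(sequences, annotations = GenomicRanges::GRanges(),
                         tracks = list()) {
  if (is.character(sequences))
    sequences <- Biostrings::DNAStringSet(sequences)
  new("GenomeBundle", sequences = sequences, annotations = annotations,
      tracks = tracks)
}

setMethod("show", "GenomeBundle", function(object) {
  cat("GenomeBundle with", length(object@sequences), "contig(s),",
      length(object@annotations), "annotation(s),",
      length(object@tracks), "track(s)\n")
  if (length(object@sequences)) {
    w <- Biostrings::width(object@sequences)
    cat("  contigs:", paste(sprintf("%s (%d bp)",
        names(object@sequences), w), collapse = ", "), "\n")
  }
  for (tr in object@tracks) cat("  track:", tr@label, "\n")
})

setMethod("show", "CoverageTrack", function(object) {
  cat("CoverageTrack [", object@label, "] over ",
      length(object@values), " contig(s)\n", sep = "")
})

#' @describeIn GenomeBundle-class contig sequences accessor
#' @param x a GenomeBundle
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))
#' @rdname GenomeBundle-class
#' @export
setMethod("sequences", "GenomeBundle", function(x) x@sequences)

#' @describeIn GenomeBundle-class annotations accessor
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname GenomeBundle-class
#' @export
setMethod("annotations", "GenomeBundle", function(x) x@annotations)

#' @describeIn GenomeBundle-class coverage-track accessor
#' @export
setGeneric("tracks", function(x) standardGeneric("tracks"))
#' @rdname GenomeBundle-class
#' @export
setMethod("tracks", "GenomeBundle", function(x) x@tracks)

#' @describeIn CoverageTrack-class per-contig coverage list accessor
#' @param x a CoverageTrack
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @rdname CoverageTrack-class
#' @export
setMethod("trackValues", "CoverageTrack", function(x) x@values)

#' @describeIn CoverageTrack-class library-type label accessor
#' @export
setGeneric("trackLabel", function(x) standardGeneric("trackLabel"))
#' @rdname CoverageTrack-class
#' @export
setMethod("trackLabel", "CoverageTrack", function(x) x@label)

#' EnrichmentReport: defense-gene neighborhood enrichment result
#'
#' Result container for the focal-vs-random comparison of per-gene
#' defense-neighbor fractions, tested with a one-sided (greater)
#' Mann-Whitney U test.  Carries all per-gene observations so they can be
#' re-plotted or exported.
#'
#' @slot focal_fractions numeric, defense fraction around each focal gene.
#' @slot random_fractions numeric, defense fraction around each sampled
#'   random gene.
#' @slot U numeric(1), the Mann-Whitney U statistic (focal vs random).
#' @slot p_value numeric(1), one-sided (greater) p-value.
#' @slot p_two_sided numeric(1), two-sided p-value, reported alongside.
#' @slot method \code{"exact"} or \code{"normal_approx"}.
#' @slot n_random_draws integer(1), number of random genes sampled.
#' @slot seed integer(1), RNG seed used for the random draw.
#' @exportClass EnrichmentReport
setClass("EnrichmentReport",
  representation(focal_fractions = "numeric", random_fractions = "numeric",
                 U = "numeric", p_value = "numeric", p_two_sided = "numeric",
                 method = "character", n_random_draws = "integer",
                 seed = "integer"))

setValidity("EnrichmentReport", function(object) {
  msg <- character()
  n <- length(object@focal_fractions); m <- length(object@random_fractions)
  if (object@U < 0 || object@U > n * m)
    msg <- c(msg, "U must lie in [0, n*m]")
  if (object@p_value <= 0 || object@p_value > 1)
    msg <- c(msg, "p_value must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "EnrichmentReport", function(object) {
  cat("EnrichmentReport:", length(object@focal_fractions), "focal vs",
      length(object@random_fractions), "random genes\n")
  cat(sprintf("  median fraction: focal %.3f, random %.3f\n",
      stats::median(object@focal_fractions),
      stats::median(object@random_fractions)))
  cat(sprintf("  U = %.1f, one-sided p = %.4g (%s), two-sided p = %.4g\n",
      object@U, object@p_value, object@method, object@p_two_sided))
})

#' ProteinStructure: atoms of a (multi-chain) protein structure
#'
#' A light-weight atom-table representation sufficient for solvent-accessible
#' surface area, interface and helix-geometry calculations.  Radii are
#' assigned per element from a declared table (C 1.70, N 1.55, O 1.52,
#' S 1.80 Angstrom).
#'
#' @slot atoms data.frame with columns \code{chain}, \code{resno},
#'   \code{resname}, \code{atom}, \code{element}, \code{x}, \code{y},
#'   \code{z}, \code{radius}.
#' @exportClass ProteinStructure
setClass("ProteinStructure", representation(atoms = "data.frame"))

setValidity("ProteinStructure", function(object) {
  msg <- character()
  need <- c("chain", "resno", "resname", "atom", "element",
            "x", "y", "z", "radius")
  miss <- setdiff(need, names(object@atoms))
  if (length(miss))
    msg <- c(msg, paste("atoms table missing columns:",
                        paste(miss, collapse = ", ")))
  else {
    xyz <- as.matrix(object@atoms[, c("x", "y", "z")])
    if (nrow(xyz) && any(!is.finite(xyz)))
      msg <- c(msg, "coordinates must be finite")
    if (nrow(object@atoms) && any(!is.finite(object@atoms$radius) |
                                  object@atoms$radius <= 0))
      msg <- c(msg, "radii must be positive and finite")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "ProteinStructure", function(object) {
  ch <- unique(object@atoms$chain)
  cat("ProteinStructure:", nrow(object@atoms), "atoms,",
      length(ch), "chain(s):", paste(ch, collapse = ", "), "\n")
})

#' @describeIn ProteinStructure-class atom-table accessor
#' @param x a ProteinStructure
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname ProteinStructure-class
#' @export
setMethod("atoms", "ProteinStructure", function(x) x@atoms)

# van der Waals radii (Angstrom) used throughout the structure module
.ELEMENT_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)

#' Construct a ProteinStructure from an atom table
#'
#' @param atoms data.frame with columns chain, resno, resname, atom, element,
#'   x, y, z (radius is filled in from the element table if absent).
#' @return A \linkS4class{ProteinStructure}.
#' @export
ProteinStructure <- function(atoms) {
  if (is.null(atoms$radius)) {
    r <- .ELEMENT_RADII[toupper(atoms$element)]
    r[is.na(r)] <- 1.70  # unknown elements treated as carbon-like
    atoms$radius <- unname(r)
  }
  new("ProteinStructure", atoms = atoms)
}
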