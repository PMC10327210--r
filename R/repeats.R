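# Four-amino-acid tandem repeat detection and cross-strain copy-number
# comparison.  Rpn C-terminal domains vary between strains of a species by
# tandem four-residue units, typically one hydrophobic plus three
# charged-or-glycine residues.

.HYDROPHOBIC_AA <- c("A", "V", "L", "I", "M", "F", "W", "Y")
.CHARGED_OR_GLY <- c("D", "E", "K", "R", "H", "G")

# lexicographically smallest rotation of a unit
.canonical_rotation <- function(unit) {
  n <- nchar(unit)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(unit, i, n), substr(unit, 1L, i - 1L)), character(1))
  min(rots)
}

# smallest p such that the unit is a repetition of its own p-prefix
.primitive_period <- function(unit) {
  n <- nchar(unit)
  for (p in seq_len(n)) {
    if (n %% p != 0L) next
    if (strrep(substr(unit, 1L, p), n %/% p) == unit) return(p)
  }
  n
}

#' Find tandem amino-acid repeats of a fixed unit length
#'
#' Reports maximal, non-overlapping tandem arrays of period
#' \code{unit_len}.  The core of each array is exact
#' (\code{region length = unit_len * copies}); an optional mismatch
#' tolerance allows additional units differing from the array's first unit
#' by at most \code{max_mismatch_per_unit} residues.  The reported unit is
#' canonicalized to its lexicographically smallest rotation so homologous
#' arrays are comparable regardless of array boundaries.  Arrays whose unit
#' has a primitive period shorter than \code{unit_len} (homopolymers,
#' period-2 units) are not reported at period \code{unit_len}.
#'
#' @param protein protein sequence (character or AAString).
#' @param unit_len repeat unit length (default 4).
#' @param min_copies smallest reportable copy number (default 2).
#' @param max_mismatch_per_unit mismatches tolerated per unit against the
#'   first unit of the array (default 0 = exact).
#' @return data.frame with columns \code{start_aa} (1-based), \code{unit}
#'   (canonical rotation), \code{unit_as_found} (phase as it occurs),
#'   \code{copies}, \code{mismatches}, \code{composition_ok},
#'   \code{offset_after_met}; zero rows when nothing is found.
#' @export
findTandemRepeats <- function(protein, unit_len = 4L, min_copies = 2L,
                              max_mismatch_per_unit = 0L) {
  s <- toupper(as.character(protein))
  n <- nchar(s)
  empty <- data.frame(start_aa = integer(), unit = character(),
                      unit_as_found = character(), copies = integer(),
                      mismatches = integer(), composition_ok = logical(),
                      offset_after_met = integer(),
                      stringsAsFactors = FALSE)
  if (n < unit_len * min_copies) return(empty)
  ch <- strsplit(s, "")[[1L]]
  regions <- list()
  i <- 1L
  while (i + unit_len * min_copies - 1L <= n) {
    first <- substr(s, i, i + unit_len - 1L)
    copies <- 1L; mism <- 0L
    repeat {
      nxt_start <- i + copies * unit_len
      if (nxt_start + unit_len - 1L > n) break
      nxt <- substr(s, nxt_start, nxt_start + unit_len - 1L)
      d <- sum(strsplit(nxt, "")[[1L]] != strsplit(first, "")[[1L]])
      if (d > max_mismatch_per_unit) break
      copies <- copies + 1L; mism <- mism + d
    }
    if (copies >= min_copies && .primitive_period(first) == unit_len) {
      regions[[length(regions) + 1L]] <-
        list(start = i, copies = copies, unit = first, mism = mism)
      i <- i + copies * unit_len          # non-overlapping
    } else i <- i + 1L
  }
  if (!length(regions)) return(empty)
  # maximality on the left: drop regions that are a suffix of a longer one
  data.frame(
    start_aa = vapply(regions, `[[`, integer(1), "start"),
    unit = vapply(regions, function(r) .canonical_rotation(r$unit),
                  character(1)),
    unit_as_found = vapply(regions, `[[`, character(1), "unit"),
    copies = vapply(regions, `[[`, integer(1), "copies"),
    mismatches = vapply(regions, `[[`, integer(1), "mism"),
    composition_ok = vapply(regions, function(r)
      classifyUnitComposition(r$unit), logical(1)),
    offset_after_met = vapply(regions, `[[`, integer(1), "start") - 1L,
    stringsAsFactors = FALSE)
}

#' Classify a repeat unit's residue composition
#'
#' TRUE iff the unit has exactly one hydrophobic residue (AVLIMFWY) and the
#' remaining three residues are charged or glycine (DEKRHG) -- the
#' composition typical of the strain-variable four-residue units in Rpn
#' C-terminal domains.
#'
#' @param unit a 4-residue string.
#' @return logical(1).
#' @export
classifyUnitComposition <- function(unit) {
  u <- toupper(as.character(unit))
  .assert(nchar(u) == 4L, "unit must be 4 residues (got '%s')", u)
  ch <- strsplit(u, "")[[1L]]
  .assert(all(ch %in% c(.HYDROPHOBIC_AA, .CHARGED_OR_GLY, "C", "N", "P",
                        "Q", "S", "T")),
          "non-amino-acid character in unit '%s'", u)
  sum(ch %in% .HYDROPHOBIC_AA) == 1L &&
    sum(ch %in% .CHARGED_OR_GLY) == 3L
}

#' Repeat-region offset after the initiating methionine
#'
#' In Rpn small proteins the variable four-residue repeats begin 8--20
#' residues after the initiating Met; offsets outside that range are
#' flagged rather than rejected.
#'
#' @param region one row of a \code{\link{findTandemRepeats}} result.
#' @param expected_range the flag-free offset range (default c(8, 20)).
#' @return list with \code{offset} (residues after Met) and \code{flagged}.
#' @export
locateRepeatOffset <- function(region, expected_range = c(8L, 20L)) {
  off <- as.integer(region$start_aa) - 1L
  list(offset = off,
       flagged = off < expected_range[1L] || off > expected_range[2L])
}

# constant-score AA substitution matrix for alignment (+1 match, -1 mismatch)
.aa_unit_matrix <- function(match = 1, mismatch = -1) {
  alph <- c(Biostrings::AA_STANDARD, "X", "*")
  m <- matrix(mismatch, length(alph), length(alph),
              dimnames = list(alph, alph))
  diag(m) <- match
  m
}

#' Compare repeat copy numbers across strain homologs
#'
#' Counts repeat copies per homolog with \code{\link{findTandemRepeats}}
#' (the region with the most copies, preferring composition-conforming
#' units), tabulates pairwise copy-number differences, and checks indel
#' consistency: in every pairwise global alignment (match +1, mismatch -1,
#' gap open -5, gap extend -1 by default), every gap block intersecting a
#' repeat region must have a length divisible by the unit length.
#'
#' @param homologs named character vector or
#'   \link[Biostrings]{AAStringSet} of homologous protein sequences
#'   (>= 2).
#' @param unit_len repeat unit length (default 4).
#' @param min_copies smallest countable array (default 2).
#' @param match,mismatch,gap_open,gap_extend alignment scoring.
#' @return list with \code{copies} (named integer), \code{units} (named
#'   character, canonical), \code{deltas} (integer vector of pairwise
#'   absolute copy differences), \code{indel_consistent} (logical).
#' @export
compareRepeatCounts <- function(homologs, unit_len = 4L, min_copies = 2L,
                                match = 1, mismatch = -1, gap_open = 5,
                                gap_extend = 1) {
  seqs <- vapply(as.character(homologs), toupper, character(1))
  .assert(length(seqs) >= 2L, "need at least two homologs")
  .assert(all(nzchar(seqs)), "empty sequence among homologs")
  if (is.null(names(seqs)) || any(names(seqs) == ""))
    names(seqs) <- paste0("seq", seq_along(seqs))
  pick_region <- function(df) {
    if (!nrow(df)) return(NULL)
    df <- df[order(-df$composition_ok, -df$copies), , drop = FALSE]
    df[1L, ]
  }
  regions <- lapply(seqs, function(s)
    pick_region(findTandemRepeats(s, unit_len, min_copies)))
  copies <- vapply(regions, function(r)
    if (is.null(r)) 0L else r$copies, integer(1))
  units <- vapply(regions, function(r)
    if (is.null(r)) NA_character_ else r$unit, character(1))
  prs <- utils::combn(length(seqs), 2L)
  deltas <- abs(copies[prs[1L, ]] - copies[prs[2L, ]])
  submat <- .aa_unit_matrix(match, mismatch)
  indel_ok <- TRUE
  for (cidx in seq_len(ncol(prs))) {
    a <- prs[1L, cidx]; b <- prs[2L, cidx]
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seqs[[a]]), Biostrings::AAString(seqs[[b]]),
      substitutionMatrix = submat, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    in_region <- function(ir, reg) {
      if (is.null(reg)) return(logical(length(ir)))
      lo <- reg$start_aa; hi <- reg$start_aa + unit_len * reg$copies - 1L
      BiocGenerics::start(ir) <= hi + 1L & BiocGenerics::end(ir) >= lo - 1L
    }
    # insertion(): blocks present in the pattern only (pattern coords);
    # deletion(): blocks present in the subject only (subject coords)
    gaps_p <- Biostrings::insertion(al)[[1L]]
    gaps_s <- Biostrings::deletion(al)[[1L]]
    wp <- BiocGenerics::width(gaps_p)
    ws <- BiocGenerics::width(gaps_s)
    bad_p <- wp %% unit_len != 0L & in_region(gaps_p, regions[[a]])
    bad_s <- ws %% unit_len != 0L & in_region(gaps_s, regions[[b]])
    if (any(bad_p) || any(bad_s)) indel_ok <- FALSE
  }
  list(copies = copies, units = units, deltas = as.integer(deltas),
       indel_consistent = indel_ok)
}

#' Insert tandem repeat units into a protein
#'
#' Utility used by the strain-panel generator and tests: inserts
#' \code{copies} adjacent copies of \code{unit} after residue
#' \code{after_aa}.
#'
#' @param protein protein sequence (character).
#' @param unit repeat unit.
#' @param copies number of copies to insert (>= 0).
#' @param after_aa residue after which the block is inserted.
#' @return character.
#' @export
insertRepeatUnits <- function(protein, unit, copies, after_aa) {
  .assert(copies >= 0L, "copies must be >= 0 (got %d)", copies)
  s <- as.character(protein)
  paste0(substr(s, 1L, after_aa), strrep(unit, copies),
         substr(s, after_aa + 1L, nchar(s)))
}
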