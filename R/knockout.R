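# Knockout design: ablate an internal start with minimal change to the
# parent coding sequence (fewest amino-acid changes, then mildest
# substitutions under BLOSUM62, then deterministic lexicographic order).

.GENETIC_CODE_CODONS <- names(Biostrings::GENETIC_CODE)

.codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

.blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# penalty of replacing amino acid a by b; 0 when synonymous
.aa_cost <- function(a, b) {
  if (a == b) return(0)
  B <- .blosum62()
  as.numeric(B[a, a] - B[a, b])
}

#' Apply a mutation plan to a coding sequence
#'
#' @param cds coding-strand CDS (character or DNAString).
#' @param plan a plan as returned by \code{\link{designItisKnockout}} (or a
#'   data.frame with \code{codon_index} and \code{new_codon} columns).
#' @return character, the mutated CDS.
#' @export
applyMutationPlan <- function(cds, plan) {
  s <- toupper(as.character(cds))
  subs <- if (is.list(plan) && !is.null(plan$codon_substitutions))
    plan$codon_substitutions else plan
  for (r in seq_len(nrow(subs))) {
    k <- subs$codon_index[r]
    substr(s, 3L * k - 2L, 3L * k) <- subs$new_codon[r]
  }
  s
}

#' Design a minimal-change knockout of an internal translation start
#'
#' Searches substitution sets over the codons overlapping the RBS window
#' and the internal start codon, increasing the set size from 1 up to
#' \code{max_codon_changes}, and returns the first (smallest) set that
#' destroys the start codon (mutated codon not in ATG/GTG/TTG) and leaves a
#' residual RBS contiguous match below \code{min_rbs}.  Among valid sets of
#' that size the plan minimizes (1) the number of parent amino-acid
#' changes, (2) the summed substitution penalty under BLOSUM62, and (3)
#' lexicographic order of the substitutions, so the design is fully
#' deterministic.  Stop codons are never introduced, and the plan is
#' rejected if it creates a new in-frame start codon with an RBS match of
#' \code{min_rbs} or more within 5 codons of the original start.  Searches
#' needing three or more substitutions enumerate RBS codon substitutions
#' from a per-codon shortlist of the eight most promising alternatives
#' (ranked by the residual each achieves alone, then mildness), which
#' bounds the combinatorics while keeping the practically reachable plans.
#'
#' @param cds parent coding sequence (character or DNAString), length
#'   divisible by 3 with terminal stop.
#' @param itis_codon_index 1-based codon index of the internal start to
#'   ablate.
#' @param max_codon_changes largest substitution set considered (default 4).
#' @param min_rbs residual RBS threshold; the plan must reach
#'   \code{residual_rbs_match < min_rbs} (default 4).
#' @param min_spacer,max_spacer RBS spacer range (nt).
#' @return list with \code{found} (logical), \code{codon_substitutions}
#'   (data.frame codon_index, old_codon, new_codon),
#'   \code{parent_aa_changes} (data.frame position, old_aa, new_aa),
#'   \code{residual_rbs_match}, \code{start_destroyed},
#'   \code{mutated_cds}.  When no plan exists within
#'   \code{max_codon_changes}, \code{found} is FALSE (no exception).
#' @export
designItisKnockout <- function(cds, itis_codon_index,
                               max_codon_changes = 4L, min_rbs = 4L,
                               min_spacer = 4L, max_spacer = 13L) {
  s <- toupper(as.character(cds))
  n <- nchar(s)
  .assert(n %% 3L == 0L, "CDS length %d not divisible by 3", n)
  ncod <- n %/% 3L
  k <- as.integer(itis_codon_index)
  codon_at <- function(seqs, j) substr(seqs, 3L * j - 2L, 3L * j)
  .assert(codon_at(s, k) %in% .START_CODONS,
          "codon %d (%s) is not a start codon", k, codon_at(s, k))
  wlen <- 6L + max_spacer
  p <- 3L * (k - 1L) + 1L                     # first base of start codon
  .assert(p - wlen >= 1L, "RBS window extends past the 5' end of the CDS")
  win_cod <- unique((((p - wlen):(p - 1L)) + 2L) %/% 3L)
  win_cod <- win_cod[win_cod >= 1L]
  window_of <- function(seqs) substr(seqs, p - wlen, p - 1L)
  residual_of <- function(seqs)
    scoreRbs(window_of(seqs), min_spacer, max_spacer)$match_len

  non_stop <- setdiff(.GENETIC_CODE_CODONS, .STOP_CODONS)
  # candidate substitutions at one codon position
  subs_at <- function(j) {
    old <- codon_at(s, j)
    alt <- setdiff(non_stop, old)
    data.frame(codon_index = j, old_codon = old, new_codon = alt,
               stringsAsFactors = FALSE)
  }
  start_subs <- subs_at(k)
  start_subs <- start_subs[!start_subs$new_codon %in% .START_CODONS, ,
                           drop = FALSE]
  rbs_subs <- do.call(rbind, lapply(win_cod, subs_at))

  # per-substitution objective components (additive over a plan)
  annotate_subs <- function(subs) {
    aa_old <- .codon_aa(subs$old_codon)
    aa_new <- .codon_aa(subs$new_codon)
    subs$chg <- aa_old != aa_new
    subs$cost <- ifelse(subs$chg,
      mapply(.aa_cost, aa_old, aa_new), 0)
    subs$lex <- sprintf("%06d%s", subs$codon_index, subs$new_codon)
    subs
  }
  verify_no_new_start <- function(mut) {
    for (j in max(1L, k - 5L):min(ncod - 1L, k + 5L)) {
      if (!codon_at(mut, j) %in% .START_CODONS) next
      pj <- 3L * (j - 1L) + 1L
      if (pj - wlen < 1L) next
      if (scoreRbs(substr(mut, pj - wlen, pj - 1L), min_spacer,
                   max_spacer)$match_len >= min_rbs)
        return(FALSE)
    }
    TRUE
  }
  finish <- function(subs) {
    mut <- applyMutationPlan(s, subs)
    aa_old <- .codon_aa(subs$old_codon); aa_new <- .codon_aa(subs$new_codon)
    chg <- aa_old != aa_new
    list(found = TRUE,
         codon_substitutions = subs[order(subs$codon_index), , drop = FALSE],
         parent_aa_changes = data.frame(position = subs$codon_index[chg],
                                        old_aa = aa_old[chg],
                                        new_aa = aa_new[chg],
                                        stringsAsFactors = FALSE),
         residual_rbs_match = residual_of(mut),
         start_destroyed = !codon_at(mut, k) %in% .START_CODONS,
         mutated_cds = mut)
  }

  start_subs <- annotate_subs(start_subs)
  rbs_subs <- annotate_subs(rbs_subs)

  # residuals after single RBS-codon substitutions (start codon never
  # overlaps the window, so residuals are independent of the start change)
  rbs_subs$residual <- vapply(seq_len(nrow(rbs_subs)), function(r) {
    mut <- s
    j <- rbs_subs$codon_index[r]
    substr(mut, 3L * j - 2L, 3L * j) <- rbs_subs$new_codon[r]
    residual_of(mut)
  }, integer(1))

  if (min_rbs <= 0L)   # residual matches are >= 0: no plan can qualify
    return(list(found = FALSE, codon_substitutions = NULL,
                parent_aa_changes = NULL,
                residual_rbs_match = NA_integer_, start_destroyed = FALSE,
                mutated_cds = NULL))

  base_residual <- residual_of(s)
  sub_cols <- c("codon_index", "old_codon", "new_codon")
  # multi-codon RBS searches (3+ total changes) work from a per-codon
  # shortlist of the most promising substitutions, ranked by the residual
  # each achieves alone, then by substitution mildness
  shortlist <- unlist(lapply(split(seq_len(nrow(rbs_subs)),
                                   rbs_subs$codon_index), function(idx) {
    o <- order(rbs_subs$residual[idx], rbs_subs$chg[idx],
               rbs_subs$cost[idx], rbs_subs$lex[idx])
    idx[o][seq_len(min(8L, length(o)))]
  }), use.names = FALSE)
  for (t in seq_len(max_codon_changes)) {
    # candidate RBS subsets of size t-1 whose residual is acceptable
    rbs_sets <- if (t == 1L) {
      if (base_residual < min_rbs) list(integer(0)) else list()
    } else if (t == 2L) {
      as.list(which(rbs_subs$residual < min_rbs))
    } else {
      sets <- utils::combn(shortlist, t - 1L, simplify = FALSE)
      sets <- Filter(function(rset)
        !anyDuplicated(rbs_subs$codon_index[rset]), sets)
      Filter(function(rset)
        residual_of(applyMutationPlan(s, rbs_subs[rset, , drop = FALSE])) <
          min_rbs, sets)
    }
    if (!length(rbs_sets)) next
    # objective components are additive and the start-codon choice is
    # independent of the RBS choice, so rank (start sub x RBS subset)
    # pairs by total (aa changes, cost) and break ties lexicographically
    set_chg <- vapply(rbs_sets, function(r) sum(rbs_subs$chg[r]), 0)
    set_cost <- vapply(rbs_sets, function(r) sum(rbs_subs$cost[r]), 0)
    set_lex <- vapply(rbs_sets, function(r)
      paste(sort(rbs_subs$lex[r]), collapse = "|"), character(1))
    ns <- nrow(start_subs); nr <- length(rbs_sets)
    tot_chg <- rep(start_subs$chg, nr) + rep(set_chg, each = ns)
    tot_cost <- rep(start_subs$cost, nr) + rep(set_cost, each = ns)
    tot_lex <- paste(rep(set_lex, each = ns),
                     rep(start_subs$lex, nr), sep = "|")
    for (idx in order(tot_chg, tot_cost, tot_lex)) {
      si <- (idx - 1L) %% ns + 1L
      ri <- (idx - 1L) %/% ns + 1L
      subs <- rbind(start_subs[si, sub_cols, drop = FALSE],
                    rbs_subs[rbs_sets[[ri]], sub_cols, drop = FALSE])
      if (!verify_no_new_start(applyMutationPlan(s, subs))) next
      .log("INFO", "knockout plan found with %d substitution(s)", t)
      return(finish(subs))
    }
  }
  list(found = FALSE, codon_substitutions = NULL, parent_aa_changes = NULL,
       residual_rbs_match = NA_integer_, start_destroyed = FALSE,
       mutated_cds = NULL)
}
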