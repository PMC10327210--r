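# Deterministic quantification helpers: SEC-MALS stoichiometry inference,
# phage titering, efficiency of plaquing and one-step burst size.

#' Infer oligomer stoichiometry from a SEC-MALS mass
#'
#' Finds the subunit composition whose theoretical mass (sum of copy
#' numbers times subunit masses) best matches the measured mass, over a
#' constrained grid: \code{single_species} fits n copies of one subunit;
#' \code{equimolar_pair} fits k copies of each of two subunits (a symmetric
#' complex); \code{free_pair} fits any copy-number pair.  Ties are broken
#' toward fewer total subunits.  The runner-up composition and its
#' residual are reported so near-calls are visible.
#'
#' @param measured_kda measured molecular weight (kDa).
#' @param subunit_masses_kda subunit masses (kDa); length 1 for
#'   \code{single_species}, length 2 for the pair constraints.
#' @param constraint \code{"single_species"}, \code{"equimolar_pair"} or
#'   \code{"free_pair"}.
#' @param max_copies largest copy number per subunit considered
#'   (default 8).
#' @param uncertainty_kda measurement uncertainty, carried through to the
#'   output for reporting.
#' @return list with \code{composition} (integer copy number per subunit),
#'   \code{theoretical_kda}, \code{residual_kda}, \code{runner_up} (list
#'   with composition, theoretical and residual), \code{constraint}.
#' @export
inferStoichiometry <- function(measured_kda, subunit_masses_kda,
                               constraint = c("single_species",
                                              "equimolar_pair",
                                              "free_pair"),
                               max_copies = 8L, uncertainty_kda = 0) {
  constraint <- match.arg(constraint)
  .assert(length(subunit_masses_kda) >= 1L, "empty subunit mass list")
  .assert(all(subunit_masses_kda > 0), "subunit masses must be positive")
  ns <- length(subunit_masses_kda)
  if (constraint == "single_species") {
    .assert(ns == 1L, "single_species requires exactly one subunit mass")
    grid <- matrix(seq_len(max_copies), ncol = 1L)
  } else {
    .assert(ns == 2L, "pair constraints require exactly two subunit masses")
    if (constraint == "equimolar_pair") {
      k <- seq_len(max_copies)
      grid <- cbind(k, k)
    } else {
      grid <- as.matrix(expand.grid(n1 = 0:max_copies, n2 = 0:max_copies))
      grid <- grid[rowSums(grid) >= 1L, , drop = FALSE]
    }
  }
  theo <- as.numeric(grid %*% subunit_masses_kda)
  resid <- abs(measured_kda - theo)
  total <- rowSums(grid)
  ord <- order(resid, total)
  pick <- function(i) list(composition = as.integer(grid[i, ]),
                           theoretical_kda = theo[i],
                           residual_kda = resid[i])
  best <- pick(ord[1L])
  runner <- if (length(ord) > 1L) pick(ord[2L]) else NULL
  c(best, list(runner_up = runner, constraint = constraint,
               measured_kda = measured_kda,
               uncertainty_kda = uncertainty_kda))
}

#' Construct a plaque-count table
#'
#' @param condition character vector of condition labels.
#' @param dilution_factor numeric vector of dilution factors (>= 1).
#' @param plaque_count integer vector of plaque counts (>= 0).
#' @param volume_ml plated volume in ml.
#' @return data.frame with the validated columns.
#' @export
plaqueTable <- function(condition, dilution_factor, plaque_count,
                        volume_ml) {
  .assert(all(plaque_count >= 0), "plaque counts must be >= 0")
  .assert(all(dilution_factor >= 1), "dilution factors must be >= 1")
  data.frame(condition = condition, dilution_factor = dilution_factor,
             plaque_count = plaque_count, volume_ml = volume_ml,
             stringsAsFactors = FALSE)
}

#' Phage titer from a plaque-count table
#'
#' Mean over countable rows (plaque counts within
#' \code{countable_range}, the standard counting window) of
#' \code{count * dilution_factor / volume}.  When no row is countable the
#' result is an explicit below-detection record carrying the detection
#' limit \code{1 * max(dilution) / volume} rather than an error.
#'
#' @param table a \code{\link{plaqueTable}} data.frame.
#' @param condition condition label to titer.
#' @param countable_range counts considered reliable (default c(3, 300)).
#' @return list with \code{pfu_per_ml} (NA when below detection),
#'   \code{below_detection}, \code{detection_limit}, \code{n_rows_used},
#'   \code{flag_discordant} (TRUE when countable dilutions disagree by
#'   more than 2-fold).
#' @export
titer <- function(table, condition, countable_range = c(3, 300)) {
  rows <- table[table$condition == condition, , drop = FALSE]
  .assert(nrow(rows) >= 1L, "no rows for condition '%s'", condition)
  est <- rows$plaque_count * rows$dilution_factor / rows$volume_ml
  ok <- rows$plaque_count >= countable_range[1L] &
        rows$plaque_count <= countable_range[2L]
  if (!any(ok)) {
    lim <- max(rows$dilution_factor / rows$volume_ml)
    return(list(pfu_per_ml = NA_real_, below_detection = TRUE,
                detection_limit = lim, n_rows_used = 0L,
                flag_discordant = FALSE))
  }
  used <- est[ok]
  list(pfu_per_ml = mean(used), below_detection = FALSE,
       detection_limit = NA_real_, n_rows_used = sum(ok),
       flag_discordant = length(used) > 1L &&
         max(used) / min(used) > 2)
}

#' Efficiency of plaquing (EOP)
#'
#' EOP is the titer on the test strain divided by the titer on the control
#' strain.  When the test titer is below detection the EOP is reported as
#' an upper bound (detection limit over control titer); an undetectable
#' control is an error since the ratio is then undefined.
#'
#' @param test,control \code{\link{plaqueTable}} data.frames.
#' @param condition condition label present in both tables.
#' @param countable_range passed to \code{\link{titer}}.
#' @return list with \code{eop}, \code{is_upper_bound}, \code{test_titer},
#'   \code{control_titer}.
#' @export
efficiencyOfPlaquing <- function(test, control, condition,
                                 countable_range = c(3, 300)) {
  tc <- titer(control, condition, countable_range)
  .assert(!tc$below_detection, "control titer below detection: EOP undefined")
  tt <- titer(test, condition, countable_range)
  if (tt$below_detection)
    list(eop = tt$detection_limit / tc$pfu_per_ml, is_upper_bound = TRUE,
         test_titer = NA_real_, control_titer = tc$pfu_per_ml)
  else
    list(eop = tt$pfu_per_ml / tc$pfu_per_ml, is_upper_bound = FALSE,
         test_titer = tt$pfu_per_ml, control_titer = tc$pfu_per_ml)
}

#' One-step growth burst size
#'
#' Burst size is the mean plateau phage concentration of a one-step growth
#' curve divided by the concentration of infected centers, optionally
#' after subtracting a free-phage baseline.
#'
#' @param curve data.frame with columns \code{time_min} and
#'   \code{pfu_per_ml}.
#' @param infected_centers_per_ml infected-center concentration (> 0).
#' @param plateau_from_min earliest time considered plateau (needs >= 2
#'   curve points at or after it).
#' @param baseline_pfu_per_ml optional free-phage baseline subtracted from
#'   the plateau mean (default 0).
#' @return list with \code{burst_size}, \code{plateau_mean},
#'   \code{n_plateau_points}.
#' @export
burstSize <- function(curve, infected_centers_per_ml, plateau_from_min,
                      baseline_pfu_per_ml = 0) {
  .assert(infected_centers_per_ml > 0,
          "infected centers must be > 0")
  sel <- curve$time_min >= plateau_from_min
  .assert(sum(sel) >= 2L,
          "need at least two plateau points at time >= %s",
          format(plateau_from_min))
  plateau <- mean(curve$pfu_per_ml[sel])
  list(burst_size = (plateau - baseline_pfu_per_ml) /
         infected_centers_per_ml,
       plateau_mean = plateau, n_plateau_points = sum(sel))
}
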