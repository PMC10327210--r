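# Structural descriptors for small helical proteins: numerical
# solvent-accessible surface area (Shrake-Rupley sphere sampling), buried
# dimer-interface area, and Calpha-geometry helix assignment.  The Rpn
# small C-terminal proteins fold as compact three-alpha-helix bundles that
# dimerize through their long first helices.

#' Read a protein structure from PDB
#'
#' Loads ATOM records via \code{bio3d}; waters and heteroatoms are excluded
#' by default.  Alternate locations are resolved by highest occupancy, then
#' altloc 'A'.  Radii are assigned from the package element table
#' (C 1.70, N 1.55, O 1.52, S 1.80 Angstrom).
#'
#' @param path path to a PDB file.
#' @param keep_hetero keep HETATM records (default FALSE; water is always
#'   dropped).
#' @return A \linkS4class{ProteinStructure}.
#' @export
readPdb <- function(path, keep_hetero = FALSE) {
  .assert(file.exists(path), "file not found: %s", path)
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  .assert(nrow(at) > 0L, "no ATOM records in %s", path)
  if (!keep_hetero) at <- at[at$type == "ATOM", , drop = FALSE]
  at <- at[!at$resid %in% c("HOH", "WAT"), , drop = FALSE]
  .assert(nrow(at) > 0L, "no protein ATOM records in %s", path)
  # altloc: keep highest occupancy, ties broken toward 'A'
  alt <- at$alt; alt[is.na(alt)] <- ""
  occ <- at$o; occ[is.na(occ)] <- 1
  key <- paste(at$chain, at$resno, at$elety)
  ord <- order(key, -occ, alt != "A", alt)
  at <- at[ord, , drop = FALSE]
  at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  at <- at[order(match(at$chain, unique(at$chain)), at$resno), ,
           drop = FALSE]
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)) || all(elem == ""))
    elem <- substr(trimws(at$elety), 1L, 1L)
  ProteinStructure(data.frame(
    chain = at$chain, resno = at$resno, resname = at$resid,
    atom = at$elety, element = toupper(trimws(elem)),
    x = at$x, y = at$y, z = at$z, stringsAsFactors = FALSE))
}

#' Write a ProteinStructure to PDB
#'
#' Coordinates are written with 3 decimals (standard PDB precision), so a
#' write/read round trip preserves them to 3 decimals.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writePdb <- function(structure, path) {
  at <- atoms(structure)
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(nrow(at)),
    ifelse(nchar(at$atom) < 4L, paste0(" ", at$atom), at$atom),
    at$resname, at$chain, at$resno, at$x, at$y, at$z, at$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

# deterministic, near-uniform points on the unit sphere (Fibonacci lattice)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Per-atom solvent-accessible surface area (Shrake-Rupley)
#'
#' Numerical SASA by uniform sphere-point sampling: each atom is expanded
#' by the probe radius, \code{n_points} points are placed on the expanded
#' sphere, and points falling inside any neighboring expanded sphere are
#' occluded.  The per-atom area is the unoccluded fraction times the full
#' sphere area.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param probe_radius solvent probe radius in Angstrom (default 1.4,
#'   water).
#' @param n_points sample points per atom (default 960; at least 92 for
#'   acceptable accuracy).
#' @param chains restrict the calculation to these chains (default: all).
#' @return numeric vector of per-atom areas (Angstrom^2) for the selected
#'   atoms, with \code{sum()} giving the total SASA.
#' @export
sasa <- function(structure, probe_radius = 1.4, n_points = 960L,
                 chains = NULL) {
  .assert(n_points >= 92L, "n_points below accuracy floor of 92")
  at <- atoms(structure)
  if (!is.null(chains)) at <- at[at$chain %in% chains, , drop = FALSE]
  n <- nrow(at)
  if (!n) return(numeric(0))
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rext <- at$radius + probe_radius
  pts <- .sphere_points(n_points)
  areas <- numeric(n)
  maxr <- max(rext)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(xyz) - xyz[i, ])^2))
    nb <- which(di < rext[i] + maxr & seq_len(n) != i)
    nb <- nb[di[nb] < rext[i] + rext[nb]]
    p <- pts * rext[i]
    p <- sweep(p, 2L, xyz[i, ], "+")
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      d2 <- (p[free, 1L] - xyz[j, 1L])^2 + (p[free, 2L] - xyz[j, 2L])^2 +
            (p[free, 3L] - xyz[j, 3L])^2
      free[free] <- d2 >= rext[j]^2
    }
    areas[i] <- 4 * pi * rext[i]^2 * sum(free) / n_points
  }
  areas
}

#' Buried interface area between two chains
#'
#' Total buried solvent-accessible surface area, the sum over both sides:
#' \code{SASA(A alone) + SASA(B alone) - SASA(A and B together)}, clamped
#' at 0 against sampling noise.  The per-side (half) convention is
#' available via \code{per_side}.
#'
#' @param structure a \linkS4class{ProteinStructure} containing both
#'   chains.
#' @param chain_a,chain_b chain identifiers.
#' @param per_side report half of the total (per-monomer convention).
#' @param probe_radius,n_points passed to \code{\link{sasa}}.
#' @return numeric(1), buried area in Angstrom^2.
#' @export
buriedInterfaceArea <- function(structure, chain_a, chain_b,
                                per_side = FALSE, probe_radius = 1.4,
                                n_points = 960L) {
  at <- atoms(structure)
  .assert(chain_a %in% at$chain, "chain '%s' missing", chain_a)
  .assert(chain_b %in% at$chain, "chain '%s' missing", chain_b)
  sub <- function(chs) ProteinStructure(
    at[at$chain %in% chs, , drop = FALSE])
  a <- sum(sasa(sub(chain_a), probe_radius, n_points))
  b <- sum(sasa(sub(chain_b), probe_radius, n_points))
  ab <- sum(sasa(sub(c(chain_a, chain_b)), probe_radius, n_points))
  buried <- max(0, a + b - ab)
  if (per_side) buried / 2 else buried
}

#' Assign alpha-helix segments from Calpha geometry
#'
#' Residue i is helical when d(CA_i, CA_i+3) lies in [4.8, 5.8] Angstrom
#' and d(CA_i, CA_i+4) lies in [5.9, 6.9] Angstrom -- the canonical
#' alpha-helix Calpha spacing.  Residues i..i+4 of each window satisfying
#' the criteria are marked, marked runs are merged across single-residue
#' gaps, and runs of at least \code{min_len} residues are reported as
#' segments (in residue order, per chain).  The assignment uses only
#' Calpha coordinates, so no hydrogen placement is needed.
#'
#' @param structure a \linkS4class{ProteinStructure}.
#' @param min_len minimum segment length in residues (default 4).
#' @return named list (per chain) of data.frames with \code{start_res} and
#'   \code{end_res}; a chain with fewer than 5 Calpha is returned empty.
#' @export
assignHelices <- function(structure, min_len = 4L) {
  at <- atoms(structure)
  ca <- at[at$atom == "CA", , drop = FALSE]
  out <- list()
  for (ch in unique(at$chain)) {
    cc <- ca[ca$chain == ch, , drop = FALSE]
    cc <- cc[order(cc$resno), , drop = FALSE]
    segs <- data.frame(start_res = integer(), end_res = integer())
    n <- nrow(cc)
    if (n >= 5L) {
      xyz <- as.matrix(cc[, c("x", "y", "z")])
      helical <- rep(FALSE, n)
      for (i in seq_len(n - 4L)) {
        # criteria require consecutive residue numbering
        if (cc$resno[i + 4L] - cc$resno[i] != 4L) next
        d13 <- sqrt(sum((xyz[i, ] - xyz[i + 3L, ])^2))
        d14 <- sqrt(sum((xyz[i, ] - xyz[i + 4L, ])^2))
        if (d13 >= 4.8 && d13 <= 5.8 && d14 >= 5.9 && d14 <= 6.9)
          helical[i:(i + 4L)] <- TRUE
      }
      # merge runs separated by a single non-helical residue
      for (i in 2:(n - 1L))
        if (!helical[i] && helical[i - 1L] && helical[i + 1L])
          helical[i] <- TRUE
      r <- rle(helical)
      ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
      for (k in which(r$values & r$lengths >= min_len))
        segs <- rbind(segs, data.frame(start_res = cc$resno[starts[k]],
                                       end_res = cc$resno[ends[k]]))
    }
    out[[ch]] <- segs
  }
  out
}

# --- toy structure generators -------------------------------------------

# Calpha trace of a canonical alpha-helix along +z: radius 2.3 A, rise
# 1.5 A/residue, 100 degrees/residue (equivalent to backbone dihedrals
# phi = -57, psi = -47)
.helix_ca <- function(n, origin = c(0, 0, 0), dir = c(0, 0, 1),
                      phase = 0) {
  t <- seq_len(n) - 1L
  r <- 2.3; rise <- 1.5; turn <- 100 * pi / 180
  local <- cbind(r * cos(phase + turn * t), r * sin(phase + turn * t),
                 rise * t)
  dir <- dir / sqrt(sum(dir^2))
  # orthonormal frame with third axis = dir
  up <- if (abs(dir[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- up - sum(up * dir) * dir; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(dir[2L] * e1[3L] - dir[3L] * e1[2L],
          dir[3L] * e1[1L] - dir[1L] * e1[3L],
          dir[1L] * e1[2L] - dir[2L] * e1[1L])
  world <- local %*% rbind(e1, e2, dir)
  sweep(world, 2L, origin, "+")
}

.ca_atoms <- function(xyz, chain, first_resno = 1L) {
  data.frame(chain = chain,
             resno = seq_len(nrow(xyz)) + first_resno - 1L,
             resname = "ALA", atom = "CA", element = "C",
             x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
             stringsAsFactors = FALSE)
}

# Calpha trace of one compact three-helix bundle chain: a long first helix
# and two shorter antiparallel helices packed alongside, joined by short
# loops
.bundle_chain_ca <- function(chain, origin = c(0, 0, 0),
                             flip = FALSE, n1 = 22L, n2 = 12L, n3 = 12L) {
  sgn <- if (flip) -1 else 1
  h1 <- .helix_ca(n1, origin = origin, dir = c(0, 0, 1))
  top <- origin[3L] + (n1 - 1L) * 1.5
  h2 <- .helix_ca(n2, origin = c(origin[1L] + sgn * 9.5, origin[2L] + 1.5,
                                 top - 2), dir = c(0, 0, -1))
  h3 <- .helix_ca(n3, origin = c(origin[1L] + sgn * 6.5,
                                 origin[2L] + 9.5,
                                 top - 2 - (n2 - 1L) * 1.5 + 1),
                  dir = c(0, 0, 1))
  loop1 <- .loop_ca(h1[nrow(h1), ], h2[1L, ], 5L)
  loop2 <- .loop_ca(h2[nrow(h2), ], h3[1L, ], 5L)
  xyz <- rbind(h1, loop1, h2, loop2, h3)
  .ca_atoms(xyz, chain)
}

# loop Calphas on a straight line between two anchors: close spacing keeps
# d(i,i+3)/d(i,i+4) outside the helical bands, so loops break segments
.loop_ca <- function(from, to, n) {
  f <- seq_len(n) / (n + 1L)
  outer(f, to - from) + matrix(from, n, 3L, byrow = TRUE)
}

#' Generate a toy structure with known ground truth
#'
#' \describe{
#'   \item{ideal_helix}{a single canonical alpha-helix of \code{n_res}
#'     Calpha (helix radius 2.3 A, rise 1.5 A, 100 deg/residue, the
#'     geometry of backbone dihedrals phi = -57, psi = -47).}
#'   \item{extended_strand}{a straight Calpha trace with 3.8 A spacing
#'     (no helical geometry).}
#'   \item{helix_bundle_dimer}{two three-helix-bundle chains (A, B) whose
#'     long first helices pack against each other -- a synthetic stand-in
#'     for a small antitoxin dimer.}
#'   \item{separated_chains}{two helices placed >= 30 A apart (no
#'     contact).}
#' }
#' Coordinates are a pure function of the arguments; \code{jitter_sd > 0}
#' adds seeded Gaussian coordinate noise.
#'
#' @param kind one of \code{"ideal_helix"}, \code{"extended_strand"},
#'   \code{"helix_bundle_dimer"}, \code{"separated_chains"}.
#' @param n_res residues per chain for the single-helix kinds (>= 6).
#' @param seed RNG seed for coordinate jitter.
#' @param jitter_sd standard deviation of optional coordinate noise
#'   (Angstrom; default 0).
#' @return A \linkS4class{ProteinStructure}.
#' @export
generateToyStructure <- function(kind = c("ideal_helix", "extended_strand",
                                          "helix_bundle_dimer",
                                          "separated_chains"),
                                 n_res = 15L, seed = 1L, jitter_sd = 0) {
  kind <- match.arg(kind)
  .assert(n_res >= 6L, "n_res must be >= 6")
  at <- switch(kind,
    ideal_helix = .ca_atoms(.helix_ca(n_res), "A"),
    extended_strand = .ca_atoms(cbind(0, 0, 3.8 * (seq_len(n_res) - 1L)),
                                "A"),
    helix_bundle_dimer = rbind(
      .bundle_chain_ca("A", origin = c(0, 0, 0)),
      .bundle_chain_ca("B", origin = c(-9.0, -1.0, 0), flip = TRUE)),
    separated_chains = rbind(
      .ca_atoms(.helix_ca(n_res), "A"),
      .ca_atoms(.helix_ca(n_res, origin = c(40, 0, 0)), "B")))
  if (jitter_sd > 0)
    at[, c("x", "y", "z")] <- .with_seed(seed,
      at[, c("x", "y", "z")] +
        matrix(stats::rnorm(3L * nrow(at), sd = jitter_sd), ncol = 3L))
  ProteinStructure(at)
}
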