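test_that("PDB reading handles minimal files and altloc selection", {
  f <- withr::local_tempfile(lines = c(
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "END"))
  s <- readPdb(f)
  expect_equal(nrow(atoms(s)), 1L)
  expect_equal(atoms(s)$chain, "A")
  expect_equal(atoms(s)$radius, 1.70)

  # altloc A/B at occupancies 0.6/0.4: A kept
  f2 <- withr::local_tempfile(lines = c(
    "ATOM      1  CA AALA A   1       0.000   0.000   0.000  0.60  0.00           C",
    "ATOM      2  CA BALA A   1       9.000   0.000   0.000  0.40  0.00           C",
    "END"))
  s2 <- readPdb(f2)
  expect_equal(nrow(atoms(s2)), 1L)
  expect_equal(atoms(s2)$x, 0)

  f3 <- withr::local_tempfile(lines = "END")
  expect_error(readPdb(f3))
})

test_that("PDB write/read round-trips coordinates to 3 decimals", {
  d <- generateToyStructure("helix_bundle_dimer")
  f <- withr::local_tempfile()
  writePdb(d, f)
  back <- readPdb(f)
  expect_equal(nrow(atoms(back)), nrow(atoms(d)))
  expect_equal(atoms(back)$x, round(atoms(d)$x, 3L))
  expect_equal(atoms(back)$y, round(atoms(d)$y, 3L))
  expect_equal(atoms(back)$z, round(atoms(d)$z, 3L))
  expect_equal(atoms(back)$chain, atoms(d)$chain)
})

.single_atom <- function(x = 0, y = 0, z = 0, chain = "A")
  data.frame(chain = chain, resno = 1L, resname = "ALA", atom = "CA",
             element = "C", x = x, y = y, z = z, stringsAsFactors = FALSE)

test_that("SASA matches the closed form for isolated spheres", {
  s1 <- ProteinStructure(.single_atom())
  got <- sum(sasa(s1))
  want <- 4 * pi * (1.70 + 1.40)^2          # 120.76 A^2
  expect_lt(abs(got - want) / want, 0.01)

  # two atoms far apart: total is the sum of isolated areas
  s2 <- ProteinStructure(rbind(.single_atom(), .single_atom(x = 100)))
  expect_equal(sum(sasa(s2)), 2 * got, tolerance = 1e-9)

  expect_error(sasa(s1, n_points = 50L), "accuracy floor")
})

test_that("SASA converges and is rigid-motion invariant", {
  d <- generateToyStructure("ideal_helix", n_res = 25L)
  a1 <- sum(sasa(d, n_points = 480L))
  a2 <- sum(sasa(d, n_points = 960L))
  expect_lt(abs(a1 - a2) / a2, 0.005)

  # rotate + translate
  at <- atoms(d)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3L)
  xyz <- as.matrix(at[, c("x", "y", "z")]) %*% R
  at$x <- xyz[, 1L] + 13.7; at$y <- xyz[, 2L] - 4.2; at$z <- xyz[, 3L] + 8
  a3 <- sum(sasa(ProteinStructure(at), n_points = 960L))
  expect_lt(abs(a3 - a2) / a2, 0.005)
})

test_that("buried area between two spheres matches the spherical-cap form", {
  # two carbon 'chains' 4 A apart; expanded radii R = 3.1 each
  s <- ProteinStructure(rbind(.single_atom(chain = "A"),
                              .single_atom(x = 4, chain = "B")))
  got <- buriedInterfaceArea(s, "A", "B", n_points = 1920L)
  R <- 3.1; d <- 4
  h <- R - d / 2                             # equal spheres
  want <- 2 * (2 * pi * R * h)               # cap on each sphere
  expect_lt(abs(got - want) / want, 0.02)

  # symmetry in the chain arguments
  expect_equal(buriedInterfaceArea(s, "B", "A", n_points = 1920L), got,
               tolerance = 1e-9)
})

test_that("separated chains bury no interface area", {
  sep <- generateToyStructure("separated_chains", n_res = 12L)
  expect_equal(buriedInterfaceArea(sep, "A", "B", n_points = 480L), 0)
})

test_that("helix assignment recovers constructed geometry", {
  h <- assignHelices(generateToyStructure("ideal_helix", n_res = 15L))
  expect_equal(nrow(h$A), 1L)
  expect_gte(h$A$end_res - h$A$start_res + 1L, 12L)

  s <- assignHelices(generateToyStructure("extended_strand", n_res = 15L))
  expect_equal(nrow(s$A), 0L)

  d <- assignHelices(generateToyStructure("helix_bundle_dimer"))
  expect_equal(nrow(d$A), 3L)
  expect_equal(nrow(d$B), 3L)
})

test_that("helix assignment is invariant to residue renumbering", {
  d <- generateToyStructure("helix_bundle_dimer")
  at <- atoms(d)
  at$resno <- at$resno + 100L
  h1 <- assignHelices(d)
  h2 <- assignHelices(ProteinStructure(at))
  expect_equal(h2$A$start_res, h1$A$start_res + 100L)
  expect_equal(h2$A$end_res, h1$A$end_res + 100L)
})
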