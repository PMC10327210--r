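test_that("stoichiometry inference reproduces the SEC-MALS calls", {
  # small antitoxin: 10.2 kDa measured, 5.4 kDa subunit -> dimer
  r <- inferStoichiometry(10.2, 5.4, "single_species",
                          uncertainty_kda = 0.2)
  expect_equal(r$composition, 2L)
  expect_equal(r$theoretical_kda, 10.8)
  expect_equal(r$residual_kda, 0.6, tolerance = 1e-9)

  # toxin-antitoxin complex: 74.1 kDa, subunits 33.3 + 5.4, equimolar
  # constraint -> 2+2 tetramer
  r2 <- inferStoichiometry(74.1, c(33.3, 5.4), "equimolar_pair",
                           uncertainty_kda = 0.5)
  expect_equal(r2$composition, c(2L, 2L))
  expect_equal(r2$theoretical_kda, 77.4)

  # exact match: single subunit, zero residual
  r3 <- inferStoichiometry(5.4, 5.4, "single_species")
  expect_equal(r3$composition, 1L)
  expect_equal(r3$residual_kda, 0)

  expect_error(inferStoichiometry(10, numeric(0), "single_species"),
               "empty")
})

test_that("unconstrained pair fitting prefers a 2:1 composition", {
  # documents why the equimolar constraint is needed: the nearest-mass
  # composition for 74.1 kDa is 2 L + 1 S (72.0, residual 2.1), not 2+2
  r <- inferStoichiometry(74.1, c(33.3, 5.4), "free_pair")
  expect_equal(r$composition, c(2L, 1L))
  expect_equal(r$residual_kda, 2.1, tolerance = 1e-9)
  eq <- inferStoichiometry(74.1, c(33.3, 5.4), "equimolar_pair")
  expect_gt(eq$residual_kda, r$residual_kda)
})

test_that("the best composition beats every grid alternative", {
  set.seed(701)
  for (i in 1:20) {
    m1 <- runif(1, 5, 40); m2 <- runif(1, 3, 20)
    meas <- runif(1, 10, 150)
    r <- inferStoichiometry(meas, c(m1, m2), "free_pair")
    grid <- expand.grid(0:8, 0:8)
    grid <- grid[rowSums(grid) >= 1, ]
    resids <- abs(meas - as.matrix(grid) %*% c(m1, m2))
    expect_equal(r$residual_kda, min(resids), tolerance = 1e-9)
  }
})

test_that("titer averages countable rows and flags discordance", {
  tb <- plaqueTable("t", 1e6, 100L, 0.1)
  expect_equal(titer(tb, "t")$pfu_per_ml, 1e9)

  # zero plaques everywhere: below detection with the declared bound
  tb0 <- plaqueTable(rep("t", 2L), c(1e2, 1e4), c(0L, 0L), 0.1)
  r0 <- titer(tb0, "t")
  expect_true(r0$below_detection)
  expect_equal(r0$detection_limit, 1e4 / 0.1)

  # two countable dilutions agreeing within 2x: clean mean
  tb2 <- plaqueTable(rep("t", 2L), c(1e6, 1e7), c(120L, 13L), 0.1)
  r2 <- titer(tb2, "t")
  expect_equal(r2$pfu_per_ml, mean(c(120 * 1e6, 13 * 1e7)) / 0.1)
  expect_false(r2$flag_discordant)

  # row order does not matter
  expect_equal(titer(tb2[2:1, ], "t")$pfu_per_ml, r2$pfu_per_ml)
  expect_error(titer(tb2, "missing"), "no rows")
})

test_that("EOP is the titer ratio, scale-invariant, and bounded", {
  ctrl <- plaqueTable("p", 1e6, 100L, 0.1)
  tst <- plaqueTable("p", 1e6, 10L, 0.1)
  r <- efficiencyOfPlaquing(tst, ctrl, "p")
  expect_equal(r$eop, 0.1)
  expect_false(r$is_upper_bound)

  same <- efficiencyOfPlaquing(ctrl, ctrl, "p")
  expect_equal(same$eop, 1.0)

  # scale invariance: multiplying all counts by c leaves EOP unchanged
  ctrl3 <- plaqueTable("p", 1e6, 300L, 0.1)
  tst3 <- plaqueTable("p", 1e6, 30L, 0.1)
  expect_equal(efficiencyOfPlaquing(tst3, ctrl3, "p")$eop, 0.1)

  # undetectable test phage: upper bound
  none <- plaqueTable("p", 1e6, 0L, 0.1)
  rb <- efficiencyOfPlaquing(none, ctrl, "p")
  expect_true(rb$is_upper_bound)
  expect_equal(rb$eop, (1e6 / 0.1) / 1e9)
  expect_error(efficiencyOfPlaquing(ctrl, none, "p"), "undefined")
})

test_that("burst size divides the plateau by infected centers", {
  curve <- data.frame(time_min = c(0, 10, 20, 30, 40, 60),
                      pfu_per_ml = c(100, 120, 800, 4600, 5100, 4900))
  r <- burstSize(curve, infected_centers_per_ml = 100,
                 plateau_from_min = 30)
  expect_equal(r$burst_size, mean(c(4600, 5100, 4900)) / 100)
  expect_equal(r$n_plateau_points, 3L)

  # flat curve equal to the centers: burst size 1
  flat <- data.frame(time_min = c(0, 30, 60), pfu_per_ml = rep(100, 3L))
  expect_equal(burstSize(flat, 100, 0)$burst_size, 1.0)

  # the plateau window selects exactly the trailing points
  r2 <- burstSize(curve, 100, plateau_from_min = 40)
  expect_equal(r2$n_plateau_points, 2L)
  expect_equal(r2$burst_size, mean(c(5100, 4900)) / 100)

  expect_error(burstSize(curve, 0, 30), "> 0")
  expect_error(burstSize(curve, 100, 61), "plateau")
})
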