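test_that("constants are positive and mutually consistent", {
  k <- fc_constants()
  expect_gt(k$kT_pN_nm, 0)
  expect_gt(k$kT_kcal_mol, 0)
  expect_gt(k$A_prefactor, 0)
  # pN nm -> kcal/mol through Avogadro agrees within 1%
  expect_equal(
    k$kT_pN_nm * 1e-21 * 6.02214076e23 / 4184, k$kT_kcal_mol,
    tolerance = 0.01
  )
  expect_error(fc_constants(kT_pN_nm = 5), "inconsistent")
})

test_that("deprotonated fraction follows the Henderson-Hasselbalch form", {
  expect_identical(deprotonated_fraction(9, 9), 0.5)
  expect_equal(deprotonated_fraction(9, 7.5), 1 / (1 + 10^1.5), tolerance = 1e-12)
  expect_gte(deprotonated_fraction(7, 12), 0.99999)
  expect_error(deprotonated_fraction(NA, 7), "finite")
  expect_error(deprotonated_fraction(8, Inf), "finite")
  # logistic symmetry: swapping pKa and pH complements the fraction
  for (pka in c(5.5, 8.3, 11)) {
    for (ph in c(4, 7.5, 12)) {
      expect_equal(
        deprotonated_fraction(pka, ph) + deprotonated_fraction(ph, pka), 1,
        tolerance = 1e-12
      )
    }
  }
})

test_that("bell_rate follows the Bell/Arrhenius law", {
  cpd <- list(
    name = "unit", pKa = 9, pH = 9, total_concentration_M = 2, # [S-] = 1 M
    dG_barrier_kT = 10.6, dx_A = 0.35, dG0_kcal_mol = 0
  )
  expect_equal(bell_rate(0, cpd), 1e7 * exp(-10.6), tolerance = 1e-9)
  expect_equal(
    bell_rate(350, cpd),
    1e7 * exp(-10.6) * exp(350 * 0.035 / 4.114),
    tolerance = 1e-9
  )
  expect_equal(
    bell_rate(100, cpd) / bell_rate(0, cpd),
    exp(100 * 0.035 / 4.114),
    tolerance = 1e-12
  )
  expect_error(bell_rate(-5, cpd), ">= 0")

  # strictly increasing in force, log-affine with slope dx/kT over 0-600 pN
  f <- seq(0, 600, by = 25)
  r <- bell_rate(f, cpd)
  expect_true(all(diff(r) > 0))
  slopes <- diff(log(r)) / diff(f)
  expect_equal(slopes, rep(0.035 / 4.114, length(slopes)), tolerance = 1e-10)

  # linear in total concentration at fixed pH
  cpd2 <- cpd
  cpd2$total_concentration_M <- 3 * cpd$total_concentration_M
  expect_equal(bell_rate(200, cpd2), 3 * bell_rate(200, cpd), tolerance = 1e-12)
  # normalized rate is concentration-independent
  expect_equal(
    bell_rate(200, cpd2, normalized = TRUE),
    bell_rate(200, cpd, normalized = TRUE),
    tolerance = 1e-12
  )
})

test_that("barrier_from_rate inverts the zero-force rate", {
  expect_equal(barrier_from_rate(1e7 * exp(-10.6)), 10.6, tolerance = 1e-12)
  expect_equal(barrier_from_rate(82.8), log(1e7 / 82.8), tolerance = 1e-12)
  expect_equal(barrier_from_rate(1e7), 0)
  expect_error(barrier_from_rate(-1), "> 0")
  expect_error(barrier_from_rate(2e7), "invalid extrapolation")

  # round trip with bell_rate at F = 0 is the identity on the barrier
  cpd <- as.list(get_compound("NAC"))
  for (b in c(2, 10.6, 11.7, 20)) {
    cpd$dG_barrier_kT <- b
    expect_equal(
      barrier_from_rate(bell_rate(0, cpd, normalized = TRUE)), b,
      tolerance = 1e-9
    )
  }
})

test_that("equilibrium reformation fraction is a two-state Boltzmann partition", {
  expect_identical(equilibrium_reformation_fraction(0), 0.5)
  expect_equal(
    equilibrium_reformation_fraction(-6.7),
    exp(-6.7 / 0.5925) / (1 + exp(-6.7 / 0.5925)),
    tolerance = 1e-12
  )
  expect_equal(
    equilibrium_reformation_fraction(7.3),
    1 / (1 + exp(-7.3 / 0.5925)),
    tolerance = 1e-12
  )
  expect_error(equilibrium_reformation_fraction(NaN), "finite")
  # antisymmetry
  for (x in c(0.1, 1, 3.3, 7.3, 15)) {
    expect_equal(
      equilibrium_reformation_fraction(x) + equilibrium_reformation_fraction(-x),
      1,
      tolerance = 1e-12
    )
  }
  # monotone increasing
  x <- seq(-10, 10, by = 0.5)
  expect_true(all(diff(equilibrium_reformation_fraction(x)) > 0))
})

test_that("titration_absorbance interpolates between the plateaus", {
  expect_equal(titration_absorbance(8.3, 0.2, 0.8, 8.3), 0.5)
  expect_equal(titration_absorbance(-50, 0.2, 0.8, 8.3), 0.2, tolerance = 1e-12)
  expect_equal(
    titration_absorbance(9.3, 0.1, 0.9, 8.3),
    0.1 + 0.8 / (1 + 10^(-1)),
    tolerance = 1e-12
  )
  expect_error(titration_absorbance(7, 0.9, 0.1, 8.3), "A_max")
})

test_that("three-level landscape is tilted by force and clamped at the wells", {
  cys_me <- get_compound("Cys-ME")
  l0 <- build_landscape(cys_me, 0)
  expect_equal(l0$energy_kT[l0$state == "product"], 7.3 / 0.5925, tolerance = 1e-12)
  expect_equal(
    l0$energy_kT[l0$state == "transition"], cys_me$dG_barrier_kT,
    tolerance = 1e-12
  )
  mesna <- get_compound("mesna")
  expect_equal(
    build_landscape(mesna, 0)$energy_kT[3], -6.7 / 0.5925,
    tolerance = 1e-12
  )
  # transition state never drops below the higher well, even at extreme force
  for (f in c(0, 350, 2000, 5000)) {
    l <- build_landscape(cys_me, f)
    expect_gte(l$energy_kT[2], max(l$energy_kT[c(1, 3)]))
  }
  expect_error(build_landscape(cys_me, -1), ">= 0")
})

test_that("packaged compound table is valid and reloadable from JSON", {
  tbl <- compound_table()
  expect_equal(nrow(tbl), 9)
  expect_true(all(tbl$pKa >= 5 & tbl$pKa <= 12))
  expect_true(all(tbl$dx_A > 0 & tbl$dx_A < 2))
  expect_true(all(tbl$dG_barrier_kT > 0))
  expect_true(all(tbl$total_concentration_M > 0))
  # named lookups and the documented reference values
  expect_equal(get_compound("cys-me")$dG0_kcal_mol, 7.3)
  expect_equal(get_compound("L-cysteine")$dG0_kcal_mol, 0)
  expect_equal(get_compound("NAC")$dG_barrier_kT, 10.6)
  expect_equal(get_compound("glutathione")$dG_barrier_kT, 11.7)
  expect_error(get_compound("dithiothreitol"), "parameter table")
  # re-read through the generic JSON reader
  path <- system.file("extdata", "compounds.json", package = "forcequench")
  expect_equal(read_compound_table(path), tbl)
})
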