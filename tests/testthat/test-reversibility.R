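test_that("quench partition models are normalized probability vectors", {
  for (nm in compound_table()$name) {
    for (m in c("equilibrium2", "boltzmann3", "empirical_linear")) {
      q <- quench_partition(nm, model = m)
      p <- c(q$p_reform, q$p_mixed, q$p_full_reduced)
      expect_true(all(p >= 0 & p <= 1))
      expect_equal(sum(p), 1, tolerance = 1e-12)
    }
  }
  expect_error(quench_partition("mesna", model = "kinetic"), "arg")
})

test_that("two-state partition matches the equilibrium fraction", {
  cpd <- as.list(get_compound("L-cysteine"))
  expect_equal(quench_partition(cpd, model = "equilibrium2")$p_reform, 0.5)
  expect_equal(
    quench_partition("mesna", model = "equilibrium2")$p_reform,
    equilibrium_reformation_fraction(-6.7),
    tolerance = 1e-12
  )
  # antisymmetric and monotone in the reduction free energy
  for (dg in c(0.5, 2, 7.3)) {
    plus <- cpd
    minus <- cpd
    plus$dG0_kcal_mol <- dg
    minus$dG0_kcal_mol <- -dg
    expect_equal(
      quench_partition(plus, model = "equilibrium2")$p_reform +
        quench_partition(minus, model = "equilibrium2")$p_reform,
      1,
      tolerance = 1e-12
    )
  }
})

test_that("three-state Boltzmann has the right limits", {
  cpd <- as.list(get_compound("L-cysteine")) # dG0 = 0, homodimer 0
  q <- quench_partition(cpd, model = "boltzmann3")
  expect_equal(q$p_reform, 1 / 3, tolerance = 1e-12)
  expect_equal(q$p_mixed, 1 / 3, tolerance = 1e-12)

  # pushing the fully reduced state to +infinity recovers the two-state model
  cpd2 <- as.list(get_compound("mesna"))
  q3 <- quench_partition(cpd2,
    dG0_homodimer_kcal_mol = 1e4, model = "boltzmann3"
  )
  q2 <- quench_partition(cpd2, model = "equilibrium2")
  expect_equal(q3$p_reform, q2$p_reform, tolerance = 1e-9)
  expect_equal(q3$p_full_reduced, 0)
})

test_that("empirical linear model clamps to the unit interval", {
  lo <- quench_partition("1-mercapto-2-propanol", model = "empirical_linear")
  expect_equal(lo$p_reform, 0)
  hi <- quench_partition("Cys-ME",
    model = "empirical_linear",
    empirical_coefs = c(slope = 0, intercept = 5)
  )
  expect_equal(hi$p_reform, 1)
})

test_that("optional first-order relaxation interpolates to the equilibrium", {
  slow <- quench_partition("Cys-ME", model = "equilibrium2", k_rev_s = 1e-9)
  expect_lt(slow$p_reform, 1e-6)
  fast <- quench_partition("Cys-ME", model = "equilibrium2", k_rev_s = 100)
  expect_equal(
    fast$p_reform,
    quench_partition("Cys-ME", model = "equilibrium2")$p_reform,
    tolerance = 1e-6
  )
})

test_that("scored reformation fraction tracks the generative probability", {
  # every rupture replayed: fraction exactly one
  probe <- tibble::tibble(
    time_s = 14 + 1:6, size_nm = 10, event_class = "reform_probe",
    segment_label = "probe", segment_id = 5L
  )
  es <- make_eventset(extra_events = probe)
  attr(es, "segment_summary") <- tibble::tibble(
    segment_id = 1:5, label = c("unfold", "test", "quench", "unfold", "probe"),
    force_pN = c(150, 350, 0, 150, 350),
    t_start = c(0, 0.5, 5.5, 13.5, 14), t_end = c(0.5, 5.5, 13.5, 14, 20),
    final_extension_nm = c(90, 150, 0, 140, 150)
  )
  r <- score_reformation(list(es), n_bootstrap = 10, seed = 1)
  expect_equal(r$fraction_reformed, 1)
  expect_equal(r$fraction_sd, 0)
  expect_error(score_reformation(list(), n_bootstrap = 10), "no accepted")

  # binomial oracle: forced p = 0.3 through the full pipeline
  cfg <- sim_config(sample_rate_Hz = 250)
  out <- run_reformation_cohort("mesna",
    n_traces = 60, config = cfg,
    seed = 12, n_bootstrap = 100, p_reform_override = 0.3
  )
  n_bonds <- 8 * out$n_accepted
  expect_equal(
    out$result$fraction_reformed, 0.3,
    tolerance = 3 * sqrt(0.3 * 0.7 / n_bonds) / 0.3
  )
})

test_that("reformation extent correlates linearly with pKa", {
  affine <- tibble::tibble(fraction_reformed = seq(0.9, 0.1, length.out = 5))
  res <- reformation_pka_correlation(affine, pKas = seq(7, 10, length.out = 5))
  expect_equal(res$r_squared, 1, tolerance = 1e-12)

  flat <- tibble::tibble(fraction_reformed = rep(0.4, 5))
  expect_equal(
    reformation_pka_correlation(flat, pKas = seq(7, 10, length.out = 5))$slope,
    0,
    tolerance = 1e-12
  )
  expect_error(
    reformation_pka_correlation(affine, pKas = 1:3), "length mismatch"
  )

  # simulated nine-compound screen under the generative linear model
  cfg <- sim_config(sample_rate_Hz = 250)
  tbl <- compound_table()
  res <- purrr::map(seq_len(nrow(tbl)), function(k) {
    run_reformation_cohort(tbl[k, ],
      n_traces = 25, model = "empirical_linear",
      config = cfg, seed = 900 + 40 * k, n_bootstrap = 20
    )$result
  })
  corr <- reformation_pka_correlation(res, tbl$pKa)
  expect_gt(corr$r_squared, 0.8)
  expect_lt(corr$slope, 0)
})
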