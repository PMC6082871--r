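test_that("a noiseless staircase is recovered step for step", {
  tr <- make_staircase(seq(0.2, 1.8, by = 0.4), rep(15, 5))
  ev <- detect_steps(tr)
  expect_equal(nrow(ev), 5)
  expect_true(all(ev$event_class == "unfold"))
  expect_equal(ev$size_nm, rep(15, 5), tolerance = 1e-12)
  expect_true(attr(ev, "accepted"))
})

test_that("a flat trace yields an empty, rejected event set", {
  withr::with_seed(1, {
    tr <- make_staircase(numeric(0), numeric(0), noise_sd = 1)
  })
  ev <- detect_steps(tr)
  expect_equal(nrow(ev), 0)
  expect_false(attr(ev, "accepted"))
  expect_match(attr(ev, "rejection_reason"), "no events")
})

test_that("detection is invariant under a constant extension offset", {
  withr::with_seed(8, {
    tr <- make_staircase(c(0.3, 0.9, 1.5), c(15, 14, 16), noise_sd = 1)
  })
  tr2 <- tr
  tr2$extension_nm <- tr2$extension_nm + 137.5
  e1 <- detect_steps(tr)
  e2 <- detect_steps(tr2)
  expect_equal(e1$time_s, e2$time_s)
  expect_equal(e1$size_nm, e2$size_nm, tolerance = 1e-9)
  expect_identical(e1$event_class, e2$event_class)
})

test_that("malformed time axes are rejected", {
  tr <- make_staircase(0.5, 15)
  bad <- tr
  bad$time_s[10] <- bad$time_s[12]
  expect_error(detect_steps(bad), "increasing|uniform")
  gap <- tr[-(50:60), ]
  expect_error(detect_steps(gap), "uniform")
})

test_that("detector recovers nearly all true events with small size errors", {
  # seeded fixture: 6 unfolding + 6 reduction steps per trace, 1 nm noise
  all_errs <- c()
  for (s in 1:20) {
    withr::with_seed(400 + s, {
      truth <- tibble::tibble(
        time_s = c(seq(0.06, 0.46, by = 0.08), 0.9 + (1:6) * 0.55),
        size_nm = c(rnorm(6, 15, 1), rnorm(6, 10, 1))
      )
      tr <- dplyr::bind_rows(
        make_staircase(truth$time_s[1:6], truth$size_nm[1:6],
          duration = 0.5, label = "unfold", force = 150, noise_sd = 1
        ),
        dplyr::mutate(
          make_staircase(truth$time_s[7:12] - 0.5, truth$size_nm[7:12],
            duration = 4.5, label = "test", force = 350, noise_sd = 1,
            offset = sum(truth$size_nm[1:6])
          ),
          time_s = time_s + 0.5, segment_id = 2L
        )
      )
    })
    all_errs <- c(all_errs, match_events(detect_steps(tr), truth))
  }
  recovered <- !is.na(all_errs) & abs(all_errs) < 1
  expect_gte(mean(recovered), 0.95)

  # simulator cohort: nearly every event located in time, median size error
  # well below the noise floor (sizes of events closer than the feedback
  # settling time are individually less accurate)
  errs <- c()
  for (s in 1:20) {
    tr <- simulate_kinetics_trace(
      "penicillamine", two_pulse_protocol(350, 9),
      seed = 400 + s
    )
    errs <- c(errs, match_events(detect_steps(tr), attr(tr, "true_events")))
  }
  expect_gt(length(errs), 250)
  expect_gte(mean(!is.na(errs)), 0.95)
  expect_lt(median(abs(errs), na.rm = TRUE), 0.5)
})

test_that("noiseless simulation and detection form an end-to-end identity", {
  # slower unfolding over a longer pulse keeps events resolvable at 1 kHz
  cfg <- sim_config(noise_sd_nm = 0, feedback_tau_s = 0, unfold_rate_150pN_s = 4)
  checked <- 0
  for (s in 1:40) {
    tr <- simulate_kinetics_trace(
      "Cys-ME", two_pulse_protocol(350, 10, unfold_duration_s = 1.5),
      config = cfg, seed = 2000 + s
    )
    te <- attr(tr, "true_events")
    # the identity requires events distinguishable at the sampling
    # resolution, away from the pulse boundary, and no cleavage inside the
    # unfolding pulse (whose ~10 nm steps are by design left unclassified)
    if (min(diff(sort(te$time_s))) < 6e-3) next
    if (any(pmin(abs(te$time_s - 1.5), te$time_s) < 6e-3)) next
    if (any(te$segment_label == "unfold" & te$event_class == "reduction")) next
    if (any(te$segment_label == "test" & te$event_class == "unfold")) next
    if (any(te$size_nm[te$event_class == "reduction"] >= 12.5) ||
      any(te$size_nm[te$event_class == "unfold"] < 11 |
        te$size_nm[te$event_class == "unfold"] > 19)) next
    checked <- checked + 1
    ev <- detect_steps(tr)
    expect_equal(nrow(ev), nrow(te))
    expect_equal(sort(ev$size_nm), sort(te$size_nm), tolerance = 1e-9)
    expect_lt(max(abs(sort(ev$time_s) - sort(te$time_s))), 2e-3)
    expect_identical(
      ev$event_class,
      te$event_class[order(te$time_s)]
    )
  }
  expect_gte(checked, 5)
})

test_that("kinetics filter applies the 5-8 event rules", {
  ok <- make_eventset()
  f <- filter_kinetics_trace(ok)
  expect_true(attr(f, "accepted"))
  expect_identical(attr(f, "rejection_reason"), "")

  few_red <- make_eventset(reduce_times = 1:4)
  expect_false(attr(filter_kinetics_trace(few_red), "accepted"))
  expect_match(
    attr(filter_kinetics_trace(few_red), "rejection_reason"),
    "fewer than 5 reduction"
  )

  many_unf <- make_eventset(unfold_times = seq(0.05, 0.45, length.out = 9))
  expect_false(attr(filter_kinetics_trace(many_unf), "accepted"))
  expect_match(
    attr(filter_kinetics_trace(many_unf), "rejection_reason"),
    "more than 8"
  )

  late <- make_eventset(extra_events = tibble::tibble(
    time_s = 2.5, size_nm = 15, event_class = "unfold",
    segment_label = "test", segment_id = 2L
  ))
  expect_false(attr(filter_kinetics_trace(late), "accepted"))
  expect_match(
    attr(filter_kinetics_trace(late), "rejection_reason"),
    "high-force pulse"
  )

  # idempotence: filtering twice changes nothing
  once <- filter_kinetics_trace(few_red)
  expect_identical(
    attributes(filter_kinetics_trace(once))[c("accepted", "rejection_reason")],
    attributes(once)[c("accepted", "rejection_reason")]
  )
})

test_that("reformation filter enforces rupture counts and extension match", {
  tr <- simulate_reformation_trace(
    "mesna", five_pulse_protocol(350, 5),
    seed = 31
  )
  ev <- detect_steps(tr)
  f <- filter_reformation_trace(ev)
  expect_true(is_logical_scalar <- is.logical(attr(f, "accepted")))

  # hand-built cases
  ok <- make_eventset()
  attr(ok, "segment_summary") <- tibble::tibble(
    segment_id = 1:5,
    label = c("unfold", "test", "quench", "unfold", "probe"),
    force_pN = c(150, 350, 0, 150, 350),
    t_start = c(0, 0.5, 5.5, 13.5, 14),
    t_end = c(0.5, 5.5, 13.5, 14, 19),
    final_extension_nm = c(90, 150, 0, 120, 148)
  )
  expect_true(attr(filter_reformation_trace(ok), "accepted"))

  few <- ok[!(ok$event_class == "reduction" & ok$segment_label == "test"), ][1:10, ]
  few2 <- ok
  attr(few2, "segment_summary")$final_extension_nm[5] <- 108 # 42 nm short
  expect_match(
    attr(filter_reformation_trace(few2), "rejection_reason"),
    "extension mismatch"
  )
  no_probe <- make_eventset()
  expect_error(filter_reformation_trace(no_probe), "probe")
})

test_that("compound steps in the test pulse are split into two reductions", {
  tr <- make_staircase(c(0.3, 0.8), c(10, 20),
    duration = 1.5, label = "test", force = 350
  )
  ev <- detect_steps(tr)
  expect_equal(sum(ev$event_class == "reduction"), 3)
  expect_equal(sort(ev$size_nm), c(10, 10, 10), tolerance = 1e-9)
  # a ~15 nm step in the test pulse still reads as late unfolding
  tr2 <- make_staircase(c(0.3, 0.8), c(10, 15),
    duration = 1.5, label = "test", force = 350
  )
  ev2 <- detect_steps(tr2)
  expect_equal(sum(ev2$event_class == "unfold"), 1)
})
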