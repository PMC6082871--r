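#' Full cleavage-kinetics pipeline for one condition
#'
#' Simulates a cohort of two-pulse trajectories for one compound at one test
#' force, runs step detection and the trace-acceptance filters, sums and
#' normalizes the accepted reduction staircases, and fits the reduction rate
#' with bootstrap uncertainty. This is the chain applied per point of the
#' rate-versus-force analysis.
#'
#' @param compound Compound record or name.
#' @param force_pN Test-pulse force.
#' @param n_traces Number of simulated recordings.
#' @param config See [sim_config()].
#' @param seed Root seed; trajectory i uses `seed + i`.
#' @param n_bootstrap Bootstrap resamples for the rate SD.
#' @param test_duration_s Test-pulse length; `NULL` sizes the pulse to about
#'   five expected lifetimes (clamped to 2-30 s).
#' @param constants See [fc_constants()].
#' @return A list with `rate` (an `fc_rate`), `summed` (`fc_summed`),
#'   `accepted` (list of accepted `fc_events`), `n_accepted`, `n_traces`.
#' @export
run_kinetics_cohort <- function(compound, force_pN, n_traces = 100,
                                config = sim_config(), seed = 1L,
                                n_bootstrap = 500, test_duration_s = NULL,
                                constants = fc_constants()) {
  compound <- as_compound(compound)
  dur <- test_duration_s %||% default_test_duration(compound, force_pN, constants)
  protocol <- two_pulse_protocol(force_pN, dur)
  accepted <- list()
  for (i in seq_len(n_traces)) {
    traj <- simulate_kinetics_trace(
      compound, protocol,
      config = config, seed = seed + i, constants = constants
    )
    ev <- filter_kinetics_trace(detect_steps(traj))
    if (is_accepted(ev)) accepted[[length(accepted) + 1]] <- ev
  }
  if (length(accepted) < 2) {
    abort("fewer than two traces passed the acceptance filters")
  }
  rate <- bootstrap_rate(accepted,
    n_bootstrap = n_bootstrap,
    seed = seed, constants = constants
  )
  list(
    rate = rate,
    summed = sum_and_normalize(accepted),
    accepted = accepted,
    n_accepted = length(accepted),
    n_traces = n_traces
  )
}

#' Rate-versus-force series and Bell/Arrhenius fit
#'
#' Runs [run_kinetics_cohort()] at each force of the series (default the
#' 300-500 pN grid in 50 pN increments) and fits the Bell/Arrhenius model to
#' the concentration-normalized rates.
#'
#' @inheritParams run_kinetics_cohort
#' @param forces_pN Test forces in pN.
#' @param n_traces Recordings per force.
#' @return A list with `rates` (tidy tibble, one row per force), `bell`
#'   (an `fc_bellfit`) and `cohorts` (per-force pipeline outputs).
#' @export
run_force_series <- function(compound, forces_pN = seq(300, 500, by = 50),
                             n_traces = 100, config = sim_config(), seed = 1L,
                             n_bootstrap = 200, constants = fc_constants()) {
  compound <- as_compound(compound)
  cohorts <- purrr::imap(setNames(forces_pN, forces_pN), function(f, nm) {
    run_kinetics_cohort(
      compound, as.numeric(f),
      n_traces = n_traces, config = config,
      seed = seed + 10000L * match(f, forces_pN),
      n_bootstrap = n_bootstrap, constants = constants
    )
  })
  rates <- rate_table(purrr::map(cohorts, "rate"))
  list(
    rates = rates,
    bell = fit_bell(rates, constants),
    cohorts = cohorts
  )
}

#' Full reformation pipeline for one compound
#'
#' Simulates five-pulse recordings, detects steps, applies the reformation
#' acceptance filter and scores the pooled reformation fraction with
#' bootstrap SD.
#'
#' @inheritParams run_kinetics_cohort
#' @param model Quench outcome model, see [quench_partition()].
#' @param test_force_pN High-force pulse (default 350 pN).
#' @param test_duration_s First high-force pulse length; defaults to 5 s
#'   (3 s for Cys-ME, whose experiments used a shorter extension).
#' @param quench_duration_s Zero-force quench (default 8 s).
#' @param probe_duration_s Probe pulse length; defaults to the test-pulse
#'   length, mirroring the symmetric five-pulse protocol.
#' @param p_reform_override Optional fixed reformation probability bypassing
#'   the quench model.
#' @return A list with `result` (an `fc_reformation`), `accepted`,
#'   `n_accepted`, `n_traces`.
#' @export
run_reformation_cohort <- function(compound, n_traces = 50,
                                   model = "equilibrium2",
                                   config = sim_config(), seed = 1L,
                                   n_bootstrap = 500,
                                   test_force_pN = 350,
                                   test_duration_s = NULL,
                                   quench_duration_s = 8,
                                   probe_duration_s = NULL,
                                   p_reform_override = NULL,
                                   constants = fc_constants()) {
  compound <- as_compound(compound)
  test_duration_s <- test_duration_s %||%
    if (tolower(compound$name) == "cys-me") 3 else 5
  probe_duration_s <- probe_duration_s %||% test_duration_s
  protocol <- five_pulse_protocol(
    test_force_pN,
    test_duration_s = test_duration_s,
    quench_duration_s = quench_duration_s,
    probe_duration_s = probe_duration_s
  )
  accepted <- list()
  for (i in seq_len(n_traces)) {
    traj <- simulate_reformation_trace(
      compound, protocol,
      config = config,
      reformation_model = model, seed = seed + i,
      p_reform_override = p_reform_override, constants = constants
    )
    ev <- filter_reformation_trace(detect_steps(traj))
    if (is_accepted(ev)) accepted[[length(accepted) + 1]] <- ev
  }
  if (!length(accepted)) abort("no traces passed the reformation filters")
  list(
    result = score_reformation(accepted, n_bootstrap = n_bootstrap, seed = seed),
    accepted = accepted,
    n_accepted = length(accepted),
    n_traces = n_traces
  )
}

#' End-to-end analysis across compounds and forces
#'
#' Convenience wrapper chaining simulation, detection, filtering, kinetics
#' and the Bell fit for a set of compounds, mirroring the full study design:
#' per-compound rate-versus-force series and (optionally) reformation
#' cohorts.
#'
#' @param compounds Character vector of compound names.
#' @param forces_pN Force grid for the kinetics series.
#' @param n_traces Recordings per (compound, force).
#' @param reformation If `TRUE`, also run a reformation cohort per compound.
#' @inheritParams run_kinetics_cohort
#' @return A list with `series` (per-compound [run_force_series()] output)
#'   and `reformation` (per-compound [run_reformation_cohort()] output or
#'   `NULL`).
#' @export
run_full_pipeline <- function(compounds, forces_pN = seq(300, 500, by = 50),
                              n_traces = 50, config = sim_config(), seed = 1L,
                              reformation = FALSE) {
  series <- purrr::imap(
    setNames(compounds, compounds),
    function(cpd, nm) {
      run_force_series(cpd, forces_pN,
        n_traces = n_traces, config = config,
        seed = seed + 1000000L * match(cpd, compounds)
      )
    }
  )
  reform <- if (reformation) {
    purrr::imap(setNames(compounds, compounds), function(cpd, nm) {
      run_reformation_cohort(cpd,
        n_traces = n_traces, config = config,
        seed = seed + 555000L + 1000L * match(cpd, compounds)
      )
    })
  }
  list(series = series, reformation = reform)
}
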