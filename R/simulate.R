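#' Simulator configuration
#'
#' Settings of the stochastic force-clamp trace generator. Defaults emulate
#' the experimental system: an 8-repeat polyprotein whose domains unfold with
#' ~15 nm steps and whose exposed disulfides cleave with ~10 nm steps, sampled
#' at 1 kHz with ~1 nm Gaussian detector noise and a ~2 ms first-order force
#' feedback settling time.
#'
#' @param n_domains Number of tandem domains (8).
#' @param step_unfold_nm Mean unfolding step size in nm (15).
#' @param step_reduce_nm Mean reduction step size in nm (10).
#' @param step_sd_nm SD of individual step sizes in nm (1).
#' @param noise_sd_nm SD of additive Gaussian extension noise in nm (1).
#' @param sample_rate_Hz Sampling frequency (1000).
#' @param feedback_tau_s First-order feedback settling time constant in s
#'   (0.002); also stands in for the instrument's 1 kHz Bessel filtering.
#' @param unfold_rate_150pN_s Per-domain unfolding rate at 150 pN in s^-1
#'   (10); chosen so that typically >= 5 of 8 domains unfold within the 0.5 s
#'   unfolding pulse.
#' @param dx_unfold_A Distance to the unfolding transition state in Angstrom
#'   (2.5), setting the force dependence of the unfolding rate.
#' @param n_traces Default number of trajectories per condition in cohort
#'   generation.
#' @param seed Default RNG seed used when a simulation call does not supply
#'   its own.
#' @return A list of class `fc_sim_config`.
#' @export
sim_config <- function(n_domains = 8,
                       step_unfold_nm = 15,
                       step_reduce_nm = 10,
                       step_sd_nm = 1,
                       noise_sd_nm = 1,
                       sample_rate_Hz = 1000,
                       feedback_tau_s = 0.002,
                       unfold_rate_150pN_s = 10,
                       dx_unfold_A = 2.5,
                       n_traces = 100,
                       seed = 1L) {
  stopifnot(
    n_domains >= 1,
    step_unfold_nm > 0, step_reduce_nm > 0, step_sd_nm >= 0,
    noise_sd_nm >= 0, sample_rate_Hz > 0, feedback_tau_s >= 0,
    unfold_rate_150pN_s > 0, dx_unfold_A > 0, n_traces >= 1
  )
  structure(
    list(
      n_domains = as.integer(n_domains),
      step_unfold_nm = step_unfold_nm,
      step_reduce_nm = step_reduce_nm,
      step_sd_nm = step_sd_nm,
      noise_sd_nm = noise_sd_nm,
      sample_rate_Hz = sample_rate_Hz,
      feedback_tau_s = feedback_tau_s,
      unfold_rate_150pN_s = unfold_rate_150pN_s,
      dx_unfold_A = dx_unfold_A,
      n_traces = as.integer(n_traces),
      seed = as.integer(seed)
    ),
    class = "fc_sim_config"
  )
}

# First event time of a Poisson clock with piecewise-constant rate.
# Vectorised over clocks: `t0` is each clock's start time; `bounds` are the
# n_seg + 1 segment boundary times; `rates` the per-segment hazards.
# Returns Inf where the clock never fires within the protocol.
piecewise_exp_times <- function(t0, bounds, rates) {
  n <- length(t0)
  rem <- stats::rexp(n)
  t_ev <- rep(Inf, n)
  for (j in seq_along(rates)) {
    a <- pmax(t0, bounds[j])
    width <- pmax(0, bounds[j + 1] - a)
    live <- is.infinite(t_ev) & width > 0 & is.finite(t0)
    if (!any(live)) next
    cap <- width * rates[j]
    hit <- live & rates[j] > 0 & rem <= cap
    t_ev[hit] <- a[hit] + rem[hit] / rates[j]
    spent <- live & !hit
    rem[spent] <- rem[spent] - cap[spent]
  }
  t_ev
}

unfold_rate <- function(F_pN, config, constants = fc_constants()) {
  config$unfold_rate_150pN_s *
    exp((F_pN - 150) * a_to_nm(config$dx_unfold_A) / constants$kT_pN_nm)
}

# Render an ideal piecewise-constant extension (jump times/sizes, absolute
# times) on the sampling grid, apply first-order feedback settling, add noise.
render_extension <- function(time_s, jump_t, jump_size, config) {
  x <- rep(0, length(time_s))
  if (length(jump_t)) {
    ord <- order(jump_t)
    lev <- cumsum(jump_size[ord])
    idx <- findInterval(time_s, jump_t[ord])
    x[idx > 0] <- lev[idx[idx > 0]]
  }
  if (config$feedback_tau_s > 0) {
    a <- exp(-1 / (config$sample_rate_Hz * config$feedback_tau_s))
    x <- as.numeric(stats::filter(x * (1 - a), a, method = "recursive"))
  }
  if (config$noise_sd_nm > 0) {
    x <- x + rnorm(length(x), 0, config$noise_sd_nm)
  }
  x
}

new_trajectory <- function(time_s, force_pN, segment_id, segment_label,
                           extension_nm, true_events, protocol, compound,
                           seed, config, extra = list()) {
  out <- tibble(
    time_s = time_s, force_pN = force_pN,
    extension_nm = extension_nm,
    segment_id = segment_id, segment_label = segment_label
  )
  attr(out, "true_events") <- true_events
  attr(out, "protocol") <- protocol
  attr(out, "compound") <- compound
  attr(out, "compound_name") <- compound$name
  attr(out, "seed") <- seed
  attr(out, "config") <- config
  for (nm in names(extra)) attr(out, nm) <- extra[[nm]]
  class(out) <- c("fc_trajectory", class(tibble()))
  out
}

sampling_grid <- function(protocol, config) {
  b <- protocol_bounds(protocol)
  total <- max(b$t_end)
  n <- floor(total * config$sample_rate_Hz)
  time_s <- (seq_len(n) - 0.5) / config$sample_rate_Hz
  seg <- findInterval(time_s, b$t_start)
  list(
    bounds = b, time_s = time_s, segment_id = seg,
    segment_label = b$label[seg], force_pN = b$force_pN[seg]
  )
}

#' Simulate a two-pulse cleavage-kinetics trajectory
#'
#' Draws per-domain unfolding times as exponential waiting times with a
#' force-dependent (Bell) unfolding rate, then per-domain disulfide reduction
#' times as independent exponential clocks started at each domain's unfolding
#' time with rate [bell_rate()] at the instantaneous clamp force. The ideal
#' extension staircase (one ~15 nm step per unfolding, one ~10 nm step per
#' reduction) is passed through the first-order feedback settling filter and
#' Gaussian noise is added. Ground-truth events are retained in the
#' `true_events` attribute for testing; they are not visible to detection.
#'
#' @param compound Compound record or name (see [compound_table()]).
#' @param protocol A two-pulse protocol from [two_pulse_protocol()].
#' @param config Simulator settings, see [sim_config()].
#' @param seed RNG seed for this trajectory; defaults to `config$seed`.
#' @param constants See [fc_constants()].
#' @return A tibble of class `fc_trajectory` with columns `time_s`,
#'   `force_pN`, `extension_nm`, `segment_id`, `segment_label` and
#'   attributes `true_events`, `protocol`, `compound`, `seed`, `config`.
#' @export
simulate_kinetics_trace <- function(compound, protocol, config = sim_config(),
                                    seed = NULL, constants = fc_constants()) {
  compound <- as_compound(compound)
  if (!is_two_pulse(protocol)) {
    abort("`protocol` must be unfold-then-test (see two_pulse_protocol())")
  }
  seed <- as.integer(seed %||% config$seed)
  withr::with_seed(seed, {
    g <- sampling_grid(protocol, config)
    b <- g$bounds
    bounds <- c(b$t_start, max(b$t_end))
    u_rates <- unfold_rate(b$force_pN, config, constants)
    r_rates <- bell_rate(b$force_pN, compound, constants)

    nd <- config$n_domains
    t_unf <- piecewise_exp_times(rep(0, nd), bounds, u_rates)
    t_red <- piecewise_exp_times(t_unf, bounds, r_rates)
    s_unf <- rnorm(nd, config$step_unfold_nm, config$step_sd_nm)
    s_red <- rnorm(nd, config$step_reduce_nm, config$step_sd_nm)

    total <- max(b$t_end)
    ev <- bind_rows(
      tibble(
        time_s = t_unf, size_nm = s_unf, event_class = "unfold",
        domain = seq_len(nd)
      ),
      tibble(
        time_s = t_red, size_nm = s_red, event_class = "reduction",
        domain = seq_len(nd)
      )
    )
    ev <- ev[is.finite(ev$time_s) & ev$time_s < total, ]
    ev <- ev[order(ev$time_s), ]
    ev$segment_label <- b$label[findInterval(ev$time_s, b$t_start)]

    x <- render_extension(g$time_s, ev$time_s, ev$size_nm, config)
    new_trajectory(
      g$time_s, g$force_pN, g$segment_id, g$segment_label, x,
      ev, protocol, compound, seed, config
    )
  })
}

#' Simulate a five-pulse reformation trajectory
#'
#' The first two pulses replay the cleavage-kinetics assay. During the
#' zero-force quench the protein collapses (extension rendered as ~0 plus
#' noise) and every cleaved disulfide independently resolves to one of three
#' outcomes according to the chosen quench model (see [quench_partition()]):
#' reformed native bond, retained mixed disulfide, or full reduction by
#' solution thiol. All unfolded domains are assumed to refold within the 8 s
#' quench; the outcome bookkeeping is carried in the `quench_outcomes`
#' attribute. In the second unfolding pulse refolded domains unfold again
#' (reformed/intact bonds give ~15 nm steps, domains without a disulfide
#' extend fully at the pulse onset within the feedback settling time), and
#' during the probe pulse only reformed bonds can be re-cleaved, producing
#' ~10 nm steps of ground-truth class `"reform_probe"`.
#'
#' @inheritParams simulate_kinetics_trace
#' @param protocol A five-pulse protocol from [five_pulse_protocol()].
#' @param reformation_model One of `"equilibrium2"`, `"boltzmann3"`,
#'   `"empirical_linear"`; passed to [quench_partition()].
#' @param p_reform_override Optional probability in `[0, 1]` that bypasses the
#'   quench model (used for calibration checks).
#' @return An `fc_trajectory` with the additional `quench_outcomes`
#'   attribute (tibble with one row per domain).
#' @export
simulate_reformation_trace <- function(compound, protocol,
                                       config = sim_config(),
                                       reformation_model = "equilibrium2",
                                       seed = NULL,
                                       p_reform_override = NULL,
                                       constants = fc_constants()) {
  compound <- as_compound(compound)
  if (!is_five_pulse(protocol)) {
    abort(paste0(
      "`protocol` must be the five-pulse reformation protocol with a ",
      "zero-force quench (see five_pulse_protocol())"
    ))
  }
  seed <- as.integer(seed %||% config$seed)
  withr::with_seed(seed, {
    g <- sampling_grid(protocol, config)
    b <- g$bounds
    nd <- config$n_domains
    quench_start <- b$t_start[3]
    quench_end <- b$t_end[3]
    total <- max(b$t_end)

    # phase 1-2: unfolding and cleavage clocks run up to the quench
    bounds12 <- c(b$t_start[1:2], quench_start)
    u12 <- unfold_rate(b$force_pN[1:2], config, constants)
    r12 <- bell_rate(b$force_pN[1:2], compound, constants)
    t_unf1 <- piecewise_exp_times(rep(0, nd), bounds12, u12)
    t_red1 <- piecewise_exp_times(t_unf1, bounds12, r12)
    s_unf <- rnorm(nd, config$step_unfold_nm, config$step_sd_nm)
    s_red <- rnorm(nd, config$step_reduce_nm, config$step_sd_nm)
    ruptured <- is.finite(t_red1)

    # quench outcome per cleaved bond
    if (is.null(p_reform_override)) {
      q <- quench_partition(compound,
        quench_time_s = protocol$duration_s[3],
        model = reformation_model, constants = constants
      )
      probs <- c(q$p_reform, q$p_mixed, q$p_full_reduced)
    } else {
      stopifnot(p_reform_override >= 0, p_reform_override <= 1)
      probs <- c(p_reform_override, 1 - p_reform_override, 0)
    }
    outcome <- rep("intact", nd)
    n_rup <- sum(ruptured)
    if (n_rup > 0) {
      outcome[ruptured] <- sample(
        c("reformed", "mixed", "full_reduced"),
        n_rup, replace = TRUE, prob = probs
      )
    }
    reformed <- outcome == "reformed"

    # phase 4-5: refolded domains with a disulfide (intact or reformed)
    # unfold again; reformed bonds can be re-cleaved in the probe pulse
    bounds45 <- c(b$t_start[4:5], total)
    u45 <- unfold_rate(b$force_pN[4:5], config, constants)
    r45 <- bell_rate(b$force_pN[4:5], compound, constants)
    has_bond <- reformed | outcome == "intact"
    t0_unf2 <- ifelse(has_bond, quench_end, Inf)
    t_unf2 <- piecewise_exp_times(t0_unf2, bounds45, u45)
    # only domains with a cleavable bond exposed by the second unfolding
    t0_red2 <- ifelse(is.finite(t_unf2) & has_bond, t_unf2, Inf)
    t_red2 <- piecewise_exp_times(t0_red2, bounds45, r45)
    s_red2 <- rnorm(nd, config$step_reduce_nm, config$step_sd_nm)

    dom <- seq_len(nd)
    ev <- bind_rows(
      tibble(time_s = t_unf1, size_nm = s_unf, event_class = "unfold", domain = dom),
      tibble(time_s = t_red1, size_nm = s_red, event_class = "reduction", domain = dom),
      tibble(time_s = t_unf2, size_nm = s_unf, event_class = "unfold", domain = dom),
      tibble(
        time_s = t_red2, size_nm = s_red2,
        event_class = ifelse(reformed, "reform_probe", "reduction"),
        domain = dom
      )
    )
    ev <- ev[is.finite(ev$time_s) & ev$time_s < total, ]
    ev <- ev[order(ev$time_s), ]
    ev$segment_label <- b$label[findInterval(ev$time_s, b$t_start)]

    # pseudo-jumps (not events): collapse at quench onset, and instant
    # re-extension of unstructured (bond-less) domains at the second
    # unfolding pulse onset
    x_before_quench <- sum(s_unf[is.finite(t_unf1) & t_unf1 < quench_start]) +
      sum(s_red[is.finite(t_red1)])
    bondless <- ruptured & !reformed
    restore <- sum((s_unf + s_red)[bondless])
    jump_t <- c(ev$time_s, quench_start, quench_end)
    jump_s <- c(ev$size_nm, -x_before_quench, restore)

    x <- render_extension(g$time_s, jump_t, jump_s, config)
    new_trajectory(
      g$time_s, g$force_pN, g$segment_id, g$segment_label, x,
      ev, protocol, compound, seed, config,
      extra = list(quench_outcomes = tibble(
        domain = dom, ruptured = ruptured, outcome = outcome
      ))
    )
  })
}

#' Generate a seeded cohort of two-pulse trajectories
#'
#' Expands the (compound, force, replicate) grid, derives one child seed per
#' trajectory from the root seed by a position counter (`seed + i` for the
#' i-th grid row), and simulates each trajectory independently, so cohorts
#' are reproducible and order-independent. Optionally writes each trajectory
#' (TSV + JSON sidecar, see [write_trajectory()]) and a run manifest.
#'
#' @param compounds Character vector of compound names or a parameter tibble.
#' @param forces_pN Numeric vector of test-pulse forces.
#' @param config See [sim_config()]; `config$n_traces` replicates per
#'   condition and `config$seed` as root seed.
#' @param test_duration_s Test-pulse duration; `NULL` sizes each pulse to
#'   capture the full kinetics (about five expected lifetimes, clamped to
#'   `[2, 30]` s).
#' @param dir Optional output directory.
#' @return A list with `trajectories` (named list of `fc_trajectory`) and
#'   `manifest` (tibble).
#' @export
generate_cohort <- function(compounds, forces_pN, config = sim_config(),
                            test_duration_s = NULL, dir = NULL) {
  if (is.character(compounds)) {
    compounds <- dplyr::bind_rows(lapply(compounds, get_compound))
  }
  if (!nrow(compounds) || !length(forces_pN)) {
    abort("`compounds` and `forces_pN` must be non-empty")
  }
  grid <- tidyr::expand_grid(
    compound_name = compounds$name,
    force_pN = forces_pN,
    replicate = seq_len(config$n_traces)
  )
  key <- with(grid, paste(compound_name, force_pN, replicate, sep = "_"))
  if (anyDuplicated(key)) abort("duplicate (compound, force, replicate) keys")
  grid$trajectory_id <- key
  grid$seed <- config$seed + seq_len(nrow(grid))

  trajectories <- purrr::pmap(grid, function(compound_name, force_pN,
                                             replicate, trajectory_id, seed) {
    cpd <- get_compound(compound_name, compounds)
    dur <- test_duration_s %||% default_test_duration(cpd, force_pN)
    simulate_kinetics_trace(
      cpd, two_pulse_protocol(force_pN, dur),
      config = config, seed = seed
    )
  })
  names(trajectories) <- key

  manifest <- grid
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    manifest$path <- file.path(dir, paste0(key, ".tsv"))
    purrr::walk2(trajectories, manifest$path, write_trajectory)
    write_manifest(manifest, config, dir)
  }
  list(trajectories = trajectories, manifest = manifest)
}

# pulse long enough to capture ~99% of the reduction kinetics
default_test_duration <- function(compound, force_pN,
                                  constants = fc_constants()) {
  r <- bell_rate(force_pN, compound, constants)
  min(30, max(2, 5 / r))
}

#' Simulate a thiolate titration curve
#'
#' Evaluates [titration_absorbance()] on a pH grid and adds Gaussian noise,
#' emulating absorbance readings at 240 nm taken from acidic to basic pH.
#'
#' @param pKa_true Generative sulfur pKa.
#' @param pH_grid Measurement pH values; should span the midpoint (a warning
#'   is raised otherwise).
#' @param noise_sd Absorbance noise SD.
#' @param seed RNG seed.
#' @param A_min,A_max Absorbance plateaus.
#' @return A tibble of class `fc_titration` with columns `pH`, `absorbance`.
#' @export
simulate_titration <- function(pKa_true, pH_grid, noise_sd = 0.01, seed = 1L,
                               A_min = 0.1, A_max = 0.9) {
  if (length(pH_grid) < 2) abort("`pH_grid` needs at least two points")
  if (min(pH_grid) > pKa_true || max(pH_grid) < pKa_true || length(pH_grid) < 4) {
    warn("pH grid does not bracket the pKa with enough points; the fit may be unreliable")
  }
  withr::with_seed(as.integer(seed), {
    ab <- titration_absorbance(pH_grid, A_min, A_max, pKa_true)
    if (noise_sd > 0) ab <- ab + rnorm(length(ab), 0, noise_sd)
    structure(
      tibble(pH = pH_grid, absorbance = ab),
      pKa_true = pKa_true,
      class = c("fc_titration", class(tibble()))
    )
  })
}

#' @export
print.fc_trajectory <- function(x, ...) {
  ev <- attr(x, "true_events")
  cat(sprintf(
    "<fc_trajectory> %s, %d samples, %d true events (seed %d)\n",
    attr(x, "compound_name") %||% "?", nrow(x), nrow(ev), attr(x, "seed")
  ))
  NextMethod()
}
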