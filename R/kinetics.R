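#' Sum and normalize reduction staircases across trajectories
#'
#' Rebuilds each accepted trace's cumulative reduction extension (the
#' staircase of reduction-class step sizes in the test pulse, aligned at the
#' test-pulse onset), normalizes it by the trace's own total reduction
#' extension, resamples it onto a common uniform grid, and averages pointwise
#' over traces. Traces ending before the grid are held at their final value.
#' The mean curve estimates the reacted fraction and approaches
#' `1 - exp(-r t)` for first-order cleavage at rate `r`.
#'
#' @param event_sets List of accepted `fc_events` from the same compound and
#'   test force.
#' @param n_grid Number of grid points (default 400).
#' @return A tibble of class `fc_summed` with columns `time_s`, `fraction`
#'   and attributes `n_traces`, `force_pN`, `compound`, `trace_matrix`.
#' @export
sum_and_normalize <- function(event_sets, n_grid = 400) {
  event_sets <- purrr::keep(event_sets, is_accepted)
  if (!length(event_sets)) abort("no accepted traces to sum")

  conds <- purrr::map(event_sets, function(e) {
    ss <- attr(e, "segment_summary")
    test <- ss[ss$label == "test", ][1, ]
    list(
      force = test$force_pN,
      onset = test$t_start,
      duration = test$t_end - test$t_start,
      compound = attr(e, "compound")$name %||% NA_character_
    )
  })
  force <- unique(round(purrr::map_dbl(conds, "force"), 6))
  cpd <- unique(purrr::map_chr(conds, "compound"))
  if (length(force) != 1 || length(cpd) != 1) {
    abort("mixed conditions: all traces must share one compound and test force")
  }
  duration <- max(purrr::map_dbl(conds, "duration"))
  grid <- seq(0, duration, length.out = n_grid)

  stairs <- purrr::map2(event_sets, conds, function(e, cn) {
    red <- e[e$event_class == "reduction" & e$segment_label == "test", ]
    tot <- sum(red$size_nm)
    if (!nrow(red) || tot <= 0) {
      abort("trace with zero reduction extension cannot be normalized")
    }
    t_rel <- sort(red$time_s - cn$onset)
    frac <- cumsum(red$size_nm[order(red$time_s)]) / tot
    idx <- findInterval(grid, t_rel)
    out <- rep(0, n_grid)
    out[idx > 0] <- frac[idx[idx > 0]]
    out
  })
  m <- do.call(rbind, stairs)

  structure(
    tibble(time_s = grid, fraction = colMeans(m)),
    n_traces = length(event_sets),
    force_pN = force,
    compound = attr(event_sets[[1]], "compound"),
    trace_matrix = m,
    class = c("fc_summed", class(tibble()))
  )
}

#' Fit a single exponential to a summed reduction trace
#'
#' Unweighted least-squares fit of `fraction = 1 - exp(-r t)` with the rate
#' constrained positive by fitting on a log scale. No offset or amplitude is
#' fitted: summed traces are normalized to `[0, 1]`. A warning is raised when
#' the trace spans less than three expected lifetimes, where censoring makes
#' the fit unreliable.
#'
#' @param trace An `fc_summed` trace (or tibble with `time_s`, `fraction`).
#' @param constants See [fc_constants()]; used for the concentration-
#'   normalized rate when the compound is known.
#' @return A list of class `fc_rate` with elements `rate_s`, `rate_sd_s`
#'   (`NA` until [bootstrap_rate()]), `n_traces`, `force_pN`,
#'   `concentration_normalized_rate` (M^-1 s^-1) and `compound_name`.
#' @export
fit_exponential <- function(trace, constants = fc_constants()) {
  t <- trace$time_s
  f <- trace$fraction
  if (length(t) < 4 || all(f <= 0) || max(f) > 1 + 1e-6) {
    abort("degenerate summed trace")
  }
  if (any(diff(stats::filter(f, rep(1 / 25, 25), sides = 2) |>
    (\(z) z[!is.na(z)])()) < -0.2)) {
    abort("summed trace is strongly non-monotonic")
  }
  r <- fit_rate_to_curve(t, f)
  if (max(t) * r < 3) {
    warn(sprintf(
      "trace spans only %.1f expected lifetimes (< 3); rate may be biased",
      max(t) * r
    ))
  }
  cpd <- attr(trace, "compound")
  s_minus <- if (!is.null(cpd)) {
    cpd$total_concentration_M * deprotonated_fraction(cpd$pKa, cpd$pH)
  } else {
    NA_real_
  }
  structure(
    list(
      rate_s = r,
      rate_sd_s = NA_real_,
      n_traces = attr(trace, "n_traces") %||% NA_integer_,
      n_bootstrap = NA_integer_,
      force_pN = attr(trace, "force_pN") %||% NA_real_,
      concentration_normalized_rate = r / s_minus,
      s_minus_M = s_minus,
      compound_name = if (!is.null(cpd)) cpd$name else NA_character_
    ),
    class = "fc_rate"
  )
}

# 1-parameter least squares for 1 - exp(-r t), solved on log(r)
fit_rate_to_curve <- function(t, f) {
  sse <- function(logr) sum((f - (1 - exp(-exp(logr) * t)))^2)
  opt <- optimize(sse, interval = c(log(1e-5), log(1e5)), tol = 1e-10)
  exp(opt$minimum)
}

#' Bootstrap the reduction rate over recordings
#'
#' Resamples the accepted traces with replacement, refits the summed and
#' normalized ensemble of each resample with a single exponential, and
#' reports the spread as the rate's standard deviation. The point estimate
#' is the fit to the full ensemble, not the mean over resamples.
#'
#' @param event_sets List of accepted `fc_events` (>= 2 traces).
#' @param n_bootstrap Number of resamples (default 500).
#' @param seed RNG seed for the resampling.
#' @inheritParams fit_exponential
#' @return An `fc_rate` with `rate_sd_s` filled in.
#' @export
bootstrap_rate <- function(event_sets, n_bootstrap = 500, seed = 1L,
                           constants = fc_constants()) {
  if (n_bootstrap < 2) abort("`n_bootstrap` must be >= 2")
  event_sets <- purrr::keep(event_sets, is_accepted)
  if (length(event_sets) < 2) abort("need at least two accepted traces")
  summed <- sum_and_normalize(event_sets)
  est <- fit_exponential(summed, constants)
  m <- attr(summed, "trace_matrix")
  t <- summed$time_s
  n <- nrow(m)
  rates <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_bootstrap), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      fit_rate_to_curve(t, colMeans(m[idx, , drop = FALSE]))
    }, numeric(1))
  })
  est$rate_sd_s <- stats::sd(rates)
  est$n_bootstrap <- as.integer(n_bootstrap)
  est
}

#' @export
print.fc_rate <- function(x, ...) {
  cat(sprintf(
    "<fc_rate> %s at %g pN: r = %.4g +/- %.2g s^-1 (n = %d traces), r/[S-] = %.4g M^-1 s^-1\n",
    x$compound_name, x$force_pN, x$rate_s, x$rate_sd_s, x$n_traces,
    x$concentration_normalized_rate
  ))
  invisible(x)
}

#' Collect rate estimates into a tidy table
#'
#' @param rates A list of `fc_rate` objects.
#' @return A tibble with one row per estimate.
#' @export
rate_table <- function(rates) {
  bind_rows(lapply(rates, function(x) {
    tibble(
      compound_name = x$compound_name,
      force_pN = x$force_pN,
      rate_s = x$rate_s,
      rate_sd_s = x$rate_sd_s,
      norm_rate_M_s = x$concentration_normalized_rate,
      n_traces = x$n_traces
    )
  }))
}
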