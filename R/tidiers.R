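#' Tidiers for fitted objects
#'
#' Broom-style methods turning fitted objects into tibbles: `tidy()` returns
#' one row per estimated quantity, `glance()` a one-row model summary.
#'
#' @param x An `fc_rate`, `fc_bellfit`, `fc_reformation` or `fc_quench`.
#' @param ... Unused.
#' @return A tibble.
#' @name fc-tidiers
NULL

#' @rdname fc-tidiers
#' @export
tidy.fc_rate <- function(x, ...) {
  tibble(
    term = c("rate_s", "norm_rate_M_s"),
    estimate = c(x$rate_s, x$concentration_normalized_rate),
    std.error = c(x$rate_sd_s, x$rate_sd_s / x$s_minus_M)
  )
}

#' @rdname fc-tidiers
#' @export
glance.fc_rate <- function(x, ...) {
  tibble(
    compound_name = x$compound_name, force_pN = x$force_pN,
    n_traces = x$n_traces, n_bootstrap = x$n_bootstrap
  )
}

#' @rdname fc-tidiers
#' @export
tidy.fc_bellfit <- function(x, ...) {
  tibble(
    term = c("dx_A", "r0_norm_M_s", "dG_barrier_kT"),
    estimate = c(x$dx_A, x$r0_norm_M_s, x$dG_barrier_kT),
    std.error = c(x$dx_sd_A, x$r0_sd, x$dG_barrier_sd_kT)
  )
}

#' @rdname fc-tidiers
#' @export
glance.fc_bellfit <- function(x, ...) {
  tibble(
    compound_name = x$compound_name,
    n_forces = x$n_forces,
    r_squared = suppressWarnings(summary(x$fit)$r.squared)
  )
}

#' @rdname fc-tidiers
#' @export
tidy.fc_reformation <- function(x, ...) {
  tibble(
    term = "fraction_reformed",
    estimate = x$fraction_reformed,
    std.error = x$fraction_sd
  )
}

#' @rdname fc-tidiers
#' @export
tidy.fc_quench <- function(x, ...) {
  tibble(
    term = c("p_reform", "p_mixed", "p_full_reduced"),
    estimate = c(x$p_reform, x$p_mixed, x$p_full_reduced)
  )
}
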