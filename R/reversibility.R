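#' Partition of cleaved disulfides over quench outcomes
#'
#' During the zero-force quench each cleaved bond resolves into one of three
#' states: the reformed native disulfide (the protein thiolate re-attacks the
#' mixed disulfide), the persisting mixed disulfide, or a fully reduced
#' protein (a second solution thiol attacks the mixed disulfide, releasing
#' the thiol homodimer). The 8 s quench is long enough that the partition is
#' treated as thermodynamically controlled and time-independent; an optional
#' first-order relaxation `p(t) = p_eq (1 - exp(-k_rev t))` is available for
#' sensitivity analysis.
#'
#' Models:
#' * `equilibrium2` - two-state Boltzmann between mixed disulfide and native
#'   bond via [equilibrium_reformation_fraction()]; `p_full_reduced = 0`.
#' * `boltzmann3` - three-state Boltzmann over (native + thiolate, mixed
#'   disulfide, fully reduced + homodimer) with energies `0`, `dG0/kT`,
#'   `(dG0 + dG0_homodimer)/kT`.
#' * `empirical_linear` - `p_reform = clamp(a pKa + b, 0, 1)` with packaged
#'   coefficients mirroring the observed linear reformation-pKa trend;
#'   the remainder is assigned to the mixed state.
#'
#' @param compound Compound record or name.
#' @param dG0_homodimer_kcal_mol Free energy of the second substitution
#'   forming the thiol homodimer; defaults to the compound's packaged value.
#' @param quench_time_s Quench duration (default 8 s).
#' @param model One of `"equilibrium2"`, `"boltzmann3"`, `"empirical_linear"`.
#' @param k_rev_s Optional reverse-reaction relaxation rate; `NULL` (default)
#'   means full thermodynamic control.
#' @param empirical_coefs Named vector `c(slope, intercept)` for the
#'   empirical model.
#' @param constants See [fc_constants()].
#' @return A list of class `fc_quench` with `p_reform`, `p_mixed`,
#'   `p_full_reduced`, `model`; probabilities sum to 1.
#' @examples
#' quench_partition("mesna", model = "equilibrium2")
#' @export
quench_partition <- function(compound,
                             dG0_homodimer_kcal_mol = NULL,
                             quench_time_s = 8,
                             model = c("equilibrium2", "boltzmann3", "empirical_linear"),
                             k_rev_s = NULL,
                             empirical_coefs = c(slope = -0.35, intercept = 3.25),
                             constants = fc_constants()) {
  model <- match.arg(model)
  compound <- as_compound(compound)
  stopifnot(quench_time_s > 0)
  dg0 <- compound$dG0_kcal_mol
  dgh <- dG0_homodimer_kcal_mol %||%
    compound$dG0_homodimer_kcal_mol %||% 0

  p <- switch(model,
    equilibrium2 = {
      pr <- equilibrium_reformation_fraction(dg0, constants)
      c(reform = pr, mixed = 1 - pr, full = 0)
    },
    boltzmann3 = {
      g <- c(0, dg0, dg0 + dgh) / constants$kT_kcal_mol
      w <- exp(-(g - min(g))) # stabilised Boltzmann weights
      p <- w / sum(w)
      c(reform = p[1], mixed = p[2], full = p[3])
    },
    empirical_linear = {
      pr <- min(1, max(0, empirical_coefs[["slope"]] * compound$pKa +
        empirical_coefs[["intercept"]]))
      c(reform = pr, mixed = 1 - pr, full = 0)
    }
  )
  if (!is.null(k_rev_s)) {
    relax <- 1 - exp(-k_rev_s * quench_time_s)
    p["mixed"] <- p["mixed"] + p["reform"] * (1 - relax)
    p["reform"] <- p["reform"] * relax
  }
  structure(
    list(
      p_reform = unname(p["reform"]),
      p_mixed = unname(p["mixed"]),
      p_full_reduced = unname(p["full"]),
      model = model,
      quench_time_s = quench_time_s,
      compound_name = compound$name
    ),
    class = "fc_quench"
  )
}

#' @export
print.fc_quench <- function(x, ...) {
  cat(sprintf(
    "<fc_quench> %s (%s, %g s): reform %.3g / mixed %.3g / fully reduced %.3g\n",
    x$compound_name, x$model, x$quench_time_s,
    x$p_reform, x$p_mixed, x$p_full_reduced
  ))
  invisible(x)
}

#' Score the disulfide reformation fraction of a five-pulse cohort
#'
#' Pools all accepted recordings: the reformation fraction is the total
#' number of probe-pulse re-cleavage events divided by the total number of
#' first-pulse rupture events. The standard deviation is estimated by
#' bootstrap over recordings, each recording treated as an independent data
#' point.
#'
#' @param event_sets List of `fc_events` that passed
#'   [filter_reformation_trace()].
#' @param n_bootstrap Number of bootstrap resamples (default 500).
#' @param seed RNG seed for the resampling.
#' @return A list of class `fc_reformation` with `fraction_reformed`,
#'   `fraction_sd`, `n_traces`, `compound_name`, `quench_time_s`.
#' @export
score_reformation <- function(event_sets, n_bootstrap = 500, seed = 1L) {
  if (n_bootstrap < 2) abort("`n_bootstrap` must be >= 2")
  event_sets <- purrr::keep(event_sets, is_accepted)
  if (!length(event_sets)) abort("no accepted reformation recordings")
  counts <- purrr::map(event_sets, function(e) {
    c(
      probe = sum(e$event_class == "reform_probe" & e$segment_label == "probe"),
      rupture = sum(e$event_class == "reduction" & e$segment_label == "test")
    )
  })
  m <- do.call(rbind, counts)
  frac <- sum(m[, "probe"]) / sum(m[, "rupture"])
  boots <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_bootstrap), function(i) {
      idx <- sample.int(nrow(m), nrow(m), replace = TRUE)
      sum(m[idx, "probe"]) / sum(m[idx, "rupture"])
    }, numeric(1))
  })
  qt <- attr(event_sets[[1]], "segment_summary")
  qdur <- if (!is.null(qt) && "quench" %in% qt$label) {
    with(qt[qt$label == "quench", ][1, ], t_end - t_start)
  } else {
    NA_real_
  }
  structure(
    list(
      fraction_reformed = frac,
      fraction_sd = stats::sd(boots),
      n_traces = length(event_sets),
      compound_name = attr(event_sets[[1]], "compound")$name %||% NA_character_,
      quench_time_s = qdur
    ),
    class = "fc_reformation"
  )
}

#' @export
print.fc_reformation <- function(x, ...) {
  cat(sprintf(
    "<fc_reformation> %s: %.1f%% +/- %.1f%% reformed (n = %d recordings)\n",
    x$compound_name, 100 * x$fraction_reformed, 100 * x$fraction_sd, x$n_traces
  ))
  invisible(x)
}

#' Correlation of reformation extent with nucleophile pKa
#'
#' Ordinary least squares of the percent disulfide reformation on the sulfur
#' pKa (or, with `x`, on any other abscissa such as the reaction standard
#' free energy). Delegates to [charge_rate_regression()].
#'
#' @param results List of `fc_reformation` objects or a tibble with a
#'   `fraction_reformed` column.
#' @param pKas Per-compound pKa values, matching `results` in order.
#' @param x Optional alternative abscissa overriding `pKas` (e.g. `dG0`).
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
reformation_pka_correlation <- function(results, pKas, x = NULL) {
  frac <- if (is.data.frame(results)) {
    results$fraction_reformed
  } else {
    purrr::map_dbl(results, "fraction_reformed")
  }
  ab <- x %||% pKas
  if (length(ab) != length(frac)) abort("length mismatch")
  charge_rate_regression(ab, 100 * frac)
}
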