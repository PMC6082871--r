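#' Bell/Arrhenius regression of reduction rate versus force
#'
#' On a semi-log plot the force dependence of the concentration-normalized
#' cleavage rate is a straight line,
#' `ln r(F)/[S-] = ln r0 + F dx / kT`.
#' A weighted linear regression of `ln(r/[S-])` on force therefore yields the
#' distance to the transition state (slope times kT) and the zero-force
#' normalized rate (intercept), from which the activation barrier follows as
#' `ln(A / r0)` via [barrier_from_rate()]. Weights are inverse variances of
#' the log rates, obtained from the bootstrap SDs by the delta method
#' (`sd(ln r) = sd(r)/r`); when no SDs are available the fit is unweighted.
#' Barrier uncertainty propagates the intercept SD only; `A` is treated as
#' exact.
#'
#' @param rates A tibble from [rate_table()] (columns `force_pN`, `rate_s`,
#'   `rate_sd_s`, `norm_rate_M_s`), or a list of `fc_rate` objects; at least
#'   two distinct forces with positive rates.
#' @param constants See [fc_constants()].
#' @return A list of class `fc_bellfit` with `dx_A`, `dx_sd_A`,
#'   `r0_norm_M_s`, `r0_sd`, `dG_barrier_kT`, `dG_barrier_sd_kT`,
#'   `n_forces`, `compound_name`, the underlying `lm` fit and the input data.
#' @export
fit_bell <- function(rates, constants = fc_constants()) {
  if (!is.data.frame(rates)) rates <- rate_table(rates)
  if (any(!is.finite(rates$norm_rate_M_s)) || any(rates$norm_rate_M_s <= 0)) {
    abort("all normalized rates must be positive and finite")
  }
  if (length(unique(rates$force_pN)) < 2) {
    abort("Bell fit requires >= 2 distinct forces")
  }
  log_r <- log(rates$norm_rate_M_s)
  w <- if (all(is.finite(rates$rate_sd_s)) && all(rates$rate_sd_s > 0)) {
    (rates$rate_s / rates$rate_sd_s)^2
  } else {
    rep(1, nrow(rates))
  }
  fit <- lm(log_r ~ force_pN, data = rates, weights = w)
  slope <- coef(fit)[["force_pN"]]
  intercept <- coef(fit)[["(Intercept)"]]
  # suppressed: "essentially perfect fit" on noiseless input
  se <- if (nrow(rates) > 2) {
    suppressWarnings(sqrt(diag(vcov(fit))))
  } else {
    c(NA_real_, NA_real_)
  }
  r0 <- exp(intercept)
  structure(
    list(
      dx_A = nm_to_a(slope * constants$kT_pN_nm),
      dx_sd_A = nm_to_a(se[[2]] * constants$kT_pN_nm),
      r0_norm_M_s = r0,
      r0_sd = r0 * se[[1]],
      dG_barrier_kT = barrier_from_rate(r0, constants),
      dG_barrier_sd_kT = se[[1]],
      n_forces = length(unique(rates$force_pN)),
      compound_name = unique(rates$compound_name)[1] %||% NA_character_,
      fit = fit,
      data = rates
    ),
    class = "fc_bellfit"
  )
}

#' @export
print.fc_bellfit <- function(x, ...) {
  cat(sprintf(
    "<fc_bellfit> %s over %d forces: dx = %.3f A, r0/[S-] = %.4g M^-1 s^-1, barrier = %.2f kT\n",
    x$compound_name, x$n_forces, x$dx_A, x$r0_norm_M_s, x$dG_barrier_kT
  ))
  invisible(x)
}

#' Fit a Henderson-Hasselbalch titration curve for the sulfur pKa
#'
#' Least-squares fit of [titration_absorbance()] with free plateaus and pKa
#' to absorbance-versus-pH data.
#'
#' @param data An `fc_titration` tibble (columns `pH`, `absorbance`) with at
#'   least four points spanning the inflection.
#' @return The input tibble with attributes `pKa_fit`, `pKa_sd`, `A_min`,
#'   `A_max` populated (class `fc_titration`).
#' @export
fit_pka <- function(data) {
  if (nrow(data) < 4) abort("need >= 4 titration points")
  if (stats::sd(data$absorbance) < 1e-12) abort("flat titration data")
  if (stats::cor(data$pH, data$absorbance) < 0) {
    abort("absorbance decreases with pH: not a thiolate titration curve")
  }
  start <- list(
    A_min = min(data$absorbance),
    A_max = max(data$absorbance),
    pKa = data$pH[which.min(abs(data$absorbance - mean(range(data$absorbance))))]
  )
  # "port" handles the zero-residual (noiseless) limit gracefully
  fit <- stats::nls(
    absorbance ~ A_min + (A_max - A_min) / (1 + 10^(pKa - pH)),
    data = data, start = start, algorithm = "port",
    control = stats::nls.control(maxiter = 200)
  )
  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  if (est[["pKa"]] < min(data$pH) || est[["pKa"]] > max(data$pH)) {
    warn("fitted pKa lies outside the measured pH range")
  }
  structure(
    as_tibble(data),
    pKa_fit = est[["pKa"]],
    pKa_sd = se[[3]],
    A_min = est[["A_min"]],
    A_max = est[["A_max"]],
    pKa_true = attr(data, "pKa_true"),
    class = c("fc_titration", class(tibble()))
  )
}

#' Ordinary least-squares association between sulfur charge and log rate
#'
#' Generic one-predictor OLS utility used for the charge/nucleophilicity
#' correlation (partial charge on the attacking sulfur versus log
#' concentration-normalized rate at fixed force) and shared by
#' [reformation_pka_correlation()].
#'
#' @param charges Predictor values (e.g. sulfur partial charges in e).
#' @param log_rates Response values (e.g. log normalized rates).
#' @return A one-row tibble with `slope`, `intercept`, `r_squared`, `n`.
#' @export
charge_rate_regression <- function(charges, log_rates) {
  if (length(charges) != length(log_rates)) abort("length mismatch")
  if (length(charges) < 3) abort("need >= 3 points")
  fit <- lm(log_rates ~ charges)
  tibble(
    slope = coef(fit)[["charges"]],
    intercept = coef(fit)[["(Intercept)"]],
    r_squared = suppressWarnings(summary(fit)$r.squared),
    n = length(charges)
  )
}
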