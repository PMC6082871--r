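#' Fraction of thiol present as reactive thiolate
#'
#' Henderson-Hasselbalch partition of a thiol between its protonated (SH) and
#' deprotonated (S-) forms. The thiolate is the nucleophile in thiol-disulfide
#' exchange, so multiplying this fraction by the total thiol concentration
#' gives the active concentration `[S-]`.
#'
#' @param pKa Sulfur acidity constant (dimensionless).
#' @param pH Solution pH.
#' @return Fraction in `[0, 1]`; vectorised over both arguments.
#' @examples
#' deprotonated_fraction(9.0, 9.0)   # 0.5 at the titration midpoint
#' deprotonated_fraction(9.0, 7.5)   # ~3% thiolate
#' @export
deprotonated_fraction <- function(pKa, pH) {
  if (!is.numeric(pKa) || !is.numeric(pH) || any(!is.finite(pKa)) || any(!is.finite(pH))) {
    abort("`pKa` and `pH` must be finite numerics")
  }
  1 / (1 + 10^(pKa - pH))
}

#' Bell/Arrhenius rate of force-activated disulfide reduction
#'
#' Bimolecular SN2 cleavage rate of a stretched disulfide bond,
#' `r(F) = A [S-] exp(-dG_barrier) exp(F dx / kT)`,
#' where the thiolate concentration `[S-]` follows from the compound's total
#' concentration, pKa and pH. Force tilts the landscape along the pulling
#' coordinate and lowers the barrier by `F dx`.
#'
#' @param F_pN Clamp force in pN (vectorised); must be non-negative.
#' @param compound A single compound record, e.g. one row of
#'   [compound_table()] (list or one-row data frame with fields `pKa`,
#'   `dG_barrier_kT`, `dx_A`, `total_concentration_M`, `pH`).
#' @param constants Physical constants, see [fc_constants()].
#' @param normalized If `TRUE`, return the concentration-normalized rate
#'   `r / [S-]` in M^-1 s^-1 instead of the observed rate in s^-1.
#' @return Rate(s) in s^-1 (or M^-1 s^-1 when `normalized = TRUE`).
#' @examples
#' cys <- get_compound("L-cysteine")
#' bell_rate(350, cys)
#' bell_rate(0, cys, normalized = TRUE)  # r0 per molar thiolate
#' @export
bell_rate <- function(F_pN, compound, constants = fc_constants(),
                      normalized = FALSE) {
  compound <- as_compound(compound)
  if (any(!is.finite(F_pN)) || any(F_pN < 0)) {
    abort("`F_pN` must be finite and >= 0")
  }
  s_minus <- compound$total_concentration_M *
    deprotonated_fraction(compound$pKa, compound$pH)
  norm <- constants$A_prefactor * exp(-compound$dG_barrier_kT) *
    exp(F_pN * a_to_nm(compound$dx_A) / constants$kT_pN_nm)
  if (normalized) norm else norm * s_minus
}

#' Activation barrier from the zero-force normalized rate
#'
#' Inverts the Arrhenius relation `r0 = A exp(-dG_barrier)` to recover the
#' zero-force activation free energy, in units of kT, from a
#' concentration-normalized zero-force rate. The pre-exponential `A` is
#' treated as exact.
#'
#' @param r0_normalized Zero-force rate per molar thiolate (M^-1 s^-1).
#' @param constants See [fc_constants()].
#' @return Barrier height in kT.
#' @examples
#' barrier_from_rate(1e7 * exp(-10.6))  # 10.6
#' @export
barrier_from_rate <- function(r0_normalized, constants = fc_constants()) {
  if (any(!is.finite(r0_normalized)) || any(r0_normalized <= 0)) {
    abort("`r0_normalized` must be finite and > 0")
  }
  if (any(r0_normalized > constants$A_prefactor)) {
    abort("`r0_normalized` exceeds the pre-exponential A: invalid extrapolation")
  }
  log(constants$A_prefactor / r0_normalized)
}

#' Equilibrium probability of disulfide reformation at zero force
#'
#' Treats reformation of the native disulfide during a zero-force quench as
#' the reverse of the reduction reaction. With reduction standard free energy
#' `dG0` (negative = reduction spontaneous), the reverse equilibrium constant
#' is `K_rev = exp(dG0 / kT)` and the reformed fraction is
#' `K_rev / (1 + K_rev)`. A thermoneutral exchange (`dG0 = 0`) therefore
#' reforms exactly half of the bonds, the 50:50 cysteine/cystine equilibrium.
#'
#' @param dG0_reduction_kcal_mol Standard free energy of the reduction
#'   reaction in kcal/mol (vectorised).
#' @param constants See [fc_constants()].
#' @return Reformed fraction in `[0, 1]`, increasing in `dG0`.
#' @examples
#' equilibrium_reformation_fraction(0)      # 0.5
#' equilibrium_reformation_fraction(-6.7)   # mesna: ~1e-5
#' @export
equilibrium_reformation_fraction <- function(dG0_reduction_kcal_mol,
                                             constants = fc_constants()) {
  if (any(!is.finite(dG0_reduction_kcal_mol))) {
    abort("`dG0_reduction_kcal_mol` must be finite")
  }
  x <- dG0_reduction_kcal_mol / constants$kT_kcal_mol
  stats::plogis(x)
}

#' Titration curve of thiolate absorbance versus pH
#'
#' Thiolate absorbs at 240 nm while the protonated thiol does not, so the
#' absorbance-pH curve is a logistic between `A_min` (fully protonated) and
#' `A_max` (fully deprotonated) with midpoint at the sulfur pKa.
#'
#' @param pH Solution pH (vectorised).
#' @param A_min,A_max Absorbance plateaus; `A_max >= A_min` required.
#' @param pKa Sulfur acidity constant.
#' @return Absorbance values.
#' @export
titration_absorbance <- function(pH, A_min, A_max, pKa) {
  if (any(A_max < A_min)) abort("`A_max` must be >= `A_min`")
  A_min + (A_max - A_min) * deprotonated_fraction(pKa, pH)
}

#' Three-level free-energy landscape of thiol-disulfide exchange under force
#'
#' Reduces the reaction profile to three levels: the intact disulfide plus
#' attacking thiolate (reference, 0 kT), the SN2 transition state, and the
#' mixed-disulfide product. Force lowers the transition state by
#' `F dx / kT`; the product level is the reduction standard free energy.
#' The tilted barrier is floored at the higher of the two wells so the
#' landscape remains a barrier-crossing picture even at forces beyond the
#' experimentally probed regime.
#'
#' @inheritParams bell_rate
#' @return A tibble of class `fc_landscape` with columns `state`
#'   (`reactant`, `transition`, `product`) and `energy_kT`.
#' @examples
#' build_landscape(get_compound("Cys-ME"), F_pN = 0)
#' @export
build_landscape <- function(compound, F_pN, constants = fc_constants()) {
  compound <- as_compound(compound)
  if (!is.finite(F_pN) || F_pN < 0) abort("`F_pN` must be finite and >= 0")
  g_reactant <- 0
  g_product <- compound$dG0_kcal_mol / constants$kT_kcal_mol
  g_ts <- compound$dG_barrier_kT -
    F_pN * a_to_nm(compound$dx_A) / constants$kT_pN_nm
  g_ts <- max(g_ts, g_reactant, g_product)
  structure(
    tibble(
      state = c("reactant", "transition", "product"),
      energy_kT = c(g_reactant, g_ts, g_product)
    ),
    compound_name = compound$name,
    force_pN = F_pN,
    class = c("fc_landscape", class(tibble()))
  )
}
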