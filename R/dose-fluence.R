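## Dose <-> fluence conversion, D = rho * Phi * L.
##
## With L the unit-density LET in keV/um and Phi in /um^2,
## D[mGy] = 160.2 * L * Phi / rho  (1.602e-9 Gy per keV/um per /cm^2).

#' Convert between absorbed dose and particle fluence
#'
#' Implements the dose-fluence relation `D = rho Phi L` with the standard
#' unit constant: `D[mGy] = 160.2 * L[keV/um] * Phi[/um^2] / rho[g/cm^3]`.
#' All tissue-level bookkeeping in the package uses `rho = 1`.
#'
#' @param dose_mGy Absorbed dose, mGy.
#' @param fluence_per_um2 Particle fluence, /um^2.
#' @param let_keVum LET at unit density, keV/um; must be positive.
#' @param density Material density, g/cm^3.
#' @return Fluence in /um^2, or dose in mGy.
#' @examples
#' fluence_from_dose(2.42, 0.2225)   # ~6.79e-2 /um^2
#' dose_from_fluence(6.79e-2, 0.2225)
#' @export
fluence_from_dose <- function(dose_mGy, let_keVum, density = 1) {
  check_dose_fluence(let_keVum, density)
  if (any(dose_mGy < 0)) abort("dose must be >= 0")
  dose_mGy * density / (DOSE_FLUENCE_CONST * let_keVum)
}

#' @rdname fluence_from_dose
#' @export
dose_from_fluence <- function(fluence_per_um2, let_keVum, density = 1) {
  check_dose_fluence(let_keVum, density)
  if (any(fluence_per_um2 < 0)) abort("fluence must be >= 0")
  DOSE_FLUENCE_CONST * let_keVum * fluence_per_um2 / density
}

check_dose_fluence <- function(let, density) {
  if (any(let <= 0)) abort("LET must be positive")
  if (any(density <= 0)) abort("density must be positive")
  invisible(NULL)
}
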