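## Stopping power (LET) and continuous-slowing-down energy degradation.

ELECTRON_MEV <- 0.510998950
BETHE_K <- 0.307075  # MeV cm^2 / mol

# Relativistic Bethe mass stopping power with Barkas effective charge,
# MeV cm^2/g for the whole ion; E in MeV/u.  Shell and density-effect
# corrections are omitted (percent-level over 10-5000 MeV/u, see vignette).
# Internal: no range guard, vectorized over `energy`.
bethe_mass_stopping <- function(ion, energy, mat) {
  mu <- nucleon_mass(ion)
  gamma <- 1 + energy / mu
  beta2 <- 1 - 1 / gamma^2
  beta <- sqrt(beta2)
  zeff <- ion$Z * (1 - exp(-125 * beta * ion$Z^(-2 / 3)))
  I <- mat$I_eV * 1e-6  # MeV
  BETHE_K * zeff^2 * mat$za / beta2 *
    (log(2 * ELECTRON_MEV * beta2 * gamma^2 / I) - beta2)
}

#' Stopping power (LET) of an ion
#'
#' Relativistic Bethe formula with Barkas effective-charge correction
#' `Z_eff = Z (1 - exp(-125 beta Z^(-2/3)))`, Bragg additivity over the
#' material composition, no shell or density-effect corrections.  The
#' returned LET is the unit-density value in keV/um (numerically the mass
#' stopping power in MeV cm^2/g divided by 10); multiply by the material
#' density for a track-averaged LET in the bulk material.
#'
#' @param ion A [ion()] or nuclide label.
#' @param energy_MeVu Kinetic energy per nucleon, MeV/u; vectorized.
#'   Supported range 10-5000 MeV/u.
#' @param mat A [material()]; defaults to unit-density tissue.
#' @return LET in keV/um at unit density.
#' @examples
#' stopping_power("p", 1000)    # ~0.22 keV/um
#' stopping_power("56Fe", 500)  # ~185 keV/um
#' @export
stopping_power <- function(ion, energy_MeVu, mat = gcr_material("tissue")) {
  ion <- as_ion(ion)
  if (any(energy_MeVu < E_MIN | energy_MeVu > E_MAX)) {
    abort(paste0("energy outside supported range [", E_MIN, ", ", E_MAX,
                 "] MeV/u"))
  }
  0.1 * bethe_mass_stopping(ion, energy_MeVu, mat)
}

# lower anchor (MeV/u) for range integrals; residual range below this is
# dropped consistently on both sides of the range-additivity identity
E_STOP <- 1

# CSDA range from E_STOP up, g/cm^2
csda_range_one <- function(ion, energy, mat) {
  if (energy <= E_STOP) return(0)
  integrate(function(e) ion$A / bethe_mass_stopping(ion, e, mat),
            E_STOP, energy, rel.tol = 1e-10, abs.tol = 0)$value
}

#' CSDA range and energy after an absorber
#'
#' `csda_range()` integrates `A dE / S(E)` from a 1 MeV/u anchor to the
#' beam energy (continuous-slowing-down approximation, straight paths, no
#' straggling).  `csda_energy_out()` inverts the range relation to give the
#' mean beam energy behind an absorber of the given areal density: it
#' solves `range(E_out) = range(E_in) - depth` and returns 0 ("stopped")
#' when the depth exhausts the range.
#'
#' @inheritParams stopping_power
#' @param energy_in_MeVu Beam energy entering the absorber, MeV/u.
#' @param depth_gcm2 Absorber areal density, g/cm^2; vectorized.
#' @return `csda_range()`: range in g/cm^2.  `csda_energy_out()`: exit
#'   energy in MeV/u (0 when the beam stops inside the absorber).
#' @examples
#' csda_range("28Si", 500, gcr_material("polyethylene"))
#' csda_energy_out("16O", 900, gcr_material("polyethylene"), 18)
#' @export
csda_range <- function(ion, energy_MeVu, mat = gcr_material("tissue")) {
  ion <- as_ion(ion)
  if (any(energy_MeVu < E_MIN | energy_MeVu > E_MAX)) {
    abort(paste0("energy outside supported range [", E_MIN, ", ", E_MAX,
                 "] MeV/u"))
  }
  vapply(energy_MeVu, function(e) csda_range_one(ion, e, mat), numeric(1))
}

#' @rdname csda_range
#' @export
csda_energy_out <- function(ion, energy_in_MeVu,
                            mat = gcr_material("tissue"), depth_gcm2) {
  ion <- as_ion(ion)
  if (any(depth_gcm2 < 0)) abort("absorber depth must be >= 0")
  r_in <- csda_range(ion, energy_in_MeVu, mat)
  vapply(depth_gcm2, function(x) {
    if (x == 0) return(energy_in_MeVu)
    resid <- r_in - x
    if (resid <= csda_range_one(ion, E_STOP + 1e-9, mat)) return(0)
    uniroot(function(e) csda_range_one(ion, e, mat) - resid,
            lower = E_STOP, upper = energy_in_MeVu,
            tol = 1e-9 * energy_in_MeVu)$root
  }, numeric(1))
}
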