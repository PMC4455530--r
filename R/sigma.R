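## Macroscopic absorption cross sections of the HZE design beams in
## polyethylene.  The package ships the nine tabulated (ion, energy)
## values; there is no cross-section model behind them, so lookups
## interpolate between tabulated energies and refuse to extrapolate.

#' Absorption cross-section table
#'
#' Loads the packaged table of macroscopic absorption cross sections
#' (cm^2/g) for the three HZE design beams at 500, 900 and 1500 MeV/u.
#'
#' @param path CSV with columns `ion`, `energy_MeVu`, `sigma_cm2_per_g`.
#' @return A tibble of class `sigma_table`.
#' @examples
#' sigma_table()
#' @export
sigma_table <- function(path = system.file("extdata", "sigma_abs.csv",
                                           package = "gcrsim")) {
  tab <- readr::read_csv(path, col_types = readr::cols(
    ion = readr::col_character(),
    energy_MeVu = readr::col_double(),
    sigma_cm2_per_g = readr::col_double()
  ))
  if (any(tab$sigma_cm2_per_g <= 0)) abort("sigma_abs values must be > 0")
  class(tab) <- c("sigma_table", class(tab))
  tab
}

#' Look up an absorption cross section
#'
#' Returns the tabulated sigma_abs at tabulated energies and interpolates
#' linearly in log(energy) between them.  Requests outside the tabulated
#' energy span, or for an ion not in the table, are an error.
#'
#' @param table A [sigma_table()].
#' @param ion Ion label or [ion()].
#' @param energy_MeVu Beam energy, MeV/u; vectorized.
#' @return sigma_abs in cm^2/g.
#' @examples
#' sigma_lookup(sigma_table(), "16O", 500)
#' @export
sigma_lookup <- function(table, ion, energy_MeVu) {
  ion <- as_ion(ion)
  sub <- table[table$ion == ion$label, ]
  if (nrow(sub) == 0) {
    abort(paste0("ion '", ion$label, "' not in the cross-section table"))
  }
  sub <- sub[order(sub$energy_MeVu), ]
  rng <- range(sub$energy_MeVu)
  if (any(energy_MeVu < rng[1] | energy_MeVu > rng[2])) {
    abort(paste0("energy outside tabulated span [", rng[1], ", ", rng[2],
                 "] MeV/u; extrapolation refused"))
  }
  stats::approx(log(sub$energy_MeVu), sub$sigma_cm2_per_g,
                xout = log(energy_MeVu), method = "linear",
                ties = "ordered")$y
}
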