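## Design validation: recompute every derivable printed cell of the
## shipped tables and report pass / tuned / fail per cell.

#' Validate a scenario design against the shipped tables
#'
#' Recomputes every derivable quantity of the design tables and compares
#' it with the printed value at printed precision:
#'
#' * absorber depths from the extinction relation (the 500 MeV/u rows
#'   are analytic; the 900/1500 MeV/u depths were transport-tuned and are
#'   reported with status `"tuned"`),
#' * every beam-row fluence from its own row's dose-fluence algebra
#'   (tolerance propagated from the rounding of the printed inputs),
#' * every light-ion fluence from the package stopping power (LET
#'   tolerance 3 percent),
#' * the column and grand dose totals.
#'
#' @param tables A [gcr_tables()] bundle.
#' @param scenarios Scenarios to validate.
#' @param let_tol Relative tolerance between the implied LET
#'   `D / (160.2 Phi)` of a printed light-ion row and the package
#'   stopping power.
#' @return A tibble with one row per checked cell: `section`, `scenario`,
#'   `ion`, `energy_MeVu`, `quantity`, `printed`, `computed`, `rel_dev`,
#'   `status` (`pass` exact at printed precision; `close` within the
#'   rounding propagated from printed inputs; `tuned` not derivable by
#'   design; `fail` otherwise).
#' @examples
#' report <- validate_field_design(gcr_tables())
#' table(report$status)
#' @export
validate_field_design <- function(tables = gcr_tables(),
                                  scenarios = c("habitat", "transfer"),
                                  let_tol = 0.03) {
  out <- list()

  ## absorber depths (Eq.-2 extinction estimate vs printed)
  ab <- tables$absorbers
  for (sc in scenarios) {
    f <- ab[[paste0("dose_fraction_", sc)]]
    xp <- ab[[paste0("xpe_", sc, "_gcm2")]]
    xc <- absorber_depth(f, ab$sigma_cm2_per_g)
    tol <- printed_rel_half_ulp(f) + printed_rel_half_ulp(ab$sigma_cm2_per_g)
    status <- dplyr::case_when(
      ab$energy_MeVu != 500 ~ "tuned",
      abs(round_like(xc, xp) - xp) < 1e-9 ~ "pass",
      abs(xc - xp) <= printed_half_ulp(xp) + tol * xp ~ "close",
      TRUE ~ "fail")
    out[[length(out) + 1]] <- tibble(
      section = "absorber_depth", scenario = sc, ion = ab$ion,
      energy_MeVu = ab$energy_MeVu, quantity = "xpe_gcm2", printed = xp,
      computed = xc, rel_dev = xc / xp - 1, status = status)
  }

  ## beam-row fluences (dose-fluence algebra of each row)
  br <- tables$beam_rows[tables$beam_rows$scenario %in% scenarios, ]
  phi <- beam_row_fluence(br)
  tol <- beam_row_fluence_tol(br)
  out <- c(out, list(tibble(
    section = "beam_fluence", scenario = br$scenario, ion = br$ion,
    energy_MeVu = br$energy_MeVu,
    quantity = paste0("fluence_", br$role),
    printed = br$fluence_per_um2, computed = phi,
    rel_dev = phi / br$fluence_per_um2 - 1,
    status = dplyr::case_when(
      abs(phi - br$fluence_per_um2) <=
        printed_half_ulp(br$fluence_per_um2) + 1e-15 ~ "pass",
      abs(phi - br$fluence_per_um2) <=
        printed_half_ulp(br$fluence_per_um2) +
        tol * br$fluence_per_um2 ~ "close",
      TRUE ~ "fail"))))

  ## light-ion fluences via the package stopping power
  li <- tables$light_ions[tables$light_ions$scenario %in% scenarios, ] %>%
    light_ion_schedule_quiet()
  implied <- li$dose_mGy / (DOSE_FLUENCE_CONST * li$fluence_printed)
  out <- c(out, list(tibble(
    section = "light_ion", scenario = li$scenario, ion = li$ion,
    energy_MeVu = li$energy_MeVu, quantity = "implied_LET",
    printed = implied, computed = li$let_keVum,
    rel_dev = li$let_keVum / implied - 1,
    status = ifelse(abs(li$let_keVum / implied - 1) <= let_tol,
                    "pass", "fail"))))

  ## totals
  cg <- tables$charge_groups
  for (sc in scenarios) {
    li_sc <- tables$light_ions[tables$light_ions$scenario == sc, ]
    grand <- sum(cg$dose_mGy[cg$scenario == sc])
    ptot <- sum(li_sc$dose_mGy[li_sc$ion == "p"])
    hetot <- sum(li_sc$dose_mGy[li_sc$ion == "4He"])
    pg <- cg$dose_mGy[cg$scenario == sc & cg$charge_group == "Z=1"]
    heg <- cg$dose_mGy[cg$scenario == sc & cg$charge_group == "Z=2"]
    tot <- tibble(
      section = "totals", scenario = sc, ion = c("all", "p", "4He"),
      energy_MeVu = NA_real_,
      quantity = c("grand_total_mGy", "proton_total_mGy",
                   "helium_total_mGy"),
      printed = c(grand, pg, heg),
      computed = c(grand, ptot, hetot),
      rel_dev = .data$computed / .data$printed - 1,
      status = ifelse(abs(round_like(.data$computed, .data$printed) -
                            .data$printed) < 1e-9, "pass", "fail"))
    out <- c(out, list(tot))
  }

  bind_rows(out)
}

# light_ion_schedule keeping the printed fluence for comparison
light_ion_schedule_quiet <- function(li) {
  li %>%
    rename(fluence_printed = "fluence_per_um2") %>%
    light_ion_schedule()
}
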