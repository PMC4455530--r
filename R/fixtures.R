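## Design-table fixtures.
##
## The six tables shipped under extdata/ carry the transport-code
## (HZETRN) dose predictions and the beam-design rows for the two
## shielding scenarios: per-charge-group annual doses, Z-group doses per
## energy bin, light-ion doses and fluences per energy, absorber
## extinction fractions and depths, and the per-beam dose/fluence design
## rows.  `gcr_tables()` loads them and refuses bundles whose cross-table
## identities fail, naming the offending table and row.

TABLE_SCHEMAS <- list(
  charge_groups = c("scenario", "charge_group", "dose_fraction", "dose_mGy"),
  zgroup_bins = c("scenario", "charge_group", "energy_bin",
                  "hzetrn_mGy", "model_mGy"),
  light_ions = c("scenario", "ion", "energy_MeVu", "dose_mGy",
                 "fluence_per_um2"),
  absorbers = c("ion", "energy_MeVu", "dose_fraction_habitat",
                "xpe_habitat_gcm2", "dose_fraction_transfer",
                "xpe_transfer_gcm2", "sigma_cm2_per_g"),
  beam_rows = c("ion", "energy_MeVu", "xpe_gcm2", "eout_MeVu", "dose_ratio",
                "role", "share", "dose_mGy", "per_gy_fluence",
                "fluence_per_um2")
)

read_fixture <- function(path, table, required) {
  if (!file.exists(path)) {
    abort(paste0("fixture file missing: ", path))
  }
  tab <- readr::read_csv(path, col_types = readr::cols(), na = "NA",
                         progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    abort(paste0("table '", table, "': missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  numeric_cols <- setdiff(required,
                          c("scenario", "charge_group", "energy_bin",
                            "ion", "role"))
  for (col in numeric_cols) {
    v <- tab[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))[1]
      abort(paste0("table '", table, "', row ", bad, ", column '", col,
                   "': non-numeric cell '", v[bad], "'"))
    }
  }
  tab
}

#' Load and validate the packaged design tables
#'
#' Reads the shielding-scenario dose tables and beam-design rows shipped
#' with the package and checks their internal identities: charge-group
#' doses summing to the scenario totals, light-ion column totals matching
#' the Z = 1 and Z = 2 group doses, primary/fragment dose shares summing
#' to one, and every design-row fluence reproducing from the dose-fluence
#' algebra of its own row at printed precision.  A violated identity is an
#' error naming the table and row.
#'
#' @param dir Directory holding the fixture CSVs (defaults to the
#'   installed package data).
#' @return A list of class `gcr_tables` with tibbles `charge_groups`,
#'   `zgroup_bins`, `light_ions`, `absorbers`, `beam_rows` (both scenarios,
#'   `scenario` column) and `sigma` (a [sigma_table()]).
#' @examples
#' tabs <- gcr_tables()
#' names(tabs)
#' @export
gcr_tables <- function(dir = system.file("extdata", package = "gcrsim")) {
  tabs <- list(
    charge_groups = read_fixture(file.path(dir, "table1_charge_groups.csv"),
                                 "charge_groups", TABLE_SCHEMAS$charge_groups),
    zgroup_bins = read_fixture(file.path(dir, "table2_zgroup_bins.csv"),
                               "zgroup_bins", TABLE_SCHEMAS$zgroup_bins),
    light_ions = read_fixture(file.path(dir, "table3_light_ions.csv"),
                              "light_ions", TABLE_SCHEMAS$light_ions),
    absorbers = read_fixture(file.path(dir, "table4_absorbers.csv"),
                             "absorbers", TABLE_SCHEMAS$absorbers),
    beam_rows = dplyr::bind_rows(
      habitat = read_fixture(file.path(dir, "table5_habitat_rows.csv"),
                             "beam_rows", TABLE_SCHEMAS$beam_rows),
      transfer = read_fixture(file.path(dir, "table6_transfer_rows.csv"),
                              "beam_rows", TABLE_SCHEMAS$beam_rows),
      .id = "scenario"),
    sigma = sigma_table(file.path(dir, "sigma_abs.csv"))
  )
  validate_tables(tabs)
  structure(tabs, class = c("gcr_tables", "list"))
}

#' @export
print.gcr_tables <- function(x, ...) {
  cat("<gcr_tables>\n")
  for (nm in setdiff(names(x), "sigma")) {
    cat("  ", nm, ": ", nrow(x[[nm]]), " rows\n", sep = "")
  }
  cat("  sigma: ", nrow(x$sigma), " (ion, energy) entries\n", sep = "")
  invisible(x)
}

# cross-table identity checks; abort with coordinates on violation
validate_tables <- function(tabs) {
  cg <- tabs$charge_groups
  for (sc in unique(cg$scenario)) {
    sub <- cg[cg$scenario == sc, ]
    if (any(sub$dose_mGy < 0)) {
      abort(paste0("charge_groups/", sc, ": negative dose"))
    }
    if (abs(sum(sub$dose_fraction) - 1) > 0.015) {
      abort(paste0("charge_groups/", sc,
                   ": dose fractions do not sum to 1"))
    }
    li <- tabs$light_ions[tabs$light_ions$scenario == sc, ]
    for (sp in c("p", "4He")) {
      zg <- if (sp == "p") "Z=1" else "Z=2"
      tot <- sum(li$dose_mGy[li$ion == sp])
      printed <- sub$dose_mGy[sub$charge_group == zg]
      if (!matches_printed(tot, printed,
                           extra_rel = sum(printed_rel_half_ulp(
                             li$dose_mGy[li$ion == sp])) / 10)) {
        abort(paste0("light_ions/", sc, "/", sp, ": column total ",
                     round(tot, 2), " != charge-group dose ", printed))
      }
    }
  }
  br <- tabs$beam_rows
  if (!all(br$role %in% c("primary", "fragments"))) {
    abort("beam_rows: role must be primary|fragments")
  }
  shares <- br %>%
    dplyr::group_by(.data$scenario, .data$ion, .data$energy_MeVu) %>%
    dplyr::summarise(s = sum(.data$share), n = dplyr::n(), .groups = "drop")
  bad <- which(shares$n != 2 | abs(shares$s - 1) > 1e-9)
  if (length(bad) > 0) {
    abort(paste0("beam_rows: primary/fragment shares of ",
                 shares$ion[bad[1]], " ", shares$energy_MeVu[bad[1]], " (",
                 shares$scenario[bad[1]], ") do not pair to 1"))
  }
  phi <- beam_row_fluence(br)
  tol <- beam_row_fluence_tol(br)
  bad <- which(abs(phi - br$fluence_per_um2) >
                 tol * abs(br$fluence_per_um2) +
                 printed_half_ulp(br$fluence_per_um2) + 1e-15)
  if (length(bad) > 0) {
    i <- bad[1]
    abort(paste0("beam_rows/", br$scenario[i], ": ", br$ion[i], " ",
                 br$energy_MeVu[i], " ", br$role[i],
                 " fluence fails the dose-fluence identity (",
                 signif(phi[i], 4), " vs ", br$fluence_per_um2[i], ")"))
  }
  invisible(tabs)
}

# Eq. 3a/3b evaluated from the other columns of each design row
beam_row_fluence <- function(br) {
  ifelse(br$role == "primary",
         br$dose_mGy / 1000 * br$per_gy_fluence,
         br$dose_mGy / 1000 * br$per_gy_fluence / br$dose_ratio)
}

# propagated printed-rounding half-width (relative) of that product
beam_row_fluence_tol <- function(br) {
  printed_rel_half_ulp(br$dose_mGy) +
    printed_rel_half_ulp(br$per_gy_fluence) +
    ifelse(br$role == "fragments", printed_rel_half_ulp(br$dose_ratio), 0)
}
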