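## broom-style accessors.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a designed reference field
#'
#' @param x A `gcr_field`.
#' @param ... Unused.
#' @return The delivery-facing columns, one row per beam component.
#' @method tidy gcr_field
#' @export
tidy.gcr_field <- function(x, ...) {
  as_tibble(x)[, c("ion", "Z", "A", "energy_MeVu", "role",
                   "absorber_gcm2", "dose_mGy", "fluence_per_um2",
                   "energy_out_MeVu", "energy_bin")]
}

#' @rdname tidy.gcr_field
#' @method glance gcr_field
#' @export
glance.gcr_field <- function(x, ...) {
  tibble(
    scenario = attr(x, "scenario"),
    n_hze_beams = nrow(unique(x[x$role != "beam", c("ion", "energy_MeVu")])),
    n_light_beams = sum(x$role == "beam"),
    total_dose_mGy = sum(x$dose_mGy),
    hze_dose_mGy = sum(x$dose_mGy[x$role != "beam"]),
    hze_fluence_per_um2 = sum(x$fluence_per_um2[x$role != "beam"]),
    light_fluence_per_um2 = sum(x$fluence_per_um2[x$role == "beam"])
  )
}

#' Tidy a multi-hit kinetics solution
#'
#' @param x A `hit_kinetics` object.
#' @param ... Unused.
#' @return `tidy()`: the long state table (`time_days`, `hits`,
#'   `fraction`).  `glance()`: one row with the end-of-window summary
#'   (mass-conservation defect, fractions with >= 1 and >= 2 hits, dead
#'   fraction).
#' @method tidy hit_kinetics
#' @export
tidy.hit_kinetics <- function(x, ...) x$states

#' @rdname tidy.hit_kinetics
#' @method glance hit_kinetics
#' @export
glance.hit_kinetics <- function(x, ...) {
  last <- x$states[x$states$time_days == max(x$states$time_days), ]
  live <- last[last$hits != "dead", ]
  h <- as.integer(live$hits)
  tibble(
    duration_days = x$window$duration_days,
    total_fluence = x$window$total_fluence,
    area_um2 = x$params$area_um2,
    tau_relax_days = x$params$tau_relax_days,
    mass_defect = abs(sum(last$fraction) - 1),
    frac_ge1 = sum(live$fraction[h >= 1]),
    frac_ge2 = sum(live$fraction[h >= 2]),
    dead = last$fraction[last$hits == "dead"]
  )
}
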