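# Absorber-depth algebra, beam fluence budgets and field assembly.

test_that("absorber depth inverts the extinction relation exactly", {
  expect_equal(absorber_depth(0.305, 0.0668), -log(0.305) / 0.0668)
  expect_identical(absorber_depth(1, 0.1), 0)
  # identity property over the working (sigma, depth) region
  for (sigma in seq(0.05, 0.15, by = 0.025)) {
    x <- seq(0, 30, by = 3)
    expect_equal(absorber_depth(exp(-sigma * x), sigma), x,
                 tolerance = 1e-12)
  }
  expect_error(absorber_depth(0, 0.1), "dose_fraction")
  expect_error(absorber_depth(1.2, 0.1), "dose_fraction")
  expect_error(absorber_depth(0.5, 0), "sigma")
})

test_that("printed 500 MeV/u depths reproduce from their extinction fractions", {
  # habitat / transfer, rounded to the printed decimal
  expect_equal(round(absorber_depth(0.305, 0.0668), 1), 17.8)
  expect_equal(round(absorber_depth(0.169, 0.0668), 1), 26.6)
  expect_equal(round(absorber_depth(0.410, 0.1307), 1), 6.8)
  expect_equal(round(absorber_depth(0.309, 0.1307), 1), 9.0)
  expect_equal(round(absorber_depth(0.299, 0.0916), 1), 13.2)
})

test_that("primary and fragment fluence follow the design algebra", {
  # oxygen 500 habitat row: group-bin dose reconstructed as 2.25/0.164
  expect_equal(primary_fluence(2.25 / 0.164, 0.164, 0.353), 7.94e-4,
               tolerance = 1e-3)
  # iron 1500 habitat fragment row
  expect_equal(fragment_fluence(2.18 / 0.724, 1 - 0.724, 0.044, 0.65),
               1.48e-4, tolerance = 2e-3)
  # oxygen 900 habitat fragment row (closed form; table prints 1.30e-3)
  expect_equal(fragment_fluence(1.96 / 0.729, 1 - 0.729, 0.428, 0.64),
               1.31e-3, tolerance = 1e-3)
  # transparent absorber: r = 1 reduces to the bare conversion
  expect_equal(fragment_fluence(10, 0.6, 0.3, 1), 10 / 1000 * 0.4 * 0.3)
  # linearity in the group dose
  expect_equal(primary_fluence(20, 0.2, 0.3), 2 * primary_fluence(10, 0.2, 0.3))
  expect_warning(out <- primary_fluence(5, 0, 0.3), "no primary share")
  expect_identical(out, 0)
  expect_error(fragment_fluence(1, 0.5, 0.3, 0), "dose_ratio")
})

test_that("light-ion schedule preserves dose totals and printed fluences", {
  li <- dplyr::filter(cached_tables()$light_ions, scenario == "habitat")
  sched <- light_ion_schedule(dplyr::select(li, -fluence_per_um2))
  expect_equal(round(sum(sched$dose_mGy[sched$ion == "p"]), 1), 120.8)
  expect_equal(round(sum(sched$dose_mGy[sched$ion == "4He"]), 2), 42.47)
  # printed 1000-MeV proton fluence within 2 percent
  p1000 <- sched$fluence_per_um2[sched$ion == "p" & sched$energy_MeVu == 1000]
  expect_equal(p1000, 6.79e-2, tolerance = 0.02)
  # zero doses give zero fluences
  z <- light_ion_schedule(tibble::tibble(ion = "p", energy_MeVu = 600,
                                         dose_mGy = 0))
  expect_identical(z$fluence_per_um2, 0)
})

test_that("assembled field has 9 HZE combinations whose fluences match print", {
  for (sc in c("habitat", "transfer")) {
    field <- cached_field(sc)
    hze <- dplyr::filter(field, role != "beam")
    expect_equal(nrow(unique(hze[, c("ion", "energy_MeVu")])), 9)
    expect_equal(nrow(hze), 18)
    printed <- dplyr::filter(cached_tables()$beam_rows, scenario == sc)
    m <- dplyr::left_join(hze, printed,
                          by = c("ion", "energy_MeVu", "role"),
                          suffix = c("", ".printed"))
    # bound: rounding propagated from the printed row inputs (dose to as
    # few as 2 significant figures, shares and ratios to 2-3)
    expect_lt(max(abs(m$fluence_per_um2 / m$fluence_per_um2.printed - 1)),
              0.035)
  }
})

test_that("field dose budgets account for the scenario grand total", {
  cg <- cached_tables()$charge_groups
  for (sc in c("habitat", "transfer")) {
    total <- sum(cached_field(sc)$dose_mGy)
    printed <- sum(cg$dose_mGy[cg$scenario == sc])
    expect_lt(abs(total - printed), 1)
  }
})

test_that("transfer-vehicle iron 500 primary fluence matches the printed row", {
  f <- cached_field("transfer")
  phi <- f$fluence_per_um2[f$ion == "56Fe" & f$energy_MeVu == 500 &
                             f$role == "primary"]
  # printed 4.98e-6 with the row dose printed to 2 significant figures
  expect_equal(phi, 4.98e-6, tolerance = 0.035)
})

test_that("absorber provenance separates analytic from transport-tuned depths", {
  for (sc in c("habitat", "transfer")) {
    hze <- dplyr::filter(cached_field(sc), role == "fragments")
    expect_setequal(hze$depth_provenance[hze$energy_MeVu == 500],
                    "extinction")
    expect_setequal(hze$depth_provenance[hze$energy_MeVu != 500], "tuned")
  }
})

test_that("z-group summary tracks the scenario reference cells", {
  tabs <- cached_tables()
  zs <- zgroup_summary(cached_field("habitat"), tabs)
  cell <- dplyr::filter(zs, charge_group == "Z=3-8", energy_bin == "<500")
  expect_equal(cell$model_mGy, 14.2)
  expect_equal(cell$hzetrn_mGy, 14.7)
  expect_lt(abs(cell$designed_mGy - cell$model_mGy), 1)
  zs_t <- zgroup_summary(cached_field("transfer"), tabs)
  cell <- dplyr::filter(zs_t, charge_group == "Z=15-28", energy_bin == ">900")
  expect_equal(cell$model_mGy, 1.3)
  expect_equal(cell$hzetrn_mGy, 1.4)
  # empty field books zero everywhere
  empty <- cached_field("habitat")[0, ]
  attr(empty, "scenario") <- "habitat"
  expect_true(all(zgroup_summary(empty, tabs)$designed_mGy == 0))
})

test_that("a missing design row aborts assembly naming the beam", {
  tabs <- cached_tables()
  broken <- tabs
  broken$beam_rows <- dplyr::filter(tabs$beam_rows,
                                    !(ion == "28Si" & energy_MeVu == 900))
  expect_error(design_reference_field("habitat", broken), "28Si")
})

test_that("tidy and glance expose the field at the right grain", {
  f <- cached_field("habitat")
  td <- tidy(f)
  expect_equal(nrow(td), nrow(f))
  expect_true(all(c("ion", "dose_mGy", "fluence_per_um2") %in% names(td)))
  g <- glance(f)
  expect_equal(g$n_hze_beams, 9)
  expect_equal(g$n_light_beams, 27)
  expect_equal(g$total_dose_mGy, sum(f$dose_mGy))
})
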