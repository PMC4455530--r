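# Multi-hit Poisson kinetics: hit rates, ODE ladder, Monte Carlo oracle.

test_that("hit rate is the fluence-rate area product", {
  expect_equal(hit_rate(0.02, 100), 2)
  expect_identical(hit_rate(0, 50), 0)
  expect_equal(hit_rate(0.01, 200), 2 * hit_rate(0.01, 100))
  expect_error(hit_rate(-1, 10), ">= 0")
})

test_that("annual proton fluence gives about one traversal per two days", {
  li <- cached_tables()$light_ions
  annual <- sum(li$fluence_per_um2[li$scenario == "habitat" & li$ion == "p"])
  hr <- hit_rate(annual / 365.25, 100)
  interval <- 1 / hr
  expect_gt(interval, 1.4)
  expect_lt(interval, 2.1)
})

test_that("parameter constructors enforce their invariants", {
  p <- kinetics_params(tau_relax_days = 7)
  expect_equal(p$decay_rate, log(2) / 7, tolerance = 1e-12)
  expect_error(kinetics_params(area_um2 = 0), "area")
  expect_error(kinetics_params(inactivation_per_hit = 1), "inactivation")
  expect_error(kinetics_params(max_hits = 3), "max_hits")
  expect_error(exposure_window(1, 0), "duration")
  expect_error(exposure_window(1, 2, duty_cycle = 1.5), "duty_cycle")
})

test_that("with no recovery or death the ladder is exactly Poisson", {
  p <- kinetics_params(area_um2 = 100, tau_relax_days = Inf,
                      inactivation_per_hit = 0, max_hits = 25)
  w <- exposure_window(0.03, 3)  # mean 3 hits by the end
  kin <- solve_hit_kinetics(p, w, times = seq(0, 3, length.out = 31))
  st <- tidy(kin)
  live <- st[st$hits != "dead", ]
  m <- 0.03 * 100 / 3 * live$time_days
  expect_lt(max(abs(live$fraction - dpois(as.integer(live$hits), m))), 1e-6)
})

test_that("a zero hit rate freezes the population", {
  kin <- solve_hit_kinetics(kinetics_params(), exposure_window(0, 5),
                            times = seq(0, 5, length.out = 11))
  st <- tidy(kin)
  expect_true(all(st$fraction[st$hits == "0"] == 1))
  expect_true(all(st$fraction[st$hits != "0"] == 0))
})

test_that("live plus dead mass is conserved across parameter settings", {
  grid <- expand.grid(tau = c(1, 7, Inf), q = c(0, 0.1, 0.5),
                      kin_rate = c(0, 0.05))
  for (i in seq_len(nrow(grid))) {
    p <- kinetics_params(area_um2 = 100, tau_relax_days = grid$tau[i],
                        inactivation_per_hit = grid$q[i],
                        death_rates = grid$kin_rate[i])
    kin <- solve_hit_kinetics(p, exposure_window(0.01, 2),
                              times = seq(0, 2, length.out = 21))
    mass <- kin$states %>%
      dplyr::group_by(time_days) %>%
      dplyr::summarise(m = sum(fraction))
    expect_lt(max(abs(mass$m - 1)), 1e-9)
  }
})

test_that("multi-hit fraction has a Poisson closed form in the pure limit", {
  p <- kinetics_params(area_um2 = 100, tau_relax_days = Inf,
                      inactivation_per_hit = 0, max_hits = 25)
  kin <- solve_hit_kinetics(p, exposure_window(0.02, 2),
                            times = seq(0, 2, length.out = 21))
  mh <- multi_hit_fraction(kin, 2)
  m <- 0.02 * 100 / 2 * mh$time_days
  expect_equal(mh$fraction, 1 - exp(-m) * (1 + m), tolerance = 1e-6)
  # all mass unhit -> zero for any k
  frozen <- solve_hit_kinetics(kinetics_params(), exposure_window(0, 1),
                               times = c(0, 1))
  expect_true(all(multi_hit_fraction(frozen, 1)$fraction == 0))
  expect_error(multi_hit_fraction(kin, 0), "k")
})

test_that("compressing a fixed fluence into fewer days raises multi-hits", {
  total <- 7.7e-3 * 100 / 100  # transfer-scale HZE fluence
  p <- kinetics_params(area_um2 = 100, tau_relax_days = 7)
  fr <- vapply(c(2, 10, 30), function(d) {
    end_frac_ge(solve_hit_kinetics(p, exposure_window(total, d),
                                   times = seq(0, d, length.out = 41)), 2)
  }, numeric(1))
  expect_true(all(diff(fr) < 0))
  # 2-day strictly exceeds 30-day
  expect_gt(fr[1], fr[3])
})

test_that("exceeding the hit-ladder truncation is an explicit error", {
  p <- kinetics_params(max_hits = 5)
  expect_error(
    solve_hit_kinetics(p, exposure_window(0.5, 2),
                       times = seq(0, 2, length.out = 11)),
    "max_hits")
})

test_that("duty cycling preserves the delivered fluence", {
  p <- kinetics_params(area_um2 = 100, tau_relax_days = Inf,
                      inactivation_per_hit = 0, max_hits = 25)
  cont <- solve_hit_kinetics(p, exposure_window(0.02, 3),
                             times = seq(0, 3, length.out = 13))
  duty <- solve_hit_kinetics(p, exposure_window(0.02, 3, duty_cycle = 1 / 3),
                             times = seq(0, 3, length.out = 13))
  # same Poisson mean at the end of each full day
  g1 <- glance(cont); g2 <- glance(duty)
  expect_equal(g2$frac_ge1, g1$frac_ge1, tolerance = 1e-6)
  expect_equal(g2$frac_ge2, g1$frac_ge2, tolerance = 1e-6)
})

test_that("Monte Carlo oracle is seed-reproducible and kills at q = 1 limit", {
  p <- kinetics_params(area_um2 = 100, tau_relax_days = 7,
                      inactivation_per_hit = 0.9)
  w <- exposure_window(7.7e-3, 2)
  a <- simulate_hit_counts(p, w, n_cells = 500, seed = 42)
  b <- simulate_hit_counts(p, w, n_cells = 500, seed = 42)
  expect_identical(a, b)
  # near-absorbing death: almost no live cell accumulates 2 hits
  last <- a[a$time_days == 2 & a$hits != "dead", ]
  ge2 <- sum(last$count[as.integer(last$hits) >= 2])
  expect_lt(ge2, 0.02 * 500)
})

test_that("ODE ladder agrees with the Monte Carlo oracle within 3 SE", {
  p <- kinetics_params(area_um2 = 100, tau_relax_days = 7)
  w <- exposure_window(7.7e-3, 2)
  n_cells <- 2e4
  mc <- simulate_hit_counts(p, w, n_cells = n_cells, seed = 9,
                            times = c(0, 1, 2))
  kin <- solve_hit_kinetics(p, w, times = c(0, 1, 2))
  joined <- dplyr::inner_join(mc, tidy(kin), by = c("time_days", "hits"),
                              suffix = c("_mc", "_ode"))
  se <- sqrt(pmax(joined$fraction_ode * (1 - joined$fraction_ode), 1e-12) /
               n_cells)
  expect_true(all(abs(joined$fraction_mc - joined$fraction_ode) <=
                    3 * se + 3 / n_cells))
})
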