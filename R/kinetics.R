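## Multi-hit Poisson kinetics of particle traversals.
##
## Cells (or sensitive tissue structures) of area A are traversed at the
## mean hit rate H_r = F * A.  The population is partitioned by
## accumulated hit number n_0, n_1, ..., n_N plus a dead pool:
##
##   dn_0/dt = -H_r n_0 + K_D sum_{i>=1} f_i n_i
##   dn_i/dt =  H_r (1 - q) n_{i-1} - (H_r + K_D + K_in,i) n_i
##
## K_D = ln2 / tau_relax resets ALL accumulated hits (flow from every n_i
## back to n_0), q branches a fraction of each hit transition into the
## dead pool ("inactivation per hit"), and K_in,i is an optional residence
## death rate.  Mass (live + dead) is conserved exactly.

#' Mean hit rate of a sensitive area
#'
#' `H_r = F * A`: the product of a fluence rate and the geometric
#' cross-sectional area it traverses.
#'
#' @param fluence_rate Particle fluence rate, /um^2 per day.
#' @param area_um2 Sensitive area, um^2.
#' @return Hit rate per day.
#' @examples
#' hit_rate(2.18 / 365.25, 100)  # ~0.6 traversals/day
#' @export
hit_rate <- function(fluence_rate, area_um2) {
  if (any(fluence_rate < 0) || any(area_um2 < 0)) {
    abort("fluence rate and area must be >= 0")
  }
  fluence_rate * area_um2
}

#' Kinetics parameters
#'
#' @param area_um2 Sensitive area A, um^2.
#' @param tau_relax_days Relaxation time of the hit-induced state (DNA
#'   repair, signalling), days; the recovery rate is `K_D = ln(2) / tau`.
#'   `Inf` disables recovery.
#' @param inactivation_per_hit Fraction q of each hit transition branched
#'   into the dead pool (default 0.1).
#' @param death_rates Per-state residence death rates `K_in(i)` (per day),
#'   recycled to `max_hits`; default 0.
#' @param survival_fractions Fractions `f_i` of recovering cells that
#'   rejoin the unhit pool (default 1: deaths are branched at hit time).
#' @param max_hits Truncation order N of the hit ladder.
#' @return A list of class `kinetics_params`.
#' @examples
#' kinetics_params(area_um2 = 100, tau_relax_days = 7)
#' @export
kinetics_params <- function(area_um2 = 100, tau_relax_days = 7,
                            inactivation_per_hit = 0.1, death_rates = 0,
                            survival_fractions = 1, max_hits = 30) {
  if (area_um2 <= 0) abort("area must be positive")
  if (tau_relax_days <= 0) abort("tau_relax must be positive")
  if (inactivation_per_hit < 0 || inactivation_per_hit >= 1) {
    abort("inactivation_per_hit must be in [0, 1)")
  }
  if (max_hits < 5) abort("max_hits must be at least 5")
  p <- list(
    area_um2 = area_um2,
    tau_relax_days = tau_relax_days,
    decay_rate = log(2) / tau_relax_days,
    inactivation_per_hit = inactivation_per_hit,
    death_rates = rep_len(death_rates, max_hits),
    survival_fractions = rep_len(survival_fractions, max_hits),
    max_hits = as.integer(max_hits)
  )
  structure(p, class = "kinetics_params")
}

#' Exposure window
#'
#' A total delivered fluence and the wall-clock duration it is spread
#' over.  `duty_cycle < 1` delivers the beam only during the first part of
#' each day (beam-on rate scaled up to preserve the total).
#'
#' @param total_fluence Total fluence over the window, /um^2.
#' @param duration_days Window length, days.
#' @param duty_cycle Fraction of each day with beam on, in (0, 1].
#' @return A list of class `exposure_window`.
#' @examples
#' exposure_window(7.7e-3, duration_days = 2)
#' @export
exposure_window <- function(total_fluence, duration_days, duty_cycle = 1) {
  if (total_fluence < 0) abort("total_fluence must be >= 0")
  if (duration_days <= 0) abort("duration must be positive")
  if (duty_cycle <= 0 || duty_cycle > 1) abort("duty_cycle must be in (0, 1]")
  structure(list(total_fluence = total_fluence,
                 duration_days = duration_days, duty_cycle = duty_cycle),
            class = "exposure_window")
}

# beam-on segments of the window: tibble(start, end, rate) covering
# [0, duration]; rate in hits/day given params$area
window_segments <- function(params, window) {
  mean_rate <- hit_rate(window$total_fluence / window$duration_days,
                        params$area_um2)
  if (window$duty_cycle == 1) {
    return(tibble(start = 0, end = window$duration_days, rate = mean_rate))
  }
  on_rate <- mean_rate / window$duty_cycle
  days <- seq_len(ceiling(window$duration_days)) - 1
  seg <- bind_rows(
    tibble(start = days, end = pmin(days + window$duty_cycle,
                                    window$duration_days), rate = on_rate),
    tibble(start = pmin(days + window$duty_cycle, window$duration_days),
           end = pmin(days + 1, window$duration_days), rate = 0)
  ) %>%
    filter(.data$end > .data$start) %>%
    arrange(.data$start)
  seg
}

#' Solve the multi-hit kinetics
#'
#' Integrates the hit-ladder ODE system over an exposure window with a
#' stiff-capable adaptive solver (deSolve lsoda, rtol 1e-8, atol 1e-12),
#' starting from the whole population unhit.  The truncation order is
#' checked a posteriori: if the top state accumulates more than 1e-9 of
#' the population the fit aborts with advice to raise `max_hits`.
#'
#' @param params A [kinetics_params()].
#' @param window An [exposure_window()].
#' @param times Output times in days (default: 201 points spanning the
#'   window).
#' @return An object of class `hit_kinetics`: list with `states` (tibble:
#'   `time_days`, `hits`, `fraction`, including a `"dead"` pseudo-state),
#'   `params`, `window`.
#' @examples
#' k <- solve_hit_kinetics(kinetics_params(), exposure_window(7.7e-3, 2))
#' glance(k)
#' @export
solve_hit_kinetics <- function(params, window, times = NULL) {
  stopifnot(inherits(params, "kinetics_params"),
            inherits(window, "exposure_window"))
  N <- params$max_hits
  if (is.null(times)) {
    times <- seq(0, window$duration_days, length.out = 201)
  }
  if (is.unsorted(times, strictly = TRUE) || times[1] != 0) {
    abort("times must be strictly increasing and start at 0")
  }
  if (max(times) > window$duration_days + 1e-9) {
    abort("times must lie inside the exposure window")
  }
  KD <- params$decay_rate
  q <- params$inactivation_per_hit
  Kin <- params$death_rates
  f <- params$survival_fractions

  rhs <- function(t, y, H) {
    n <- y[1:(N + 1)]
    hit_out <- H * n * c(rep(1, N), 0)      # no transitions out of n_N
    recov <- KD * n[-1]
    dn <- numeric(N + 1)
    dn[1] <- -H * n[1] + sum(f * recov)
    dn[-1] <- (1 - q) * hit_out[-(N + 1)] - hit_out[-1] - recov -
      Kin * n[-1]
    ddead <- q * sum(hit_out) + sum((1 - f) * recov) + sum(Kin * n[-1])
    list(c(dn, ddead))
  }

  segs <- window_segments(params, window)
  y <- c(1, rep(0, N), 0)
  out <- matrix(NA_real_, nrow = length(times), ncol = N + 2)
  out[1, ] <- y
  for (s in seq_len(nrow(segs))) {
    idx <- which(times > segs$start[s] + 1e-12 &
                   times <= segs$end[s] + 1e-12)
    seg_times <- unique(c(segs$start[s], times[idx], segs$end[s]))
    sol <- deSolve::lsoda(y, seg_times, rhs, parms = segs$rate[s],
                          rtol = 1e-8, atol = 1e-12)
    if (length(idx) > 0) {
      out[idx, ] <- sol[match(times[idx], sol[, 1]), -1, drop = FALSE]
    }
    y <- sol[nrow(sol), -1]
  }
  colnames(out) <- c(paste0("n", 0:N), "dead")

  if (max(out[, N + 1]) >= 1e-9) {
    abort(paste0("truncation violated: n_", N, " reached ",
                 signif(max(out[, N + 1]), 3),
                 "; increase max_hits"))
  }
  states <- as_tibble(out) %>%
    mutate(time_days = times) %>%
    tidyr::pivot_longer(-"time_days", names_to = "hits",
                        values_to = "fraction") %>%
    mutate(hits = ifelse(.data$hits == "dead", "dead",
                         sub("^n", "", .data$hits)))
  structure(list(states = states, params = params, window = window),
            class = "hit_kinetics")
}

#' @export
print.hit_kinetics <- function(x, ...) {
  g <- glance(x)
  cat("<hit_kinetics: ", x$window$duration_days, "-day window, H_r = ",
      signif(hit_rate(x$window$total_fluence / x$window$duration_days,
                      x$params$area_um2), 4), "/day>\n", sep = "")
  cat("  end of window: >=1 hit ", signif(100 * g$frac_ge1, 3),
      "%, >=2 hits ", signif(100 * g$frac_ge2, 3), "%, dead ",
      signif(100 * g$dead, 3), "%\n", sep = "")
  invisible(x)
}

#' Fraction of cells with at least k hits
#'
#' @param kin A [solve_hit_kinetics()] result.
#' @param k Minimum accumulated hit count (k >= 1).
#' @return Tibble `time_days`, `fraction` (live cells with >= k hits).
#' @examples
#' k <- solve_hit_kinetics(kinetics_params(), exposure_window(7.7e-3, 2))
#' tail(multi_hit_fraction(k, 2))
#' @export
multi_hit_fraction <- function(kin, k = 2) {
  stopifnot(inherits(kin, "hit_kinetics"))
  if (k < 1) abort("k must be >= 1")
  kin$states %>%
    filter(.data$hits != "dead") %>%
    mutate(h = as.integer(.data$hits)) %>%
    filter(.data$h >= k) %>%
    group_by(.data$time_days) %>%
    summarise(fraction = sum(.data$fraction), .groups = "drop")
}

#' Per-cell Monte Carlo oracle for the hit kinetics
#'
#' Simulates individual cells under the same model by thinning a
#' homogeneous event stream: candidate events arrive at the maximal total
#' rate, and each is accepted as a hit (probability proportional to the
#' instantaneous beam-on hit rate, killing the cell with probability q) or
#' as a full reset of the accumulated hits (rate K_D).  Used to validate
#' the deterministic ladder; reproducible for a fixed seed.
#'
#' @inheritParams solve_hit_kinetics
#' @param n_cells Number of cells to simulate (>= 1e4 for a useful check).
#' @param seed RNG seed.
#' @param times Output times (default: 21 points spanning the window).
#' @return Tibble `time_days`, `hits` (`"dead"` or an integer count),
#'   `count`, `fraction`.
#' @export
simulate_hit_counts <- function(params, window, n_cells = 1e4, seed = 1,
                                times = NULL) {
  stopifnot(inherits(params, "kinetics_params"),
            inherits(window, "exposure_window"))
  if (is.null(times)) {
    times <- seq(0, window$duration_days, length.out = 21)
  }
  segs <- window_segments(params, window)
  rate_at <- function(t) {
    segs$rate[findInterval(t, segs$start, rightmost.closed = TRUE)]
  }
  Hmax <- max(segs$rate)
  KD <- if (is.finite(params$decay_rate)) params$decay_rate else 0
  q <- params$inactivation_per_hit
  Rmax <- Hmax + KD
  N <- params$max_hits
  Tend <- window$duration_days
  nt <- length(times)

  counts <- matrix(0L, nrow = nt, ncol = N + 2,
                   dimnames = list(NULL, c(0:N, "dead")))
  withr::with_seed(seed, {
    for (cell in seq_len(n_cells)) {
      t <- 0; h <- 0L; alive <- TRUE; ptr <- 1L
      while (t < Tend) {
        t_next <- if (Rmax > 0) t + rexp(1, Rmax) else Tend
        upto <- min(t_next, Tend)
        while (ptr <= nt && times[ptr] <= upto + 1e-12) {
          counts[ptr, h + 1L] <- counts[ptr, h + 1L] + 1L
          ptr <- ptr + 1L
        }
        t <- t_next
        if (t >= Tend) break
        u <- runif(1) * Rmax
        if (u < rate_at(t)) {
          if (runif(1) < q) { alive <- FALSE; break }
          h <- min(h + 1L, N)
        } else if (u < rate_at(t) + KD) {
          h <- 0L
        }
      }
      if (!alive && ptr <= nt) {
        counts[ptr:nt, N + 2L] <- counts[ptr:nt, N + 2L] + 1L
      }
    }
  })
  as_tibble(counts) %>%
    mutate(time_days = times) %>%
    tidyr::pivot_longer(-"time_days", names_to = "hits",
                        values_to = "count") %>%
    mutate(fraction = .data$count / n_cells)
}
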