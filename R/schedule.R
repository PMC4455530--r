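## Fraction-by-fraction delivery schedules.
##
## In space the order of particle arrivals is random, weighted by each
## component's fluence; a delivery schedule emulates that with a seeded
## weighted shuffle of repeated beam fractions, switching beams at the
## accelerator's inter-fraction time.

#' Scheduling policy
#'
#' @param fractions_per_beam Number of fractions each beam-energy
#'   combination is split into (default 10).
#' @param switch_time_min Inter-fraction beam-switching time, minutes
#'   (default 1, the rapid-switching capability assumed for the design).
#' @param beam_on_min Beam-on time per fraction, minutes; 0 by default
#'   since switching dominates for small per-pulse particle numbers.
#' @param seed Base RNG seed; replicate experiments derive their own seed
#'   as `seed + replicate`.
#' @param weighting Fraction-ordering weights: each fraction is drawn
#'   proportionally to its beam's total `"fluence"` (default) or `"dose"`.
#' @return A list of class `schedule_policy`.
#' @examples
#' schedule_policy(seed = 42)
#' @export
schedule_policy <- function(fractions_per_beam = 10, switch_time_min = 1,
                            beam_on_min = 0, seed = 1,
                            weighting = c("fluence", "dose")) {
  weighting <- match.arg(weighting)
  if (fractions_per_beam < 1) abort("fractions_per_beam must be >= 1")
  if (switch_time_min <= 0) abort("switch_time must be positive")
  if (beam_on_min < 0) abort("beam_on time must be >= 0")
  structure(list(fractions_per_beam = as.integer(fractions_per_beam),
                 switch_time_min = switch_time_min,
                 beam_on_min = beam_on_min, seed = seed,
                 weighting = weighting),
            class = "schedule_policy")
}

# collapse a designed field to one row per deliverable beam: HZE
# primary/fragment components share a beam-energy combination
field_beams <- function(field) {
  field %>%
    group_by(.data$ion, .data$energy_MeVu) %>%
    summarise(absorber_gcm2 = max(.data$absorber_gcm2),
              dose_mGy = sum(.data$dose_mGy),
              fluence_per_um2 = sum(.data$fluence_per_um2),
              .groups = "drop")
}

#' Randomized fraction order for a designed field
#'
#' Expands every beam-energy combination of the field into
#' `fractions_per_beam` fractions and orders them by a seeded weighted
#' shuffle: fractions are drawn one at a time without replacement with
#' probability proportional to their beam weight (implemented via
#' exponential sort keys, so the order is reproducible bit-for-bit for a
#' given seed).  The fraction multiset is independent of the seed.
#'
#' @param field A [design_reference_field()] result (or any tibble with
#'   `ion`, `energy_MeVu`, `absorber_gcm2`, `dose_mGy`,
#'   `fluence_per_um2`).
#' @param policy A [schedule_policy()].
#' @param replicate Replicate index; shifts the seed so each replicate
#'   experiment gets its own reproducible order.
#' @return A tibble of class `gcr_schedule`: `index`, `ion`,
#'   `energy_MeVu`, `absorber_gcm2`, `pulses`, `t_min` (scheduled start,
#'   minutes from session start).
#' @examples
#' field <- design_reference_field("habitat")
#' sched <- schedule_exposures(field, schedule_policy(seed = 7))
#' nrow(sched)  # 36 beams x 10 fractions
#' @export
schedule_exposures <- function(field, policy = schedule_policy(),
                               replicate = 0) {
  if (nrow(field) == 0) abort("cannot schedule an empty field")
  beams <- field_beams(field)
  w <- switch(policy$weighting,
              fluence = beams$fluence_per_um2,
              dose = beams$dose_mGy)
  if (any(w <= 0)) abort("beam weights must be positive for ordering")
  fractions <- beams[rep(seq_len(nrow(beams)),
                         each = policy$fractions_per_beam), ]
  wf <- rep(w, each = policy$fractions_per_beam)
  keys <- withr::with_seed(policy$seed + replicate,
                           rexp(length(wf)) / wf)
  ord <- order(keys)
  out <- fractions[ord, ] %>%
    mutate(index = row_number(), pulses = 1L,
           t_min = (row_number() - 1) *
             (policy$switch_time_min + policy$beam_on_min)) %>%
    select("index", "ion", "energy_MeVu", "absorber_gcm2", "pulses",
           "t_min")
  attr(out, "policy") <- policy
  class(out) <- c("gcr_schedule", class(out))
  out
}

#' Session duration of a schedule
#'
#' Total wall-clock time: `fractions x (switch_time + beam_on_time)`.
#' At the default 1-min switching and ~360 fractions this is about 6 h;
#' re-weighting toward more proton/helium fractions stretches a session
#' to the 8-10 h scale.
#'
#' @param schedule A [schedule_exposures()] result.
#' @param policy The [schedule_policy()]; defaults to the one the
#'   schedule was built with.
#' @return Duration in minutes.
#' @examples
#' field <- design_reference_field("habitat")
#' sched <- schedule_exposures(field, schedule_policy(seed = 7))
#' session_duration(sched) / 60  # hours
#' @export
session_duration <- function(schedule, policy = attr(schedule, "policy")) {
  if (nrow(schedule) == 0) abort("empty schedule")
  nrow(schedule) * (policy$switch_time_min + policy$beam_on_min)
}
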