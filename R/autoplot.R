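## ggplot2 views of the result types.

#' Plot a designed reference field
#'
#' Bar chart of the per-beam dose budget, faceted by energy bin, with the
#' primary / fragments / light-ion components stacked per ion.
#'
#' @param object A `gcr_field`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gcr_field
#' @export
autoplot.gcr_field <- function(object, ...) {
  df <- tidy(object) %>%
    mutate(ion = factor(.data$ion, levels = unique(.data$ion)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ion, y = .data$dose_mGy,
                                   fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~energy_bin) +
    ggplot2::labs(
      title = paste0("Reference field dose budget (",
                     attr(object, "scenario"), ")"),
      x = NULL, y = "annual dose, mGy", fill = "component") +
    ggplot2::theme_minimal()
}

#' Plot multi-hit kinetics
#'
#' Time courses of the fractions of cells with exactly one and with two
#' or more accumulated hits, plus the dead fraction when present.
#'
#' @param object A `hit_kinetics` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot hit_kinetics
#' @export
autoplot.hit_kinetics <- function(object, ...) {
  states <- object$states
  live <- states[states$hits != "dead", ]
  h <- as.integer(live$hits)
  df <- bind_rows(
    live[h == 1, ] %>% group_by(.data$time_days) %>%
      summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
      mutate(curve = "1 hit"),
    live[h >= 2, ] %>% group_by(.data$time_days) %>%
      summarise(fraction = sum(.data$fraction), .groups = "drop") %>%
      mutate(curve = ">1 hit"),
    states[states$hits == "dead", ] %>%
      select("time_days", "fraction") %>% mutate(curve = "dead")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_days,
                                   y = 100 * .data$fraction,
                                   colour = .data$curve)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "exposure time, days", y = "% of cells",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a delivery schedule
#'
#' Timeline of the session: each fraction drawn at its scheduled time,
#' coloured by ion.
#'
#' @param object A `gcr_schedule`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot gcr_schedule
#' @export
autoplot.gcr_schedule <- function(object, ...) {
  df <- as_tibble(object) %>%
    mutate(beam = paste0(.data$ion, " ", .data$energy_MeVu))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t_min / 60, y = .data$beam,
                                   colour = .data$ion)) +
    ggplot2::geom_point(shape = 124, size = 3, show.legend = FALSE) +
    ggplot2::labs(x = "session time, h", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
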