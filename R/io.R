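## Writers and readers for designed fields and schedules.
##
## CSV: comma-separated, dot decimal, UTF-8, one header row; doubles are
## written with full (round-trip) precision.  JSON: one record per row
## plus the scenario, full precision.

#' Write / read a designed field
#'
#' @param field A [design_reference_field()] result.
#' @param path Output path; format from the extension (`.json` or `.csv`)
#'   unless `format` is given.
#' @param format `"json"` or `"csv"`.
#' @return `write_field()` the path, invisibly; `read_field()` a
#'   `gcr_field` tibble equal to the written one at full float precision.
#' @examples
#' f <- design_reference_field("habitat")
#' p <- tempfile(fileext = ".json")
#' write_field(f, p)
#' all.equal(read_field(p), f)
#' @export
write_field <- function(field, path, format = NULL) {
  format <- format %||% sub(".*\\.", "", path)
  if (format == "json") {
    payload <- list(scenario = attr(field, "scenario"),
                    beams = as_tibble(field))
    jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                         na = "null")
  } else if (format == "csv") {
    readr::write_csv(cbind(scenario = attr(field, "scenario"),
                           as_tibble(field)), path)
  } else {
    abort(paste0("unsupported field format '", format, "'"))
  }
  invisible(path)
}

#' @rdname write_field
#' @export
read_field <- function(path, format = NULL) {
  format <- format %||% sub(".*\\.", "", path)
  if (format == "json") {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    field <- as_tibble(payload$beams)
    scenario <- payload$scenario
  } else if (format == "csv") {
    # base parser: exact decimal -> double round trip
    field <- as_tibble(utils::read.csv(path))
    scenario <- field$scenario[1]
    field$scenario <- NULL
  } else {
    abort(paste0("unsupported field format '", format, "'"))
  }
  attr(field, "scenario") <- scenario
  class(field) <- c("gcr_field", class(field))
  field
}

#' Write / read a delivery schedule
#'
#' @param schedule A [schedule_exposures()] result.
#' @param path CSV path.
#' @return The path / the schedule tibble.
#' @export
write_schedule <- function(schedule, path) {
  readr::write_csv(as_tibble(schedule), path)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  out <- as_tibble(utils::read.csv(path))
  out$index <- as.integer(out$index)
  out$pulses <- as.integer(out$pulses)
  class(out) <- c("gcr_schedule", class(out))
  out
}
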