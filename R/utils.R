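## Printed-precision helpers.
##
## The design tables are transcribed at the precision they were printed.
## When a recomputed quantity is compared against a printed one, the match
## is judged at that precision: a printed value x with d decimals stands
## for anything in x +/- 0.5 * 10^-d, and a product of printed factors
## inherits the sum of their relative half-widths.

# number of decimals carried by the printed value (shortest d with
# round(x, d) == x)
printed_decimals <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(NA_integer_)
    for (d in 0:15) if (abs(round(v, d) - v) <= 1e-12 * max(1, abs(v))) {
      return(d)
    }
    15L
  }, integer(1))
}

# absolute half-width of the printed rounding interval
printed_half_ulp <- function(x) 0.5 * 10^-printed_decimals(x)

# relative half-width (NA-safe, 0 for NA inputs so they drop out of sums)
printed_rel_half_ulp <- function(x) {
  out <- printed_half_ulp(x) / abs(x)
  out[is.na(out)] <- 0
  out
}

# does `computed` reproduce `printed` once printing precision is honoured?
# `extra_rel` widens the band by the propagated rounding of the inputs the
# computation consumed.
matches_printed <- function(computed, printed, extra_rel = 0) {
  abs(computed - printed) <=
    printed_half_ulp(printed) + extra_rel * abs(printed) + 1e-12
}

# round to the number of significant figures a printed value carries
round_like <- function(computed, printed) {
  d <- printed_decimals(printed)
  round(computed, d)
}
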