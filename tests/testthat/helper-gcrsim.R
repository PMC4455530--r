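# shared fixtures: load the packaged tables once per test run
.cache <- new.env(parent = emptyenv())

cached_tables <- function() {
  if (is.null(.cache$tabs)) .cache$tabs <- gcr_tables()
  .cache$tabs
}

cached_field <- function(scenario) {
  key <- paste0("field_", scenario)
  if (is.null(.cache[[key]])) {
    .cache[[key]] <- design_reference_field(scenario, cached_tables())
  }
  .cache[[key]]
}

tissue <- function() {
  if (is.null(.cache$tissue)) .cache$tissue <- gcr_material("tissue")
  .cache$tissue
}

polyethylene <- function() {
  if (is.null(.cache$pe)) .cache$pe <- gcr_material("polyethylene")
  .cache$pe
}

# end-of-window live fraction with >= k hits
end_frac_ge <- function(kin, k) {
  mh <- multi_hit_fraction(kin, k)
  mh$fraction[which.max(mh$time_days)]
}
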