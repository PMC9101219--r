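# quick construction of glucose series for tests
make_series <- function(values, start = "2020-01-01 00:00:00",
                        interval_min = 5, id = NULL) {
  s <- tibble::tibble(
    timestamp = as.POSIXct(start, tz = "UTC") +
      (seq_along(values) - 1) * interval_min * 60,
    glucose = as.numeric(values))
  if (!is.null(id)) attr(s, "individual_id") <- id
  s
}

# all-corruption-off mess rates
no_mess <- list(null_row = 0, duplicate_row = 0, low_error_code = 0,
                high_spike = 0, alt_timestamp_format = 0)

# small clean in-memory cohort for cohort-level tests
make_clean_cohort <- function(n, days, seed, tag = "id", ...) {
  cfg <- synthetic_config(n_individuals = n, days_per_individual = days,
                          mess_rates = no_mess, seed = seed, ...)
  co <- generate_cohort(cfg, format = "clean")
  co
}
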