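#' Configuration for the synthetic CGM cohort generator
#'
#' Builds a validated configuration object for [generate_individual()] and
#' [generate_cohort()]. The generator emulates the structure of donated
#' Nightscout-style CGM data: ~5-minute sampling, a mean-reverting
#' first-order autoregressive (AR(1)) glucose process around a per-individual
#' baseline, an additive circadian sinusoid with a morning nadir, a
#' late-evening maximum in short-term variability, a seasonal dip in
#' variability over the summer months, a small positive mean offset for
#' female individuals, and realistic data mess (null strings, duplicated
#' timestamps, device error codes, implausible spikes, and mixed timestamp
#' dialects).
#'
#' @param n_individuals Number of individuals in the cohort.
#' @param days_per_individual Days of data per individual. A single number
#'   (same for everyone), a vector of length `n_individuals`, or `NULL` to
#'   sample per-individual durations from [sample_days_lognormal()] (median
#'   377 days, mirroring the donation-length distribution of large AID data
#'   commons).
#' @param sampling_interval Minutes between consecutive readings (default 5).
#' @param baseline_mean Cohort-level mean glucose in mg/dL (default 139).
#' @param baseline_sd Target per-individual process SD in mg/dL
#'   (default 49.8).
#' @param between_mean_sd SD of the between-individual spread of true mean
#'   glucose, mg/dL; individual means are truncated to \[70, 250\].
#' @param between_sd_sdlog Log-scale SD of the lognormal between-individual
#'   spread of true process SD.
#' @param circadian_amplitude Amplitude of the circadian mean sinusoid,
#'   mg/dL. The sinusoid minimum falls at the centre of the nadir clock hour
#'   so that the nadir hour is the unique lowest hour-of-day bucket in
#'   expectation.
#' @param circadian_nadir_hour Clock hour (0-23) of the circadian minimum.
#' @param sd_peak_hour Clock hour of maximum short-term variability.
#' @param sd_circadian_modulation Fractional amplitude of the circadian
#'   modulation of innovation SD.
#' @param seasonal_sd_modulation Fractional reduction of innovation SD at the
#'   mid-summer trough (smooth cosine over the year, minimum between June
#'   and July).
#' @param gender_mean_offset mg/dL added to the true mean of female
#'   individuals.
#' @param excursion_fraction Fraction of the residual (non-circadian)
#'   variance carried by the within-day excursion component: smooth random
#'   harmonics (periods 24/k h, k = 1..`excursion_harmonics`) with fresh
#'   Gaussian coefficients each day and an exactly zero mean over each day.
#'   This is the meal-scale structure of real CGM traces: large, smooth
#'   intraday swings that do not accumulate into day-to-day drift of the
#'   individual's mean.
#' @param excursion_harmonics Number of harmonics in the excursion
#'   component.
#' @param ar1_coefficient AR(1) coefficient per 5-minute lag, in \[0, 1),
#'   for the residual noise component. The per-step coefficient is
#'   `ar1_coefficient^(sampling_interval/5)`, so the process timescale does
#'   not depend on the sampling interval.
#' @param gender_counts Named integer vector `c(male=, female=)` giving the
#'   number of individuals reporting each gender; the remainder of the
#'   cohort has missing gender (default 50 male, 28 female, rest missing).
#'   Scaled proportionally when `n_individuals` differs from their total
#'   plus the default 44 missing.
#' @param mess_rates Named list of per-row corruption probabilities:
#'   `null_row`, `duplicate_row`, `low_error_code`, `high_spike`,
#'   `alt_timestamp_format`. Categories are mutually exclusive per row and
#'   their sum must be at most 1.
#' @param demog_spearman Named vector of target Spearman correlations for
#'   the demographics copula: `tdd_basal`, `weight_tdd`, `weight_basal`.
#' @param start_date_range Character vector of two dates; each individual's
#'   recording start date is drawn uniformly between them.
#' @param seed Integer seed; the same seed and configuration give
#'   bit-identical output.
#'
#' @return An object of class `cgm_synthetic_config` (a validated list).
#' @examples
#' cfg <- synthetic_config(n_individuals = 4, days_per_individual = 2, seed = 1)
#' cfg$baseline_mean
#' @export
synthetic_config <- function(n_individuals = 122,
                             days_per_individual = NULL,
                             sampling_interval = 5,
                             baseline_mean = 139,
                             baseline_sd = 49.8,
                             between_mean_sd = 30,
                             between_sd_sdlog = 0.2,
                             circadian_amplitude = 20,
                             circadian_nadir_hour = 8,
                             sd_peak_hour = 23,
                             sd_circadian_modulation = 0.1,
                             seasonal_sd_modulation = 0.15,
                             gender_mean_offset = 4,
                             excursion_fraction = 0.7,
                             excursion_harmonics = 3L,
                             ar1_coefficient = 0.95,
                             gender_counts = c(male = 50, female = 28),
                             mess_rates = list(),
                             demog_spearman = c(tdd_basal = 0.69,
                                                weight_tdd = 0.63,
                                                weight_basal = 0.61),
                             start_date_range = c("2016-01-01", "2020-12-31"),
                             seed = 20220502) {
  default_mess <- list(null_row = 0.005, duplicate_row = 0.005,
                       low_error_code = 0.002, high_spike = 0.0005,
                       alt_timestamp_format = 0.05)
  stopifnot(is.list(mess_rates))
  unknown <- setdiff(names(mess_rates), names(default_mess))
  if (length(unknown)) {
    stop("unknown mess_rates entries: ", paste(unknown, collapse = ", "))
  }
  mess <- utils::modifyList(default_mess, mess_rates)

  if (!is.numeric(n_individuals) || n_individuals < 1) {
    stop("n_individuals must be a positive count")
  }
  if (!is.numeric(sampling_interval) || sampling_interval <= 0) {
    stop("sampling_interval must be positive minutes")
  }
  if (!is.null(days_per_individual)) {
    if (any(days_per_individual <= 0)) stop("days_per_individual must be positive")
    if (!length(days_per_individual) %in% c(1L, as.integer(n_individuals))) {
      stop("days_per_individual must have length 1 or n_individuals")
    }
  }
  if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
    stop("ar1_coefficient must lie in [0, 1)")
  }
  if (excursion_fraction < 0 || excursion_fraction >= 1) {
    stop("excursion_fraction must lie in [0, 1)")
  }
  if (excursion_harmonics < 1) stop("excursion_harmonics must be >= 1")
  rates <- unlist(mess)
  if (any(rates < 0 | rates > 1)) stop("mess_rates must lie in [0, 1]")
  exclusive <- rates[c("null_row", "duplicate_row", "low_error_code", "high_spike")]
  if (sum(exclusive) > 1) stop("corruption mess_rates must sum to at most 1")
  if (baseline_sd < 0 || baseline_mean <= 0) {
    stop("baseline_mean must be positive and baseline_sd non-negative")
  }
  if (baseline_sd > 0 && baseline_sd^2 <= circadian_amplitude^2 / 2) {
    stop("baseline_sd too small for circadian_amplitude: ",
         "need baseline_sd^2 > circadian_amplitude^2 / 2")
  }
  if (!all(c("male", "female") %in% names(gender_counts))) {
    stop("gender_counts needs named entries male and female")
  }

  structure(list(
    n_individuals = as.integer(n_individuals),
    days_per_individual = days_per_individual,
    sampling_interval = sampling_interval,
    baseline_mean = baseline_mean,
    baseline_sd = baseline_sd,
    between_mean_sd = between_mean_sd,
    between_sd_sdlog = between_sd_sdlog,
    circadian_amplitude = circadian_amplitude,
    circadian_nadir_hour = circadian_nadir_hour,
    sd_peak_hour = sd_peak_hour,
    sd_circadian_modulation = sd_circadian_modulation,
    seasonal_sd_modulation = seasonal_sd_modulation,
    gender_mean_offset = gender_mean_offset,
    excursion_fraction = excursion_fraction,
    excursion_harmonics = as.integer(excursion_harmonics),
    ar1_coefficient = ar1_coefficient,
    gender_counts = gender_counts,
    mess_rates = mess,
    demog_spearman = demog_spearman,
    start_date_range = as.Date(start_date_range),
    seed = as.integer(seed)
  ), class = "cgm_synthetic_config")
}

#' Sample per-individual recording durations
#'
#' Donation lengths in community data commons are heavily right-skewed: many
#' individuals contribute a few months, a few contribute years. A lognormal
#' with median 377 days reproduces that shape.
#'
#' @param n Number of individuals.
#' @param median_days Median duration in days.
#' @param sdlog Log-scale SD.
#' @param min_days,max_days Truncation bounds.
#' @return Integer vector of day counts.
#' @export
sample_days_lognormal <- function(n, median_days = 377, sdlog = 0.6,
                                  min_days = 14, max_days = 1460) {
  d <- stats::rlnorm(n, meanlog = log(median_days), sdlog = sdlog)
  as.integer(pmin(pmax(round(d), min_days), max_days))
}

# Circadian mean component at clock-hour th (fractional hours): a sinusoid
# whose minimum sits at the centre of the nadir clock hour.
circadian_component <- function(th, amplitude, nadir_hour) {
  -amplitude * cos(2 * pi * (th - (nadir_hour + 0.5)) / 24)
}

#' Generate one synthetic individual's raw CGM entries
#'
#' Simulates the clean glucose process (AR(1) around baseline + circadian
#' sinusoid, innovation SD modulated by time of day and season), clips clean
#' values to \[40, 400\] so that every out-of-range value in the raw output
#' is attributable to injected corruption, then injects data mess according
#' to `config$mess_rates`. Corruption categories are mutually exclusive per
#' row and a duplicated row is always an uncorrupted copy, so the recorded
#' injection counts match a downstream cleaning audit exactly.
#'
#' @param config A [synthetic_config()].
#' @param individual_index 1-based index of the individual within the cohort
#'   (drives the per-individual RNG stream).
#' @param gender `"male"`, `"female"`, or `"missing"`; female individuals
#'   receive `gender_mean_offset` on their true mean.
#' @param days Number of days (default: resolved from the config).
#' @param start_date Recording start date (default: drawn from
#'   `config$start_date_range`).
#' @param format `"raw"` returns Nightscout-style rows with string timestamps
#'   and injected mess; `"clean"` returns the uncorrupted numeric series
#'   (requires all corruption rates to be zero) and is intended for large
#'   simulation studies where the string round-trip is irrelevant.
#' @return A list with `rows` (tibble: `dateString`, `sgv` for raw;
#'   `timestamp`, `glucose` for clean) and `truth`, a one-row tibble with
#'   the individual's true process mean and SD, gender, and exact injected
#'   mess counts per category.
#' @examples
#' cfg <- synthetic_config(n_individuals = 1, days_per_individual = 1, seed = 7)
#' out <- generate_individual(cfg, 1, gender = "male")
#' head(out$rows)
#' out$truth
#' @export
generate_individual <- function(config, individual_index,
                                gender = c("missing", "male", "female"),
                                days = NULL, start_date = NULL,
                                format = c("raw", "clean")) {
  stopifnot(inherits(config, "cgm_synthetic_config"))
  gender <- match.arg(gender)
  format <- match.arg(format)
  if (individual_index < 1 || individual_index > config$n_individuals) {
    stop("individual_index out of range")
  }
  set.seed(config$seed + 7919L * as.integer(individual_index))

  if (is.null(days)) {
    d <- config$days_per_individual
    days <- if (is.null(d)) {
      sample_days_lognormal(1)
    } else if (length(d) == 1L) d else d[[individual_index]]
  }
  days <- as.integer(days)
  if (days <= 0) stop("days must be a positive count")
  if (is.null(start_date)) {
    rng <- config$start_date_range
    start_date <- rng[1] + floor(runif(1) * (as.numeric(rng[2] - rng[1]) + 1))
  }
  start_date <- as.Date(start_date)

  # per-individual true process parameters
  true_mean <- config$baseline_mean +
    if (gender == "female") config$gender_mean_offset else 0
  if (config$between_mean_sd > 0) {
    true_mean <- min(max(rnorm(1, true_mean, config$between_mean_sd), 70), 250)
  }
  true_sd <- if (config$between_sd_sdlog > 0) {
    config$baseline_sd * stats::rlnorm(1, 0, config$between_sd_sdlog)
  } else {
    config$baseline_sd
  }
  # keep the AR component variance positive under the circadian amplitude
  min_sd <- sqrt(config$circadian_amplitude^2 / 2) * 1.05
  true_sd <- max(true_sd, min_sd)

  per_day <- as.integer(round(24 * 60 / config$sampling_interval))
  n <- days * per_day
  step_min <- config$sampling_interval
  secs <- (seq_len(n) - 1) * step_min * 60
  ts <- as.POSIXct(start_date, tz = "UTC") + secs
  th <- (secs / 3600) %% 24
  day_idx <- (seq_len(n) - 1) %/% per_day

  circ <- circadian_component(th, config$circadian_amplitude,
                              config$circadian_nadir_hour)
  resid_var <- true_sd^2 - config$circadian_amplitude^2 / 2
  exc_var <- resid_var * config$excursion_fraction
  ar_var <- resid_var - exc_var

  # seasonal modulation of the stochastic components, per day; normalised
  # to unit mean-square over the individual's days so the marginal SD stays
  # at true_sd while month-to-month SD ratios keep the seasonal shape
  day_dates <- start_date + unique(day_idx)
  season_day <- 1 - config$seasonal_sd_modulation *
    (0.5 + 0.5 * cos(2 * pi * (data.table::month(day_dates) - 6.5) / 12))
  season_day <- season_day / sqrt(mean(season_day^2))

  # within-day excursion: random harmonics, exactly day-mean-zero
  exc <- numeric(n)
  if (exc_var > 0) {
    K <- config$excursion_harmonics
    th_day <- th[seq_len(per_day)]
    basis_c <- sapply(seq_len(K), function(k) cos(2 * pi * k * th_day / 24))
    basis_s <- sapply(seq_len(K), function(k) sin(2 * pi * k * th_day / 24))
    sig_k <- sqrt(exc_var / K)
    a <- matrix(rnorm(days * K, 0, sig_k), days, K) * season_day
    b <- matrix(rnorm(days * K, 0, sig_k), days, K) * season_day
    exc <- as.numeric(t(a %*% t(basis_c) + b %*% t(basis_s)))
  }

  # AR(1) residual with circadian + seasonal innovation-SD modulation
  x <- numeric(n)
  if (ar_var > 0) {
    phi <- config$ar1_coefficient^(step_min / 5)
    innov_sd <- sqrt(ar_var * (1 - phi^2))
    burn <- 200L
    innov <- rnorm(n + burn)
    circ_mod <- 1 + config$sd_circadian_modulation *
      cos(2 * pi * (th - (config$sd_peak_hour + 0.5)) / 24)
    circ_mod <- circ_mod / sqrt(mean(circ_mod^2))
    innov[(burn + 1):(n + burn)] <- innov[(burn + 1):(n + burn)] *
      circ_mod * season_day[day_idx + 1]
    x <- as.numeric(stats::filter(innov * innov_sd, phi,
                                  method = "recursive"))[-seq_len(burn)]
  }
  glucose <- round(pmin(pmax(true_mean + circ + exc + x, 40), 400))

  if (format == "clean") {
    if (any(unlist(config$mess_rates[c("null_row", "duplicate_row",
                                       "low_error_code", "high_spike")]) > 0)) {
      stop("format = 'clean' requires all corruption mess_rates to be zero")
    }
    truth <- tibble::tibble(
      individual_index = individual_index, gender = gender,
      true_mean = true_mean, true_sd = true_sd,
      clean_mean = mean(glucose),
      clean_sd = if (n >= 2) sd(glucose) else NA_real_,
      days = days, start_date = start_date, n_rows_clean = n,
      n_null = 0L, n_duplicate = 0L, n_low_error = 0L,
      n_spike_clamped = 0L, n_spike_removed = 0L, n_alt_timestamp = 0L)
    return(list(rows = tibble::tibble(timestamp = ts, glucose = glucose),
                truth = truth))
  }

  # --- corruption injection (mutually exclusive categories per row) ---
  rates <- config$mess_rates
  u <- runif(n)
  cut1 <- rates$null_row
  cut2 <- cut1 + rates$duplicate_row
  cut3 <- cut2 + rates$low_error_code
  cut4 <- cut3 + rates$high_spike
  cat <- integer(n)                       # 0 clean, 1 null, 2 dup, 3 low, 4 spike
  cat[u < cut1] <- 1L
  cat[u >= cut1 & u < cut2] <- 2L
  cat[u >= cut2 & u < cut3] <- 3L
  cat[u >= cut3 & u < cut4] <- 4L

  sgv <- as.character(glucose)
  sgv[cat == 1L] <- "null"
  low_codes <- c(1, 2, 3, 5, 9, 10, 12, 38)  # device error terms, all < 39
  n_low <- sum(cat == 3L)
  if (n_low) sgv[cat == 3L] <- as.character(sample(low_codes, n_low, TRUE))
  n_spike <- sum(cat == 4L)
  spike_vals <- integer(0)
  if (n_spike) {
    spike_vals <- as.integer(round(runif(n_spike, 420, 1200)))
    sgv[cat == 4L] <- as.character(spike_vals)
  }

  # timestamp dialects
  date_str <- format_timestamp_dialects(ts, rates$alt_timestamp_format)

  rows <- tibble::tibble(dateString = date_str$str, sgv = sgv)
  dup_idx <- which(cat == 2L)
  if (length(dup_idx)) {
    # insert a verbatim copy immediately after each duplicated row
    ord <- sort(c(seq_len(n), dup_idx))
    rows <- rows[ord, ]
  }

  truth <- tibble::tibble(
    individual_index = individual_index, gender = gender,
    true_mean = true_mean, true_sd = true_sd,
    clean_mean = mean(glucose),
    clean_sd = if (n >= 2) sd(glucose) else NA_real_,
    days = days, start_date = start_date,
    n_rows_clean = sum(cat %in% c(0L, 2L)),
    n_null = sum(cat == 1L),
    n_duplicate = length(dup_idx),
    n_low_error = n_low,
    n_spike_clamped = sum(spike_vals > 400 & spike_vals <= 1000),
    n_spike_removed = sum(spike_vals > 1000),
    n_alt_timestamp = date_str$n_alt)
  list(rows = rows, truth = truth)
}

# Render POSIXct timestamps in the four dialects found in donated entries
# files: ISO-with-T/Z (the default), plain datetime, day-of-week prefixed,
# and timezone-abbreviation suffixed. All four are parseable downstream.
format_timestamp_dialects <- function(ts, alt_rate) {
  n <- length(ts)
  str <- format(ts, "%Y-%m-%dT%H:%M:%SZ")
  alt <- which(runif(n) < alt_rate)
  if (length(alt)) {
    plain <- format(ts[alt], "%Y-%m-%d %H:%M:%S")
    kind <- sample(3L, length(alt), TRUE)
    dows <- c("Mon", "Tue", "Wed", "Thu", "Fri", "Sat", "Sun")
    zones <- c("GMT", "PDT", "CES", "CST")
    wd <- dows[((as.integer(format(ts[alt], "%u")) - 1L) %% 7L) + 1L]
    str[alt] <- ifelse(kind == 1L, plain,
                ifelse(kind == 2L, paste(wd, plain),
                       paste(plain, sample(zones, length(alt), TRUE))))
  }
  list(str = str, n_alt = length(alt))
}

#' Generate a full synthetic cohort
#'
#' Draws per-individual durations, genders (default 50 male / 28 female with
#' the remainder unreported), generates each individual's raw entries via
#' [generate_individual()], builds a self-reported demographics table whose
#' (weight, total daily insulin, daily basal insulin) triplet follows a
#' Gaussian copula with strong positive rank dependence, and records the
#' full ground truth. With `out_dir` set, writes per-individual entries CSV
#' files (roughly a third of individuals split across 2-3 files to exercise
#' file merging), the demographics CSV, and a ground-truth JSON.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory, or `NULL` to return everything in
#'   memory.
#' @param format Passed to [generate_individual()].
#' @return A list with `entries` (named list of tibbles, one per
#'   individual), `demographics` (tibble), `truth` (tibble), and `paths`
#'   (when written to disk).
#' @examples
#' cfg <- synthetic_config(n_individuals = 3, days_per_individual = 1, seed = 2)
#' cohort <- generate_cohort(cfg)
#' cohort$demographics[, c("individual_id", "gender", "weight_kg")]
#' @export
generate_cohort <- function(config, out_dir = NULL,
                            format = c("raw", "clean")) {
  stopifnot(inherits(config, "cgm_synthetic_config"))
  format <- match.arg(format)
  n <- config$n_individuals

  set.seed(config$seed)
  ids <- sprintf("%08d", sample.int(99999999L, n))
  genders <- assign_genders(n, config$gender_counts)

  entries <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    out <- generate_individual(config, i, gender = genders[i], format = format)
    entries[[i]] <- out$rows
    truth[[i]] <- out$truth
  }
  truth <- dplyr::bind_rows(truth)
  truth$individual_id <- ids
  names(entries) <- ids

  demographics <- generate_demographics(config, ids, genders, truth)

  result <- list(entries = entries, demographics = demographics, truth = truth)
  if (!is.null(out_dir)) {
    result$paths <- write_cohort(result, out_dir, config)
  }
  result
}

assign_genders <- function(n, gender_counts) {
  n_m <- gender_counts[["male"]]
  n_f <- gender_counts[["female"]]
  ref_total <- n_m + n_f + 44          # default cohort shape: 44 unreported
  if (n == n_m + n_f) {
    g <- c(rep("male", n_m), rep("female", n_f))
  } else if (n == ref_total) {
    g <- c(rep("male", n_m), rep("female", n_f), rep("missing", n - n_m - n_f))
  } else {
    n_m2 <- round(n * n_m / ref_total)
    n_f2 <- round(n * n_f / ref_total)
    if (n_m2 + n_f2 > n) n_f2 <- n - n_m2
    g <- c(rep("male", n_m2), rep("female", n_f2),
           rep("missing", n - n_m2 - n_f2))
  }
  sample(g)
}

# Demographics table following the self-report survey schema. The numeric
# triplet (weight, total daily insulin, basal insulin) is drawn from a
# Gaussian copula with lognormal marginals; rank-correlation targets are
# converted to latent Pearson correlations via r = 2*sin(pi*rho/6).
generate_demographics <- function(config, ids, genders, truth) {
  n <- length(ids)
  rho <- config$demog_spearman
  r <- 2 * sin(pi * rho / 6)
  # order: weight, tdd, basal
  R <- matrix(c(1, r[["weight_tdd"]], r[["weight_basal"]],
                r[["weight_tdd"]], 1, r[["tdd_basal"]],
                r[["weight_basal"]], r[["tdd_basal"]], 1), 3, 3)
  ev <- eigen(R, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 1e-8))) %*% t(ev$vectors)
  z <- matrix(rnorm(3 * n), n, 3) %*% L
  u <- pnorm(z)
  weight <- round(stats::qlnorm(u[, 1], log(78), 0.18), 1)
  tdd <- round(stats::qlnorm(u[, 2], log(40), 0.35), 2)
  basal <- round(stats::qlnorm(u[, 3], log(20), 0.35), 2)

  age <- pmax(round(rnorm(n, 36, 12)), 6)
  ref <- as.Date("2021-06-01")
  birth_date <- ref - round(age * 365.25) - sample.int(300L, n, TRUE)
  diag_age <- pmin(pmax(round(age * stats::rbeta(n, 2, 4)), 1), age - 1)
  diagnosed_date <- birth_date + round(diag_age * 365.25)
  pump_date <- diagnosed_date + sample.int(3650L, n, TRUE)
  cgm_date <- diagnosed_date + sample.int(3650L, n, TRUE)
  loop_date <- pmax(pump_date, cgm_date) + sample.int(720L, n, TRUE)
  countries <- c("USA", "Germany", "UK", "Canada", "Australia", "Sweden",
                 "Netherlands", "France", "Italy", "Spain")
  country <- sample(countries, n, TRUE,
                    prob = c(45, 12, 6, rep(3, 7)))
  height <- round(rnorm(n, 172, 9), 1)
  carbs <- round(stats::qlnorm(runif(n), log(170), 0.4))
  hba1c <- round(pmin(pmax(rnorm(n, 6.6, 0.6), 4.8), 9.5), 1)
  hba1c_date <- ref - sample.int(400L, n, TRUE)
  aid_type <- sample(c("OpenAPS", "AndroidAPS", "Loop"), n, TRUE,
                     prob = c(0.4, 0.35, 0.25))

  demo <- tibble::tibble(
    individual_id = ids,
    gender = ifelse(genders == "missing", NA_character_, genders),
    date_of_birth = birth_date,
    diagnosed_date = diagnosed_date,
    date_of_pump_use = pump_date,
    date_of_cgm_use = cgm_date,
    date_of_loop_init = loop_date,
    country = country,
    weight_kg = weight,
    height_cm = height,
    total_daily_insulin_units = tdd,
    daily_basal_insulin_units = basal,
    total_daily_carbs = carbs,
    last_hba1c = hba1c,
    last_hba1c_date = hba1c_date,
    aid_type = aid_type)

  # field-level missingness mirroring the survey's missing-report counts
  # (per 122 respondents): pump 19, cgm 17, loop 20, aid type 15, birth 5,
  # country 1, weight 4, height 3, tdd 8, basal 3, carbs 17, hba1c 6.
  miss <- c(date_of_pump_use = 19, date_of_cgm_use = 17, date_of_loop_init = 20,
            aid_type = 15, date_of_birth = 5, country = 1, weight_kg = 4,
            height_cm = 3, total_daily_insulin_units = 8,
            daily_basal_insulin_units = 3, total_daily_carbs = 17,
            last_hba1c = 6, last_hba1c_date = 6)
  for (col in names(miss)) {
    k <- round(n * miss[[col]] / 122)
    if (k > 0) demo[[col]][sample.int(n, k)] <- NA
  }
  demo
}

write_cohort <- function(result, out_dir, config) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  ids <- names(result$entries)
  entry_paths <- list()
  for (i in seq_along(ids)) {
    id <- ids[i]
    dir_i <- file.path(out_dir, id)
    dir.create(dir_i, showWarnings = FALSE)
    rows <- result$entries[[i]]
    # every third individual is split across multiple files to exercise
    # the per-individual merge
    n_files <- if (i %% 3 == 0 && nrow(rows) >= 3) 2L + (i %% 2L) else 1L
    splits <- if (n_files == 1L) list(rows) else {
      split(rows, cut(seq_len(nrow(rows)), n_files, labels = FALSE))
    }
    paths <- character(n_files)
    for (j in seq_len(n_files)) {
      paths[j] <- file.path(dir_i, sprintf("entries_%02d.csv", j))
      data.table::fwrite(splits[[j]], paths[j])
    }
    entry_paths[[id]] <- paths
  }
  demo_path <- file.path(out_dir, "demographics.csv")
  data.table::fwrite(result$demographics, demo_path)
  truth_path <- file.path(out_dir, "ground_truth.json")
  truth <- result$truth
  truth$start_date <- as.character(truth$start_date)
  jsonlite::write_json(truth, truth_path, dataframe = "rows", digits = NA)
  list(entries = entry_paths, demographics = demo_path, truth = truth_path)
}
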