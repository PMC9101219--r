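profile_granularities <- c("hour_of_day", "day_of_week", "day_of_month",
                           "month")

bucket_levels <- function(granularity) {
  switch(granularity,
         hour_of_day = 0:23,
         day_of_week = 1:7,      # 1 = Monday ... 7 = Sunday
         day_of_month = 1:31,
         month = 1:12,
         stop("unknown granularity: ", granularity))
}

bucket_of <- function(timestamp, granularity) {
  switch(granularity,
         hour_of_day = data.table::hour(timestamp),
         day_of_week = (data.table::wday(timestamp) + 5L) %% 7L + 1L,
         day_of_month = data.table::mday(timestamp),
         month = data.table::month(timestamp))
}

#' Calendar-bucket statistics for one glucose series
#'
#' Buckets readings by a calendar component of their wall-clock timestamp
#' (hour of day 0-23, day of week Mon=1..Sun=7, day of month 1-31, or month
#' 1-12) and computes count, mean, SD, min, max and quartiles per bucket.
#' Every bucket of the granularity appears in the output; empty buckets
#' carry count 0 and missing statistics, and buckets with a single reading
#' have missing SD. Bucket counts always sum to the series length.
#'
#' @param series Cleaned series tibble (`timestamp`, `glucose`).
#' @param granularity One of `"hour_of_day"`, `"day_of_week"`,
#'   `"day_of_month"`, `"month"`.
#' @return Tibble: `granularity`, `bucket`, `count`, `mean`, `sd`, `min`,
#'   `max`, `q1`, `q2`, `q3` (plus `individual_id` when the series carries
#'   one).
#' @examples
#' s <- tibble::tibble(
#'   timestamp = as.POSIXct("2020-03-03 10:00:00", tz = "UTC") + 0:11 * 300,
#'   glucose = 100 + 0:11)
#' group_stats(s, "day_of_week")[3, ]
#' @export
group_stats <- function(series, granularity = profile_granularities) {
  granularity <- match.arg(granularity)
  assert_series(series, 1L)
  dt <- data.table::data.table(
    bucket = bucket_of(series$timestamp, granularity),
    glucose = series$glucose)
  stats <- dt[, {
    q <- quantile(glucose, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    list(count = .N, mean = mean(glucose),
         sd = if (.N >= 2) sd(glucose) else NA_real_,
         min = min(glucose), max = max(glucose),
         q1 = q[1], q2 = q[2], q3 = q[3])
  }, by = "bucket"]
  full <- data.table::data.table(bucket = bucket_levels(granularity))
  out <- stats[full, on = "bucket"]
  out$count[is.na(out$count)] <- 0L
  out <- tibble::as_tibble(out[order(out$bucket)])
  out <- dplyr::bind_cols(tibble::tibble(granularity = granularity,
                                         .rows = nrow(out)), out)
  id <- attr(series, "individual_id")
  if (!is.null(id)) {
    out <- dplyr::bind_cols(tibble::tibble(individual_id = id,
                                           .rows = nrow(out)), out)
  }
  out
}

#' Calendar-bucket profiles for a whole cohort
#'
#' @param series_list Named list of cleaned series tibbles.
#' @param granularity As in [group_stats()].
#' @return Tibble of per-individual bucket statistics.
#' @export
cohort_profiles <- function(series_list, granularity = profile_granularities) {
  granularity <- match.arg(granularity)
  rows <- lapply(names(series_list), function(id) {
    s <- series_list[[id]]
    attr(s, "individual_id") <- id
    group_stats(s, granularity)
  })
  dplyr::bind_rows(rows)
}

#' Gender-averaged calendar profiles
#'
#' Averages per-individual bucket statistics across the individuals of each
#' gender, weighting individuals equally regardless of how much data they
#' contributed: for each bucket, the unweighted mean of the per-individual
#' bucket means and likewise of the per-individual bucket SDs. Individuals
#' with no data in a bucket are excluded from that bucket's average, and
#' the number of contributors is reported. A pooled mode (all readings of a
#' gender pooled before computing bucket statistics) is available for
#' comparison.
#'
#' @param profiles Tibble from [cohort_profiles()] (per-individual mode)
#'   or a named list of series (required for pooled mode).
#' @param demographics Tibble with `individual_id` and `gender`.
#' @param mode `"per_individual"` (default) or `"pooled"`.
#' @param granularity Required for pooled mode.
#' @return Tibble: `gender`, `granularity`, `bucket`, `n_individuals`,
#'   `mean`, `sd` (in per-individual mode, `mean` is a mean of means and
#'   `sd` a mean of SDs).
#' @export
gender_averaged_profile <- function(profiles, demographics,
                                    mode = c("per_individual", "pooled"),
                                    granularity = NULL) {
  mode <- match.arg(mode)
  gend <- demographics[!is.na(demographics$gender),
                       c("individual_id", "gender")]
  if (nrow(gend) == 0) stop("no individuals with reported gender")

  if (mode == "pooled") {
    if (!is.list(profiles) || is.data.frame(profiles)) {
      stop("pooled mode requires the named list of series")
    }
    granularity <- match.arg(granularity, profile_granularities)
    rows <- lapply(seq_len(nrow(gend)), function(i) {
      id <- gend$individual_id[i]
      s <- profiles[[id]]
      if (is.null(s)) return(NULL)
      tibble::tibble(gender = gend$gender[i],
                     bucket = bucket_of(s$timestamp, granularity),
                     glucose = s$glucose)
    })
    pooled <- dplyr::bind_rows(rows)
    out <- pooled |>
      dplyr::group_by(.data$gender, .data$bucket) |>
      dplyr::summarise(n_individuals = NA_integer_,
                       mean = mean(.data$glucose),
                       sd = sd(.data$glucose), .groups = "drop")
    out$granularity <- granularity
    return(out[, c("gender", "granularity", "bucket", "n_individuals",
                   "mean", "sd")])
  }

  joined <- dplyr::inner_join(profiles, gend, by = "individual_id")
  if (nrow(joined) == 0) stop("no gendered individuals in profiles")
  joined |>
    dplyr::filter(.data$count > 0) |>
    dplyr::group_by(.data$gender, .data$granularity, .data$bucket) |>
    dplyr::summarise(n_individuals = dplyr::n(),
                     mean = mean(.data$mean),
                     sd = mean(.data$sd, na.rm = TRUE),
                     .groups = "drop")
}
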