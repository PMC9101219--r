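#' Risk-transform parameters for the blood-glucose risk indices
#'
#' The low/high blood-glucose indices (LBGI/HBGI) are built on a symmetrising
#' transform of the glucose scale,
#' `f(g) = scale * ((ln g)^log_exponent - centering)`, whose root lies at
#' about 112.5 mg/dL; readings below the root contribute to hypoglycemia
#' risk, readings above it to hyperglycemia risk, each with squared risk
#' `risk_multiplier * f(g)^2`. The constants are the published values of
#' the risk-index methodology and are exposed here as configuration rather
#' than hidden in code.
#'
#' @param scale,log_exponent,centering,risk_multiplier Transform constants.
#' @return A list of class `cgm_risk_params`.
#' @export
risk_transform_params <- function(scale = 1.509, log_exponent = 1.084,
                                  centering = 5.381, risk_multiplier = 10) {
  structure(list(scale = scale, log_exponent = log_exponent,
                 centering = centering, risk_multiplier = risk_multiplier),
            class = "cgm_risk_params")
}

assert_series <- function(series, min_n = 1L) {
  if (!is.data.frame(series) || !all(c("glucose") %in% names(series))) {
    stop("series must be a data frame with a glucose column")
  }
  if (nrow(series) < min_n) {
    stop("series needs at least ", min_n, " readings, has ", nrow(series))
  }
  invisible(series)
}

#' Pooled summary statistics of a glucose series
#'
#' Interday statistics over the full pooled reading series: count, mean,
#' min, max, quartiles (linear interpolation between order statistics),
#' IQR, sample SD (n-1 denominator), and CV as a percentage of the mean.
#'
#' @param series Cleaned series tibble with a `glucose` column.
#' @return One-row tibble: `count`, `mean`, `min`, `max`, `q1`, `q2`, `q3`,
#'   `iqr`, `sd`, `cv`.
#' @examples
#' summary_stats(tibble::tibble(glucose = c(70, 100, 180, 250)))
#' @export
summary_stats <- function(series) {
  assert_series(series, 2L)
  g <- series$glucose
  q <- unname(quantile(g, c(0.25, 0.5, 0.75), type = 7))
  m <- mean(g)
  s <- sd(g)
  tibble::tibble(count = length(g), mean = m, min = min(g), max = max(g),
                 q1 = q[1], q2 = q[2], q3 = q[3], iqr = q[3] - q[1],
                 sd = s, cv = 100 * s / m)
}

#' Time in / outside the target glucose range
#'
#' Percentage of readings inside the clinical target range \[70, 180\] mg/dL
#' (inclusive), strictly below 70 (hypoglycemia), and strictly above 180
#' (hyperglycemia). The three percentages partition the readings and sum to
#' exactly 100.
#'
#' @param series Cleaned series tibble.
#' @param lower,upper Range bounds in mg/dL.
#' @return One-row tibble: `tir`, `tor_below_70`, `tor_above_180`.
#' @examples
#' time_in_ranges(tibble::tibble(glucose = c(65, 100, 200, 180, 70)))
#' @export
time_in_ranges <- function(series, lower = 70, upper = 180) {
  assert_series(series, 1L)
  g <- series$glucose
  n <- length(g)
  tibble::tibble(tir = 100 * sum(g >= lower & g <= upper) / n,
                 tor_below_70 = 100 * sum(g < lower) / n,
                 tor_above_180 = 100 * sum(g > upper) / n)
}

#' Percentage of readings outside a k-SD band around the mean
#'
#' Percent of readings outside \[mean - k*SD, mean + k*SD\]. The SD multiple
#' `k` is a free parameter of the definition; the default of 1 reproduces
#' the ~28-29% seen for near-normal glucose distributions.
#'
#' @param series Cleaned series tibble (>= 2 readings).
#' @param k Positive SD multiple.
#' @return Percentage (scalar). A constant series (SD 0) returns 0.
#' @export
percent_outside_range <- function(series, k = 1) {
  assert_series(series, 2L)
  stopifnot(k > 0)
  g <- series$glucose
  s <- sd(g)
  if (s == 0) return(0)
  m <- mean(g)
  100 * sum(g < m - k * s | g > m + k * s) / length(g)
}

#' Low and high blood-glucose risk indices (LBGI / HBGI)
#'
#' Each reading is mapped through the risk transform of
#' [risk_transform_params()]; readings on the hypoglycemic side of the root
#' (f < 0) contribute `risk_multiplier * f^2` to LBGI and zero to HBGI, and
#' symmetrically for the hyperglycemic side. Both indices are means over
#' all readings, so they are non-negative and a constant euglycemic series
#' scores near zero on both.
#'
#' @param series Cleaned series tibble, all values positive.
#' @param params A [risk_transform_params()].
#' @return One-row tibble: `lbgi`, `hbgi`.
#' @examples
#' blood_glucose_risk_indices(tibble::tibble(glucose = rep(100, 10)))
#' @export
blood_glucose_risk_indices <- function(series,
                                       params = risk_transform_params()) {
  assert_series(series, 1L)
  g <- series$glucose
  if (any(g <= 0)) stop("glucose values must be positive")
  f <- params$scale * (log(g)^params$log_exponent - params$centering)
  r <- params$risk_multiplier * f^2
  tibble::tibble(lbgi = mean(ifelse(f < 0, r, 0)),
                 hbgi = mean(ifelse(f > 0, r, 0)))
}

#' J-index
#'
#' Combined magnitude-and-spread glycemic variability score:
#' `0.001 * (mean + SD)^2`, with mean and SD in mg/dL. Scales with the
#' square of the glucose scale.
#'
#' @param series Cleaned series tibble (>= 2 readings).
#' @return Scalar J-index.
#' @export
j_index <- function(series) {
  assert_series(series, 2L)
  g <- series$glucose
  0.001 * (mean(g) + sd(g))^2
}

#' Glucose management indicator (GMI)
#'
#' Expected HbA1c-equivalent percentage from mean glucose:
#' `3.31 + 0.02392 * mean` (mean in mg/dL). Strictly increasing in mean
#' glucose.
#'
#' @param series Cleaned series tibble.
#' @param intercept,slope Published regression constants of the indicator.
#' @return GMI in percent.
#' @examples
#' gmi(tibble::tibble(glucose = rep(139, 10)))
#' @export
gmi <- function(series, intercept = 3.31, slope = 0.02392) {
  assert_series(series, 1L)
  intercept + slope * mean(series$glucose)
}

#' Glucose rate of change between consecutive readings
#'
#' For each consecutive pair of readings with time gap `0 < dt <= max_gap`
#' minutes, the rate of change `(g_i - g_{i-1}) / dt` in mg/dL per minute.
#' Pairs spanning longer gaps (sensor outages) are skipped and counted, not
#' interpolated, to avoid spurious near-zero slopes across outages.
#'
#' @param series Cleaned series tibble with strictly increasing
#'   `timestamp`.
#' @param max_gap Maximum pair gap in minutes (default 30).
#' @return A list with `roc` (tibble: `midpoint` timestamp, `roc`),
#'   `roc_sd` (SD of the rates, n-1 denominator; `NA` with < 2 pairs), and
#'   `skipped_pairs`.
#' @examples
#' s <- tibble::tibble(
#'   timestamp = as.POSIXct("2020-01-01", tz = "UTC") + c(0, 300),
#'   glucose = c(100, 110))
#' rate_of_change(s)$roc$roc
#' @export
rate_of_change <- function(series, max_gap = 30) {
  assert_series(series, 2L)
  stopifnot(max_gap > 0, "timestamp" %in% names(series))
  t_num <- as.numeric(series$timestamp)
  dt <- diff(t_num) / 60
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  dv <- diff(series$glucose)
  keep <- dt <= max_gap
  roc <- dv[keep] / dt[keep]
  mid <- series$timestamp[-length(t_num)][keep] + (dt[keep] * 60) / 2
  list(roc = tibble::tibble(midpoint = mid, roc = roc),
       roc_sd = if (length(roc) >= 2) sd(roc) else NA_real_,
       skipped_pairs = sum(!keep))
}

#' Full per-individual glycemic-variability summary
#'
#' Composes every metric into one row: pooled summary statistics, time in
#' and outside range, percent outside the k-SD band, J-index, LBGI/HBGI,
#' GMI, and the SD of the glucose rate of change.
#'
#' @param series Cleaned series tibble (`timestamp`, `glucose`,
#'   >= 2 readings).
#' @param por_k SD multiple for [percent_outside_range()].
#' @param roc_max_gap Minutes, for [rate_of_change()].
#' @param risk_params A [risk_transform_params()].
#' @return One-row tibble with `individual_id` (if known) and all metric
#'   columns.
#' @export
gv_summary <- function(series, por_k = 1, roc_max_gap = 30,
                       risk_params = risk_transform_params()) {
  assert_series(series, 2L)
  stats <- summary_stats(series)
  ranges <- time_in_ranges(series)
  risk <- blood_glucose_risk_indices(series, risk_params)
  out <- dplyr::bind_cols(
    stats, ranges,
    tibble::tibble(por = percent_outside_range(series, por_k),
                   j_index = j_index(series)),
    risk,
    tibble::tibble(gmi = gmi(series),
                   roc_sd = rate_of_change(series, roc_max_gap)$roc_sd))
  id <- attr(series, "individual_id")
  if (!is.null(id)) out <- dplyr::bind_cols(tibble::tibble(individual_id = id), out)
  out
}

#' GV summaries for a whole cohort
#'
#' @param series_list Named list of cleaned series tibbles.
#' @param ... Passed to [gv_summary()].
#' @return Tibble, one row per individual.
#' @export
gv_summary_cohort <- function(series_list, ...) {
  stopifnot(is.list(series_list), length(series_list) > 0)
  rows <- lapply(names(series_list), function(id) {
    s <- series_list[[id]]
    attr(s, "individual_id") <- id
    gv_summary(s, ...)
  })
  dplyr::bind_rows(rows)
}
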