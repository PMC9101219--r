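#' Pairwise-complete Spearman correlation matrix
#'
#' Rank correlations between self-reported demographics features with
#' two-sided p-values, using pairwise-complete observations (mirroring
#' per-field missingness in voluntary surveys; no imputation). Pairs with
#' fewer than `min_n` complete observations are flagged missing. P-values
#' are reported raw; the number of tests performed is returned so callers
#' can judge multiplicity.
#'
#' @param demographics Data frame of demographics records.
#' @param features Character vector of numeric column names to correlate.
#' @param min_n Minimum pairwise-complete observations (default 3).
#' @return A list of class `cgm_correlation_matrix` with matrices `rho`,
#'   `p_value`, `n`, plus `features` and `n_tests`.
#' @export
spearman_matrix <- function(demographics, features, min_n = 3) {
  missing_cols <- setdiff(features, names(demographics))
  if (length(missing_cols)) {
    stop("unknown feature(s): ", paste(missing_cols, collapse = ", "))
  }
  k <- length(features)
  rho <- p <- n <- matrix(NA_real_, k, k, dimnames = list(features, features))
  diag(rho) <- 1
  diag(p) <- 0
  n_tests <- 0L
  for (i in seq_len(k)) {
    xi <- as.numeric(demographics[[features[i]]])
    diag(n)[i] <- sum(!is.na(xi))
    for (j in seq_len(k)) {
      if (j <= i) next
      xj <- as.numeric(demographics[[features[j]]])
      ok <- !is.na(xi) & !is.na(xj)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) >= min_n) {
        ct <- suppressWarnings(
          cor.test(xi[ok], xj[ok], method = "spearman", exact = FALSE))
        rho[i, j] <- rho[j, i] <- unname(ct$estimate)
        p[i, j] <- p[j, i] <- ct$p.value
        n_tests <- n_tests + 1L
      }
    }
  }
  structure(list(rho = rho, p_value = p, n = n, features = features,
                 n_tests = n_tests),
            class = "cgm_correlation_matrix")
}

#' @export
print.cgm_correlation_matrix <- function(x, digits = 2, ...) {
  cat("Spearman correlation matrix (pairwise complete), ",
      x$n_tests, " tests\n", sep = "")
  print(round(x$rho, digits))
  invisible(x)
}

#' Min-max normalise numeric columns to \[0, 1\]
#'
#' Scales each column as `(x - min) / (max - min)` over the pooled data.
#' When comparing strata (e.g. genders), normalisation is applied to the
#' pooled table *before* stratifying, so between-stratum ordering of any
#' monotone summary is preserved.
#'
#' @param table Data frame.
#' @param cols Columns to scale (default: all numeric columns).
#' @return The table with scaled columns.
#' @export
minmax_normalize <- function(table, cols = NULL) {
  if (is.null(cols)) {
    cols <- names(table)[vapply(table, is.numeric, logical(1))]
  }
  for (col in cols) {
    x <- table[[col]]
    rng <- range(x, na.rm = TRUE)
    if (!is.finite(rng[1]) || rng[1] == rng[2]) {
      stop("column has no spread (constant or all-missing): ", col)
    }
    table[[col]] <- (x - rng[1]) / (rng[2] - rng[1])
  }
  table
}

#' Shapiro-Wilk normality flag
#'
#' @param values Numeric sample, 3 <= n <= 5000, with non-zero spread.
#' @param alpha Significance level for the flag.
#' @return A list with `p_value` and `is_normal` (`p > alpha`).
#' @export
normality_flag <- function(values, alpha = 0.05) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000, n = ", n)
  if (diff(range(values)) == 0) stop("degenerate (constant) sample")
  p <- shapiro.test(values)$p.value
  list(p_value = p, is_normal = p > alpha)
}

#' Per-gender distribution summary of a GV metric
#'
#' Joins per-individual GV summaries with demographics, drops (and counts)
#' individuals with missing gender, and summarises the chosen metric per
#' gender: n, min, mean, max, quartiles, skewness sign, and a Shapiro-Wilk
#' normality flag.
#'
#' @param metrics Tibble from [gv_summary_cohort()] (needs
#'   `individual_id`).
#' @param demographics Demographics tibble with `individual_id` and
#'   `gender`.
#' @param metric Name of the metric column to summarise.
#' @return Tibble with one row per gender plus attribute `n_missing_gender`.
#' @export
stratify_by_gender <- function(metrics, demographics, metric) {
  if (!metric %in% names(metrics)) stop("unknown metric: ", metric)
  joined <- dplyr::inner_join(
    metrics, demographics[, c("individual_id", "gender")],
    by = "individual_id")
  n_missing <- sum(is.na(joined$gender))
  joined <- joined[!is.na(joined$gender), ]
  for (g in c("male", "female")) {
    if (sum(joined$gender == g) < 3) {
      stop("fewer than 3 individuals in stratum: ", g)
    }
  }
  # copy the metric into a scratch column: summary outputs named like the
  # metric (e.g. "mean") would otherwise mask the data column mid-summarise
  joined$.value <- joined[[metric]]
  out <- joined |>
    dplyr::group_by(.data$gender) |>
    dplyr::summarise(
      n = dplyr::n(),
      min = min(.data$.value),
      mean = mean(.data$.value),
      max = max(.data$.value),
      q1 = quantile(.data$.value, 0.25, type = 7),
      q2 = quantile(.data$.value, 0.5, type = 7),
      q3 = quantile(.data$.value, 0.75, type = 7),
      skew_sign = sign(mean((.data$.value - mean(.data$.value))^3)),
      shapiro_p = normality_flag(.data$.value)$p_value,
      is_normal = normality_flag(.data$.value)$is_normal,
      .groups = "drop")
  attr(out, "n_missing_gender") <- n_missing
  out
}

default_cluster_features <- function() {
  c("mean", "sd", "cv", "tir", "tor_below_70", "tor_above_180",
    "lbgi", "hbgi", "j_index", "gmi", "roc_sd")
}

#' Agglomerative clustering of glucose profiles
#'
#' Represents each individual's glucose profile as their z-scored GV-metric
#' vector (length-invariant across individuals with unequal recording
#' durations) and clusters with Euclidean distance and, by default, Ward
#' linkage. Returns the full merge tree, flat labels at the requested cut,
#' and the largest relative gap between successive merge heights — a small
#' gap means the dendrogram offers no natural cut, i.e. no distinct
#' clusters.
#'
#' @param metrics Tibble from [gv_summary_cohort()].
#' @param features Metric columns to use (default
#'   [default_cluster_features()]).
#' @param linkage hclust method: `"ward.D2"` (default), `"single"`,
#'   `"complete"`, or `"average"`.
#' @param k Number of flat clusters to cut (default 2); alternatively `h`,
#'   a cut height.
#' @param h Optional cut height (overrides `k`).
#' @param gap_threshold Relative merge-height gap above which the
#'   dendrogram is deemed to contain distinct clusters (default 2).
#' @return A list of class `cgm_cluster_result`: `hclust`, `labels`
#'   (named), `feature_matrix` (z-scored), `height_gap` (max ratio of
#'   successive merge heights), `distinct_clusters` (logical).
#' @export
cluster_profiles <- function(metrics, features = default_cluster_features(),
                             linkage = c("ward.D2", "single", "complete",
                                         "average"),
                             k = 2, h = NULL, gap_threshold = 2) {
  linkage <- match.arg(linkage)
  features <- intersect(features, names(metrics))
  if (nrow(metrics) < 2) stop("need at least 2 individuals to cluster")
  if (!is.null(k) && is.null(h) && k > nrow(metrics)) {
    stop("more clusters requested than individuals")
  }
  m <- as.matrix(metrics[, features])
  rownames(m) <- metrics$individual_id %||% as.character(seq_len(nrow(m)))
  keep <- apply(m, 2, function(col) stats::var(col, na.rm = TRUE) > 0)
  m <- m[, keep, drop = FALSE]
  z <- scale(m)
  hc <- hclust(dist(z, method = "euclidean"), method = linkage)
  labels <- if (!is.null(h)) cutree(hc, h = h) else cutree(hc, k = k)
  # relative gaps between successive merge heights, judged over the top of
  # the tree (early merges have near-zero heights and meaningless ratios)
  heights <- hc$height
  hh <- tail(heights[heights > 0], 11)
  gap <- if (length(hh) >= 2) max(hh[-1] / hh[-length(hh)]) else Inf
  structure(list(hclust = hc, labels = labels, feature_matrix = z,
                 height_gap = gap,
                 distinct_clusters = is.finite(gap) && gap > gap_threshold),
            class = "cgm_cluster_result")
}

#' @export
print.cgm_cluster_result <- function(x, ...) {
  cat("Agglomerative clustering of", nrow(x$feature_matrix), "profiles (",
      x$hclust$method, "linkage )\n")
  cat("flat clusters:", paste(table(x$labels), collapse = " / "),
      "| max merge-height gap ratio:", round(x$height_gap, 2),
      if (x$distinct_clusters) "(distinct clusters)" else "(no distinct clusters)",
      "\n")
  invisible(x)
}
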