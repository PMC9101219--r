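test_that("summary statistics use linear-interpolation quartiles and n-1 SD", {
  s <- make_series(c(70, 100, 180, 250))
  st <- summary_stats(s)
  expect_equal(st$q1, 92.5)
  expect_equal(st$q2, 140)
  expect_equal(st$q3, 197.5)
  expect_equal(st$iqr, 105)
  expect_equal(st$sd, sd(c(70, 100, 180, 250)))
  expect_equal(st$cv, 100 * st$sd / st$mean)

  const <- summary_stats(make_series(rep(100, 5)))
  expect_equal(const$mean, 100)
  expect_equal(const$sd, 0)
  expect_equal(const$cv, 0)
  expect_equal(const$iqr, 0)

  expect_error(summary_stats(make_series(numeric(0))), "at least")
  expect_error(summary_stats(make_series(100)), "at least")
})

test_that("time in range uses inclusive [70, 180] and partitions to 100", {
  r <- time_in_ranges(make_series(c(65, 100, 200, 180, 70)))
  expect_equal(r$tir, 60)
  expect_equal(r$tor_below_70, 20)
  expect_equal(r$tor_above_180, 20)
  expect_equal(unlist(time_in_ranges(make_series(rep(100, 4)))),
               c(tir = 100, tor_below_70 = 0, tor_above_180 = 0))
  expect_equal(unlist(time_in_ranges(make_series(rep(60, 4)))),
               c(tir = 0, tor_below_70 = 100, tor_above_180 = 0))
})

test_that("percent outside the k-SD band matches the normal closed form", {
  expect_equal(percent_outside_range(make_series(rep(100, 10))), 0)
  set.seed(1)
  g <- make_series(rnorm(2e5, 140, 30))
  expect_lt(abs(percent_outside_range(g, k = 1) - 31.73), 0.6)
  expect_lt(abs(percent_outside_range(g, k = 3) - 0.27), 0.12)
})

test_that("risk indices evaluate the published transform", {
  near_root <- blood_glucose_risk_indices(make_series(rep(112.5, 5)))
  expect_lt(near_root$lbgi, 0.01)
  expect_lt(near_root$hbgi, 0.01)

  at100 <- blood_glucose_risk_indices(make_series(rep(100, 5)))
  expect_equal(at100$lbgi, 0.4820511, tolerance = 1e-6)
  expect_equal(at100$hbgi, 0)

  at180 <- blood_glucose_risk_indices(make_series(rep(180, 5)))
  expect_equal(at180$lbgi, 0)
  expect_equal(at180$hbgi, 7.729312, tolerance = 1e-6)

  expect_error(blood_glucose_risk_indices(make_series(c(100, -5))), "positive")
})

test_that("j-index formula and quadratic scaling", {
  expect_equal(j_index(make_series(rep(100, 5))), 10)
  s <- make_series(c(110, 150, 139, 170, 95))
  expect_equal(j_index(make_series(s$glucose * 2)), 4 * j_index(s))
})

test_that("gmi is the linear map of mean glucose", {
  expect_equal(round(gmi(make_series(rep(139, 3))), 2), 6.63)
  expect_equal(gmi(make_series(rep(100, 3))), 5.702)
  expect_gt(gmi(make_series(rep(150, 3))), gmi(make_series(rep(140, 3))))
})

test_that("rate of change divides value change by minutes and skips long gaps", {
  s <- make_series(c(100, 110))
  expect_equal(rate_of_change(s)$roc$roc, 2)

  const <- rate_of_change(make_series(rep(120, 10)))
  expect_true(all(const$roc$roc == 0))
  expect_equal(const$roc_sd, 0)

  gappy <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") +
      c(0, 300, 600, 7200, 7500),
    glucose = c(100, 110, 105, 200, 210))
  out <- rate_of_change(gappy, max_gap = 30)
  expect_identical(out$skipped_pairs, 1L)
  expect_length(out$roc$roc, 3)
})

test_that("gv_summary composes components and is deterministic", {
  s <- make_series(rep(100, 10))
  g <- gv_summary(s)
  expect_equal(g$tir, 100)
  expect_equal(g$cv, 0)
  expect_equal(g$j_index, 10)
  expect_equal(g$hbgi, 0)
  expect_equal(g$gmi, 5.702)
  expect_equal(g$roc_sd, 0)
  expect_identical(gv_summary(s), gv_summary(s))
})

test_that("metric scale behaviour: CV invariant, SD linear, J-index quadratic", {
  set.seed(8)
  for (i in 1:10) {
    x <- runif(30, 60, 250)
    s1 <- make_series(x)
    s2 <- make_series(3 * x)
    a <- summary_stats(s1); b <- summary_stats(s2)
    expect_equal(b$cv, a$cv)
    expect_equal(b$sd, 3 * a$sd)
    expect_equal(j_index(s2), 9 * j_index(s1))
  }
})

test_that("partition identity holds exactly on random series", {
  set.seed(12)
  for (i in 1:50) {
    x <- round(runif(sample(2:40, 1), 39, 400))
    r <- time_in_ranges(make_series(x))
    expect_equal(r$tir + r$tor_below_70 + r$tor_above_180, 100,
                 tolerance = 1e-12)
  }
})

test_that("every metric matches the brute-force oracle on small series", {
  set.seed(99)
  for (i in 1:60) {
    n <- sample(3:20, 1)
    x <- round(runif(n, 40, 400))
    times <- cumsum(c(0, sample(c(5, 5, 5, 10, 45), n - 1, TRUE)))
    s <- tibble::tibble(
      timestamp = as.POSIXct("2020-01-01", tz = "UTC") + times * 60,
      glucose = x)
    g <- gv_summary(s)
    expect_equal(g$mean, oracle_mean(x), tolerance = 1e-9)
    expect_equal(g$sd, oracle_sd(x), tolerance = 1e-9)
    expect_equal(g$q1, oracle_quantile(x, 0.25), tolerance = 1e-9)
    expect_equal(g$q3, oracle_quantile(x, 0.75), tolerance = 1e-9)
    expect_equal(c(tir = g$tir, tor_below_70 = g$tor_below_70,
                   tor_above_180 = g$tor_above_180),
                 oracle_ranges(x), tolerance = 1e-9)
    expect_equal(g$por, oracle_por(x), tolerance = 1e-9)
    expect_equal(c(lbgi = g$lbgi, hbgi = g$hbgi), oracle_risk(x),
                 tolerance = 1e-9)
    expect_equal(g$j_index, oracle_j_index(x), tolerance = 1e-9)
    expect_equal(g$gmi, oracle_gmi(x), tolerance = 1e-9)
    expect_equal(g$roc_sd, oracle_roc_sd(times, x), tolerance = 1e-9)
  }
})
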