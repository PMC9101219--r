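test_that("all four timestamp dialects parse to the same wall-clock time", {
  expect_equal(parse_timestamp("2018-08-04T23:58:50Z"),
               as.POSIXct("2018-08-04 23:58:50", tz = "UTC"))
  expect_equal(parse_timestamp("2018-08-06 07:00:00"),
               as.POSIXct("2018-08-06 07:00:00", tz = "UTC"))
  expect_equal(parse_timestamp("Mon 2018-08-06 07:00:00"),
               as.POSIXct("2018-08-06 07:00:00", tz = "UTC"))
  for (tz in c("GMT", "PDT", "CES", "CST")) {
    expect_equal(parse_timestamp(paste("2018-08-04 23:58:50", tz)),
                 as.POSIXct("2018-08-04 23:58:50", tz = "UTC"),
                 label = tz)
  }
})

test_that("unparseable timestamps return NA rather than raising", {
  bad <- c("not-a-date", "", "2018-13-40 99:99:99", "2018-08-04 23:58:50 XYZ")
  out <- parse_timestamp(bad)
  expect_true(all(is.na(out)))
  expect_length(out, 4)
})

test_that("value cleaning applies removal and clamp rules with exact counters", {
  rows <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 1:6 * 300,
    value = c("38", "39", "100", "450", "1001", "null"))
  out <- clean_values(rows)
  expect_equal(out$rows$glucose, c(39, 100, 400))
  expect_identical(out$report$null_removed, 1L)
  expect_identical(out$report$below_39_removed, 1L)
  expect_identical(out$report$above_1000_removed, 1L)
  expect_identical(out$report$clamped_to_400, 1L)
  expect_identical(out$report$rows_in, 6L)
  expect_identical(out$report$rows_out, 3L)
})

test_that("already-clean values pass through with zero counters", {
  rows <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 1:2 * 300,
    value = c("70", "180"))
  out <- clean_values(rows)
  expect_equal(out$rows$glucose, c(70, 180))
  counts <- out$report[, c("null_removed", "nonfinite_removed",
                           "below_39_removed", "above_1000_removed",
                           "clamped_to_400")]
  expect_true(all(unlist(counts) == 0))
})

test_that("non-finite values drop and the 400 boundary is not clamped", {
  rows <- tibble::tibble(
    timestamp = as.POSIXct("2020-01-01", tz = "UTC") + 1:2 * 300,
    value = c("inf", "400"))
  out <- clean_values(rows)
  expect_equal(out$rows$glucose, 400)
  expect_identical(out$report$nonfinite_removed, 1L)
  expect_identical(out$report$clamped_to_400, 0L)
})

test_that("merge keeps the first entry per duplicated timestamp", {
  t0 <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  t1 <- t0 + 300
  rows <- tibble::tibble(timestamp = c(t0, t0, t1), glucose = c(100, 120, 110))
  out <- merge_and_deduplicate(rows)
  expect_equal(out$rows$glucose, c(100, 110))
  expect_identical(out$duplicates_removed, 1L)

  # disjoint files concatenate chronologically
  a <- make_series(rep(100, 10), start = "2020-01-01 00:00:00")
  b <- make_series(rep(120, 10), start = "2020-02-01 00:00:00")
  m <- merge_and_deduplicate(list(b, a))
  expect_identical(nrow(m$rows), 20L)
  expect_true(all(diff(m$rows$timestamp) > 0))

  # idempotence
  again <- merge_and_deduplicate(m$rows)
  expect_identical(again$rows, m$rows)
  expect_identical(again$duplicates_removed, 0L)
})

test_that("cleaning counters reconcile with rows in and out (conservation)", {
  cfg <- synthetic_config(n_individuals = 2, days_per_individual = 10, seed = 41)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, out_dir = dir)
  loaded <- load_cohort(dir)
  r <- loaded$reports
  expect_equal(r$rows_out,
               r$rows_in - r$null_removed - r$nonfinite_removed -
                 r$unparseable_timestamp_removed - r$below_39_removed -
                 r$above_1000_removed - r$duplicates_removed)
  for (s in loaded$series) {
    expect_true(all(s$glucose >= 39 & s$glucose <= 400))
    expect_true(all(diff(s$timestamp) > 0))
  }
})

test_that("cleaning a cleaned series is a no-op (idempotence)", {
  cfg <- synthetic_config(n_individuals = 1, days_per_individual = 5, seed = 43)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, out_dir = dir)
  id <- co$truth$individual_id[1]
  first <- load_individual(file.path(dir, id))

  redir <- withr::local_tempdir()
  dir.create(file.path(redir, id))
  rows <- tibble::tibble(
    dateString = format(first$series$timestamp, "%Y-%m-%dT%H:%M:%SZ"),
    sgv = as.character(first$series$glucose))
  data.table::fwrite(rows, file.path(redir, id, "entries_01.csv"))
  second <- load_individual(file.path(redir, id))
  expect_equal(second$series$glucose, first$series$glucose)
  counts <- second$report[, c("null_removed", "nonfinite_removed",
                              "unparseable_timestamp_removed",
                              "below_39_removed", "above_1000_removed",
                              "clamped_to_400", "duplicates_removed")]
  expect_true(all(unlist(counts) == 0))
})

test_that("an individual split across files equals the single-file load", {
  cfg <- synthetic_config(n_individuals = 1, days_per_individual = 6,
                          mess_rates = no_mess, seed = 47)
  out <- generate_individual(cfg, 1, gender = "female")
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "split"))
  dir.create(file.path(dir, "whole"))
  n <- nrow(out$rows)
  cuts <- list(1:500, 501:1100, 1101:n)
  for (j in 1:3) {
    data.table::fwrite(out$rows[cuts[[j]], ],
                       file.path(dir, "split", sprintf("entries_%02d.csv", j)))
  }
  data.table::fwrite(out$rows, file.path(dir, "whole", "entries_01.csv"))
  split_load <- load_individual(file.path(dir, "split"))
  whole_load <- load_individual(file.path(dir, "whole"))
  expect_equal(split_load$series$glucose, whole_load$series$glucose)
  expect_equal(split_load$series$timestamp, whole_load$series$timestamp)
})

test_that("json entries variant is accepted", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "x"))
  rows <- data.frame(dateString = c("2020-01-01T00:00:00Z",
                                    "2020-01-01T00:05:00Z"),
                     sgv = c("100", "110"))
  jsonlite::write_json(rows, file.path(dir, "x", "entries.json"))
  out <- load_individual(file.path(dir, "x"))
  expect_equal(out$series$glucose, c(100, 110))
})

test_that("clean series round-trips through the canonical CSV format", {
  s <- make_series(c(80, 120, 300))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clean_series(s, path)
  back <- read_clean_series(path)
  expect_equal(back$glucose, s$glucose)
  expect_equal(back$timestamp, s$timestamp)
})
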