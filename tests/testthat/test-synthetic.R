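test_that("configuration validation rejects invalid parameters", {
  expect_error(synthetic_config(sampling_interval = 0), "sampling_interval")
  expect_error(synthetic_config(n_individuals = 2, days_per_individual = -1),
               "days_per_individual")
  expect_error(synthetic_config(ar1_coefficient = 1), "ar1_coefficient")
  expect_error(synthetic_config(mess_rates = list(null_row = 1.5)), "mess_rates")
  expect_error(synthetic_config(mess_rates = list(bogus = 0.1)), "unknown")
  expect_error(synthetic_config(baseline_sd = 5, circadian_amplitude = 20),
               "circadian_amplitude")
  cfg <- synthetic_config(n_individuals = 2, days_per_individual = 1)
  expect_error(generate_individual(cfg, 3), "out of range")
})

test_that("degenerate configuration yields a constant series at baseline", {
  cfg <- synthetic_config(n_individuals = 1, days_per_individual = 2,
                          baseline_sd = 0, circadian_amplitude = 0,
                          between_mean_sd = 0, between_sd_sdlog = 0,
                          sd_circadian_modulation = 0,
                          mess_rates = no_mess, seed = 3)
  out <- generate_individual(cfg, 1, gender = "male")
  expect_true(all(out$rows$sgv == "139"))
  expect_equal(nrow(out$rows), 2 * 288)
})

test_that("identical seed and configuration give bit-identical output", {
  cfg <- synthetic_config(n_individuals = 3, days_per_individual = 2, seed = 9)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$entries, b$entries)
  expect_identical(a$demographics, b$demographics)
  expect_identical(a$truth, b$truth)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_cohort(cfg, out_dir = d1)
  generate_cohort(cfg, out_dir = d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  expect_identical(unname(tools::md5sum(file.path(d1, f1))),
                   unname(tools::md5sum(file.path(d2, f2))))
})

test_that("injected corruption counts follow their rates and are recorded exactly", {
  cfg <- synthetic_config(
    n_individuals = 1, days_per_individual = 35, seed = 21,
    mess_rates = list(null_row = 0, duplicate_row = 0, low_error_code = 0.01,
                      high_spike = 0, alt_timestamp_format = 0))
  out <- generate_individual(cfg, 1, gender = "male")
  n_rows <- 35L * 288L                    # 10,080 source rows
  n_low <- sum(suppressWarnings(as.numeric(out$rows$sgv)) < 39, na.rm = TRUE)
  expect_identical(n_low, as.integer(out$truth$n_low_error))
  # binomial expectation ~ 100 at rate 0.01
  expect_gt(out$truth$n_low_error, 60)
  expect_lt(out$truth$n_low_error, 140)
  expect_identical(nrow(out$rows), n_rows)  # no duplicates inserted
})

test_that("a 90-day individual at stated parameters recovers mean and SD", {
  cfg <- synthetic_config(n_individuals = 1, days_per_individual = 90,
                          baseline_mean = 139, baseline_sd = 49.8,
                          between_mean_sd = 0, between_sd_sdlog = 0,
                          mess_rates = no_mess, seed = 17)
  out <- generate_individual(cfg, 1, gender = "male")
  g <- as.numeric(out$rows$sgv)
  expect_lt(abs(mean(g) - 139), 3)
  expect_lt(abs(sd(g) - 49.8), 4)
})

test_that("cohort writes one directory per individual and a demographics row each", {
  cfg <- synthetic_config(n_individuals = 1, days_per_individual = 1,
                          mess_rates = no_mess, seed = 5)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg, out_dir = dir)
  dirs <- list.dirs(dir, recursive = FALSE)
  expect_length(dirs, 1)
  expect_identical(nrow(co$demographics), 1L)
  expect_true(file.exists(file.path(dir, "demographics.csv")))
  expect_true(file.exists(file.path(dir, "ground_truth.json")))
})

test_that("default gender ratio is 50 male / 28 female of 78 reporting", {
  cfg <- synthetic_config(n_individuals = 122, days_per_individual = 1, seed = 2)
  set.seed(cfg$seed)
  g <- table(factor(cgmgv:::assign_genders(122, cfg$gender_counts),
                    levels = c("male", "female", "missing")))
  expect_identical(unname(g[["male"]]), 50L)
  expect_identical(unname(g[["female"]]), 28L)
  expect_identical(unname(g[["missing"]]), 44L)
})

test_that("demographics copula recovers configured insulin-basal rank dependence", {
  cfg <- synthetic_config(n_individuals = 200, days_per_individual = 1, seed = 31)
  set.seed(cfg$seed)
  ids <- sprintf("%08d", 1:200)
  genders <- cgmgv:::assign_genders(200, cfg$gender_counts)
  demo <- cgmgv:::generate_demographics(cfg, ids, genders, NULL)
  rho <- suppressWarnings(cor.test(demo$total_daily_insulin_units,
                                   demo$daily_basal_insulin_units,
                                   method = "spearman", exact = FALSE))$estimate
  expect_lt(abs(rho - 0.69), 0.10)
  # all numeric fields positive when present
  for (col in c("weight_kg", "height_cm", "total_daily_insulin_units",
                "daily_basal_insulin_units", "total_daily_carbs", "last_hba1c")) {
    expect_true(all(demo[[col]] > 0, na.rm = TRUE), label = col)
  }
})

test_that("sampled durations are plausible and within bounds", {
  set.seed(1)
  d <- sample_days_lognormal(500)
  expect_true(all(d >= 14 & d <= 1460))
  expect_lt(abs(median(d) - 377), 40)
})
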