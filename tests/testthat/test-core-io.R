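test_that("CSV parsing builds records and rejects bad rows by index", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("body_size,wing",
               "10.5,4.2",
               "12.0,5.0",
               "15.5,6.1"), f)
  d <- read_individuals_csv(f)
  expect_s3_class(d, "allometry_data")
  expect_equal(nrow(d), 3)
  expect_equal(attr(d, "organs"), "wing")
  expect_equal(attr(d, "size_scale"), "raw")
  expect_equal(d$body_size, c(10.5, 12.0, 15.5))

  writeLines(c("body_size,wing",
               "10.5,4.2",
               "0,5.0",         # non-positive body size
               "12.0,banana",   # unparseable organ size
               "13.0,"), f)     # missing organ is fine
  expect_warning(d2 <- read_individuals_csv(f), "2, 3")
  expect_equal(nrow(d2), 2)
  expect_true(is.na(d2$wing[2]))

  writeLines(c("body_size,wing", "0,1", "-3,2"), f)
  expect_warning(expect_error(read_individuals_csv(f), "no usable rows"))
})

test_that("column mapping is honoured and missing mapped columns error", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("pupa,genotype,wing_area",
               "10,wt,4", "12,wt,5", "14,mut,6"), f)
  d <- read_individuals_csv(f, column_map = list(
    body_size = "pupa", group = "genotype",
    organs = c(wing = "wing_area")))
  expect_equal(attr(d, "organs"), "wing")
  expect_equal(d$group, c("wt", "wt", "mut"))

  expect_error(
    read_individuals_csv(f, column_map = list(body_size = "nope",
                                              organs = c(wing = "wing_area"))),
    "missing")
})

test_that("write/read CSV round-trips randomized datasets", {
  for (seed in c(11, 12, 13)) {
    d <- rand_raw_dataset(seed)
    f <- withr::local_tempfile(fileext = ".csv")
    write_dataset_csv(d, f)
    d2 <- read_individuals_csv(f, column_map = list(
      organs = c(wing = "wing", genital = "genital")))
    for (col in c("body_size", "wing", "genital"))
      expect_equal(d2[[col]], d[[col]], tolerance = 1e-12)
    expect_equal(d2$group, d$group)
    expect_equal(d2$treatment, d$treatment)
    expect_equal(d2$temperature, d$temperature)
  }
})

test_that("log transform is exact, reversible, and state-checked", {
  d <- allometry_data(data.frame(body_size = rep(100, 3),
                                 wing = c(10, 20, 40)))
  dl <- log_transform(d, base = 10)
  expect_equal(dl$body_size, rep(2, 3))
  expect_equal(attr(dl, "size_scale"), "log")
  expect_equal(attr(dl, "log_base"), 10)
  expect_error(log_transform(dl), "already")
  expect_error(log_transform(d, base = 1), "base")

  d <- rand_raw_dataset(21)
  back <- exp_transform(log_transform(d, base = exp(1)))
  expect_equal(back$body_size, d$body_size, tolerance = 1e-12)
  expect_equal(back$wing, d$wing, tolerance = 1e-12)
})

test_that("the allometric slope is invariant to the log base", {
  d <- rand_raw_dataset(31, n = 30)
  b_e <- allometric_coefficient(log_transform(d, exp(1)), "wing")
  b_10 <- allometric_coefficient(log_transform(d, 10), "wing")
  expect_equal(b_e$fit$slope, b_10$fit$slope, tolerance = 1e-12)
})

test_that("JSON results are schema-versioned, round-trip, deterministic", {
  fit <- sma(x = c(1, 2, 3, 4, 6), y = c(2.1, 3.9, 6.2, 8.0, 12.3))
  f1 <- withr::local_tempfile(fileext = ".json")
  f2 <- withr::local_tempfile(fileext = ".json")
  write_results_json(fit, f1, seed = 7, parameters = list(alpha = 0.05))
  write_results_json(fit, f2, seed = 7, parameters = list(alpha = 0.05))
  expect_identical(readLines(f1), readLines(f2))  # byte-identical

  back <- read_results_json(f1)
  expect_equal(back$schema_version, "1.0")
  expect_equal(back$result_type, "sma")
  expect_equal(back$seed, 7)
  for (fld in c("n", "slope", "intercept", "r", "alpha"))
    expect_equal(back$result[[fld]], fit[[fld]], tolerance = 1e-12)
  expect_equal(unlist(back$result$ci), fit$ci, tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(write_results_json(list(f = function(x) x),
                                  withr::local_tempfile()),
               "unserializable")
})

test_that("dataset constructor enforces positivity and vocabulary", {
  expect_error(allometry_data(data.frame(body_size = c(1, -2), wing = 1:2)),
               "non-positive")
  expect_error(allometry_data(data.frame(wing = 1:3)), "body_size")
  d <- rand_raw_dataset(41)
  expect_error(allometric_coefficient(log_transform(d), "antenna"),
               "unknown organ")
  sub <- filter_records(d, d$group == "g1")
  expect_s3_class(sub, "allometry_data")
  expect_equal(attr(sub, "organs"), c("wing", "genital"))
})
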