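test_that("record ingestion validates rows and reports rejections", {
  # 12-row fixture: 2 missing endpoints, all else valid -> 10 + 2
  rec <- make_records(sprintf("sp%02d", 1:12), latitude = 10)
  rec$endpoint_temp[c(3, 7)] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(rec, path, row.names = FALSE)
  out <- read_tolerance_table(path)
  expect_equal(nrow(out$records), 10)
  expect_equal(nrow(out$rejections), 2)
  expect_true(all(grepl("endpoint_temp", out$rejections$reason)))

  # unknown realm is an enum violation, not a silent drop
  rec2 <- make_records("spA")
  rec2$realm <- "estuarine"
  write.csv(rec2, path, row.names = FALSE)
  out2 <- read_tolerance_table(path)
  expect_equal(nrow(out2$records), 0)
  expect_match(out2$rejections$reason, "unknown realm")

  # empty table with a valid header
  write.csv(rec[0, ], path, row.names = FALSE)
  out3 <- read_tolerance_table(path)
  expect_equal(nrow(out3$records), 0)
  expect_equal(nrow(out3$rejections), 0)

  # missing required column is a schema error
  write.csv(rec[, setdiff(names(rec), "endpoint_temp")], path, row.names = FALSE)
  expect_error(read_tolerance_table(path), "schema error")

  # column mapping binds arbitrary source headers
  rec4 <- make_records("spA")
  names(rec4)[names(rec4) == "endpoint_temp"] <- "CTmax_C"
  write.csv(rec4, path, row.names = FALSE)
  out4 <- read_tolerance_table(path, schema_config = list(endpoint_temp = "CTmax_C"))
  expect_equal(out4$records$endpoint_temp, 35)
})

test_that("assay durations follow the ramp arithmetic and reported trials", {
  dyn <- make_records("spA", assay_type = "dynamic", endpoint_temp = 34,
                      start_temp = 25, ramp_rate = 18, trial_duration = NA)
  expect_equal(assay_duration(dyn), 0.5)

  stat <- make_records("spA", trial_duration = 24)
  expect_equal(assay_duration(stat), 24)

  # explicit reported duration preferred over the ramp-derived one
  both <- make_records("spA", assay_type = "dynamic", endpoint_temp = 34,
                       start_temp = 25, ramp_rate = 18, trial_duration = 2)
  expect_equal(assay_duration(both), 2)

  # endpoint below start is invalid methodology (caught at validation too)
  bad <- make_records("spA", assay_type = "dynamic", endpoint_temp = 34,
                      start_temp = 36, ramp_rate = 18, trial_duration = NA)
  expect_error(assay_duration(bad), "invalid methodology")
  expect_match(validate_tolerance_records(bad), "not above start")

  bad2 <- make_records("spA", assay_type = "dynamic", endpoint_temp = 34,
                       start_temp = 25, ramp_rate = -1, trial_duration = NA)
  expect_error(assay_duration(bad2), "invalid methodology")
})

test_that("1-hour standardisation matches the log-duration formula", {
  expect_equal(standardise_to_one_hour(38, 1, -1.26), 38)
  expect_equal(standardise_to_one_hour(38, 10, -1.26), 39.26)
  expect_equal(standardise_to_one_hour(40, 0.25, -1.26),
               40 + 1.26 * log10(0.25), tolerance = 1e-12)
  expect_equal(standardise_to_one_hour(40, 0.25, -1.26), 39.2414,
               tolerance = 1e-4)

  # natural-log base is honoured and never silently mixed
  sl <- structure(list(slope = -1.26, log_base = "natural"),
                  class = "duration_slope")
  expect_equal(standardise_to_one_hour(38, exp(1), sl), 38 + 1.26)

  expect_error(standardise_to_one_hour(38, 0, -1.26), "domain error")

  # for a negative slope, standardised values increase with duration
  d <- c(0.1, 0.5, 1, 5, 24, 96)
  v <- standardise_to_one_hour(35, d, -1.26)
  expect_true(all(diff(v) > 0))
  # idempotence at the reference duration: re-standardising a 1-h value is a no-op
  expect_equal(standardise_to_one_hour(v, 1, -1.26), v)
})

test_that("acclimation centring is per-species and leaves endpoints untouched", {
  rec <- make_records(c("A", "A", "A", "B"), acclimation_temp = c(15, 20, 25, 12),
                      endpoint_temp = c(30, 31, 32, 33))
  out <- centre_acclimation(rec)
  expect_equal(out$acclimation_std[out$species == "A"], c(-5, 0, 5))
  expect_equal(out$acclimation_std[out$species == "B"], 0)
  expect_equal(out$endpoint_temp, rec$endpoint_temp)
  # per-species means are exactly zero; the cross-species mean need not be
  mus <- tapply(out$acclimation_std, out$species, mean)
  expect_equal(as.numeric(mus), c(0, 0))

  # species with no acclimation data are excluded and reported
  rec2 <- rbind(rec, make_records("C", acclimation_temp = NA))
  out2 <- centre_acclimation(rec2)
  expect_false("C" %in% out2$species)
  expect_equal(attr(out2, "excluded")$species, "C")
})

test_that("median-latitude selection uses the lower-middle tie-break", {
  rec <- make_records(rep("A", 3), latitude = c(30, 10, 20))
  expect_equal(select_median_latitude(rec)$latitude, 20)
  rec4 <- make_records(rep("A", 4), latitude = c(10, 20, 30, 40))
  expect_equal(select_median_latitude(rec4)$latitude, 20)
  one <- make_records("A", latitude = 42)
  expect_equal(select_median_latitude(one)$latitude, 42)
  expect_error(select_median_latitude(make_records("A")), "missing latitude")
})

test_that("dataset accounting counts records, species and populations", {
  # 3 species x 2 latitudes x 2 acclimation temps = 12 records
  rec <- do.call(rbind, lapply(c("A", "B", "C"), function(s) {
    make_records(rep(s, 4), latitude = c(10, 10, 12, 12),
                 acclimation_temp = c(15, 25, 15, 25))
  }))
  tab <- dataset_summary(rec)
  all_row <- tab[tab$group == "all", ]
  expect_equal(all_row$records, 12)
  expect_equal(all_row$species, 3)
  expect_equal(all_row$populations, 6)
  expect_equal(all_row$pct_species_multi_population, 100)
  expect_equal(all_row$mean_n_acclimation_temps, 2)
  expect_equal(all_row$pct_species_multi_acclimation, 100)
  expect_equal(all_row$mean_range_acclimation, 10)
  expect_equal(all_row$mean_range_latitude, 2)

  empty <- dataset_summary(rec[0, ])
  expect_true(all(empty$records == 0) && all(empty$species == 0))
})

test_that("duration-slope bootstrap is deterministic and has a null at flat data", {
  set.seed(4)
  # null structure: tolerance unrelated to duration
  rec <- make_records(rep(sprintf("sp%02d", 1:20), each = 3),
                      trial_duration = rep(c(0.5, 4, 48), 20))
  rec$endpoint_temp <- 35 + rnorm(nrow(rec), 0, 0.3)
  s1 <- estimate_duration_slope(rec, n_bootstrap = 20, rng_seed = 9)
  expect_lt(abs(s1$slope), 0.15)

  s2 <- estimate_duration_slope(rec, n_bootstrap = 20, rng_seed = 9)
  expect_identical(s1$replicates, s2$replicates)

  flat <- make_records(sprintf("sp%02d", 1:5), trial_duration = 1)
  expect_error(estimate_duration_slope(flat), "unidentifiable")
  expect_error(estimate_duration_slope(rec, n_bootstrap = 0), "parameter error")
})
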