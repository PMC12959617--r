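test_that("simulated trees are unit-depth, reproducible pure-birth trees", {
  t2 <- simulate_tree(2, seed = 1)
  depths <- ape::node.depth.edgelength(t2)[1:2]
  expect_equal(depths, c(1, 1))

  ta <- simulate_tree(30, seed = 5)
  tb <- simulate_tree(30, seed = 5)
  expect_identical(ape::write.tree(ta), ape::write.tree(tb))

  t100 <- simulate_tree(100, seed = 2)
  expect_equal(length(unique(t100$tip.label)), 100)
  expect_equal(max(ape::node.depth.edgelength(t100)), 1)

  expect_error(simulate_tree(1), "parameter error")
})

test_that("noise-free temperature fields obey their closed forms", {
  grid <- grid_spec(10, 6)
  cubes <- simulate_temperature_cubes(grid, years = 2, noise_sd = 0, seed = 3)
  # climatological annual max = latitudinal mean + seasonal amplitude, exactly
  expected_m <- 27 - 24 * (abs(grid$lat) / 65)^1.3 +
    (1.5 + 8.5 * abs(grid$lat) / 65)
  expect_equal(climatological_annual_max(cubes$marine), expected_m,
               tolerance = 1e-10)
  # freshwater sits above marine by the configured total contrast
  expect_equal(climatological_annual_max(cubes$freshwater) -
                 climatological_annual_max(cubes$marine),
               rep(synthetic_truth()$realm_maxT_offset, length(grid$lat)),
               tolerance = 1e-10)

  # noise-free CV of a pure 52-week sinusoid: amplitude * sqrt(26/51) / mean
  amp <- 1.5 + 8.5 * abs(grid$lat) / 65
  meanK <- 27 - 24 * (abs(grid$lat) / 65)^1.3 + 273.15
  expect_equal(within_year_cv(cubes$marine), amp * sqrt(26 / 51) / meanK,
               tolerance = 1e-10)

  # near-equatorial cells with noise: CV close to the noise-only level
  grid_eq <- grid_spec(2, 4, lat_range = c(-0.5, 0.5))
  cube_eq <- simulate_temperature_cubes(grid_eq, years = 4, noise_sd = 0.8,
                                        seed = 4)$marine
  noise_only <- sqrt(1.5^2 * 26 / 51 + 0.8^2) / (300.15)
  expect_equal(mean(within_year_cv(cube_eq)), noise_only, tolerance = 0.1)
})

test_that("range bands are contiguous, clipped, and phylogenetically structured", {
  grid <- grid_spec(12, 5)
  tree <- simulate_tree(15, seed = 7)
  masks <- suppressWarnings(simulate_ranges(grid, tree, breadth = 1000, seed = 7))
  expect_equal(masks[[1]]$cells, seq_along(grid$lat))

  masks1 <- suppressWarnings(simulate_ranges(grid, tree, breadth = 1e-6, seed = 7))
  expect_lte(length(masks1[[3]]$cells), grid$nlon)

  # Brownian band centres: phylogenetic and geographic distance correlate
  cors <- vapply(1:10, function(s) {
    tr <- simulate_tree(25, seed = s + 100)
    mk <- suppressWarnings(simulate_ranges(grid_spec(20, 2), tr, seed = s))
    ctr <- attr(mk, "centres")
    pd <- ape::cophenetic.phylo(tr)[names(ctr), names(ctr)]
    gd <- abs(outer(ctr, ctr, "-"))
    lower <- lower.tri(pd)
    cor(pd[lower], gd[lower])
  }, numeric(1))
  expect_gt(mean(cors), 0.1)
})

test_that("record generation obeys its noise-free arithmetic", {
  tr <- simulate_tree(12, seed = 9)
  expo <- data.frame(species = tr$tip.label, realm = "marine",
                     max_habitat_temp = seq(10, 30, length.out = 12),
                     thermal_variability = 0.015)
  truth <- synthetic_truth(sigma_phylo = 0, sigma_species = 0, sigma_resid = 0,
                           anchor_resid_sd = 0)
  rec <- simulate_records(tr, expo, truth = truth,
                          design = list(n_acclim = 1, records_per_level = 3),
                          seed = 10)
  # correcting out the exact duration effect leaves tolerance exactly linear
  # in habitat maximum (one acclimation level -> centred acclimation is 0)
  ht1h <- standardise_to_one_hour(rec$endpoint_temp, assay_duration(rec),
                                  truth$duration_slope_true)
  fit <- lm(ht1h ~ expo$max_habitat_temp[match(rec$species, expo$species)])
  expect_equal(unname(coef(fit)), c(truth$intercept_true, truth$maxT_slope_true),
               tolerance = 1e-9)
  expect_lt(suppressWarnings(summary(fit)$sigma), 1e-9)  # exact fit

  # regressing endpoints on log10 duration within a species recovers the
  # generating slope exactly (doubling duration shifts by slope * log10(2))
  one <- rec[rec$species == rec$species[1], ]
  if (length(unique(round(assay_duration(one), 8))) > 1) {
    fit_d <- lm(one$endpoint_temp ~ log10(assay_duration(one)))
    expect_equal(unname(coef(fit_d)[2]), truth$duration_slope_true,
                 tolerance = 1e-9)
  }

  # acclimation design: centred values per species average zero and span the
  # requested spacing
  rec4 <- simulate_records(tr, expo, truth = truth,
                           design = list(n_acclim = 4, acclim_spacing = 3,
                                         records_per_level = 1), seed = 11)
  cent <- centre_acclimation(rec4)
  expect_equal(max(abs(tapply(cent$acclimation_std, cent$species, mean))), 0,
               tolerance = 1e-10)
  expect_equal(sort(unique(round(cent$acclimation_std, 6))),
               c(-4.5, -1.5, 1.5, 4.5))
})

test_that("bundles are deterministic and round-trip through disk", {
  cfg <- list(n_species = 8, grid = grid_spec(6, 4), years = 2,
              design = list(n_acclim = 2, records_per_level = 1))
  b1 <- make_bundle(cfg, seed = 99)
  b2 <- make_bundle(cfg, seed = 99)
  expect_identical(b1$records, b2$records)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))

  dir1 <- file.path(withr::local_tempdir(), "b1")
  dir2 <- file.path(withr::local_tempdir(), "b2")
  write_bundle(b1, dir1)
  write_bundle(b2, dir2)
  expect_identical(unname(tools::md5sum(file.path(dir1, "records.csv"))),
                   unname(tools::md5sum(file.path(dir2, "records.csv"))))

  back <- read_bundle(dir1)
  expect_equal(back$records$endpoint_temp, b1$records$endpoint_temp,
               tolerance = 1e-12)
  expect_equal(sort(names(back$masks)), sort(names(b1$masks)))
  expect_equal(back$truth$arr_base, b1$truth$arr_base)
  expect_equal(back$cubes$marine$values, b1$cubes$marine$values,
               tolerance = 1e-12)
})

test_that("generated worlds reproduce the qualitative realm ordering", {
  b <- make_bundle(list(n_species = 60, grid = grid_spec(10, 6), years = 3,
                        design = list(n_acclim = 3, records_per_level = 1)),
                   seed = 17)
  e <- b$exposure
  fw <- e$realm == "freshwater"
  ma <- e$realm == "marine"
  expect_gt(mean(e$max_habitat_temp[fw]), mean(e$max_habitat_temp[ma]))
  expect_gt(mean(e$thermal_variability[fw]), mean(e$thermal_variability[ma]))
  sp_eff <- attr(b$records, "species_effects")
  sp_eff <- merge(sp_eff, e, by = "species")
  expect_gt(mean(sp_eff$arr[sp_eff$realm == "freshwater"]),
            mean(sp_eff$arr[sp_eff$realm == "marine"]))
})
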