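#' Ground-truth parameter set for a synthetic study
#'
#' The generating counterparts of every fitted quantity: the log-duration
#' slope, the ARR structure (baseline, thermal-variability coefficient,
#' realm offsets, negative quadratic acclimation curvature), the habitat
#' slope of basal tolerance, the phylogenetic signal and variance
#' components, the freshwater-vs-marine habitat contrasts, and the
#' acclimation-anchor regression. Defaults are set to the study conditions:
#' duration slope -1.26 degrees C per log10-hour, overall ARR near 0.2 with
#' freshwater fishes more plastic, basal tolerance rising 0.46 degrees C per
#' degree of habitat maximum, freshwater habitats 3.23 degrees C hotter and
#' 0.0063 more variable (CV) than marine ones.
#'
#' @param ... Overrides for any field.
#' @return Object of class `synthetic_truth` (a named list).
#' @export
synthetic_truth <- function(...) {
  truth <- list(
    duration_slope_true = -1.26,
    log_base = "log10",
    arr_base = 0.12,              # ARR of a marine species at zero CV
    arr_tvar_coef = 3.0,          # ARR gain per unit CV
    arr_realm_offsets = c(marine = 0, freshwater = 0.06, brackish = 0.05),
    quad_accT_coef = -0.015,      # curvature of tolerance in acclimation
    maxT_slope_true = 0.46,
    intercept_true = 20,
    lambda_true = 0.8,
    sigma_phylo = 2.5,
    sigma_species = 1.5,
    sigma_resid = 0.75,
    realm_maxT_offset = 3.23,     # freshwater - marine annual maxima
    realm_cv_offset = 0.0063,     # freshwater - marine within-year CV
    anchor_intercept = 4,         # actual AccT ~ a + b * MaxHabitatT
    anchor_slope = 0.8,
    anchor_resid_sd = 1.5,
    seed = NA_integer_
  )
  over <- list(...)
  stopifnot(all(names(over) %in% names(truth)))
  truth[names(over)] <- over
  stopifnot(truth$arr_base >= 0, truth$arr_base < 1,
            truth$quad_accT_coef <= 0,
            truth$sigma_phylo >= 0, truth$sigma_species >= 0,
            truth$sigma_resid >= 0)
  class(truth) <- "synthetic_truth"
  truth
}

#' Simulate a pure-birth phylogeny scaled to unit depth
#'
#' @param n_species Number of tips (>= 2).
#' @param seed Integer seed; the Newick string is deterministic per seed.
#' @return An ultrametric `ape::phylo` with tips `sp001`, `sp002`, ... and
#'   root-to-tip depth 1.
#' @export
simulate_tree <- function(n_species, seed = 1) {
  if (n_species < 2) stop("parameter error: n_species must be >= 2")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  tree <- ape::rphylo(n_species, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("sp%03d", seq_len(n_species))
  tree
}

#' Default grid specification for synthetic temperature fields
#'
#' @param nlat,nlon Grid dimensions.
#' @param lat_range Latitudinal extent of cell centres.
#' @return List describing the grid, with per-cell `lat`/`lon` vectors
#'   (cells ordered latitude-major).
#' @export
grid_spec <- function(nlat = 20, nlon = 20, lat_range = c(-65, 65)) {
  lats <- seq(lat_range[1], lat_range[2], length.out = nlat)
  lons <- seq(-180, 180, length.out = nlon + 1)[seq_len(nlon)]
  list(nlat = nlat, nlon = nlon, lat_range = lat_range,
       lat = rep(lats, each = nlon), lon = rep(lons, times = nlat),
       row_lat = lats)
}

# deterministic components of the synthetic climate, degrees C / Kelvin
climate_mean_C <- function(lat) 27 - 24 * (abs(lat) / 65)^1.3
climate_amplitude_K <- function(lat) 1.5 + 8.5 * (abs(lat) / 65)

#' Simulate freshwater and marine weekly temperature cubes
#'
#' Each cell's weekly temperature is a latitudinal mean gradient (warm
#' equator, cold poles) plus a seasonal sinusoid whose amplitude grows with
#' absolute latitude (peaking mid-year in the north, at year turn in the
#' south, so the 52-week grid hits the crest exactly), plus Gaussian noise.
#' The freshwater field is warmer and more seasonal than the marine one:
#' the truth's `realm_cv_offset` sets an extra freshwater amplitude (via
#' the CV of a sinusoid, amplitude/sqrt(2)/mean), and `realm_maxT_offset`
#' fixes the total freshwater-minus-marine contrast in annual maxima, so
#' the exposure pipeline should recover both contrasts. Noise-free, the
#' climatological annual maximum is exactly mean + amplitude.
#'
#' @param grid A [grid_spec()].
#' @param years Number of years.
#' @param truth A [synthetic_truth()] (realm offsets are read from it).
#' @param noise_sd Weekly Gaussian noise, Kelvin.
#' @param seed Integer seed.
#' @return List with `freshwater` and `marine` [temp_cube()]s.
#' @export
simulate_temperature_cubes <- function(grid, years = 10,
                                       truth = synthetic_truth(),
                                       noise_sd = 0.5, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  n_cells <- length(grid$lat)
  weeks <- 1:52
  t_ref <- 288.15
  amp_offset <- truth$realm_cv_offset * sqrt(2) * t_ref
  mean_offset <- truth$realm_maxT_offset - amp_offset

  build <- function(realm) {
    meanK <- climate_mean_C(grid$lat) + 273.15
    amp <- climate_amplitude_K(grid$lat)
    if (realm == "freshwater") {
      meanK <- meanK + mean_offset
      amp <- amp + amp_offset
    }
    peak <- ifelse(grid$lat >= 0, 13, 39)
    seasonal <- amp * cos(outer(2 * pi * (-peak) / 52, 2 * pi * weeks / 52, "+"))
    arr <- array(NA_real_, c(n_cells, 52, years))
    for (yr in seq_len(years)) {
      arr[, , yr] <- meanK + seasonal +
        if (noise_sd > 0) matrix(stats::rnorm(n_cells * 52, 0, noise_sd),
                                 n_cells, 52) else 0
    }
    temp_cube(arr, grid$lat, grid$lon, seq_len(years) + 1975, realm = realm,
              units = "K")
  }
  list(freshwater = build("freshwater"), marine = build("marine"))
}

#' Simulate phylogenetically structured latitudinal-band range masks
#'
#' Each species occupies a contiguous latitudinal band (all longitudes).
#' Band centres evolve by Brownian motion on the tree, so geographically
#' (hence thermally) similar species are also close phylogenetically, and
#' habitat exposure inherits phylogenetic structure.
#'
#' @param grid A [grid_spec()].
#' @param tree Tree whose tips name the species.
#' @param breadth Band breadth in degrees latitude (scalar or per species).
#' @param seed Integer seed.
#' @return Named list of [range_mask()]s (plus attribute `centres`).
#' @export
simulate_ranges <- function(grid, tree, breadth = 20, seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  raw <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  span <- diff(grid$lat_range)
  centre <- grid$lat_range[1] + span * stats::pnorm(raw / stats::sd(raw))
  breadth <- rep_len(breadth, length(centre))
  masks <- stats::setNames(vector("list", length(centre)), names(centre))
  clipped <- 0L
  for (i in seq_along(centre)) {
    lo <- centre[i] - breadth[i] / 2
    hi <- centre[i] + breadth[i] / 2
    if (lo < grid$lat_range[1] || hi > grid$lat_range[2]) clipped <- clipped + 1L
    cells <- which(grid$lat >= lo & grid$lat <= hi)
    if (length(cells) == 0) {
      cells <- which(abs(grid$lat - centre[i]) == min(abs(grid$lat - centre[i])))
    }
    masks[[i]] <- range_mask(names(centre)[i], cells, source = "synthetic")
  }
  if (clipped > 0) warning(clipped, " range band(s) clipped to the grid")
  attr(masks, "centres") <- centre
  masks
}

#' Simulate assay records with known tolerance structure
#'
#' Builds a record table whose generating model mirrors the fitted one:
#' species basal (1-h) tolerance is an intercept plus `maxT_slope_true`
#' times the species' maximum habitat temperature plus a lambda-scaled
#' Brownian phylogenetic deviate (sd `sigma_phylo`) plus an iid species
#' deviate (sd `sigma_species`); each record then adds the contextual ARR
#' (baseline + thermal-variability coefficient x species CV + realm
#' offset) times the centred acclimation temperature, the negative
#' quadratic acclimation term, the duration effect
#' (`duration_slope_true` x log10 duration), and residual noise. Assays
#' are a mix of static trials (long fixed durations) and dynamic ramps
#' (start temperature and ramp rate reported; duration derivable), with
#' actual acclimation temperatures tied to habitat maxima through the
#' anchor regression.
#'
#' @param tree Tree over the species.
#' @param exposure Data.frame (species, realm, max_habitat_temp,
#'   thermal_variability) — typically the pipeline's own exposure output on
#'   the simulated cubes, so recovery is tested end to end.
#' @param truth A [synthetic_truth()].
#' @param design List: `n_acclim` levels per species (default 4),
#'   `acclim_spacing` degrees between levels (default 3),
#'   `records_per_level` (default 2), `prop_dynamic` (default 0.5),
#'   `n_latitudes` collection latitudes per species (default 2),
#'   `latitudes` optional named per-species latitude.
#' @param seed Integer seed.
#' @return Data.frame of records in the canonical input schema.
#' @export
simulate_records <- function(tree, exposure, truth = synthetic_truth(),
                             design = list(), seed = 1) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  dg <- utils::modifyList(list(n_acclim = 4, acclim_spacing = 3,
                               records_per_level = 2, prop_dynamic = 0.5,
                               n_latitudes = 2, latitudes = NULL), design)
  sp <- exposure$species
  m <- length(sp)

  # species-level effects: lambda-scaled Brownian + iid
  Cl <- phylo_correlation(tree, lambda = truth$lambda_true, species = sp)
  phylo_eff <- as.numeric(truth$sigma_phylo * (t(chol(Cl)) %*% stats::rnorm(m)))
  sp_eff <- stats::rnorm(m, 0, truth$sigma_species)
  basal <- truth$intercept_true + truth$maxT_slope_true * exposure$max_habitat_temp +
    phylo_eff + sp_eff
  arr_sp <- truth$arr_base + truth$arr_tvar_coef * exposure$thermal_variability +
    truth$arr_realm_offsets[exposure$realm]

  acc_mean <- truth$anchor_intercept + truth$anchor_slope * exposure$max_habitat_temp +
    stats::rnorm(m, 0, truth$anchor_resid_sd)
  offsets <- (seq_len(dg$n_acclim) - (dg$n_acclim + 1) / 2) * dg$acclim_spacing

  lat_sp <- if (!is.null(dg$latitudes)) dg$latitudes[sp] else
    stats::runif(m, -60, 60)

  rows <- vector("list", m)
  rid <- 0L
  for (i in seq_len(m)) {
    lats_i <- lat_sp[i] + c(0, stats::rnorm(max(0, dg$n_latitudes - 1), 0, 0.7))
    nlev <- dg$n_acclim
    recs <- list()
    for (a in seq_len(nlev)) {
      accT <- acc_mean[i] + offsets[a]
      acc_std <- offsets[a]  # offsets are centred by construction
      for (r in seq_len(dg$records_per_level)) {
        rid <- rid + 1L
        ht1h <- basal[i] + arr_sp[i] * acc_std + truth$quad_accT_coef * acc_std^2
        dynamic <- stats::runif(1) < dg$prop_dynamic
        if (dynamic) {
          d <- exp(stats::runif(1, log(0.25), log(4)))
          ramp <- sample(c(1, 3, 6, 18), 1)
        } else {
          d <- sample(c(1, 24, 96), 1)
          ramp <- NA_real_
        }
        logd <- if (truth$log_base == "log10") log10(d) else log(d)
        endpoint <- ht1h + truth$duration_slope_true * logd +
          stats::rnorm(1, 0, truth$sigma_resid)
        start <- if (dynamic) endpoint - ramp * d else NA_real_
        recs[[length(recs) + 1L]] <- data.frame(
          record_id = sprintf("r%05d", rid),
          species = sp[i],
          realm = exposure$realm[i],
          assay_type = if (dynamic) "dynamic" else "static",
          endpoint_temp = endpoint,
          start_temp = start,
          ramp_rate = if (dynamic) ramp else NA_real_,
          trial_duration = if (dynamic) NA_real_ else d,
          acclimation_temp = accT,
          acclimation_duration = 14,
          latitude = sample(lats_i, 1),
          study_id = paste0(sp[i], "_st", sample(1:2, 1)),
          stringsAsFactors = FALSE)
      }
    }
    rows[[i]] <- do.call(rbind, recs)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$abs_latitude <- abs(out$latitude)
  attr(out, "species_effects") <- data.frame(
    species = sp, basal = basal, arr = as.numeric(arr_sp),
    phylo = phylo_eff, iid = sp_eff)
  out
}

#' Generate a complete synthetic study bundle
#'
#' Orchestrates tree, realms, range masks, temperature cubes, exposure
#' summaries (computed with the pipeline's own aggregation operators on the
#' simulated cubes) and assay records, all from one seed with an
#' independent RNG stream per stage.
#'
#' @param config List of overrides: `n_species` (default 300), `grid`
#'   (a [grid_spec()]), `years` (10), `noise_sd` (0.5 K), `truth`
#'   (a [synthetic_truth()]), `design` (passed to [simulate_records()]),
#'   `realm_probs` (named, default c(freshwater = .52, marine = .37,
#'   brackish = .11)), `breadth` (20).
#' @param seed Integer master seed.
#' @return Object of class `synthetic_bundle`: list with `tree`, `cubes`,
#'   `masks`, `records`, `exposure`, `species_realm`, `truth`.
#' @export
make_bundle <- function(config = list(), seed = 1) {
  cf <- utils::modifyList(
    list(n_species = 300, grid = grid_spec(), years = 10, noise_sd = 0.5,
         truth = synthetic_truth(), design = list(),
         realm_probs = c(freshwater = 0.52, marine = 0.37, brackish = 0.11),
         breadth = 20),
    config)
  truth <- cf$truth
  truth$seed <- seed
  stage_seed <- function(k) (seed + k * 7919L) %% 2000000011L

  tree <- simulate_tree(cf$n_species, seed = stage_seed(1))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(stage_seed(2))
  realm <- sample(names(cf$realm_probs), cf$n_species, replace = TRUE,
                  prob = cf$realm_probs)
  species_realm <- stats::setNames(realm, tree$tip.label)

  # range breadth is itself a heritable (Brownian, log-scale) niche trait, so
  # exposure keeps phylogenetic structure beyond what latitude explains
  set.seed(stage_seed(6))
  log_b <- ape::rTraitCont(tree, model = "BM", sigma = 0.4)
  breadth <- pmin(pmax(cf$breadth * exp(log_b - mean(log_b)), 5), 45)
  # edge bands clip by design at these breadths; no need to warn here
  masks <- suppressWarnings(
    simulate_ranges(cf$grid, tree, breadth = breadth, seed = stage_seed(3)))
  cubes <- simulate_temperature_cubes(cf$grid, years = cf$years, truth = truth,
                                      noise_sd = cf$noise_sd,
                                      seed = stage_seed(4))
  expo <- exposure_for_species(cubes$freshwater, cubes$marine, masks,
                               species_realm)$exposure
  # collection latitude falls somewhere inside the species' range band, so
  # latitude tracks thermal exposure (as in real survey data) without being
  # a deterministic proxy for it
  set.seed(stage_seed(7))
  centres <- attr(masks, "centres")
  coll_lat <- centres + stats::runif(length(centres), -0.4, 0.4) * breadth
  coll_lat <- pmin(pmax(coll_lat, cf$grid$lat_range[1]), cf$grid$lat_range[2])
  design <- utils::modifyList(list(latitudes = coll_lat), cf$design)
  records <- simulate_records(tree, expo, truth = truth, design = design,
                              seed = stage_seed(5))
  structure(list(tree = tree, cubes = cubes, masks = masks, records = records,
                 exposure = expo, species_realm = species_realm, truth = truth,
                 grid = cf$grid),
            class = "synthetic_bundle")
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' records.csv, tree.nwk, cubes as long-format CSV + JSON sidecars, masks
#' as a two-column CSV (species, cell), truth.json.
#'
#' @param bundle A [make_bundle()] result.
#' @param dir Output directory (created).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$records, file.path(dir, "records.csv"),
                   row.names = FALSE)
  ape::write.tree(bundle$tree, file.path(dir, "tree.nwk"))
  write_temp_cube(bundle$cubes$freshwater, file.path(dir, "cube_freshwater"))
  write_temp_cube(bundle$cubes$marine, file.path(dir, "cube_marine"))
  mask_df <- do.call(rbind, lapply(bundle$masks, function(mk) {
    data.frame(species = mk$species, cell = mk$cells)
  }))
  utils::write.csv(mask_df, file.path(dir, "masks.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(species = names(bundle$species_realm),
               realm = unname(bundle$species_realm)),
    file.path(dir, "species_realm.csv"), row.names = FALSE)
  tr <- bundle$truth
  tr$arr_realm_offsets <- as.list(tr$arr_realm_offsets)
  jsonlite::write_json(unclass(tr), file.path(dir, "truth.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  records <- utils::read.csv(file.path(dir, "records.csv"),
                             stringsAsFactors = FALSE)
  tree <- ape::read.tree(file.path(dir, "tree.nwk"))
  cubes <- list(freshwater = read_temp_cube(file.path(dir, "cube_freshwater")),
                marine = read_temp_cube(file.path(dir, "cube_marine")))
  mask_df <- utils::read.csv(file.path(dir, "masks.csv"))
  masks <- lapply(split(mask_df$cell, mask_df$species), function(cells) NULL)
  masks <- stats::setNames(
    lapply(split(mask_df, mask_df$species), function(d) {
      range_mask(d$species[1], d$cell, source = "synthetic")
    }), NULL)
  names(masks) <- vapply(masks, `[[`, character(1), "species")
  sr <- utils::read.csv(file.path(dir, "species_realm.csv"))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  truth$arr_realm_offsets <- unlist(truth$arr_realm_offsets)
  class(truth) <- "synthetic_truth"
  structure(list(tree = tree, cubes = cubes, masks = masks, records = records,
                 exposure = NULL, species_realm = stats::setNames(sr$realm, sr$species),
                 truth = truth),
            class = "synthetic_bundle")
}
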