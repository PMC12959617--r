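#' Run the full analysis pipeline
#'
#' Orchestrates the stages end to end on a synthetic bundle (or a directory
#' written by [write_bundle()]): (1) harmonise — durations, bootstrapped
#' log-duration slope, 1-hour standardisation, acclimation centring;
#' (2) exposure — per-species habitat maxima and thermal variability from
#' the cubes and range masks; (3) fits — tolerance models 1-3 as
#' phylogenetic mixed models and the two exposure PGLS models; (4) metrics —
#' per-species ARR, warming tolerance and time gained; (5) map — global
#' prediction layers from model 3 with the acclimation anchor, uncertainty
#' mask and realm combination. Outputs are written under `out_dir` as plain
#' text and a provenance manifest (inputs, seeds, stage outputs, md5
#' digests) is returned and written as JSON.
#'
#' @param bundle A `synthetic_bundle`, or a directory path readable by
#'   [read_bundle()].
#' @param out_dir Output directory.
#' @param config List of overrides: `slope` (`"fit"` or numeric),
#'   `n_bootstrap` (50), `seed` (1), `log_base` (`"log10"`), `percentile`
#'   (97.5), `warming_rate` (degrees C/yr or NULL), `sd_threshold` (NULL =
#'   90th percentile), `fit_models` (character subset, default all),
#'   `slope_tree` (logical, use the phylogeny in the duration model;
#'   default FALSE).
#' @return The manifest (list), invisibly; all stage outputs on disk.
#' @export
run_pipeline <- function(bundle, out_dir, config = list()) {
  cf <- utils::modifyList(
    list(slope = "fit", n_bootstrap = 50, seed = 1, log_base = "log10",
         percentile = 97.5, warming_rate = NULL, sd_threshold = NULL,
         fit_models = c("model1", "model2", "model3", "pgls_maxT", "pgls_cv"),
         slope_tree = FALSE),
    config)
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = cf$seed, config = cf[setdiff(names(cf), "fit_models")],
                   stages = list())
  stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e) {
      stop("pipeline aborted at stage '", name, "': ", conditionMessage(e),
           call. = FALSE)
    })
    manifest$stages[[name]] <<- list(completed = TRUE)
    res
  }

  # 1. harmonise ------------------------------------------------------------
  harm <- stage("harmonise", {
    tol <- if (is.data.frame(bundle$records)) {
      rec <- bundle$records
      reasons <- validate_tolerance_records(rec)
      list(records = rec[!nzchar(reasons), , drop = FALSE],
           rejections = data.frame(row = which(nzchar(reasons)),
                                   reason = reasons[nzchar(reasons)]))
    } else bundle$records
    h <- harmonise_records(tol$records, slope = cf$slope,
                           n_bootstrap = cf$n_bootstrap, rng_seed = cf$seed,
                           log_base = cf$log_base,
                           tree = if (cf$slope_tree) bundle$tree else NULL)
    utils::write.csv(h$records, file.path(out_dir, "harmonised.csv"),
                     row.names = FALSE)
    utils::write.csv(tol$rejections, file.path(out_dir, "rejections.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(slope = h$slope$slope, slope_sd = h$slope$slope_sd,
           n_bootstrap = h$slope$n_bootstrap, log_base = h$slope$log_base),
      file.path(out_dir, "duration_slope.json"), digits = NA, auto_unbox = TRUE)
    h
  })

  # 2. exposure ---------------------------------------------------------------
  expo <- stage("exposure", {
    e <- exposure_for_species(bundle$cubes$freshwater, bundle$cubes$marine,
                              bundle$masks, bundle$species_realm,
                              percentile = cf$percentile)
    utils::write.csv(e$exposure, file.path(out_dir, "exposure.csv"),
                     row.names = FALSE)
    e$exposure
  })

  # 3. fits -------------------------------------------------------------------
  fits <- stage("fit", {
    rec <- merge(harm$records, expo, by = c("species", "realm"))
    fits <- list()
    for (mid in intersect(cf$fit_models, c("model1", "model2", "model3"))) {
      dat <- rec
      if (mid == "model1") dat <- dat[!is.na(dat$latitude), , drop = FALSE]
      ds <- build_design(dat, mid)
      fits[[mid]] <- fit_mixed(ds, tree = bundle$tree,
                               species_ids = dat$species)
      write_phylo_fit(fits[[mid]], file.path(out_dir, paste0("fit_", mid, ".json")))
    }
    pgls_ids <- intersect(cf$fit_models, c("pgls_maxT", "pgls_cv"))
    if (length(pgls_ids)) {
      sp_tab <- species_table(harm$records, expo)
      for (mid in pgls_ids) {
        ds <- build_design(sp_tab, mid)
        fits[[mid]] <- fit_pgls(ds, tree = bundle$tree)
        write_phylo_fit(fits[[mid]], file.path(out_dir, paste0("fit_", mid, ".json")))
      }
    }
    fits
  })

  # 4. metrics -----------------------------------------------------------------
  metrics <- stage("metrics", {
    mfit <- fits$model3 %||% fits$model2
    if (is.null(mfit)) return(NULL)
    mt <- plasticity_table(mfit, expo, warming_rate = cf$warming_rate)
    utils::write.csv(mt, file.path(out_dir, "metrics.csv"), row.names = FALSE)
    mt
  })

  # 5. map ---------------------------------------------------------------------
  layers <- stage("map", {
    mfit <- fits$model3 %||% fits$model2
    if (is.null(mfit) || is.null(bundle$cubes)) return(NULL)
    anchor <- fit_acclimation_anchor(harm$records, expo)
    jsonlite::write_json(unclass(anchor), file.path(out_dir, "anchor.json"),
                         digits = NA, auto_unbox = TRUE)
    acc_range <- range(harm$records$acclimation_std)
    per_realm <- lapply(c(freshwater = "freshwater", marine = "marine"),
      function(rl) {
        cube <- bundle$cubes[[rl]]
        ly <- predict_layers(mfit, climatological_annual_max(cube),
                             within_year_cv(cube), realm = rl,
                             anchor = anchor, acc_range = acc_range)
        apply_uncertainty_mask(ly, cf$sd_threshold)
      })
    comb <- combine_realms(per_realm$freshwater, per_realm$marine)
    write_prediction_layers(comb, file.path(out_dir, "layers_global"))
    comb
  })

  # provenance ------------------------------------------------------------------
  outs <- list.files(out_dir, full.names = TRUE)
  outs <- outs[!grepl("manifest\\.json$", outs)]
  manifest$outputs <- stats::setNames(as.list(unname(tools::md5sum(outs))),
                                      basename(outs))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(list(manifest = manifest, harmonised = harm, exposure = expo,
                 fits = fits, metrics = metrics, layers = layers))
}

#' Per-species table for the exposure PGLS models
#'
#' One row per species: the record at the species' median collection
#' latitude supplies the latitude; exposure metrics are joined by species.
#' Species with no latitude at all are dropped (reported via attribute).
#'
#' @param records Harmonised records.
#' @param exposure Exposure summaries.
#' @return Data.frame: species, realm, latitude, abs_latitude,
#'   max_habitat_temp, thermal_variability.
#' @export
species_table <- function(records, exposure) {
  sp_rows <- lapply(split(records, records$species), function(d) {
    if (all(is.na(d$latitude))) return(NULL)
    select_median_latitude(d)
  })
  sp_rows <- sp_rows[!vapply(sp_rows, is.null, logical(1))]
  reps <- do.call(rbind, sp_rows)
  out <- merge(reps[, c("species", "realm", "latitude")],
               exposure[, c("species", "max_habitat_temp", "thermal_variability")],
               by = "species")
  out$abs_latitude <- abs(out$latitude)
  rownames(out) <- NULL
  out
}
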