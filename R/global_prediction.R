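#' Empirical acclimation anchor
#'
#' Spatial predictions are not tied to a particular species, so the
#' acclimation temperature used per gridcell is the one that coincides with
#' the cell's maximum weekly water temperature. Observed acclimation
#' temperatures rise with habitat maxima but with slope < 1, so the
#' centred ("standardised") acclimation value that corresponds to a habitat
#' maximum T is `T − (a + b T)`, where a, b come from the ordinary
#' regression of actual acclimation temperature on species maximum habitat
#' temperature.
#'
#' @param records Tolerance records with `acclimation_temp` and `species`.
#' @param exposure Exposure table with `species` and `max_habitat_temp`.
#' @return Object of class `acclimation_anchor`: list with `intercept`,
#'   `slope`, `residual_sd`, `n_species`.
#' @export
fit_acclimation_anchor <- function(records, exposure) {
  dat <- merge(records[, c("species", "acclimation_temp")],
               exposure[, c("species", "max_habitat_temp")], by = "species")
  n_sp <- length(unique(dat$species))
  if (n_sp < 10) stop("insufficient data: anchor regression needs >= 10 species")
  fit <- stats::lm(acclimation_temp ~ max_habitat_temp, data = dat)
  cf <- stats::coef(fit)
  structure(list(intercept = unname(cf[1]), slope = unname(cf[2]),
                 residual_sd = stats::sigma(fit), n_species = n_sp,
                 se_slope = summary(fit)$coefficients[2, 2]),
            class = "acclimation_anchor")
}

#' Anchor acclimation value for a habitat maximum
#'
#' @param anchor An `acclimation_anchor`.
#' @param max_habitat_temp Degrees C (vectorised).
#' @return Standardised acclimation temperature (degrees C) at which the
#'   actual acclimation temperature coincides with the habitat maximum.
#' @export
anchor_acclimation <- function(anchor, max_habitat_temp) {
  max_habitat_temp - (anchor$intercept + anchor$slope * max_habitat_temp)
}

#' Per-gridcell prediction layers from a fitted tolerance model
#'
#' Applies a fitted model (model 3 for the published workflow) to gridded
#' inputs: per cell, heat tolerance is predicted at the anchor acclimation
#' value; the ARR layer is the +1 degree C forward difference of the
#' prediction in acclimation (the "warming scenario" contrast); warming
#' tolerance, time gained by plasticity (Eq 3 form) and the prediction SE
#' (coefficient uncertainty propagated through the design row) complete the
#' layer set. Cells whose anchor acclimation falls outside the fitted
#' acclimation range are flagged as extrapolation.
#'
#' @param fit A `phylo_fit` (model 2 or 3).
#' @param maxT_layer Per-cell climatological annual maximum, degrees C.
#' @param cv_layer Per-cell thermal variability (same length).
#' @param realm `"freshwater"` or `"marine"`: which map is being predicted.
#' @param anchor An `acclimation_anchor`.
#' @param acc_range Acclimation range of the fitted data (length-2), used
#'   for the extrapolation flag; default derived from the stored basis is
#'   not available, so pass the fitted records' range when known.
#' @return Object of class `prediction_layers`: list of equal-length
#'   per-cell vectors (`max_habitat_temp`, `thermal_variability`,
#'   `acclimation_std_anchor`, `heat_tolerance`, `arr`,
#'   `warming_tolerance`, `time_gained_pct`, `prediction_sd`, `mask`,
#'   `extrapolated`, `realm_tag`) plus `metadata`.
#' @export
predict_layers <- function(fit, maxT_layer, cv_layer, realm, anchor,
                           acc_range = NULL) {
  if (length(maxT_layer) != length(cv_layer)) {
    stop("co-registration error: layers differ in length")
  }
  n <- length(maxT_layer)
  ok <- !is.na(maxT_layer) & !is.na(cv_layer)
  acc0 <- anchor_acclimation(anchor, maxT_layer)

  nd <- data.frame(max_habitat_temp = maxT_layer,
                   thermal_variability = cv_layer,
                   realm = realm, acclimation_std = acc0)
  pr0 <- predict(fit, nd, se = TRUE)
  nd1 <- nd
  nd1$acclimation_std <- acc0 + 1
  pr1 <- predict(fit, nd1)

  ht <- ifelse(ok, pr0$fit, NA_real_)
  arr <- ifelse(ok, pr1 - pr0$fit, NA_real_)
  wt <- warming_tolerance(ht, maxT_layer)
  tg <- ifelse(!is.na(arr) & arr < 1, (1 / (1 - arr) - 1) * 100, NA_real_)
  extrap <- if (is.null(acc_range)) rep(FALSE, n) else
    !is.na(acc0) & (acc0 < min(acc_range) | acc0 > max(acc_range))

  structure(list(
    max_habitat_temp = maxT_layer,
    thermal_variability = cv_layer,
    acclimation_std_anchor = ifelse(ok, acc0, NA_real_),
    heat_tolerance = ht,
    arr = arr,
    warming_tolerance = wt,
    time_gained_pct = tg,
    prediction_sd = ifelse(ok, pr0$se, NA_real_),
    mask = rep(FALSE, n),
    extrapolated = extrap,
    realm_tag = ifelse(ok, realm, NA_character_),
    metadata = list(model_id = fit$design$model_id, realm = realm,
                    anchor = unclass(anchor)[c("intercept", "slope")],
                    sd_threshold = NA_real_)
  ), class = "prediction_layers")
}

layer_fields <- c("max_habitat_temp", "thermal_variability",
                  "acclimation_std_anchor", "heat_tolerance", "arr",
                  "warming_tolerance", "time_gained_pct", "prediction_sd")
derived_fields <- c("heat_tolerance", "arr", "warming_tolerance",
                    "time_gained_pct")

#' Mask high-uncertainty cells
#'
#' Cells whose prediction SD exceeds the threshold are masked: the mask is
#' set and all derived layers are blanked (NA). The threshold is recorded
#' in the layer metadata. The published maps leave such regions uncoloured.
#'
#' @param layers A `prediction_layers`.
#' @param sd_threshold Degrees C; default the 90th percentile of the
#'   layer's prediction SD.
#' @return The masked `prediction_layers`.
#' @export
apply_uncertainty_mask <- function(layers, sd_threshold = NULL) {
  sdv <- layers$prediction_sd
  if (is.null(sd_threshold)) {
    sd_threshold <- stats::quantile(sdv[!is.na(sdv)], 0.9, type = 7)
  }
  mask <- !is.na(sdv) & sdv > sd_threshold
  layers$mask <- mask
  for (f in derived_fields) layers[[f]][mask] <- NA_real_
  layers$metadata$sd_threshold <- unname(sd_threshold)
  layers
}

#' Combine freshwater and marine prediction layers into one global set
#'
#' Cells with freshwater predictions take the freshwater values; remaining
#' cells with marine predictions take the marine values (freshwater
#' priority on overlap, counted and reported); cells in neither stay
#' missing. Per-cell provenance is kept in `realm_tag`.
#'
#' @param fresh,marine `prediction_layers` on the same grid.
#' @return A combined `prediction_layers`; the number of overlapping cells
#'   resolved by the priority rule is in `metadata$overlap_cells`.
#' @export
combine_realms <- function(fresh, marine) {
  if (length(fresh$heat_tolerance) != length(marine$heat_tolerance)) {
    stop("co-registration error: realm layers differ in length")
  }
  have_f <- !is.na(fresh$realm_tag)
  have_m <- !is.na(marine$realm_tag)
  overlap <- sum(have_f & have_m)
  out <- marine
  fields <- c(layer_fields, "mask", "extrapolated", "realm_tag")
  for (f in fields) {
    v <- marine[[f]]
    v[have_f] <- fresh[[f]][have_f]
    out[[f]] <- v
  }
  out$metadata <- list(
    model_id = fresh$metadata$model_id,
    realm = "combined", overlap_cells = overlap,
    sd_threshold = c(freshwater = fresh$metadata$sd_threshold,
                     marine = marine$metadata$sd_threshold))
  out
}

#' Write prediction layers as plain text
#'
#' One CSV row per cell with every layer as a column, plus a JSON metadata
#' sidecar (fit id, anchor, mask threshold).
#'
#' @param layers A `prediction_layers`.
#' @param path Base path (writes `<path>.csv`, `<path>.json`).
#' @return The base path, invisibly.
#' @export
write_prediction_layers <- function(layers, path) {
  df <- as.data.frame(layers[c(layer_fields, "mask", "extrapolated",
                               "realm_tag")])
  df <- cbind(cell = seq_len(nrow(df)), df)
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(layers$metadata, paste0(path, ".json"),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}
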