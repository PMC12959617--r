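#' Acclimation response ratio from a fitted model
#'
#' The ARR is the change in heat tolerance per degree change in (centred)
#' acclimation temperature: the derivative of the fitted linear predictor
#' with respect to `acclimation_std`, evaluated at a context (thermal
#' variability, realm, and an acclimation evaluation point, default the
#' species-mean, i.e. `acclimation_std = 0`). The quadratic acclimation
#' term's contribution is computed exactly from the stored orthogonal
#' basis, so the result is the true derivative at the evaluation point, not
#' an approximation that assumes the quadratic vanishes at the centre.
#'
#' @param fit A `phylo_fit` of model 2 or model 3 (any fit whose design
#'   carries acclimation terms).
#' @param thermal_variability Dimensionless CV value(s).
#' @param realm `"marine"`, `"freshwater"` or `"brackish"` (recycled).
#' @param acclimation_std Evaluation point(s), degrees C (default 0).
#' @param latitude Latitude value(s), needed only for model 1 designs.
#' @return Numeric ARR value(s), degrees C gained per degree of
#'   acclimation.
#' @export
arr_from_fit <- function(fit, thermal_variability = NA_real_,
                         realm = "marine", acclimation_std = 0,
                         latitude = NA_real_) {
  design <- fit$design
  has_acc <- any(vapply(design$terms, `[[`, character(1), "name") == "AccT")
  if (!has_acc) stop("contract error: fit has no acclimation terms")
  n <- max(length(thermal_variability), length(realm),
           length(acclimation_std), length(latitude))
  nd <- data.frame(
    thermal_variability = rep_len(thermal_variability, n),
    realm = rep_len(realm, n),
    acclimation_std = rep_len(acclimation_std, n),
    latitude = rep_len(latitude, n),
    max_habitat_temp = 0)
  D <- design_acc_derivative(design, nd)
  as.numeric(D %*% fit$coefficients$estimate)
}

#' Warming tolerance (thermal safety margin)
#'
#' Heat tolerance minus maximum habitat temperature; positive values are a
#' safety margin, negative values mean habitat maxima already exceed the
#' measured (or modelled) tolerance.
#'
#' @param heat_tolerance,max_habitat_temp Degrees C (vectorised).
#' @return Degrees C.
#' @export
warming_tolerance <- function(heat_tolerance, max_habitat_temp) {
  heat_tolerance - max_habitat_temp
}

#' Time until overheating without and with plasticity
#'
#' Under a constant warming rate, the time until habitat maxima reach the
#' (1-h standardised) heat tolerance is `t1 = warming_tolerance / rate`
#' without plasticity. With plasticity (ARR > 0), each degree of warming
#' buys back ARR degrees of tolerance, extending the time to
#' `t2 = t1 / (1 − ARR)`. Already-overheated cases (negative warming
#' tolerance) are flagged and given t1 = t2 = 0 rather than negative
#' times.
#'
#' @param warming_tol Warming tolerance, degrees C.
#' @param warming_rate Degrees C per year, > 0.
#' @param arr ARR in \[0, 1); `arr >= 1` is an error (infinite time).
#' @return Data.frame with `t1`, `t2` (years) and `overheated` flag.
#' @export
overheating_times <- function(warming_tol, warming_rate, arr) {
  if (any(warming_rate <= 0)) stop("warming_rate must be positive")
  if (any(arr >= 1)) stop("infinite time: arr >= 1 implies no overheating")
  over <- warming_tol < 0
  t1 <- ifelse(over, 0, warming_tol / warming_rate)
  t2 <- t1 / (1 - arr)
  data.frame(t1 = t1, t2 = t2, overheated = over)
}

#' Time gained by plasticity (%)
#'
#' The relative extension of the time until overheating afforded by
#' acclimation, `(1/(1 − ARR) − 1) x 100`. Independent of the warming rate:
#' faster warming shortens t1 and t2 proportionally.
#'
#' @param arr ARR in \[0, 1).
#' @return Percent.
#' @export
time_gained_pct <- function(arr) {
  if (any(arr >= 1)) stop("domain error: arr must be < 1")
  (1 / (1 - arr) - 1) * 100
}

#' Per-species plasticity metrics table
#'
#' Combines a fitted tolerance model with exposure summaries: per species,
#' the ARR at the species-mean acclimation temperature, the modelled heat
#' tolerance at that point, warming tolerance, overheating times (when a
#' warming rate is given) and time gained by plasticity.
#'
#' @param fit A `phylo_fit` of model 2 or 3.
#' @param exposure Exposure data.frame (species, realm, max_habitat_temp,
#'   thermal_variability).
#' @param warming_rate Optional degrees C per year; required for t1/t2.
#' @return Data.frame, one row per species.
#' @export
plasticity_table <- function(fit, exposure, warming_rate = NULL) {
  nd <- data.frame(
    species = exposure$species,
    realm = exposure$realm,
    max_habitat_temp = exposure$max_habitat_temp,
    thermal_variability = exposure$thermal_variability,
    acclimation_std = 0)
  ht <- predict(fit, nd)
  arr <- arr_from_fit(fit, thermal_variability = nd$thermal_variability,
                      realm = nd$realm, acclimation_std = 0)
  arr_c <- pmin(arr, 1 - 1e-9)
  out <- data.frame(
    species = exposure$species,
    realm = exposure$realm,
    heat_tolerance = ht,
    max_habitat_temp = exposure$max_habitat_temp,
    arr = arr,
    warming_tolerance = warming_tolerance(ht, exposure$max_habitat_temp),
    time_gained_pct = time_gained_pct(arr_c))
  if (!is.null(warming_rate)) {
    tt <- overheating_times(out$warming_tolerance, warming_rate, arr_c)
    out$t1 <- tt$t1
    out$t2 <- tt$t2
    out$overheated <- tt$overheated
  }
  out
}
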