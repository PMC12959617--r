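REALMS <- c("freshwater", "marine", "brackish")
ASSAY_TYPES <- c("static", "dynamic")

#' Default column mapping for tolerance tables
#'
#' Maps the canonical record fields onto source-file column headers. Any
#' field can be rebound by supplying a named list (or a YAML file parsed
#' into one) whose names are canonical fields and whose values are the
#' headers used in the CSV.
#'
#' @return Named list of canonical field -> column name.
#' @export
default_column_mapping <- function() {
  list(
    record_id            = "record_id",
    species              = "species",
    realm                = "realm",
    assay_type           = "assay_type",
    endpoint_temp        = "endpoint_temp",
    start_temp           = "start_temp",
    ramp_rate            = "ramp_rate",
    trial_duration       = "trial_duration",
    acclimation_temp     = "acclimation_temp",
    acclimation_duration = "acclimation_duration",
    latitude             = "latitude",
    study_id             = "study_id"
  )
}

#' Read and validate a thermal-tolerance record table
#'
#' Reads a CSV of upper thermal-limit assay records (critical thermal maxima
#' from dynamic ramping assays, lethal temperatures from static assays),
#' validates each row against the record invariants, and returns the
#' accepted records together with a rejection report. Rows that violate an
#' invariant are never silently dropped: each appears in the report with the
#' reason for rejection.
#'
#' Required fields: species, realm, assay_type, endpoint_temp,
#' acclimation_temp. Dynamic records must additionally carry either
#' (start_temp and ramp_rate) or an explicit trial_duration; static records
#' must carry trial_duration. Units are fixed: degrees C, hours, degrees C
#' per hour, decimal degrees.
#'
#' @param path CSV file path.
#' @param schema_config Named list mapping canonical fields to source column
#'   headers; defaults from [default_column_mapping()]. A path to a YAML
#'   file is also accepted.
#' @return List with elements `records` (data.frame of validated records,
#'   one per accepted row, with canonical column names plus `abs_latitude`)
#'   and `rejections` (data.frame with `row`, `record_id`, `reason`).
#' @export
read_tolerance_table <- function(path, schema_config = default_column_mapping()) {
  if (!file.exists(path)) stop("tolerance table not found: ", path)
  if (is.character(schema_config) && length(schema_config) == 1L) {
    schema_config <- yaml::read_yaml(schema_config)
  }
  mapping <- utils::modifyList(default_column_mapping(), as.list(schema_config))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)

  required <- c("species", "realm", "assay_type", "endpoint_temp", "acclimation_temp")
  missing_cols <- vapply(required, function(f) !(mapping[[f]] %in% names(raw)), logical(1))
  if (any(missing_cols)) {
    stop("schema error: required column(s) not found: ",
         paste(unlist(mapping[required[missing_cols]]), collapse = ", "))
  }

  get_col <- function(field, numeric = FALSE) {
    cn <- mapping[[field]]
    if (is.null(cn) || !(cn %in% names(raw))) return(rep(NA, nrow(raw)))
    v <- raw[[cn]]
    if (numeric) suppressWarnings(as.numeric(v)) else as.character(v)
  }

  n <- nrow(raw)
  rec <- data.frame(
    record_id            = get_col("record_id"),
    species              = get_col("species"),
    realm                = tolower(trimws(get_col("realm"))),
    assay_type           = tolower(trimws(get_col("assay_type"))),
    endpoint_temp        = get_col("endpoint_temp", numeric = TRUE),
    start_temp           = get_col("start_temp", numeric = TRUE),
    ramp_rate            = get_col("ramp_rate", numeric = TRUE),
    trial_duration       = get_col("trial_duration", numeric = TRUE),
    acclimation_temp     = get_col("acclimation_temp", numeric = TRUE),
    acclimation_duration = get_col("acclimation_duration", numeric = TRUE),
    latitude             = get_col("latitude", numeric = TRUE),
    study_id             = get_col("study_id"),
    stringsAsFactors = FALSE
  )
  if (all(is.na(rec$record_id))) rec$record_id <- as.character(seq_len(n))

  reasons <- validate_tolerance_records(rec)
  keep <- !nzchar(reasons)
  rejections <- data.frame(
    row = which(!keep),
    record_id = rec$record_id[!keep],
    reason = reasons[!keep],
    stringsAsFactors = FALSE
  )
  records <- rec[keep, , drop = FALSE]
  rownames(records) <- NULL
  records$abs_latitude <- abs(records$latitude)
  list(records = records, rejections = rejections)
}

# one reason string per row; "" = valid
validate_tolerance_records <- function(rec) {
  n <- nrow(rec)
  reasons <- character(n)
  add <- function(idx, msg) {
    idx <- which(idx & !nzchar(reasons))
    reasons[idx] <<- msg
    reasons
  }
  reasons <- add(is.na(rec$species) | !nzchar(rec$species), "missing species")
  reasons <- add(!(rec$realm %in% REALMS), "unknown realm")
  reasons <- add(!(rec$assay_type %in% ASSAY_TYPES), "unknown assay type")
  reasons <- add(is.na(rec$endpoint_temp), "missing endpoint_temp")
  reasons <- add(is.na(rec$acclimation_temp), "missing acclimation_temp")

  dyn <- rec$assay_type == "dynamic"
  has_ramp <- !is.na(rec$start_temp) & !is.na(rec$ramp_rate)
  has_dur <- !is.na(rec$trial_duration)
  reasons <- add(dyn & !has_ramp & !has_dur,
                 "dynamic record needs start_temp+ramp_rate or trial_duration")
  reasons <- add(dyn & has_ramp & !is.na(rec$ramp_rate) & rec$ramp_rate <= 0,
                 "non-positive ramp_rate")
  reasons <- add(dyn & has_ramp & rec$ramp_rate > 0 &
                   rec$endpoint_temp <= rec$start_temp,
                 "endpoint_temp not above start_temp in dynamic assay")
  reasons <- add(!dyn & !has_dur, "static record missing trial_duration")
  reasons <- add(has_dur & rec$trial_duration <= 0, "non-positive trial_duration")
  reasons
}

#' Assay exposure duration in hours
#'
#' Static assays report their trial duration directly. For dynamic (ramping)
#' assays the realised duration is derived from the ramp:
#' (endpoint − start) / ramp rate — unless an explicit trial duration was
#' reported, which is preferred as it reflects the realised trial.
#'
#' @param records Data.frame of validated tolerance records.
#' @return Numeric vector of durations (hours), one per record.
#' @export
assay_duration <- function(records) {
  dyn <- records$assay_type == "dynamic"
  dur <- records$trial_duration
  need_ramp <- dyn & is.na(dur)
  if (any(need_ramp)) {
    rr <- records$ramp_rate[need_ramp]
    if (any(is.na(rr) | rr <= 0)) {
      stop("invalid methodology: dynamic record without positive ramp_rate or explicit duration")
    }
    dur[need_ramp] <- (records$endpoint_temp[need_ramp] - records$start_temp[need_ramp]) / rr
  }
  if (any(is.na(dur))) stop("invalid methodology: record without resolvable duration")
  if (any(dur <= 0)) stop("invalid methodology: non-positive assay duration")
  dur
}

#' Estimate the heat tolerance vs. log-duration slope by bootstrap
#'
#' Tolerated temperature falls with exposure time, so endpoints from assays
#' of different durations are not directly comparable. The slope of heat
#' tolerance on log duration is estimated by bootstrap: in each replicate a
#' single dynamic record is sampled per species-by-study combination (dynamic
#' assay durations are partly methodological, so this isolates the duration
#' effect from repeated measurements), pooled with all static records, and a
#' mixed model of endpoint temperature on log duration with a species random
#' intercept is fitted (with a phylogenetic random effect as well when a
#' tree is supplied). The returned slope is the mean across replicates and
#' its SD the spread across replicates.
#'
#' @param records Validated tolerance records (see [read_tolerance_table()]).
#' @param n_bootstrap Number of bootstrap replicates (default 50).
#' @param rng_seed Integer seed; the result is deterministic given the seed.
#' @param log_base `"log10"` (default) or `"natural"`.
#' @param tree Optional `phylo` tree; when supplied the per-replicate model
#'   adds a phylogenetic random intercept (REML).
#' @return Object of class `duration_slope`: list with `slope`, `slope_sd`,
#'   `n_bootstrap`, `log_base`, `replicates`.
#' @export
estimate_duration_slope <- function(records, n_bootstrap = 50, rng_seed = 1,
                                    log_base = c("log10", "natural"),
                                    tree = NULL) {
  log_base <- match.arg(log_base)
  if (n_bootstrap < 1) stop("parameter error: n_bootstrap must be >= 1")
  dur <- assay_duration(records)
  if (length(unique(round(dur, 10))) < 2) {
    stop("unidentifiable slope: all assay durations identical")
  }
  logf <- if (log_base == "log10") log10 else log
  dat <- data.frame(
    y = records$endpoint_temp,
    log_dur = logf(dur),
    species = records$species,
    study = if (!is.null(records$study_id)) {
      ifelse(is.na(records$study_id), "s1", records$study_id)
    } else "s1",
    assay_type = records$assay_type,
    stringsAsFactors = FALSE
  )
  dyn <- dat[dat$assay_type == "dynamic", , drop = FALSE]
  stat <- dat[dat$assay_type == "static", , drop = FALSE]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(rng_seed)

  slopes <- vapply(seq_len(n_bootstrap), function(b) {
    if (nrow(dyn) > 0) {
      grp <- interaction(dyn$species, dyn$study, drop = TRUE)
      pick <- tapply(seq_len(nrow(dyn)), grp, function(ix) {
        if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)]
      })
      sub <- rbind(dyn[unlist(pick), , drop = FALSE], stat)
    } else {
      sub <- stat
    }
    fit_duration_model(sub, tree)
  }, numeric(1))

  structure(
    list(slope = mean(slopes), slope_sd = stats::sd(slopes),
         n_bootstrap = n_bootstrap, log_base = log_base,
         replicates = slopes),
    class = "duration_slope"
  )
}

# single-replicate duration model; species random intercept (lmer), or the
# phylogenetic mixed model when a tree is given; falls back to OLS when the
# grouping is degenerate
fit_duration_model <- function(sub, tree) {
  if (!is.null(tree)) {
    ds <- design_duration(sub)
    fit <- fit_mixed(ds, tree = tree, species_ids = sub$species)
    return(fit$coefficients["log_dur", "estimate"])
  }
  if (length(unique(sub$species)) > 2 && nrow(sub) > length(unique(sub$species)) + 2) {
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(y ~ log_dur + (1 | species), data = sub, REML = TRUE)
      )),
      error = function(e) NULL
    )
    if (!is.null(fit)) return(unname(lme4::fixef(fit)["log_dur"]))
  }
  unname(stats::coef(stats::lm(y ~ log_dur, data = sub))["log_dur"])
}

# minimal design object for the duration model (used with fit_mixed)
design_duration <- function(sub) {
  X <- cbind(`(Intercept)` = 1, log_dur = sub$log_dur)
  structure(list(X = X, y = sub$y, model_id = "duration_model",
                 term_info = NULL), class = "tol_design")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Standardise an endpoint temperature to a 1-hour exposure
#'
#' Applies the fitted log-duration slope to correct an assay endpoint to the
#' temperature that would have been tolerated for exactly 1 hour:
#' `endpoint − slope * log(duration / 1h)`, in the slope's log base. At a
#' duration of 1 h the endpoint is returned unchanged. With a negative
#' slope, endpoints from longer-than-1 h assays are corrected upward.
#'
#' @param endpoint_temp Endpoint temperature(s), degrees C.
#' @param duration Assay duration(s), hours; must be positive.
#' @param slope A `duration_slope` object, or a bare numeric slope (then
#'   `log_base` applies).
#' @param log_base Log base when `slope` is bare numeric.
#' @return Standardised heat tolerance, degrees C at 1 h.
#' @export
standardise_to_one_hour <- function(endpoint_temp, duration, slope,
                                    log_base = c("log10", "natural")) {
  if (inherits(slope, "duration_slope")) {
    log_base <- slope$log_base
    slope <- slope$slope
  } else {
    log_base <- match.arg(log_base)
  }
  if (any(duration <= 0)) stop("domain error: duration must be positive")
  logf <- if (log_base == "log10") log10 else log
  endpoint_temp - slope * logf(duration)
}

#' Centre acclimation temperatures within species
#'
#' Actual acclimation temperature is strongly confounded with habitat
#' temperature (warm-water species are acclimated warm), so the models use
#' the acclimation temperature expressed relative to the species mean:
#' `acclimation_std = acclimation_temp − mean(acclimation_temp | species)`.
#' Per species the centred values average zero by construction.
#'
#' @param records Data.frame of tolerance records with `acclimation_temp`.
#' @return The records with an added `acclimation_std` column. Records of
#'   species with no acclimation data at all are dropped from the output and
#'   returned in the `"excluded"` attribute.
#' @export
centre_acclimation <- function(records) {
  has_acc <- !is.na(records$acclimation_temp)
  sp_ok <- unique(records$species[has_acc])
  excluded <- records[!(records$species %in% sp_ok), , drop = FALSE]
  out <- records[records$species %in% sp_ok & has_acc, , drop = FALSE]
  mu <- tapply(out$acclimation_temp, out$species, mean)
  out$acclimation_std <- out$acclimation_temp - as.numeric(mu[out$species])
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Select the record at the species' median collection latitude
#'
#' When a species has records from several latitudes, a single
#' representative record is taken at the median of the distinct latitudes;
#' for an even count the lower of the two middle latitudes is used (a fixed,
#' documented tie-break). Among records at the chosen latitude the first is
#' returned.
#'
#' @param records Records of a single species with a `latitude` column.
#' @return One-row data.frame. Errors if no record has a latitude.
#' @export
select_median_latitude <- function(records) {
  lat <- records$latitude
  if (all(is.na(lat))) stop("missing latitude: no record carries a latitude")
  lats <- sort(unique(lat[!is.na(lat)]))
  med <- lats[ceiling(length(lats) / 2)]  # lower-middle for even counts
  records[which(!is.na(lat) & lat == med)[1L], , drop = FALSE]
}

#' Dataset accounting by realm
#'
#' Tabulates, per realm and overall: record and species counts, population
#' counts (a population is a species at a distinct collection latitude), the
#' share of species with multiple populations, acclimation-design richness
#' (mean number of distinct acclimation temperatures per species, share of
#' species with more than one, mean within-species range), and the mean
#' within-species latitudinal range.
#'
#' @param records Validated tolerance records.
#' @return Data.frame, one row per realm plus `"all"`.
#' @export
dataset_summary <- function(records) {
  summarise_group <- function(rec, label) {
    if (nrow(rec) == 0) {
      return(data.frame(group = label, records = 0L, species = 0L,
                        populations = 0L, pct_species_multi_population = 0,
                        mean_n_acclimation_temps = 0,
                        pct_species_multi_acclimation = 0,
                        mean_range_acclimation = 0, mean_range_latitude = 0))
    }
    sp <- unique(rec$species)
    pop_per_sp <- vapply(sp, function(s) {
      l <- unique(rec$latitude[rec$species == s])
      max(1L, length(l[!is.na(l)]))
    }, integer(1))
    acc_per_sp <- vapply(sp, function(s) {
      length(unique(rec$acclimation_temp[rec$species == s]))
    }, integer(1))
    range_or_0 <- function(v) if (length(v) < 2) 0 else diff(range(v))
    acc_range <- vapply(sp, function(s)
      range_or_0(unique(rec$acclimation_temp[rec$species == s])), numeric(1))
    lat_range <- vapply(sp, function(s) {
      l <- rec$latitude[rec$species == s]
      range_or_0(unique(l[!is.na(l)]))
    }, numeric(1))
    data.frame(
      group = label,
      records = nrow(rec),
      species = length(sp),
      populations = sum(pop_per_sp),
      pct_species_multi_population = 100 * mean(pop_per_sp > 1),
      mean_n_acclimation_temps = mean(acc_per_sp),
      pct_species_multi_acclimation = 100 * mean(acc_per_sp > 1),
      mean_range_acclimation = mean(acc_range),
      mean_range_latitude = mean(lat_range)
    )
  }
  out <- rbind(
    summarise_group(records, "all"),
    do.call(rbind, lapply(REALMS, function(r) {
      summarise_group(records[records$realm == r, , drop = FALSE], r)
    }))
  )
  rownames(out) <- NULL
  out
}

#' Harmonise a record table end to end
#'
#' Convenience wrapper chaining duration derivation, slope estimation (or a
#' fixed slope), 1-hour standardisation and per-species acclimation
#' centring; the model-ready table gains `duration_h`, `heat_tolerance_std`
#' and `acclimation_std` columns.
#'
#' @param records Validated records.
#' @param slope `"fit"` to estimate, or a numeric fixed slope, or a
#'   `duration_slope`.
#' @param n_bootstrap,rng_seed,log_base,tree Passed to
#'   [estimate_duration_slope()] when fitting.
#' @return List with `records` (harmonised), `slope` (`duration_slope`).
#' @export
harmonise_records <- function(records, slope = "fit", n_bootstrap = 50,
                              rng_seed = 1, log_base = "log10", tree = NULL) {
  records$duration_h <- assay_duration(records)
  if (identical(slope, "fit")) {
    slope <- estimate_duration_slope(records, n_bootstrap = n_bootstrap,
                                     rng_seed = rng_seed, log_base = log_base,
                                     tree = tree)
  } else if (is.numeric(slope)) {
    slope <- structure(list(slope = slope, slope_sd = 0, n_bootstrap = 0L,
                            log_base = log_base, replicates = numeric(0)),
                       class = "duration_slope")
  }
  records$heat_tolerance_std <- standardise_to_one_hour(
    records$endpoint_temp, records$duration_h, slope)
  records <- centre_acclimation(records)
  list(records = records, slope = slope)
}
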