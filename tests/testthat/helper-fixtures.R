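# small in-code fixtures shared across test files

# hand-buildable record table (valid by construction unless overridden)
make_records <- function(species, realm = "marine", assay_type = "static",
                         endpoint_temp = 35, start_temp = NA_real_,
                         ramp_rate = NA_real_, trial_duration = 1,
                         acclimation_temp = 20, latitude = NA_real_,
                         study_id = "s1") {
  n <- length(species)
  data.frame(
    record_id = sprintf("r%02d", seq_len(n)),
    species = species,
    realm = rep_len(realm, n),
    assay_type = rep_len(assay_type, n),
    endpoint_temp = rep_len(endpoint_temp, n),
    start_temp = rep_len(start_temp, n),
    ramp_rate = rep_len(ramp_rate, n),
    trial_duration = rep_len(trial_duration, n),
    acclimation_temp = rep_len(acclimation_temp, n),
    acclimation_duration = 14,
    latitude = rep_len(latitude, n),
    study_id = rep_len(study_id, n),
    stringsAsFactors = FALSE)
}

# five-tip ultrametric tree with distinct structure, depth 1
tree5 <- function() {
  ape::read.tree(text = "((A:0.3,B:0.3):0.7,((C:0.4,D:0.4):0.4,E:0.8):0.2);")
}

# naive triple-loop oracles for the exposure aggregations
brute_annual_max <- function(values) {
  d <- dim(values)
  out <- numeric(d[1])
  for (i in seq_len(d[1])) {
    ymax <- numeric(0)
    for (y in seq_len(d[3])) {
      w <- values[i, , y]
      if (sum(!is.na(w)) >= max(2, d[2] / 2)) ymax <- c(ymax, max(w, na.rm = TRUE))
    }
    out[i] <- if (length(ymax)) mean(ymax) else NA_real_
  }
  out - 273.15
}

brute_within_year_cv <- function(values) {
  d <- dim(values)
  out <- numeric(d[1])
  for (i in seq_len(d[1])) {
    cvs <- numeric(0)
    for (y in seq_len(d[3])) {
      w <- values[i, , y]
      w <- w[!is.na(w)]
      if (length(w) >= max(2, d[2] / 2)) cvs <- c(cvs, sd(w) / mean(w))
    }
    out[i] <- if (length(cvs)) mean(cvs) else NA_real_
  }
  out
}

brute_percentile <- function(vals, p) {
  # linear-interpolation quantile written out longhand
  vals <- sort(vals)
  n <- length(vals)
  h <- (n - 1) * p / 100 + 1
  lo <- floor(h)
  hi <- ceiling(h)
  vals[lo] + (h - lo) * (vals[hi] - vals[lo])
}

# small synthetic species table + fitted model 3 reused by several files
small_model3_fit <- function(seed = 11, n_species = 40) {
  tree <- simulate_tree(n_species, seed = seed)
  set.seed(seed)
  realm <- sample(c("freshwater", "marine", "brackish"), n_species, TRUE,
                  c(.5, .4, .1))
  realm[1:3] <- c("freshwater", "marine", "brackish")  # keep design full rank
  expo <- data.frame(
    species = tree$tip.label,
    realm = realm,
    max_habitat_temp = runif(n_species, 10, 30),
    thermal_variability = runif(n_species, 0.005, 0.03))
  rec <- simulate_records(tree, expo, truth = synthetic_truth(),
                          design = list(n_acclim = 3, records_per_level = 2),
                          seed = seed + 1)
  h <- harmonise_records(rec, slope = -1.26, log_base = "log10")
  dat <- merge(h$records, expo, by = c("species", "realm"))
  ds <- build_design(dat, "model3")
  fit <- suppressWarnings(fit_mixed(ds, tree = tree, species_ids = dat$species))
  list(fit = fit, data = dat, tree = tree, exposure = expo)
}
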