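#' Construct a weekly water-temperature cube
#'
#' In-memory container for gridded weekly water temperatures: a 3-d array
#' of cell x week-of-year x year, stored in Kelvin. Cells live on a regular
#' latitude/longitude grid; each cell carries its centre coordinates.
#' Inputs declared in degrees C are converted on construction. Week-53
#' values (leap layouts) should be folded into week 52 by averaging before
#' construction; [fold_week53()] does this.
#'
#' @param values Numeric array `[n_cells, n_weeks, n_years]`, or a matrix
#'   `[n_cells, n_weeks]` for a single year.
#' @param lat,lon Cell-centre coordinates, length `n_cells`.
#' @param years Calendar years covered.
#' @param realm One of `"freshwater"`, `"marine"`.
#' @param units `"K"` (default) or `"C"`; C input is converted to Kelvin.
#' @return Object of class `temp_cube`.
#' @export
temp_cube <- function(values, lat, lon, years, realm = c("freshwater", "marine"),
                      units = c("K", "C")) {
  realm <- match.arg(realm)
  units <- match.arg(units)
  if (length(dim(values)) == 2L) dim(values) <- c(dim(values), 1L)
  stopifnot(length(dim(values)) == 3L,
            dim(values)[1] == length(lat),
            length(lat) == length(lon),
            dim(values)[3] == length(years))
  if (units == "C") values <- values + 273.15
  if (any(values <= 0, na.rm = TRUE)) {
    stop("data integrity: temperatures must be positive on the Kelvin scale")
  }
  structure(list(values = values, lat = lat, lon = lon, years = years,
                 weeks_per_year = dim(values)[2], realm = realm),
            class = "temp_cube")
}

#' @export
print.temp_cube <- function(x, ...) {
  cat(sprintf("temp_cube (%s): %d cells x %d weeks x %d years\n",
              x$realm, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3]))
  invisible(x)
}

#' Fold a 53rd week into week 52 by averaging
#'
#' Keeps cubes rectangular across years with differing week counts.
#'
#' @param values Array `[cells, 53, years]`.
#' @return Array `[cells, 52, years]`.
#' @export
fold_week53 <- function(values) {
  if (dim(values)[2] != 53L) return(values)
  out <- values[, 1:52, , drop = FALSE]
  out[, 52, ] <- (values[, 52, ] + values[, 53, ]) / 2
  out
}

#' Range mask: set of grid cells a species occupies
#'
#' @param species Species name.
#' @param cells Integer cell indices into the cube grid.
#' @param source `"synthetic"` or `"supplied"`.
#' @return Object of class `range_mask`.
#' @export
range_mask <- function(species, cells, source = c("synthetic", "supplied")) {
  source <- match.arg(source)
  cells <- sort(unique(as.integer(cells)))
  if (length(cells) == 0) stop("range mask must be non-empty: ", species)
  structure(list(species = species, cells = cells, source = source),
            class = "range_mask")
}

# a (cell, year) with < 50% of weeks present is dropped from that year's
# aggregations to avoid biased within-year statistics
year_usable <- function(slice_na, n_weeks) {
  colSums(!slice_na) >= n_weeks / 2 & colSums(!slice_na) >= 2
}

#' Climatological mean annual maximum temperature
#'
#' Per grid cell: the maximum weekly temperature within each year, averaged
#' over the climatology period (the cube's years). Output in degrees C.
#' Years with fewer than half their weeks present at a cell are excluded
#' for that cell; a cell with no usable year is NA.
#'
#' @param cube A [temp_cube()].
#' @return Numeric vector, one value (degrees C) per cell.
#' @export
climatological_annual_max <- function(cube) {
  v <- cube$values
  d <- dim(v)
  out <- vapply(seq_len(d[1]), function(i) {
    sl <- v[i, , , drop = TRUE]
    if (d[3] == 1L) sl <- matrix(sl, ncol = 1)
    ok <- year_usable(is.na(sl), d[2])
    if (!any(ok)) return(NA_real_)
    mean(apply(sl[, ok, drop = FALSE], 2, max, na.rm = TRUE))
  }, numeric(1))
  out - 273.15
}

#' Within-year coefficient of variation of weekly temperature
#'
#' Per grid cell and year: sd/mean of the weekly temperatures on the Kelvin
#' scale; then the mean of these yearly CVs across the climatology period.
#' The Kelvin scale makes the CV a dimensionless measure of seasonality
#' that is comparable across realms.
#'
#' @param cube A [temp_cube()].
#' @return Numeric vector, one dimensionless CV per cell.
#' @export
within_year_cv <- function(cube) {
  v <- cube$values
  d <- dim(v)
  vapply(seq_len(d[1]), function(i) {
    sl <- v[i, , , drop = TRUE]
    if (d[3] == 1L) sl <- matrix(sl, ncol = 1)
    ok <- year_usable(is.na(sl), d[2])
    if (!any(ok)) return(NA_real_)
    cvs <- apply(sl[, ok, drop = FALSE], 2, function(w) {
      w <- w[!is.na(w)]
      m <- mean(w)
      if (m <= 0) stop("data integrity: non-positive mean on Kelvin scale")
      stats::sd(w) / m
    })
    mean(cvs)
  }, numeric(1))
}

#' Maximum habitat temperature over a species range
#'
#' The stated percentile (default 97.5) of the climatological annual-maximum
#' layer across the cells of the species' range, using the
#' linear-interpolation quantile (R type 7) so the value is reproducible
#' bit for bit.
#'
#' @param layer Per-cell values in degrees C (from
#'   [climatological_annual_max()]).
#' @param mask A [range_mask()].
#' @param percentile Percentile in \[0, 100\] (default 97.5).
#' @return Single numeric, degrees C.
#' @export
max_habitat_temperature <- function(layer, mask, percentile = 97.5) {
  vals <- layer[mask$cells]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no data: all range cells missing for ", mask$species)
  unname(stats::quantile(vals, probs = percentile / 100, type = 7))
}

#' Range-mean thermal variability
#'
#' Unweighted mean of the per-cell within-year CV layer over the cells of
#' the species' range.
#'
#' @param cv_layer Per-cell CVs (from [within_year_cv()]).
#' @param mask A [range_mask()].
#' @return Single dimensionless numeric.
#' @export
thermal_variability <- function(cv_layer, mask) {
  vals <- cv_layer[mask$cells]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("no data: all range cells missing for ", mask$species)
  mean(vals)
}

#' Per-species thermal exposure summaries
#'
#' Routes each species to its realm's temperature cube (freshwater species
#' to the freshwater cube; marine and brackish species to the marine/SST
#' cube), then summarises maximum habitat temperature and thermal
#' variability over its range mask.
#'
#' @param fresh_cube,marine_cube [temp_cube()]s (either may be NULL if no
#'   species needs it).
#' @param masks Named list of [range_mask()]s (names = species).
#' @param species_realm Named character vector: realm per species.
#' @param percentile Percentile for the habitat maximum.
#' @return List with `exposure` (data.frame: species, realm,
#'   max_habitat_temp, thermal_variability, n_cells) and `skipped`
#'   (character vector of species without a usable mask).
#' @export
exposure_for_species <- function(fresh_cube, marine_cube, masks, species_realm,
                                 percentile = 97.5) {
  layers <- list()
  get_layers <- function(realm) {
    cube <- if (realm == "freshwater") fresh_cube else marine_cube
    key <- if (realm == "freshwater") "freshwater" else "marine"
    if (is.null(layers[[key]])) {
      if (is.null(cube)) stop("no cube supplied for realm ", key)
      layers[[key]] <<- list(maxT = climatological_annual_max(cube),
                             cv = within_year_cv(cube))
    }
    layers[[key]]
  }
  species <- names(species_realm)
  skipped <- character(0)
  rows <- list()
  for (sp in species) {
    mk <- masks[[sp]]
    if (is.null(mk)) {
      skipped <- c(skipped, sp)
      next
    }
    ly <- get_layers(species_realm[[sp]])
    res <- tryCatch(
      data.frame(
        species = sp,
        realm = unname(species_realm[[sp]]),
        max_habitat_temp = max_habitat_temperature(ly$maxT, mk, percentile),
        thermal_variability = thermal_variability(ly$cv, mk),
        n_cells = length(mk$cells)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) skipped <- c(skipped, sp) else rows[[sp]] <- res
  }
  exposure <- if (length(rows)) do.call(rbind, rows) else
    data.frame(species = character(0), realm = character(0),
               max_habitat_temp = numeric(0), thermal_variability = numeric(0),
               n_cells = integer(0))
  rownames(exposure) <- NULL
  list(exposure = exposure, skipped = skipped)
}

#' Write / read a temperature cube as plain text
#'
#' Long-format CSV (cell, week, year, kelvin) plus a JSON sidecar holding
#' the grid coordinates and realm, so cubes round-trip without binary
#' formats.
#'
#' @param cube A [temp_cube()].
#' @param path Base path; writes `<path>.csv` and `<path>.json`.
#' @return `write_temp_cube`: the base path, invisibly. `read_temp_cube`:
#'   the cube.
#' @export
write_temp_cube <- function(cube, path) {
  d <- dim(cube$values)
  df <- data.frame(
    cell = rep(seq_len(d[1]), times = d[2] * d[3]),
    week = rep(rep(seq_len(d[2]), each = d[1]), times = d[3]),
    year = rep(cube$years, each = d[1] * d[2]),
    kelvin = as.vector(cube$values)
  )
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(lat = cube$lat, lon = cube$lon, years = cube$years,
         realm = cube$realm, weeks_per_year = cube$weeks_per_year),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_temp_cube
#' @export
read_temp_cube <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  df <- utils::read.csv(paste0(path, ".csv"))
  n_cells <- length(meta$lat)
  arr <- array(NA_real_, c(n_cells, meta$weeks_per_year, length(meta$years)))
  yr_idx <- match(df$year, meta$years)
  arr[cbind(df$cell, df$week, yr_idx)] <- df$kelvin
  temp_cube(arr, meta$lat, meta$lon, meta$years, realm = meta$realm, units = "K")
}
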