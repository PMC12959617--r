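# thermofish

Heat tolerance and its plasticity in freshwater and marine fishes: an
analysis pipeline from raw thermal-limit assays to global maps of warming
tolerance and of the time that acclimation buys before overheating.

## The problem and who this is for

Upper thermal limits of fishes are reported from incompatible protocols —
dynamic CTmax ramps and static LTmax trials — whose endpoints depend on
exposure duration. Comparative thermal ecologists who want to relate
tolerance to the temperatures species actually experience, and to quantify
how much acclimation shifts tolerance, need those records harmonised, the
habitat side quantified from gridded water temperatures over species
ranges, and the comparison done with phylogenetic models. `thermofish`
implements that chain as a tested R package plus a set of numbered
analysis drivers.

## The models at its core

* **Harmonisation**: endpoints are corrected to a 1-hour exposure,
  `HT_1h = HT_obs − b·log10(d)`, with the log-duration slope `b` estimated
  by a 50-replicate bootstrap (one dynamic record per species-study per
  replicate, pooled with static records, species random intercept).
* **Exposure**: per species, `MaxHabitatT` = 97.5th percentile across the
  range of the 30-year mean annual maximum weekly temperature, and
  `Tvariability` = range-mean of the across-year average within-year CV of
  weekly temperature (Kelvin scale).
* **Phylogenetic models**: PGLS with profiled Pagel's λ for exposure ~
  realm + |lat| + |lat|²; and REML phylogenetic mixed models (phylogeny +
  species random intercepts) for heat tolerance, e.g. model 3:

  `HT_1h ~ MaxHabitatT + Tvariability + AccT + AccT:Tvariability + Realm + AccT:Realm + AccT²`

  with `AccT` the within-species-centred acclimation temperature and
  `AccT²` an orthogonal quadratic.
* **Plasticity**: the acclimation response ratio `ARR = ∂HT/∂AccT`
  (model-derived, context-specific); warming tolerance
  `WT = HT_1h − MaxHabitatT`; times to overheating `t1 = WT/rate`,
  `t2 = t1/(1 − ARR)`; and the rate-free time gained by plasticity
  `t3 = (1/(1 − ARR) − 1)×100%`.
* **Global maps**: model 3 applied per gridcell at an empirically anchored
  acclimation value, ARR as the +1 °C warming-scenario contrast,
  uncertainty masking, and freshwater-priority realm combination.

A full synthetic-data generator (phylogeny, seasonal temperature fields,
range masks, assay records) with known ground truth backs every stage, so
the whole pipeline is testable offline; see the methods vignette
(`vignettes/thermal-plasticity-methods.Rmd`) for the model details and the
generator's defaults and limitations.

## Worked example

```r
library(thermofish)

# a synthetic study: 60 species, 12 x 8 grid, 5 years of weekly temperatures
b <- make_bundle(list(n_species = 60, grid = grid_spec(12, 8), years = 5),
                 seed = 42)

# harmonise to 1 h (bootstrapped log10-duration slope)
h <- harmonise_records(b$records, slope = "fit", n_bootstrap = 50,
                       rng_seed = 42)
sprintf("slope: %.3f +- %.4f", h$slope$slope, h$slope$slope_sd)
#> "slope: -1.169 +- 0.0321"      # generating value was -1.26

# model 3: tolerance ~ exposure + acclimation x (variability, realm)
dat <- merge(h$records, b$exposure, by = c("species", "realm"))
fit <- fit_mixed(build_design(dat, "model3"), tree = b$tree,
                 species_ids = dat$species)
fit
#> phylo_fit [reml] model3: n = 480 obs, 60 species
#>                      estimate       se       t      p     ci_lo    ci_hi
#> (Intercept)           12.3713  12.7835  0.9678 0.3332  -12.6843  37.4270
#> MaxHabitatT            0.6122   0.3554  1.7225 0.0850   -0.0844   1.3088
#> ...
#> AccT                   0.1224   0.0461  2.6566 0.0079    0.0321   0.2128
#> AccT2                 -2.8697   0.7489 -3.8319 0.0001   -4.3375  -1.4019
#> variance components:
#>    phylo  species residual
#>  4.12879  3.77800  0.56082
#> R2 marginal = 0.328, conditional = 0.956

arr <- arr_from_fit(fit, thermal_variability = b$exposure$thermal_variability,
                    realm = b$exposure$realm)
sprintf("mean ARR %.3f; time gained at ARR 0.2: %.0f%%",
        mean(arr), time_gained_pct(0.2))
#> "mean ARR 0.222; time gained at ARR 0.2: 25%"
```

The AccT coefficient (0.122, the ARR of a marine species in a thermally
constant habitat) recovers the generating value 0.12; the negative AccT²
term is the diminishing return of warm acclimation; an ARR of 0.2 buys 25%
more time before overheating, independent of the warming rate.

## The analysis

`analysis/01_simulate.R` … `06_global_maps.R` run the study end to end at
the default scale (300 species, 20 x 20 grid, 10 years), writing tables
under `results/`: the dataset accounting, the fitted duration slope,
per-species exposure, the three tolerance models and two exposure PGLS
fits, per-species plasticity metrics with the local-adaptation sensitivity
refit, and the combined global prediction layers. Each script prints what
it found; run them in order from the repository root.

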