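---
title: "Methods: heat tolerance, habitat exposure, and plasticity in fishes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: heat tolerance, habitat exposure, and plasticity in fishes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The scientific problem

Fish upper thermal limits are measured with incompatible protocols: dynamic
(CTmax) assays ramp temperature until loss of function, static (LTmax)
assays hold a fixed temperature and score mortality after a set time.
Because tolerated temperature falls with exposure duration, raw endpoints
are not comparable across studies. Once harmonised, thermal limits can be
confronted with the temperatures species actually experience — their
*exposure* — and with their capacity to shift limits by warm acclimation —
their *plasticity*, summarised by the acclimation response ratio (ARR,
degrees of tolerance gained per degree of acclimation). `thermofish`
implements that full chain: harmonisation, exposure, phylogenetic
regression, ARR extraction, and global maps of warming tolerance and of the
time gained by plasticity.

# Harmonisation to a 1-hour exposure

Endpoints are corrected to a common 1-hour duration with

$$HT_{1h} = HT_{obs} - b \cdot \log_{10}(d / 1\,\mathrm{h}),$$

where $d$ is the assay duration (reported for static trials; derived as
(endpoint − start)/ramp rate for dynamic trials, with an explicitly
reported duration preferred when both are available) and $b$ is the slope
of tolerance on log duration. $b$ is estimated by a 50-replicate bootstrap:
each replicate keeps a single dynamic record per species-by-study
combination (dynamic durations are partly methodological, so this prevents
pseudo-replication), pools all static records, and fits tolerance on
log duration with a species random intercept (`lme4`), or the full
phylogenetic mixed model when a tree is supplied. The reported slope is
the mean across replicates; its SD quantifies resampling spread only — it
is *not* the sampling SD of the estimator across datasets, which is an
order of magnitude larger at a few hundred species.

Two open choices were fixed as follows. The log base is $\log_{10}$ by
default (a slope near −1.26 is plausible under either base; the
`duration_slope` object carries its base so estimation and standardisation
can never silently mix bases). The bootstrap model uses a species random
intercept only; a study-level random effect is not included because study
and species are heavily aliased once one dynamic record per species-study
is kept.

Static LT50 and LT100 records are treated identically — a single duration
correction is applied to all records, with no mortality-fraction
adjustment.

# Thermal exposure

Exposure is computed from weekly water-temperature cubes (cell x
week-of-year x year, stored in Kelvin) and per-species range masks:

* **Maximum habitat temperature**: per cell, the maximum weekly temperature
  of each year averaged over the climatology period; per species, the
  97.5th percentile of that layer across its range, using the
  linear-interpolation quantile (R type 7) so the value is bit-for-bit
  reproducible. The percentile of the values 1..100 at 97.5 is 97.525
  under this rule.
* **Thermal variability**: per cell and year, the coefficient of variation
  of weekly temperature **on the Kelvin scale**; averaged over years, then
  averaged (unweighted) over the range's cells. Kelvin is the defensible
  scale here — a CV needs a ratio scale, and observed CV magnitudes
  (differences of ~0.006 being ~50% effects) are only consistent with a
  ~273–300 denominator. A property test asserts that adding a Kelvin
  constant strictly decreases the CV, which guards against accidental
  Celsius/Kelvin mixing.

Degenerate data rules: a (cell, year) with fewer than half its weeks
present is dropped from both aggregations for that year (it would bias the
within-year CV); 53-week years are folded into week 52 by averaging; realm
routing sends freshwater species to the freshwater cube and both marine
and brackish species to the sea-surface cube. Means across cells are
unweighted (not area-weighted), matching the per-gridcell definition of
the metrics.

Because no NetCDF/GeoTIFF-capable R package is part of this package's
dependency set, cubes, masks and prediction layers serialise as long-format
CSV with a JSON sidecar; the in-memory containers and all aggregation
semantics are format-agnostic.

# The statistical models

Three models of 1-h heat tolerance are fitted to record-level data, with
acclimation temperature centred within species (AccT below is this centred
value; centring removes the strong habitat–acclimation confound):

* **Model 1**: signed latitude with quadratic and cubic terms (hemispheres
  may differ), AccT, AccT-by-latitude interactions, and a quadratic AccT
  term.
* **Model 2**: maximum habitat temperature, thermal variability, AccT,
  AccT x variability, and the quadratic AccT term.
* **Model 3**: model 2 plus realm (reference: marine, the largest group
  contrast of interest being freshwater vs marine) and AccT x realm.

Latitude enters as raw polynomials (the printed formulas use plain powers
and the sign matters across hemispheres); the quadratic acclimation term
is an *orthogonal* second-degree polynomial built on the fitted sample —
zero mean, zero correlation with the linear term — whose basis is stored
with the fit so that predictions and derivatives on new data reuse it
exactly.

## Estimation

The paper-scale models are linear mixed models with two species-level
random intercepts: a phylogenetic effect with Brownian correlation from
the tree (Pagel's lambda fixed at 1 inside the mixed model, the
signal strength being carried by the ratio of the phylogenetic variance to
the total — the convention of Bayesian phylogenetic multilevel software)
and an iid species effect. Variance components maximise the restricted
likelihood. The REML criterion is evaluated through the Woodbury identity,
so each evaluation costs O(m^3) in the number of species m rather than
O(n^3) in records; a Nelder-Mead search over log-variances is polished by
BFGS. Fixed-effect intervals are normal-approximation 95% intervals from
the GLS covariance at the optimum; across the parameter-recovery suite
their empirical coverage is indistinguishable from nominal (estimate SD /
mean SE ratio ~1.03 at 300 species). A `backend = "mcmc"` request errors:
the deterministic REML backend is the supported estimator, and point
estimates and intervals of this model class agree closely with Bayesian
fits at these sample sizes.

For the sensitivity analysis against local adaptation, a third random
intercept for population (species x collection latitude) can be added; on
synthetic data generated *without* local adaptation the ARR moves by less
than 0.05, mirroring the published check.

Exposure metrics (one value per species) are analysed by PGLS with
Pagel's lambda estimated by profile maximum likelihood on [0, 1]
(coefficients and the residual variance are profiled out analytically; the
optimum is checked against a 21-point grid so no spurious local optimum is
returned). Realm and absolute latitude (quadratic) are the covariates. An
independent cross-check against `nlme::gls` with `ape::corPagel` is part
of the test suite; the implementation itself is self-contained.

Marginal and conditional R² follow the variance-partition definition:
fixed-effect prediction variance over total (marginal), adding the random
variances to the numerator (conditional).

# Plasticity metrics

The ARR is the derivative of the fitted predictor with respect to centred
acclimation: the AccT coefficient, plus the variability interaction times
the context CV, plus the realm contrast, plus the quadratic term's
derivative at the evaluation point. The quadratic contribution is
evaluated *exactly* from the stored orthogonal basis (a two-point central
difference is exact for a quadratic) — it is not assumed to vanish at the
centre. Species-level ARRs are reported at the species-mean acclimation
(centred value 0).

With warming tolerance $WT = HT_{1h} - T_{max,habitat}$ and a warming rate
$r$, the time to overheating is $t_1 = WT/r$ without plasticity and
$t_2 = t_1/(1-\mathrm{ARR})$ with it. As printed, the time equations have
habitat maximum minus tolerance in the numerator, which is negative
exactly when a species still has thermal headroom; since the quantity is
defined as a *time until overheating*, the implementation uses $WT/r$
(positive headroom gives positive time) and flags already-overheated cases
($WT < 0$) with $t_1 = t_2 = 0$ rather than returning negative times. The
time gained by plasticity,
$t_3 = (1/(1-\mathrm{ARR}) - 1) \times 100\%$, cancels the warming rate; a
property test verifies rate independence over a parameter grid. No default
warming rate is set — the rate is required only when $t_1, t_2$ are
requested.

# Global prediction

Per-gridcell predictions use model 3 with the cell's climatological
maximum and CV as inputs. The acclimation value used per cell is the
*anchor*: the centred acclimation at which a species' actual acclimation
temperature would coincide with the cell's maximum weekly temperature,
derived from the ordinary regression of actual acclimation on species
maximum habitat temperature (the direction — acclimation on habitat
maximum — follows the description of positive/negative standardised values
around the coincidence line). The per-cell ARR is the +1 degree forward
difference of the prediction (a warming scenario), exactly as defined for
the maps — note this equals the exact derivative evaluated half a degree
above the anchor for a quadratic predictor, which is how the
internal-consistency test states it. Prediction SDs propagate coefficient
uncertainty through the design row; cells above an SD threshold (default:
the 90th percentile of the layer, recorded in metadata) are masked, and
cells whose anchor falls outside the fitted acclimation range are flagged
as extrapolation but not masked. Freshwater and marine layers combine with
freshwater priority on overlap (coasts and estuaries), with per-cell
provenance retained and the overlap counted.

# The synthetic-data generator

Every pipeline stage is testable without downloads because the generator
produces a complete study with known truth:

* **Phylogeny**: pure-birth tree scaled to unit depth.
* **Climate cubes**: per cell, a latitudinal mean gradient (27 °C at the
  equator falling to 3 °C at 65°), a seasonal sinusoid whose amplitude
  grows from 1.5 K to 10 K with absolute latitude (crest placed exactly on
  a sampled week, so the noise-free annual maximum is exactly mean +
  amplitude), weekly Gaussian noise (0.5 K), and freshwater offsets fixed
  so the freshwater-minus-marine contrasts are +3.23 °C in annual maxima
  and +0.0063 in CV — the observed realm contrasts, used as the study
  conditions.
* **Ranges**: contiguous latitudinal bands; band centres evolve by
  Brownian motion on the tree and band breadth is itself a heritable
  log-scale trait around 20°, so exposure is phylogenetically structured.
  Collection latitudes fall within the band (with ~0.7° jitter between a
  species' populations, matching the narrow observed within-species
  latitudinal ranges), so latitude tracks exposure without being a
  deterministic proxy for it.
* **Records**: species basal tolerance = 20 + 0.46 x maximum habitat
  temperature + a lambda-scaled Brownian deviate (sd 2.5, lambda 0.8) + an
  iid species deviate (sd 1.5); each record adds ARR(context) x centred
  acclimation with ARR = 0.12 + 3.0 x CV + {0, +0.06, +0.05} for
  {marine, freshwater, brackish}, a negative quadratic acclimation term
  (−0.015 °C per °C²), the duration effect −1.26 x log10(duration), and
  residual noise (sd 0.75). Actual acclimation temperatures follow the
  anchor regression (intercept 4, slope 0.8, residual sd 1.5). Assays mix
  static trials (1, 24 or 96 h) and dynamic ramps (1–18 °C/h, 0.25–4 h)
  with start temperatures derived so the ramp arithmetic is exact.

Defaults sit at the study conditions: 300 species, four acclimation levels
3 °C apart (a 9 °C within-species range), two records per level, a 20 x 20
grid spanning 65°S–65°N, 10 years of weeks, realm frequencies
0.52/0.37/0.11 (freshwater/marine/brackish). Under these conditions the
overall mean ARR is about 0.20–0.22 and the model-2 marginal R² about
35–45%. Every stage draws from its own RNG stream derived from the bundle
seed, so stages are independently reproducible and byte-identical per
seed.

What the generator does **not** emulate — and what passing tests therefore
do not demonstrate about real data: realistic coastlines or river
networks (all cells are "water" for both realms); longitudinal range
structure; study-level methodological idiosyncrasies beyond duration;
local adaptation (deliberately absent, so the sensitivity analysis has a
known null); taxonomic error; and within-range heritable microhabitat
choice — the last means the exposure PGLS recovers weaker phylogenetic
signal (lambda roughly 0.2–0.7) than real fishes show, because in the
synthetic world exposure is largely a smooth function of the (heritable)
band geometry already captured by latitude and realm.

# Problem sizes and numerical choices

Parameter-recovery tests run 20 seeded replicates at 200–300 species —
large enough that interval coverage is near-asymptotic, small enough that
the whole suite runs in a few minutes on one CPU. Other fixed numerical
choices, gathered for reference: quantile type 7 everywhere a percentile
is taken; the median-latitude representative record resolves even counts
to the lower of the two middle latitudes; variance optimisation runs on
log-variances with a boundary warning below 1e-8 of the largest
component; PGLS lambda is compared against both interval endpoints
because the profile can be monotone; design matrices are checked for rank
and the offending collinear columns are named; realm contrast columns are
built only for realm levels present in the data.

# Known limitations

REML intervals ignore variance-component uncertainty (a percent-level
effect at these sizes); the duration-slope uncertainty is not propagated
into downstream standard errors (measurement-error modelling is out of
scope); there is no MCMC backend; gridded I/O is plain text; and the
global maps inherit every caveat of predicting from species-level models
into cells not tied to any particular species.
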