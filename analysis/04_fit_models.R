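#!/usr/bin/env Rscript
# Stage 4: the heat-tolerance models. Model 1 explains 1-h tolerance by
# (signed, cubic) latitude and acclimation; model 2 by habitat thermal
# maxima and variability; model 3 adds realm and its acclimation
# interaction. All are REML phylogenetic mixed models with phylogeny and
# species random intercepts.

suppressMessages(library(thermofish))

bundle <- read_bundle("results/bundle")
harm_rec <- read.csv("results/harmonised.csv")
expo <- read.csv("results/exposure.csv")
dat <- merge(harm_rec, expo, by = c("species", "realm"))

fits <- list()
for (mid in c("model1", "model2", "model3")) {
  d <- dat
  if (mid == "model1") d <- d[!is.na(d$latitude), , drop = FALSE]
  ds <- build_design(d, mid)
  fits[[mid]] <- suppressWarnings(
    fit_mixed(ds, tree = bundle$tree, species_ids = d$species))
  write_phylo_fit(fits[[mid]], file.path("results", paste0("fit_", mid, ".json")))
  cat(sprintf("%s: n = %d records, %d species; marginal R2 = %.1f%%, conditional = %.1f%%\n",
              mid, fits[[mid]]$n_obs, fits[[mid]]$n_species,
              100 * fits[[mid]]$r2_marginal, 100 * fits[[mid]]$r2_conditional))
}
cat("\nHabitat conditions vs latitude as predictors: marginal R2 ",
    sprintf("%.1f%% (model 2) vs %.1f%% (model 1)\n",
            100 * fits$model2$r2_marginal, 100 * fits$model1$r2_marginal))

cat("\nModel 3 fixed effects:\n")
print(round(fits$model3$coefficients[, c("estimate", "ci_lo", "ci_hi", "p")], 4))
cat("\nFits written to results/fit_model{1,2,3}.json\n")
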