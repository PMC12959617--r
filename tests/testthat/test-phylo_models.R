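test_that("lambda-scaled phylogenetic correlation behaves at its limits", {
  tr <- tree5()
  expect_equal(phylo_correlation(tr, 0), diag(5),
               ignore_attr = TRUE)

  # two tips sharing half their root-to-tip path -> off-diagonal 0.5
  cherry <- ape::read.tree(text = "((A:0.5,B:0.5):0.5,C:1);")
  C <- phylo_correlation(cherry, 1, species = c("A", "B", "C"))
  expect_equal(C["A", "B"], 0.5)
  expect_equal(C["A", "C"], 0)

  # symmetric and PSD for random trees and lambdas (eigen-decomposition check)
  for (s in 1:5) {
    tr10 <- simulate_tree(10, seed = s)
    Cl <- phylo_correlation(tr10, runif(1))
    expect_equal(Cl, t(Cl))
    expect_gte(min(eigen(Cl, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
  }

  expect_error(phylo_correlation(tree5(), 1, species = c("A", "Z")),
               "missing from tree.*Z")
})

test_that("design construction matches the printed model formulas", {
  set.seed(2)
  n <- 40
  dat <- data.frame(
    species = sprintf("s%02d", 1:n),
    heat_tolerance_std = rnorm(n, 30),
    acclimation_std = rnorm(n, 0, 3),
    latitude = runif(n, -50, 50),
    max_habitat_temp = runif(n, 10, 30),
    thermal_variability = runif(n, 0.005, 0.03),
    realm = sample(c("marine", "freshwater", "brackish"), n, TRUE))

  d2 <- build_design(dat, "model2")
  expect_equal(ncol(d2$X), 6)   # intercept, MaxT, Tvar, AccT, AccT:Tvar, AccT2
  d3 <- build_design(dat, "model3")
  expect_equal(ncol(d3$X), 10)  # + 2 realm contrasts + 2 AccT:realm contrasts
  d1 <- build_design(dat, "model1")
  expect_equal(ncol(d1$X), 9)   # intercept, 3 lat powers, AccT, 3 interactions, AccT2

  # orthogonal quadratic acclimation column: zero mean, orthogonal to linear
  q <- d2$X[, "AccT2"]
  expect_equal(mean(q), 0, tolerance = 1e-12)
  expect_equal(sum(q * dat$acclimation_std), 0, tolerance = 1e-10)
  # interaction columns are products of their parents
  expect_equal(d2$X[, "AccT:Tvariability"],
               dat$acclimation_std * dat$thermal_variability)

  # the stored basis reproduces the same columns on new data
  expect_equal(design_matrix(d3, dat[7:9, ]), d3$X[7:9, ], ignore_attr = TRUE)

  bad <- dat
  bad$realm[1] <- "estuarine"
  expect_error(build_design(bad, "model3"), "unknown realm")
  const <- dat
  const$acclimation_std <- 0
  expect_error(build_design(const, "model2"), "degenerate design")
})

test_that("PGLS equals OLS at lambda 0 and a dense-solve oracle in general", {
  tr <- tree5()
  set.seed(5)
  x <- rnorm(5)
  y <- 1 + 2 * x + rnorm(5, 0, 0.5)
  d <- list(X = cbind(`(Intercept)` = 1, x = x), y = y,
            species = c("A", "B", "C", "D", "E"))

  fit0 <- fit_pgls(d, tr, lambda = 0)
  ols <- coef(lm(y ~ x))
  expect_equal(fit0$coefficients$estimate, unname(ols), tolerance = 1e-10)

  # free-lambda fit must equal the closed-form (X'V^-1X)^-1 X'V^-1 y at its lambda
  fit <- fit_pgls(d, tr)
  V <- phylo_correlation(tr, fit$lambda, species = d$species)
  Vi <- solve(V)
  beta_oracle <- solve(t(d$X) %*% Vi %*% d$X, t(d$X) %*% Vi %*% y)
  expect_equal(fit$coefficients$estimate, as.numeric(beta_oracle),
               tolerance = 1e-8)

  # no spurious optimum: profile at the returned lambda beats a 21-point grid
  tr50 <- simulate_tree(50, seed = 3)
  C <- phylo_correlation(tr50, 1)
  set.seed(6)
  x50 <- rnorm(50)
  y50 <- 1 + x50 + as.numeric(t(chol(0.7 * C + 0.3 * diag(50))) %*% rnorm(50))
  d50 <- list(X = cbind(1, x50), y = y50, species = tr50$tip.label)
  f50 <- fit_pgls(d50, tr50)
  grid_ll <- pgls_profile(d50, tr50, seq(0, 1, by = 0.05))
  expect_gte(f50$log_likelihood, max(grid_ll) - 1e-6)
})

test_that("PGLS agrees with nlme::gls under a Pagel correlation", {
  skip_if_not_installed("nlme")
  tr <- simulate_tree(60, seed = 13)
  C <- phylo_correlation(tr, 1)
  set.seed(14)
  x <- rnorm(60)
  y <- 2 + 0.8 * x + as.numeric(t(chol(1.5 * (0.8 * C + 0.2 * diag(60)))) %*% rnorm(60))
  d <- list(X = cbind(1, x), y = y, species = tr$tip.label)
  fit <- fit_pgls(d, tr)

  df <- data.frame(y = y, x = x, species = tr$tip.label)
  ref <- nlme::gls(y ~ x, data = df,
                   correlation = ape::corPagel(0.5, tr, form = ~ species),
                   method = "ML")
  expect_equal(fit$lambda, as.numeric(ref$modelStruct$corStruct),
               tolerance = 1e-3)
  expect_equal(fit$coefficients$estimate, unname(coef(ref)), tolerance = 1e-4)
})

test_that("REML mixed model matches lme4 when there is no phylogeny term", {
  set.seed(8)
  n_sp <- 25
  sp <- rep(sprintf("s%02d", 1:n_sp), each = 4)
  u <- rnorm(n_sp, 0, 1.5)
  x <- rnorm(length(sp))
  y <- 3 + 0.6 * x + u[as.integer(factor(sp))] + rnorm(length(sp), 0, 0.7)
  d <- list(X = cbind(`(Intercept)` = 1, x = x), y = y, species = sp,
            model_id = "unit")
  class(d) <- "tol_design"
  fit <- fit_mixed(d, tree = NULL, species_ids = sp)
  ref <- lme4::lmer(y ~ x + (1 | sp), REML = TRUE)
  expect_equal(fit$coefficients$estimate, unname(lme4::fixef(ref)),
               tolerance = 1e-4)
  vc <- as.data.frame(lme4::VarCorr(ref))
  expect_equal(unname(fit$variance_components["species"]), vc$vcov[1],
               tolerance = 1e-3)
  expect_equal(unname(fit$variance_components["residual"]), vc$vcov[2],
               tolerance = 1e-3)
  # REML criterion improves along the optimisation (running minimum reaches
  # the final value from the first evaluation)
  expect_lte(min(fit$optimiser_trace), fit$optimiser_trace[1])
  expect_equal(min(fit$optimiser_trace), -2 * fit$log_likelihood,
               tolerance = 1e-8)
})

test_that("degenerate and star-tree limits reduce to simpler models", {
  # truth has no species or phylo variance -> variances collapse, coefs ~ OLS
  set.seed(9)
  sp <- rep(sprintf("s%02d", 1:20), each = 3)
  x <- rnorm(60)
  y <- 1 + 2 * x + rnorm(60, 0, 0.5)
  d <- list(X = cbind(1, x), y = y, species = sp)
  class(d) <- "tol_design"
  fit <- suppressWarnings(fit_mixed(d, tree = NULL, species_ids = sp))
  expect_lt(unname(fit$variance_components["species"]), 0.05)
  expect_equal(fit$coefficients$estimate, unname(coef(lm(y ~ x))),
               tolerance = 0.02)

  # star phylogeny: phylo term is indistinguishable from an iid species term,
  # so coefficients match the species-only fit
  star <- ape::stree(20, type = "star")
  star$edge.length <- rep(1, nrow(star$edge))
  star$tip.label <- sprintf("s%02d", 1:20)
  set.seed(10)
  u <- rnorm(20, 0, 1.2)
  y2 <- 1 + 0.5 * x + u[as.integer(factor(sp))] + rnorm(60, 0, 0.6)
  d2 <- list(X = cbind(1, x), y = y2, species = sp)
  class(d2) <- "tol_design"
  f_star <- suppressWarnings(fit_mixed(d2, tree = star, species_ids = sp))
  f_iid <- suppressWarnings(fit_mixed(d2, tree = NULL, species_ids = sp))
  expect_equal(f_star$coefficients$estimate, f_iid$coefficients$estimate,
               tolerance = 1e-6)
  # total species-level variance is what is identified
  expect_equal(sum(f_star$variance_components[c("phylo", "species")]),
               unname(f_iid$variance_components["species"]), tolerance = 1e-3)
})

test_that("predictions are invariant to row order and R2 matches its oracle", {
  sm <- small_model3_fit()
  fit <- sm$fit
  nd <- sm$data[sample(nrow(sm$data)), ]
  p1 <- predict(fit, nd)
  p2 <- predict(fit, nd[order(nd$record_id), ])
  expect_equal(p1[order(nd$record_id)], p2)

  # direct variance-ratio oracle for marginal / conditional R2
  yhat <- as.numeric(fit$design$X %*% fit$coefficients$estimate)
  vfix <- var(yhat)
  vran <- sum(fit$variance_components[c("phylo", "species")])
  vres <- unname(fit$variance_components["residual"])
  r2 <- r_squared(fit)
  expect_equal(unname(r2["marginal"]), vfix / (vfix + vran + vres),
               tolerance = 1e-10)
  expect_equal(unname(r2["conditional"]),
               (vfix + vran) / (vfix + vran + vres), tolerance = 1e-10)
  expect_true(r2["marginal"] <= r2["conditional"] && r2["conditional"] <= 1)

  # all random variances zero -> marginal equals conditional; zero fixed
  # effects -> marginal 0
  fake <- fit
  fake$variance_components <- c(phylo = 0, species = 0, residual = vres)
  r2f <- r_squared(fake)
  expect_equal(unname(r2f["marginal"]), unname(r2f["conditional"]))
  fake2 <- fit
  fake2$coefficients$estimate <- rep(0, nrow(fit$coefficients))
  expect_equal(unname(r_squared(fake2)["marginal"]), 0)
})

test_that("population-nested random intercepts barely move the ARR when no
           local adaptation was generated", {
  sm <- small_model3_fit(seed = 19)
  dat <- sm$data
  pop <- paste(dat$species, round(dat$latitude, 1))
  fit_pop <- suppressWarnings(
    fit_mixed(sm$fit$design, tree = sm$tree, species_ids = dat$species,
              population_ids = pop))
  arr0 <- arr_from_fit(sm$fit, thermal_variability = 0.015, realm = "marine")
  arr1 <- arr_from_fit(fit_pop, thermal_variability = 0.015, realm = "marine")
  expect_lt(abs(arr0 - arr1), 0.05)
  expect_true("population" %in% names(fit_pop$variance_components))
})

test_that("fits round-trip through JSON", {
  sm <- small_model3_fit(seed = 23, n_species = 20)
  path <- withr::local_tempfile(fileext = ".json")
  write_phylo_fit(sm$fit, path)
  back <- read_phylo_fit(path)
  expect_equal(back$coefficients$estimate, sm$fit$coefficients$estimate,
               tolerance = 1e-12)
  expect_equal(unlist(back$variance_components),
               sm$fit$variance_components, tolerance = 1e-12)
  expect_equal(back$model_id, "model3")
})
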