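#' Phylogenetic correlation structure under Pagel's lambda
#'
#' Species-by-species correlation implied by Brownian motion on the tree,
#' with off-diagonal entries (shared root-to-tip path over total depth)
#' multiplied by lambda. lambda = 0 gives the identity (star phylogeny);
#' lambda = 1 the full Brownian structure.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @param lambda Signal strength in \[0, 1\].
#' @param species Optional character vector; the matrix is ordered to these
#'   names, and an error lists any not present as tips.
#' @return Correlation matrix with unit diagonal.
#' @export
phylo_correlation <- function(tree, lambda = 1, species = NULL) {
  stopifnot(lambda >= 0, lambda <= 1)
  C <- ape::vcv(tree, corr = TRUE)
  if (!is.null(species)) {
    missing <- setdiff(species, rownames(C))
    if (length(missing)) {
      stop("species missing from tree: ", paste(missing, collapse = ", "))
    }
    C <- C[species, species, drop = FALSE]
  }
  Cl <- lambda * C
  diag(Cl) <- 1
  Cl
}

# ---- design construction ---------------------------------------------------

# each term: name; build(nd) -> column; dacc(nd) -> d(column)/d(acclimation_std)
term_const <- function(name, build, dacc = function(nd) rep(0, nrow(nd))) {
  list(name = name, build = build, dacc = dacc)
}

#' Build the response and fixed-effect design for one of the study models
#'
#' Supported models of 1-hour-standardised heat tolerance:
#' \describe{
#'   \item{model1}{signed latitude with quadratic and cubic terms, centred
#'     acclimation temperature, their interactions, and an orthogonal
#'     quadratic acclimation term.}
#'   \item{model2}{maximum habitat temperature, thermal variability, centred
#'     acclimation temperature, the acclimation-by-variability interaction,
#'     and the orthogonal quadratic acclimation term.}
#'   \item{model3}{model2 plus realm and the acclimation-by-realm
#'     interaction (reference level: marine).}
#'   \item{pgls_maxT / pgls_cv}{per-species exposure metric on realm and
#'     absolute latitude (quadratic), for PGLS.}
#' }
#' The quadratic acclimation term is an orthogonal polynomial constructed
#' on the fitted sample (zero mean, zero correlation with the linear term);
#' its basis is stored so predictions on new data reuse it, and so the
#' acclimation derivative (the ARR) can be evaluated exactly at any point.
#'
#' @param data Data.frame with the fields the model references
#'   (`heat_tolerance_std`, `acclimation_std`, `latitude`,
#'   `max_habitat_temp`, `thermal_variability`, `realm`, `species`).
#' @param model_id One of `"model1"`, `"model2"`, `"model3"`,
#'   `"pgls_maxT"`, `"pgls_cv"`.
#' @return Object of class `tol_design`: list with `X`, `y`, `species`,
#'   `model_id`, `terms`, `acc_basis`, `realm_levels`, `data_fields`.
#' @export
build_design <- function(data, model_id = c("model1", "model2", "model3",
                                            "pgls_maxT", "pgls_cv")) {
  model_id <- match.arg(model_id)
  need <- switch(model_id,
    model1 = c("heat_tolerance_std", "latitude", "acclimation_std"),
    model2 = c("heat_tolerance_std", "max_habitat_temp", "thermal_variability",
               "acclimation_std"),
    model3 = c("heat_tolerance_std", "max_habitat_temp", "thermal_variability",
               "acclimation_std", "realm"),
    pgls_maxT = c("max_habitat_temp", "realm", "abs_latitude"),
    pgls_cv = c("thermal_variability", "realm", "abs_latitude"))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing fields for ", model_id, ": ",
                         paste(miss, collapse = ", "))
  if ("realm" %in% need && !all(data$realm %in% REALMS)) {
    stop("unknown realm level: ",
         paste(setdiff(unique(data$realm), REALMS), collapse = ", "))
  }

  response <- switch(model_id, pgls_maxT = "max_habitat_temp",
                     pgls_cv = "thermal_variability", "heat_tolerance_std")
  y <- data[[response]]

  acc_basis <- NULL
  terms <- list(term_const("(Intercept)", function(nd) rep(1, nrow(nd))))

  add_acc_terms <- function(terms, covariates) {
    # linear acclimation term and its interactions with named covariates
    terms <- c(terms, list(term_const("AccT",
      build = function(nd) nd$acclimation_std,
      dacc = function(nd) rep(1, nrow(nd)))))
    for (cv in names(covariates)) {
      f <- covariates[[cv]]
      terms <- c(terms, list(local({
        ff <- f
        term_const(paste0("AccT:", cv),
          build = function(nd) nd$acclimation_std * ff(nd),
          dacc = function(nd) ff(nd))
      })))
    }
    terms
  }

  if (model_id %in% c("model1", "model2", "model3")) {
    x <- data$acclimation_std
    if (stats::var(x) <= 0) stop("degenerate design: constant acclimation_std")
    p <- stats::poly(x, 2)
    acc_basis <- attr(p, "coefs")
  }
  acc_quad_col <- function(nd) {
    stats::poly(nd$acclimation_std, 2, coefs = acc_basis)[, 2]
  }
  acc_quad_dacc <- function(nd) {
    # the basis column is an exact quadratic in acclimation_std, so a
    # central difference with any step is its exact derivative
    x <- nd$acclimation_std
    up <- nd; up$acclimation_std <- x + 1
    dn <- nd; dn$acclimation_std <- x - 1
    (acc_quad_col(up) - acc_quad_col(dn)) / 2
  }

  if (model_id == "model1") {
    if (stats::var(data$latitude) <= 0) stop("degenerate design: constant latitude")
    for (k in 1:3) {
      terms <- c(terms, list(local({
        kk <- k
        term_const(paste0("Lat", if (kk > 1) kk else ""),
                   function(nd) nd$latitude^kk)
      })))
    }
    terms <- add_acc_terms(terms, list(
      Lat = function(nd) nd$latitude,
      Lat2 = function(nd) nd$latitude^2,
      Lat3 = function(nd) nd$latitude^3))
    terms <- c(terms, list(term_const("AccT2", acc_quad_col, acc_quad_dacc)))
  } else if (model_id %in% c("model2", "model3")) {
    terms <- c(terms, list(
      term_const("MaxHabitatT", function(nd) nd$max_habitat_temp),
      term_const("Tvariability", function(nd) nd$thermal_variability)))
    terms <- add_acc_terms(terms, list(
      Tvariability = function(nd) nd$thermal_variability))
    if (model_id == "model3") {
      realms_present <- intersect(c("freshwater", "brackish"),
                                  unique(data$realm))
      for (r in realms_present) {
        terms <- c(terms, list(local({
          rr <- r
          term_const(paste0("Realm", rr),
                     function(nd) as.numeric(nd$realm == rr))
        })))
      }
      for (r in realms_present) {
        terms <- c(terms, list(local({
          rr <- r
          term_const(paste0("AccT:Realm", rr),
            build = function(nd) nd$acclimation_std * (nd$realm == rr),
            dacc = function(nd) as.numeric(nd$realm == rr))
        })))
      }
    }
    terms <- c(terms, list(term_const("AccT2", acc_quad_col, acc_quad_dacc)))
  } else {
    # PGLS exposure models: realm + absolute latitude (quadratic)
    for (r in c("freshwater", "brackish")) {
      terms <- c(terms, list(local({
        rr <- r
        term_const(paste0("Realm", rr),
                   function(nd) as.numeric(nd$realm == rr))
      })))
    }
    terms <- c(terms, list(
      term_const("AbsLat", function(nd) nd$abs_latitude),
      term_const("AbsLat2", function(nd) nd$abs_latitude^2)))
  }

  design <- structure(
    list(X = NULL, y = y, species = data$species, model_id = model_id,
         terms = terms, acc_basis = acc_basis,
         realm_levels = c("marine", "freshwater", "brackish"),
         response = response),
    class = "tol_design")
  design$X <- design_matrix(design, data)

  qrX <- qr(design$X)
  if (qrX$rank < ncol(design$X)) {
    bad <- colnames(design$X)[qrX$pivot[(qrX$rank + 1):ncol(design$X)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  design
}

#' Evaluate a design's fixed-effect matrix on (new) data
#'
#' @param design A `tol_design`.
#' @param newdata Data.frame with the fields the design references.
#' @return Numeric matrix with one column per fitted term.
#' @export
design_matrix <- function(design, newdata) {
  cols <- lapply(design$terms, function(tm) tm$build(newdata))
  X <- do.call(cbind, cols)
  colnames(X) <- vapply(design$terms, `[[`, character(1), "name")
  X
}

# d X / d acclimation_std, row-wise (for ARR)
design_acc_derivative <- function(design, newdata) {
  cols <- lapply(design$terms, function(tm) tm$dacc(newdata))
  D <- do.call(cbind, cols)
  colnames(D) <- vapply(design$terms, `[[`, character(1), "name")
  D
}

# ---- PGLS ------------------------------------------------------------------

# chol-based GLS pieces for correlation matrix V: returns beta, rss (V-metric),
# logdetV, XtViX
gls_solve <- function(X, y, V) {
  R <- chol(V)
  Xt <- backsolve(R, X, transpose = TRUE)
  yt <- backsolve(R, y, transpose = TRUE)
  XtViX <- crossprod(Xt)
  beta <- solve(XtViX, crossprod(Xt, yt))
  r <- yt - Xt %*% beta
  list(beta = beta, rss = sum(r^2), logdetV = 2 * sum(log(diag(R))),
       XtViX = XtViX)
}

pgls_loglik <- function(lambda, X, y, C) {
  n <- length(y)
  V <- lambda * C
  diag(V) <- 1
  g <- gls_solve(X, y, V)
  sigma2 <- g$rss / n
  -0.5 * (n * log(2 * pi * sigma2) + g$logdetV + n)
}

#' Phylogenetic generalised least squares with Pagel's lambda
#'
#' One observation per species. lambda is estimated by maximising the
#' profile likelihood of the GLS model over \[0, 1\] (the residual variance
#' and coefficients are profiled out analytically); coefficients are the
#' generalised least-squares estimates at the optimal lambda, with t
#' statistics on n − p degrees of freedom.
#'
#' @param design A `tol_design` built on a per-species table (or any list
#'   with `X`, `y`, `species`).
#' @param tree `ape::phylo` covering all species in the design.
#' @param lambda Fix lambda instead of estimating (e.g. 0 for OLS).
#' @return Object of class `phylo_fit`.
#' @export
fit_pgls <- function(design, tree, lambda = NULL) {
  X <- design$X
  y <- design$y
  species <- design$species
  if (anyDuplicated(species)) stop("fit_pgls expects one row per species")
  C <- phylo_correlation(tree, lambda = 1, species = species)
  n <- length(y)
  p <- ncol(X)

  if (is.null(lambda)) {
    opt <- stats::optimise(function(l) pgls_loglik(l, X, y, C),
                           interval = c(0, 1), maximum = TRUE, tol = 1e-8)
    cand <- c(opt$maximum, 0, 1)
    ll <- vapply(cand, function(l) pgls_loglik(l, X, y, C), numeric(1))
    lambda <- cand[which.max(ll)]
  }
  V <- lambda * C
  diag(V) <- 1
  g <- gls_solve(X, y, V)
  sigma2 <- g$rss / n
  loglik <- pgls_loglik(lambda, X, y, C)
  vcov_beta <- solve(g$XtViX) * (g$rss / (n - p))
  se <- sqrt(diag(vcov_beta))
  est <- as.numeric(g$beta)
  tval <- est / se
  coefs <- data.frame(
    estimate = est, se = se, t = tval,
    p = 2 * stats::pt(-abs(tval), df = n - p),
    ci_lo = est - stats::qt(0.975, n - p) * se,
    ci_hi = est + stats::qt(0.975, n - p) * se,
    row.names = colnames(X))

  # GLS R^2 on fixed effects (no random components in PGLS)
  r2 <- 1 - g$rss / gls_solve(matrix(1, n, 1), y, V)$rss
  structure(
    list(backend = "pgls", coefficients = coefs, vcov_beta = vcov_beta,
         lambda = lambda, sigma2 = sigma2,
         variance_components = c(residual = sigma2),
         r2_marginal = r2, r2_conditional = NA_real_,
         log_likelihood = loglik, n_obs = n, n_species = n,
         design = design, convergence = 0L),
    class = "phylo_fit")
}

#' Profile log-likelihood of the PGLS model over a lambda grid
#'
#' @param design A `tol_design` (one row per species).
#' @param tree `ape::phylo`.
#' @param lambdas Grid of lambda values.
#' @return Numeric vector of profile log-likelihoods.
#' @export
pgls_profile <- function(design, tree, lambdas = seq(0, 1, by = 0.05)) {
  C <- phylo_correlation(tree, lambda = 1, species = design$species)
  vapply(lambdas, function(l) pgls_loglik(l, design$X, design$y, C), numeric(1))
}

# ---- phylogenetic linear mixed model (REML) --------------------------------

# V = sigma_e^2 I + Z G Z', G block-diagonal:
#   species block  : sigma_p^2 C + sigma_s^2 I   (phylo + iid species, lambda
#                    fixed at 1 inside the mixed model; signal strength is
#                    carried by the ratio sigma_p^2 / total)
#   population blk : sigma_pop^2 I  (optional, nested in species)
# All REML quantities use the Woodbury identity so each evaluation costs
# O(q^3) in q = n_species (+ n_populations), never O(n^3).
mixed_reml_env <- function(y, X, species_ids, C, population_ids = NULL) {
  sp <- factor(species_ids, levels = if (!is.null(C)) rownames(C) else
    unique(species_ids))
  m <- nlevels(sp)
  Zs <- stats::model.matrix(~ sp - 1)
  Z <- Zs
  npop <- 0L
  if (!is.null(population_ids)) {
    pp <- factor(population_ids)
    npop <- nlevels(pp)
    Z <- cbind(Zs, stats::model.matrix(~ pp - 1))
  }
  list(
    y = y, X = X, C = C, m = m, npop = npop, n = length(y), p = ncol(X),
    ZtZ = crossprod(Z), ZtX = crossprod(Z, X), Zty = crossprod(Z, y),
    XtX = crossprod(X), Xty = crossprod(X, y), yty = sum(y^2)
  )
}

# theta: log variances c(phylo?, species, pop?, resid); returns -2 REML
# log-likelihood and, if full = TRUE, the coefficient solution
mixed_reml_eval <- function(theta, env, has_phylo, full = FALSE) {
  i <- 1L
  s2p <- if (has_phylo) exp(theta[i]) else 0
  if (has_phylo) i <- i + 1L
  s2s <- exp(theta[i]); i <- i + 1L
  s2pop <- if (env$npop > 0) exp(theta[i]) else NULL
  if (env$npop > 0) i <- i + 1L
  s2e <- exp(theta[i])

  m <- env$m
  Gs <- diag(s2s, m)
  if (has_phylo) Gs <- Gs + s2p * env$C
  # block inverse / logdet of G
  Rg <- tryCatch(chol(Gs), error = function(e) NULL)
  if (is.null(Rg)) return(if (full) NULL else 1e10)
  logdetG <- 2 * sum(log(diag(Rg)))
  Gs_inv <- chol2inv(Rg)
  q <- m + env$npop
  Ginv <- matrix(0, q, q)
  Ginv[1:m, 1:m] <- Gs_inv
  if (env$npop > 0) {
    idx <- (m + 1):q
    diag(Ginv)[idx] <- 1 / s2pop
    logdetG <- logdetG + env$npop * log(s2pop)
  }

  M <- s2e * Ginv + env$ZtZ
  Rm <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(Rm)) return(if (full) NULL else 1e10)
  logdetM <- 2 * sum(log(diag(Rm)))

  # A' V^-1 B = (A'B - (Z'A)' M^-1 (Z'B)) / s2e
  solveM <- function(B) backsolve(Rm, backsolve(Rm, B, transpose = TRUE))
  MiZtX <- solveM(env$ZtX)
  MiZty <- solveM(env$Zty)
  XtViX <- (env$XtX - crossprod(env$ZtX, MiZtX)) / s2e
  XtViy <- (env$Xty - crossprod(env$ZtX, MiZty)) / s2e
  ytViy <- (env$yty - crossprod(env$Zty, MiZty)) / s2e

  Rx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(Rx)) return(if (full) NULL else 1e10)
  beta <- backsolve(Rx, backsolve(Rx, XtViy, transpose = TRUE))
  yPy <- as.numeric(ytViy - crossprod(XtViy, beta))
  if (yPy <= 0) return(if (full) NULL else 1e10)
  logdetV <- (env$n - q) * log(s2e) + logdetM + logdetG
  logdetXtViX <- 2 * sum(log(diag(Rx)))
  m2ll <- (env$n - env$p) * log(2 * pi) + logdetV + logdetXtViX + yPy

  if (!full) return(as.numeric(m2ll))
  list(m2ll = as.numeric(m2ll), beta = as.numeric(beta),
       vcov_beta = chol2inv(Rx),
       variances = c(phylo = if (has_phylo) s2p else NA_real_,
                     species = s2s,
                     population = if (env$npop > 0) s2pop else NA_real_,
                     residual = s2e))
}

#' Phylogenetic linear mixed model by REML
#'
#' Fits heat tolerance (or any response) on the design's fixed effects with
#' random intercepts for phylogeny (Brownian correlation across species,
#' from the tree) and species identity, plus optionally populations nested
#' within species. Variance components maximise the restricted likelihood;
#' the likelihood is evaluated through the Woodbury identity so cost scales
#' with the number of species, not records. Fixed-effect intervals are
#' normal-approximation 95% intervals from the GLS covariance at the
#' optimum.
#'
#' @param design A `tol_design` (record-level; multiple rows per species).
#' @param tree Optional `ape::phylo`; omit to drop the phylogenetic term.
#' @param species_ids Character vector of species per record; defaults to
#'   `design$species`.
#' @param population_ids Optional population identifier per record (e.g.
#'   species x collection latitude) for the local-adaptation sensitivity
#'   structure.
#' @param backend `"reml"` (default). `"mcmc"` is not implemented.
#' @return Object of class `phylo_fit` with coefficients, variance
#'   components, marginal/conditional R2 and the optimiser trace.
#' @export
fit_mixed <- function(design, tree = NULL, species_ids = design$species,
                      population_ids = NULL, backend = c("reml", "mcmc")) {
  backend <- match.arg(backend)
  if (backend == "mcmc") {
    stop("mcmc backend is not implemented; use backend = 'reml'")
  }
  X <- design$X
  y <- design$y
  has_phylo <- !is.null(tree)
  C <- NULL
  if (has_phylo) {
    C <- phylo_correlation(tree, lambda = 1, species = unique(species_ids))
  }
  env <- mixed_reml_env(y, X, species_ids, C, population_ids)

  v0 <- max(stats::var(stats::lm.fit(X, y)$residuals), 1e-6)
  k <- 1L + has_phylo + (env$npop > 0)
  theta0 <- log(c(rep(v0 / (k + 1), k), v0 / (k + 1) + v0 / 2))

  trace <- numeric(0)
  fn <- function(th) {
    val <- mixed_reml_eval(th, env, has_phylo)
    trace <<- c(trace, val)
    val
  }
  opt <- stats::optim(theta0, fn, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  opt2 <- tryCatch(
    stats::optim(opt$par, fn, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-12)),
    error = function(e) opt)
  if (!is.null(opt2$value) && is.finite(opt2$value) && opt2$value <= opt$value) {
    opt <- opt2
  }
  if (!is.finite(opt$value) || opt$value >= 1e10) {
    stop("fit_mixed did not converge; optimiser trace attached",
         call. = FALSE)
  }
  sol <- mixed_reml_eval(opt$par, env, has_phylo, full = TRUE)
  if (any(opt$par < log(1e-8 * max(exp(opt$par))))) {
    warning("variance component at boundary (collapsed toward zero)")
  }

  est <- sol$beta
  se <- sqrt(diag(sol$vcov_beta))
  z <- est / se
  coefs <- data.frame(
    estimate = est, se = se, t = z,
    p = 2 * stats::pnorm(-abs(z)),
    ci_lo = est - 1.96 * se, ci_hi = est + 1.96 * se,
    row.names = colnames(X))

  vc <- sol$variances[!is.na(sol$variances)]
  fit <- structure(
    list(backend = "reml", coefficients = coefs, vcov_beta = sol$vcov_beta,
         lambda = NA_real_, variance_components = vc,
         log_likelihood = -sol$m2ll / 2, n_obs = env$n, n_species = env$m,
         design = design, optimiser_trace = trace,
         convergence = opt$convergence),
    class = "phylo_fit")
  r2 <- r_squared(fit)
  fit$r2_marginal <- r2[["marginal"]]
  fit$r2_conditional <- r2[["conditional"]]
  fit
}

#' @export
print.phylo_fit <- function(x, ...) {
  cat(sprintf("phylo_fit [%s] %s: n = %d obs, %d species\n", x$backend,
              x$design$model_id %||% "", x$n_obs, x$n_species))
  print(round(x$coefficients, 4))
  cat("variance components:\n")
  print(round(x$variance_components, 5))
  if (!is.na(x$lambda)) cat(sprintf("lambda = %.3f\n", x$lambda))
  cat(sprintf("R2 marginal = %.3f, conditional = %.3f\n",
              x$r2_marginal, x$r2_conditional))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Marginal and conditional R-squared of a mixed fit
#'
#' Variance-partition R2: marginal is the variance of the fixed-effect
#' predictions over (that variance + all random-effect variances + residual
#' variance); conditional adds the random-effect variances to the
#' numerator.
#'
#' @param fit A `phylo_fit` from [fit_mixed()].
#' @return Named numeric: `marginal`, `conditional`.
#' @export
r_squared <- function(fit) {
  yhat <- as.numeric(fit$design$X %*% fit$coefficients$estimate)
  vf <- stats::var(yhat)
  vc <- fit$variance_components
  vr <- sum(vc[setdiff(names(vc), "residual")])
  ve <- vc[["residual"]]
  tot <- vf + vr + ve
  if (tot <= 0) stop("undefined R2: zero total variance")
  c(marginal = vf / tot, conditional = (vf + vr) / tot)
}

#' Fixed-effect predictions from a fitted model
#'
#' Evaluates the stored design (including the stored orthogonal acclimation
#' basis) on new data and returns the fixed-effect linear predictor, with
#' its standard error from the coefficient covariance when requested.
#'
#' @param object A `phylo_fit`.
#' @param newdata Data.frame with the design's fields.
#' @param se Logical; also return prediction SEs (coefficient uncertainty
#'   propagated through the design row).
#' @param ... Unused.
#' @return Numeric vector, or list with `fit` and `se`.
#' @export
predict.phylo_fit <- function(object, newdata, se = FALSE, ...) {
  X <- design_matrix(object$design, newdata)
  mu <- as.numeric(X %*% object$coefficients$estimate)
  if (!se) return(mu)
  s <- sqrt(rowSums((X %*% object$vcov_beta) * X))
  list(fit = mu, se = s)
}

#' Serialise / restore a fit as JSON
#'
#' Exports coefficients, variance components, lambda, R2 and the orthogonal
#' acclimation basis so a fit round-trips losslessly through text.
#'
#' @param fit A `phylo_fit`.
#' @param path Output JSON path.
#' @return `write_phylo_fit`: the path, invisibly; `read_phylo_fit` returns
#'   the restored list (coefficients and metadata; the design matrix itself
#'   is not serialised).
#' @export
write_phylo_fit <- function(fit, path) {
  out <- list(
    backend = fit$backend, model_id = fit$design$model_id,
    coefficients = cbind(term = rownames(fit$coefficients), fit$coefficients),
    vcov_beta = as.matrix(fit$vcov_beta),
    variance_components = as.list(fit$variance_components),
    lambda = fit$lambda, r2_marginal = fit$r2_marginal,
    r2_conditional = fit$r2_conditional,
    log_likelihood = fit$log_likelihood,
    n_obs = fit$n_obs, n_species = fit$n_species,
    acc_basis = fit$design$acc_basis)
  jsonlite::write_json(out, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_phylo_fit
#' @export
read_phylo_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
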