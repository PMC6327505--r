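## Model fitting and structural identifiability for wash-in kinetics.
##
## The full parameter set of the two-strain wash-in model is
##   mu_parent, km_parent, yield_parent, mu_mutant, km_mutant, yield_mutant,
##   amount (emergence amount in the chosen mode), t_emerge.
## The pseudo-parameter "yield" may be used instead of the two per-strain
## yields: it sets a biomass yield common to both strains, which is how the
## non-identifiable yield/emergence pair is exposed (observed fractions
## constrain only amount/yield, never each alone).

PARAM_NAMES <- c("mu_parent", "km_parent", "yield_parent",
                 "mu_mutant", "km_mutant", "yield_mutant",
                 "amount", "t_emerge")

#' Fit specification for the wash-in model
#'
#' @param free Named list mapping free parameter names to `c(lower, upper)`
#'   bounds (all bounds must be positive; optimisation runs in log space).
#'   Allowed names: `r paste0('\x60', PARAM_NAMES, '\x60', collapse = ", ")`,
#'   plus `yield` (a single yield shared by both strains).
#' @param fixed Named numeric vector/list of the remaining parameter values.
#' @param loss `"logit"` (residuals on the logit-frequency scale, default;
#'   stabilises the sigmoidal rise) or `"fraction"`.
#' @param weights Optional per-observation weights.
#' @return A `fit_spec` object.
#' @export
fit_spec <- function(free, fixed, loss = c("logit", "fraction"),
                     weights = NULL) {
  loss <- match.arg(loss)
  if (!is.list(free) || is.null(names(free)) || !length(free))
    abort("'free' must be a non-empty named list of c(lower, upper) bounds")
  fixed <- as.list(fixed)
  allowed <- c(PARAM_NAMES, "yield")
  bad <- setdiff(c(names(free), names(fixed)), allowed)
  if (length(bad)) abort("unknown parameter(s): %s", paste(bad, collapse = ", "))
  if (length(intersect(names(free), names(fixed))))
    abort("parameters cannot be both free and fixed")
  for (nm in names(free)) {
    b <- free[[nm]]
    if (length(b) != 2L || any(!is.finite(b)) || b[1] <= 0 || b[1] >= b[2])
      abort("bounds for '%s' must satisfy 0 < lower < upper", nm)
  }
  covered <- function(p) {
    nms <- c(names(free), names(fixed))
    p %in% nms ||
      (p %in% c("yield_parent", "yield_mutant") && "yield" %in% nms)
  }
  missing <- PARAM_NAMES[!vapply(PARAM_NAMES, covered, TRUE)]
  if (length(missing))
    abort("every model parameter must be free or fixed; missing: %s",
          paste(missing, collapse = ", "))
  structure(list(free = free, fixed = fixed, loss = loss, weights = weights),
            class = "fit_spec")
}

# assemble a full named parameter list from free values + fixed values
assemble_params <- function(theta, fixed) {
  p <- c(as.list(theta), fixed)
  if (!is.null(p$yield)) {
    p$yield_parent <- p$yield
    p$yield_mutant <- p$yield
  }
  p
}

# predicted observations for one full parameter list:
# logit(fraction) at `generations` (+ log total biomass if include_biomass)
washin_predict <- function(p, config, generations,
                           emergence_mode = "frequency",
                           t_unit = "generations",
                           include_biomass = FALSE, eps = 1e-9,
                           rtol = 1e-8, atol = 1e-10) {
  parent <- strain_params("parent", p$mu_parent, p$km_parent, p$yield_parent)
  mutant <- strain_params("mutant", p$mu_mutant, p$km_mutant, p$yield_mutant)
  em <- emergence_spec(p$t_emerge, p$amount, mode = emergence_mode,
                       unit = t_unit)
  t_end <- generations_to_hours(max(generations), config$D) + 1e-6
  sim <- simulate_washin(parent, mutant, config, em, t_end,
                         sample_generations = generations,
                         rtol = rtol, atol = atol)
  out <- logit(pmin(pmax(sim$fractions$fraction, eps), 1 - eps))
  if (include_biomass) {
    keep <- match_generations(
      hours_to_generations(sim$trajectory$times, config$D), generations)
    out <- c(out, log(pmax(rowSums(sim$trajectory$x)[keep], 1e-300)))
  }
  out
}

washin_residuals <- function(theta, spec, obs, config, emergence_mode,
                             t_unit, biomass = NULL) {
  p <- assemble_params(theta, spec$fixed)
  # Clip observed and predicted fractions identically. With read depths the
  # clip is the half-read continuity correction, so a zero-count sample and
  # a model fraction of zero agree instead of producing a huge logit gap.
  eps <- if (!is.null(obs$depth)) 1 / (2 * max(obs$depth)) else 1e-6
  pred <- washin_predict(p, config, obs$generations,
                         emergence_mode = emergence_mode, t_unit = t_unit,
                         include_biomass = !is.null(biomass), eps = eps)
  nf <- length(obs$generations)
  f_obs <- pmin(pmax(obs$fraction, eps), 1 - eps)
  if (spec$loss == "logit") {
    r <- logit(f_obs) - pred[seq_len(nf)]
  } else {
    r <- f_obs - inv_logit(pred[seq_len(nf)])
  }
  if (!is.null(spec$weights)) r <- r * sqrt(spec$weights)
  if (!is.null(biomass))
    r <- c(r, log(pmax(biomass$biomass, 1e-300)) - pred[-seq_len(nf)])
  r
}

#' Fit the wash-in competition model to a fraction time series
#'
#' Bounded nonlinear least squares (multi-start, L-BFGS-B in log-parameter
#' space) of the two-strain chemostat wash-in model against an observed
#' variant-fraction series, optionally augmented with total-biomass
#' observations. The result carries a linearised covariance and structural
#' identifiability diagnostics: parameter pairs estimable only as ratios are
#' flagged from the near-null eigenvectors of the Fisher information matrix.
#'
#' @param data A [fraction_series()] with at least 2 observations.
#' @param spec A [fit_spec()].
#' @param config A [chemostat_config()].
#' @param biomass Optional data.frame with columns `generation`, `biomass`
#'   (total biomass observations; included as log-scale residuals).
#' @param emergence_mode `"frequency"` or `"absolute"` (meaning of the
#'   `amount` parameter).
#' @param t_unit Unit of `t_emerge`: `"generations"` or `"hours"`.
#' @param n_starts Number of multi-start initialisations (Latin hypercube in
#'   log-bounds; the first start is the log-midpoint). Default 8.
#' @param seed Seed for the multi-start design. Default 1363.
#' @param null_threshold Relative FIM eigenvalue below which a direction is
#'   declared near-null (see [sensitivity_washin()]).
#' @return A `fit_result`: estimates, residual_sum, covariance (with
#'   `singular` attribute), identifiable_combos, n_obs, convergence info.
#' @export
fit_washin <- function(data, spec, config, biomass = NULL,
                       emergence_mode = c("frequency", "absolute"),
                       t_unit = c("generations", "hours"),
                       n_starts = 8L, seed = 1363L, null_threshold = 1e-6) {
  stopifnot(inherits(data, "fraction_series"), inherits(spec, "fit_spec"),
            inherits(config, "chemostat_config"))
  emergence_mode <- match.arg(emergence_mode)
  t_unit <- match.arg(t_unit)
  if (length(data$generations) < 2L) abort("need at least 2 observations")
  free_nm <- names(spec$free)
  np <- length(free_nm)
  lo <- log(vapply(spec$free, `[`, 0, 1))
  hi <- log(vapply(spec$free, `[`, 0, 2))

  objective <- function(lth) {
    theta <- setNames(exp(lth), free_nm)
    r <- tryCatch(washin_residuals(theta, spec, data, config,
                                   emergence_mode, t_unit, biomass),
                  error = function(e) NULL)
    if (is.null(r) || any(!is.finite(r))) return(1e12)
    sum(r^2)
  }

  starts <- multi_start(lo, hi, n_starts, seed)
  fits <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    fits[[i]] <- tryCatch(
      optim(starts[i, ], objective, method = "L-BFGS-B",
            lower = lo, upper = hi,
            control = list(maxit = 300, factr = 1e7)),
      error = function(e) list(value = Inf))
  }
  vals <- vapply(fits, `[[`, 0, "value")
  if (all(!is.finite(vals)) || min(vals) >= 1e12)
    abort("non-finite loss at all multi-start initialisations")
  best <- fits[[which.min(vals)]]
  theta <- setNames(exp(best$par), free_nm)

  # linearised covariance (Gauss-Newton) on the natural parameter scale
  J <- residual_jacobian(theta, spec, data, config, emergence_mode, t_unit,
                         biomass)
  n_obs <- nrow(J)
  jtj <- crossprod(J)
  ev <- eigen(jtj, symmetric = TRUE)
  singular <- ev$values[np] < null_threshold * max(ev$values[1], 1e-300)
  dof <- max(n_obs - np, 1L)
  sigma2 <- best$value / dof
  covariance <- sigma2 * pseudo_inverse(jtj)
  dimnames(covariance) <- list(free_nm, free_nm)

  sens <- sensitivity_washin(assemble_params(theta, spec$fixed), config,
                             data$generations, free = free_nm,
                             emergence_mode = emergence_mode, t_unit = t_unit,
                             include_biomass = !is.null(biomass),
                             null_threshold = null_threshold)

  structure(list(estimates = theta, residual_sum = best$value,
                 covariance = covariance, singular = singular,
                 identifiable_combos = sens$ratio_pairs,
                 sensitivity = sens, n_obs = n_obs,
                 convergence = best$convergence,
                 start_values = vals, spec = spec),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>\n  estimates:\n")
  print(signif(x$estimates, 5))
  cat(sprintf("  residual_sum = %.4g on %d observations\n",
              x$residual_sum, x$n_obs))
  if (x$singular)
    cat("  covariance: SINGULAR (ratio-only identifiable directions present)\n")
  if (length(x$identifiable_combos))
    cat("  estimable only as ratios:",
        paste(x$identifiable_combos, collapse = "; "), "\n")
  invisible(x)
}

# midpoint + stratified Latin-hypercube starts in log-bound space
multi_start <- function(lo, hi, n_starts, seed) {
  np <- length(lo)
  s <- matrix((lo + hi) / 2, 1L, np)
  if (n_starts > 1L) {
    u <- with_seed(seed, {
      m <- matrix(0, n_starts - 1L, np)
      for (j in seq_len(np))
        m[, j] <- (sample(n_starts - 1L) - runif(n_starts - 1L)) /
          (n_starts - 1L)
      m
    })
    s <- rbind(s, sweep(sweep(u, 2L, hi - lo, `*`), 2L, lo, `+`))
  }
  s
}

residual_jacobian <- function(theta, spec, obs, config, emergence_mode,
                              t_unit, biomass, rel_step = 1e-4) {
  r0 <- washin_residuals(theta, spec, obs, config, emergence_mode, t_unit,
                         biomass)
  J <- matrix(0, length(r0), length(theta))
  for (j in seq_along(theta)) {
    h <- rel_step * theta[j]
    up <- dn <- theta
    up[j] <- theta[j] + h
    dn[j] <- theta[j] - h
    J[, j] <- (washin_residuals(up, spec, obs, config, emergence_mode,
                                t_unit, biomass) -
               washin_residuals(dn, spec, obs, config, emergence_mode,
                                t_unit, biomass)) / (2 * h)
  }
  J
}

pseudo_inverse <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE)
  keep <- ev$values > tol * max(ev$values[1], 1e-300)
  inv <- ifelse(keep, 1 / ev$values, 0)
  ev$vectors %*% (inv * t(ev$vectors))
}

#' Finite-difference sensitivity and Fisher-information analysis
#'
#' Computes central finite differences of the predicted observations with
#' respect to the log of each free parameter (so a near-null direction of
#' `(1, 1)` means the pair is constrained only through its ratio), forms the
#' Fisher-information-style matrix `FIM = J' J`, and reports eigenvalues,
#' eigenvectors and near-null directions (eigenvalue below
#' `null_threshold * max eigenvalue`). Near-null directions whose weight is
#' concentrated on two equal-sign log-parameters are additionally summarised
#' as ratio-only pairs.
#'
#' @param params Full named parameter list (see [fit_spec()] names; must
#'   contain all of `mu_parent, km_parent, yield_parent, mu_mutant,
#'   km_mutant, yield_mutant, amount, t_emerge`, or `yield` in place of the
#'   two per-strain yields).
#' @param config A [chemostat_config()].
#' @param generations Observation generations.
#' @param free Character vector of parameter names to perturb.
#' @param perturbation Relative step for the central differences, in
#'   (0, 0.1].
#' @param include_biomass Also observe log total biomass (this is what makes
#'   the yield/emergence pair identifiable).
#' @param emergence_mode,t_unit See [fit_washin()].
#' @param null_threshold Relative eigenvalue threshold for near-null
#'   directions (default 1e-6).
#' @return A `sensitivity_report`: `jacobian`, `fim`, `eigenvalues`,
#'   `eigenvectors`, `near_null_directions` (matrix, one column each),
#'   `ratio_pairs` (character).
#' @export
sensitivity_washin <- function(params, config, generations, free,
                               perturbation = 0.01, include_biomass = FALSE,
                               emergence_mode = "frequency",
                               t_unit = "generations",
                               null_threshold = 1e-6) {
  if (!is.numeric(perturbation) || perturbation <= 0 || perturbation > 0.1)
    abort("'perturbation' must lie in (0, 0.1]")
  params <- assemble_params(params, list())
  miss <- setdiff(PARAM_NAMES, names(params))
  if (length(miss)) abort("params missing: %s", paste(miss, collapse = ", "))
  bad <- setdiff(free, c(PARAM_NAMES, "yield"))
  if (length(bad)) abort("unknown free parameter(s): %s",
                         paste(bad, collapse = ", "))

  perturb <- function(nm, factor) {
    p <- params
    if (nm == "yield") {
      p$yield_parent <- p$yield_parent * factor
      p$yield_mutant <- p$yield_mutant * factor
    } else p[[nm]] <- p[[nm]] * factor
    p
  }
  h <- perturbation
  pred <- function(p) washin_predict(p, config, generations,
                                     emergence_mode = emergence_mode,
                                     t_unit = t_unit,
                                     include_biomass = include_biomass)
  base <- pred(params)
  J <- matrix(0, length(base), length(free),
              dimnames = list(NULL, free))
  for (j in seq_along(free)) {
    up <- pred(perturb(free[j], exp(h)))
    dn <- pred(perturb(free[j], exp(-h)))
    if (identical(up, dn) && !identical(up, base))
      abort("step underflow: perturbing '%s' leaves predictions unchanged",
            free[j])
    J[, j] <- (up - dn) / (2 * h)
  }
  fim <- crossprod(J)
  ev <- eigen(fim, symmetric = TRUE)    # eigenvalues sorted descending
  thresh <- null_threshold * max(ev$values[1], 1e-300)
  null_idx <- which(ev$values < thresh)
  near_null <- ev$vectors[, null_idx, drop = FALSE]
  rownames(near_null) <- free
  rownames(ev$vectors) <- free

  ratio_pairs <- character()
  for (k in seq_len(ncol(near_null))) {
    v <- near_null[, k]
    o <- order(abs(v), decreasing = TRUE)
    if (length(v) >= 2L && sum(v[o[1:2]]^2) > 0.9 * sum(v^2) &&
        sign(v[o[1]]) == sign(v[o[2]]))
      ratio_pairs <- c(ratio_pairs,
                       paste(sort(free[o[1:2]]), collapse = "/"))
  }
  structure(list(jacobian = J, fim = fim, eigenvalues = ev$values,
                 eigenvectors = ev$vectors,
                 near_null_directions = near_null,
                 ratio_pairs = unique(ratio_pairs),
                 null_threshold = null_threshold,
                 perturbation = perturbation),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("<sensitivity_report>\n  FIM eigenvalues:",
      paste(signif(x$eigenvalues, 3), collapse = ", "), "\n")
  if (ncol(x$near_null_directions))
    cat("  near-null directions:", ncol(x$near_null_directions),
        if (length(x$ratio_pairs))
          paste0("(ratio-only: ", paste(x$ratio_pairs, collapse = "; "), ")"),
        "\n")
  invisible(x)
}

#' Parameter-recovery experiment (simulate, corrupt, refit)
#'
#' Repeatedly generates wash-in data from known truth, corrupts the variant
#' fractions with binomial sequencing noise at the stated depth, refits the
#' model, and summarises bias, RMSE and (Wald) confidence-interval coverage
#' per free parameter and for the Monod-constant ratio
#' `km_parent / km_mutant` when both constants are free (the ratio is the
#' identifiable combination; the raw values are not).
#'
#' @param truth Full named parameter list (see [sensitivity_washin()]).
#' @param config A [chemostat_config()].
#' @param generations Sampling generations.
#' @param free Named list of bounds for the free parameters, as in
#'   [fit_spec()].
#' @param depth Pyrosequencing read depth per sample.
#' @param n_reps Number of replicates, >= 1.
#' @param seed Master seed; replicate r uses a derived sub-seed.
#' @param emergence_mode,t_unit,n_starts See [fit_washin()].
#' @param level Confidence level for coverage (default 0.95).
#' @return A `recovery_table`: data.frame with one row per quantity
#'   (columns `quantity, truth, mean_est, bias, rel_bias, rmse, coverage,
#'   identifiable`), plus attributes `n_fail` and `fits`.
#' @export
recover_parameters <- function(truth, config, generations, free,
                               depth = 1000, n_reps = 20, seed = 1,
                               emergence_mode = "frequency",
                               t_unit = "generations", n_starts = 4L,
                               level = 0.95) {
  if (n_reps < 1) abort("n_reps must be >= 1")
  truth <- assemble_params(truth, list())
  fixed <- truth[setdiff(PARAM_NAMES, names(free))]
  if ("yield" %in% names(free))
    fixed <- truth[setdiff(PARAM_NAMES,
                           c(names(free), "yield_parent", "yield_mutant"))]
  spec <- fit_spec(free = free, fixed = fixed)
  true_f <- washin_predict(truth, config, generations,
                           emergence_mode = emergence_mode, t_unit = t_unit)
  true_frac <- inv_logit(true_f)

  both_km <- all(c("km_parent", "km_mutant") %in% names(free))
  quantities <- c(names(free), if (both_km) "km_ratio")
  true_vals <- c(vapply(names(free), function(nm)
    if (nm == "yield") truth$yield_parent else truth[[nm]], 0),
    if (both_km) truth$km_parent / truth$km_mutant)
  names(true_vals) <- quantities

  est <- matrix(NA_real_, n_reps, length(quantities),
                dimnames = list(NULL, quantities))
  cover <- matrix(NA, n_reps, length(quantities),
                  dimnames = list(NULL, quantities))
  combos <- character()
  singular <- logical()
  n_fail <- 0L
  z <- qnorm(1 - (1 - level) / 2)
  fits <- vector("list", n_reps)

  for (r in seq_len(n_reps)) {
    counts <- with_seed(sub_seed(seed, r),
                        rbinom(length(true_frac), depth, true_frac))
    obs <- fraction_series(generations, counts / depth, depth = rep(depth,
                           length(generations)))
    fit <- tryCatch(
      fit_washin(obs, spec, config, emergence_mode = emergence_mode,
                 t_unit = t_unit, n_starts = n_starts,
                 seed = sub_seed(seed, 10000 + r)),
      error = function(e) e)
    if (inherits(fit, "error")) { n_fail <- n_fail + 1L; next }
    fits[[r]] <- fit
    th <- fit$estimates
    se <- sqrt(pmax(diag(fit$covariance), 0))
    for (nm in names(free)) {
      est[r, nm] <- th[nm]
      cover[r, nm] <- abs(th[nm] - true_vals[nm]) <= z * se[nm]
    }
    if (both_km) {
      ratio <- th["km_parent"] / th["km_mutant"]
      est[r, "km_ratio"] <- ratio
      # delta method on log ratio with the (pseudo-inverse) covariance
      g <- rep(0, length(th)); names(g) <- names(th)
      g["km_parent"] <- 1 / th["km_parent"]
      g["km_mutant"] <- -1 / th["km_mutant"]
      v <- drop(t(g) %*% fit$covariance %*% g)
      if (is.finite(v) && v >= 0) {
        ci <- log(ratio) + c(-1, 1) * z * sqrt(v)
        cover[r, "km_ratio"] <- log(true_vals["km_ratio"]) >= ci[1] &&
          log(true_vals["km_ratio"]) <= ci[2]
      }
    }
    combos <- c(combos, fit$identifiable_combos)
    singular <- c(singular, fit$singular)
  }

  ratio_only <- unique(combos)
  identifiable <- !(quantities %in% unlist(strsplit(ratio_only, "/")))
  tab <- data.frame(
    quantity = quantities, truth = unname(true_vals),
    mean_est = colMeans(est, na.rm = TRUE),
    bias = colMeans(est, na.rm = TRUE) - unname(true_vals),
    rel_bias = colMeans(est, na.rm = TRUE) / unname(true_vals) - 1,
    rmse = sqrt(colMeans(sweep(est, 2L, true_vals)^2, na.rm = TRUE)),
    coverage = colMeans(cover, na.rm = TRUE),
    identifiable = identifiable, row.names = NULL)
  structure(tab, class = c("recovery_table", "data.frame"),
            n_fail = n_fail, ratio_pairs = ratio_only,
            singular_share = mean(singular), fits = fits)
}
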