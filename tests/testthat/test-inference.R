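make_noise_free_data <- function(gens = seq(0, 445, by = 20)) {
  truth <- truth_params()
  cfg <- default_config()
  pred <- chemevol:::washin_predict(truth, cfg, gens)
  fraction_series(gens, plogis(pred))
}

test_that("fit loss at the true parameters of noise-free data is zero", {
  truth <- truth_params()
  cfg <- default_config()
  fs <- make_noise_free_data()
  spec <- fit_spec(free = list(km_parent = c(0.005, 1)),
                   fixed = truth[setdiff(chemevol:::PARAM_NAMES,
                                         "km_parent")])
  r <- chemevol:::washin_residuals(c(km_parent = truth$km_parent), spec, fs,
                                   cfg, "frequency", "generations")
  expect_lt(sum(r^2), 1e-10)
})

test_that("noise-free fit recovers the K_M ratio within 1% and flags the raw pair", {
  truth <- truth_params()
  cfg <- default_config()
  fs <- make_noise_free_data()
  spec <- fit_spec(free = list(km_parent = c(0.005, 1),
                               km_mutant = c(5e-4, 0.1)),
                   fixed = truth[setdiff(chemevol:::PARAM_NAMES,
                                         c("km_parent", "km_mutant"))])
  fit <- fit_washin(fs, spec, cfg, n_starts = 4)
  ratio <- fit$estimates["km_parent"] / fit$estimates["km_mutant"]
  expect_equal(unname(ratio), 10, tolerance = 0.01)
  expect_true(fit$singular)
  expect_true("km_mutant/km_parent" %in% fit$identifiable_combos)
  # best multi-start value is the reported optimum
  expect_lte(fit$residual_sum, min(fit$start_values) + 1e-12)
  expect_error(fit_spec(free = list(), fixed = truth), "named list")
  expect_error(fit_spec(free = list(km_parent = c(0.005, 1)),
                        fixed = truth["mu_parent"]), "missing")
})

test_that("null recovery: a neutral pair yields a selection rate indistinguishable from zero", {
  truth <- truth_params()
  truth$mu_mutant <- truth$mu_parent   # neutral: identical growth params
  truth$km_mutant <- truth$km_parent
  truth$amount <- 0.25
  truth$t_emerge <- 10
  cfg <- default_config()
  gens <- seq(0, 445, by = 20)
  pred <- chemevol:::washin_predict(truth, cfg, gens)
  fs <- fraction_series(gens, plogis(pred))
  spec <- fit_spec(free = list(mu_mutant = c(0.3, 1.2)),
                   fixed = truth[setdiff(chemevol:::PARAM_NAMES,
                                         "mu_mutant")])
  fit <- fit_washin(fs, spec, cfg, n_starts = 4)
  mu_hat <- fit$estimates["mu_mutant"]
  se <- sqrt(fit$covariance["mu_mutant", "mu_mutant"])
  s_hat <- monod_rate(strain_params("m", unname(mu_hat), truth$km_mutant),
                      0.25) - cfg$D
  s_se <- se * 0.25 / (truth$km_mutant + 0.25)  # delta method
  expect_lt(abs(s_hat), max(2 * s_se, 1e-6))
})

test_that("FIM near-null directions align with the documented ratio pairs", {
  truth <- truth_params()
  cfg <- default_config()
  gens <- seq(0, 445, by = 20)
  angle_to_11 <- function(v) acos(min(abs(sum(v / sqrt(sum(v^2)) *
                                               c(1, 1) / sqrt(2))), 1)) *
    180 / pi
  s1 <- sensitivity_washin(truth, cfg, gens,
                           free = c("km_parent", "km_mutant"))
  expect_equal(ncol(s1$near_null_directions), 1L)
  expect_lt(angle_to_11(s1$near_null_directions[, 1]), 5)
  expect_identical(s1$ratio_pairs, "km_mutant/km_parent")

  ta <- truth
  ta$amount <- 0.005
  ta$yield <- 0.02
  s2 <- sensitivity_washin(ta, cfg, gens, free = c("yield", "amount"),
                           emergence_mode = "absolute")
  expect_equal(ncol(s2$near_null_directions), 1L)
  expect_lt(angle_to_11(s2$near_null_directions[, 1]), 5)
  expect_identical(s2$ratio_pairs, "amount/yield")

  # a single well-determined parameter has strictly positive information
  s3 <- sensitivity_washin(truth, cfg, gens, free = "mu_mutant")
  expect_gt(s3$eigenvalues[1], 0)
  expect_length(s3$ratio_pairs, 0)
  expect_true(all(diff(s1$eigenvalues) <= 0))   # sorted descending
  expect_equal(s1$fim, t(s1$fim))
  expect_error(sensitivity_washin(truth, cfg, gens, free = "km_parent",
                                  perturbation = 0.5), "perturbation")
})

test_that("absolute biomass observations make the yield/amount pair identifiable", {
  truth <- truth_params()
  truth$amount <- 0.005
  truth$yield <- 0.02
  cfg <- default_config()
  gens <- seq(0, 445, by = 20)
  s_frac <- sensitivity_washin(truth, cfg, gens, free = c("yield", "amount"),
                               emergence_mode = "absolute")
  s_both <- sensitivity_washin(truth, cfg, gens, free = c("yield", "amount"),
                               emergence_mode = "absolute",
                               include_biomass = TRUE)
  cond <- function(s) s$eigenvalues[1] / max(s$eigenvalues[2], 1e-300)
  expect_gt(cond(s_frac) / cond(s_both), 10)
  expect_length(s_both$ratio_pairs, 0)
})

test_that("parameter recovery: unbiased at zero noise, depth controls ratio RMSE", {
  truth <- truth_params()
  cfg <- default_config()
  gens <- seq(0, 445, by = 20)
  free <- list(km_parent = c(0.005, 1), km_mutant = c(5e-4, 0.1))
  # zero-noise surrogate: enormous depth, single rep
  rec0 <- recover_parameters(truth, cfg, gens, free, depth = 1e7,
                             n_reps = 1, seed = 3)
  r0 <- rec0[rec0$quantity == "km_ratio", ]
  expect_lt(abs(r0$rel_bias), 0.01)
  expect_false(all(rec0$identifiable[rec0$quantity != "km_ratio"]))

  rec_lo <- recover_parameters(truth, cfg, gens, free, depth = 10,
                               n_reps = 8, seed = 5)
  rec_hi <- recover_parameters(truth, cfg, gens, free, depth = 10000,
                               n_reps = 8, seed = 5)
  rmse <- function(r) r$rmse[r$quantity == "km_ratio"]
  expect_gt(rmse(rec_lo), rmse(rec_hi))
  expect_true(is.finite(rmse(rec_lo)))
  expect_equal(attr(rec_hi, "n_fail"), 0L)
})

test_that("fit covariance agrees with Monte-Carlo scatter in order of magnitude", {
  truth <- truth_params()
  cfg <- default_config()
  gens <- seq(0, 445, by = 20)
  # a single identifiable parameter keeps the covariance non-degenerate
  free <- list(mu_mutant = c(0.45, 0.65))
  rec <- recover_parameters(truth, cfg, gens, free, depth = 1000,
                            n_reps = 12, seed = 9, n_starts = 2)
  fits <- Filter(Negate(is.null), attr(rec, "fits"))
  ests <- vapply(fits, function(f) f$estimates["mu_mutant"], 0)
  ses <- vapply(fits, function(f) sqrt(f$covariance["mu_mutant",
                                                    "mu_mutant"]), 0)
  expect_gt(mean(ses) / sd(ests), 0.1)
  expect_lt(mean(ses) / sd(ests), 10)
})
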