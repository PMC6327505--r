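test_that("selection_rate matches the invasion-rate formula and the ODE log-slope", {
  p <- default_parent()
  m <- default_mutant()
  cfg <- default_config()
  expect_equal(selection_rate(p, p, cfg), 0)
  # oracle: S* = 0.25, mu_m = 0.55 * 0.25 / 0.26 - 0.5
  expect_equal(selection_rate(p, m, cfg), 0.55 * 0.25 / 0.26 - 0.5)
  worse <- strain_params("worse", 0.7, 0.3)
  expect_lt(selection_rate(p, worse, cfg), 0)
  expect_error(selection_rate(strain_params("p", 0.4, 0.1), m, cfg),
               class = "chemevol_washout")
  # joint K_M rescaling leaves the rate unchanged
  p2 <- strain_params("p", 0.7, 0.1 * 3, 0.02)
  m2 <- strain_params("m", 0.55, 0.01 * 3, 0.02)
  expect_equal(selection_rate(p2, m2, cfg), selection_rate(p, m, cfg))

  # ODE oracle: early slope of log(x_m/x_p) while the mutant is rare
  sim <- simulate_washin(p, m, cfg, emergence_spec(0, 1e-6), t_end = 60,
                         sample_generations = seq(0, 40, 2))
  traj <- sim$trajectory
  lr <- log(traj$x[, 2] / traj$x[, 1])
  slope <- coef(lm(lr ~ traj$times))[2]
  expect_equal(unname(slope), selection_rate(p, m, cfg), tolerance = 1e-3)
})

test_that("wash-in simulation honours emergence and drives fixation", {
  p <- default_parent()
  m <- default_mutant()
  cfg <- default_config()
  em <- emergence_spec(70, 0.01)
  sim <- simulate_washin(p, m, cfg, em, generations_to_hours(445, 0.5) + 1)
  f <- sim$fractions$fraction
  g <- sim$fractions$generations
  expect_true(all(f[g < 70] == 0))
  expect_true(all(diff(f[g >= 70]) >= 0))
  expect_gte(f[which.min(abs(g - 440))], 0.97)
  # frequency conservation at every trajectory point
  fr <- sim$trajectory$x / rowSums(sim$trajectory$x)
  expect_lt(max(abs(rowSums(fr) - 1)), 1e-12)
  # neutral pair: fraction constant at its initial value
  m0 <- strain_params("twin", p$mu_max, p$K_M, p$yield)
  sim0 <- simulate_washin(p, m0, cfg, emergence_spec(0, 0.25), t_end = 300)
  expect_lt(max(abs(sim0$fractions$fraction - 0.25)), 1e-6)
  expect_error(simulate_washin(p, m, cfg, emergence_spec(1000, 0.01, unit =
    "hours"), t_end = 500), "not before t_end")
})

test_that("fraction dynamics depend on K_M only through the ratio (quasi-steady limit)", {
  p <- default_parent()
  m <- default_mutant()
  cfg <- default_config()
  em <- emergence_spec(70, 0.01)
  t_end <- generations_to_hours(445, 0.5) + 1
  f_ref <- simulate_washin(p, m, cfg, em, t_end)$fractions$fraction
  for (c_scale in c(0.5, 2)) {
    f_sc <- simulate_washin(
      strain_params("p", 0.7, 0.1 * c_scale, 0.02),
      strain_params("m", 0.55, 0.01 * c_scale, 0.02),
      cfg, em, t_end)$fractions$fraction
    # exact only for S* << S_in; at S*/S_in = 1% the error is ~1e-3
    expect_lt(max(abs(f_ref - f_sc)), 2e-3)
  }
})

test_that("absolute emergence: scaling both yields with the amount is exact", {
  cfg <- default_config()
  em1 <- emergence_spec(70, 0.005, mode = "absolute")
  em2 <- emergence_spec(70, 0.015, mode = "absolute")
  t_end <- generations_to_hours(445, 0.5) + 1
  f1 <- simulate_washin(default_parent(), default_mutant(), cfg, em1,
                        t_end)$fractions$fraction
  f2 <- simulate_washin(strain_params("p", 0.7, 0.1, 0.06),
                        strain_params("m", 0.55, 0.01, 0.06),
                        cfg, em2, t_end)$fractions$fraction
  expect_lt(max(abs(f1 - f2)), 1e-8)
})

test_that("positive selection crosses any threshold below 1 in finite time", {
  p <- default_parent()
  m <- default_mutant()
  cfg <- default_config()
  sim <- simulate_washin(p, m, cfg, emergence_spec(0, 1e-6),
                         generations_to_hours(600, 0.5),
                         sample_generations = seq(0, 600, 5))
  f <- sim$fractions$fraction
  rising <- f < 1 - 1e-9          # strictly increasing until saturation
  expect_true(all(diff(f[rising]) > 0))
  expect_true(all(diff(f) >= 0))
  for (thr in c(0.01, 0.5, 0.97, 0.999))
    expect_true(any(f >= thr))
})

test_that("logistic closed form, calibration and inversion", {
  expect_equal(logistic_fraction(0.5, 0, 123), 0.5)
  expect_error(logistic_fraction(0, 0.1, 10), "boundary")
  expect_error(logistic_fraction(1, 0.1, 10), "boundary")
  cal <- calibrate_logistic(70, 0.01, 210, 0.5)
  expect_equal(logistic_fraction(cal$f0, cal$s, 70), 0.01)
  expect_equal(logistic_fraction(cal$f0, cal$s, 210), 0.5)
  expect_gte(logistic_fraction(cal$f0, cal$s, 445), 0.97)
  # inversion round trip
  g <- time_to_fraction(cal$f0, cal$s, 0.8)
  expect_equal(logistic_fraction(cal$f0, cal$s, g), 0.8)
  expect_identical(time_to_fraction(0.2, 0, 0.2), 0)
  expect_identical(time_to_fraction(0.2, 0, 0.8), Inf)
  expect_identical(time_to_fraction(0.2, -0.1, 0.8), Inf)
})

test_that("logistic approximation tracks the ODE while substrate is near the parent steady state", {
  p <- default_parent()
  m <- default_mutant()
  cfg <- default_config()
  s_gen <- selection_coefficient(p, m, cfg)   # selection_rate * ln2 / D
  sim <- simulate_washin(p, m, cfg, emergence_spec(0, 0.01),
                         generations_to_hours(260, 0.5),
                         sample_generations = seq(0, 250, 2))
  g <- sim$fractions$generations
  f_ode <- sim$fractions$fraction
  f_log <- logistic_fraction(0.01, s_gen, g)
  S <- sim$trajectory$S[match(generations_to_hours(g, 0.5),
                              sim$trajectory$times)]
  near <- abs(S - 0.25) < 0.02 * 0.25
  expect_gt(sum(near), 3)
  expect_lt(max(abs(f_ode - f_log)[near]), 0.02)
  # on the looser 5% substrate band the approximation drifts to ~3%
  near5 <- abs(S - 0.25) < 0.05 * 0.25
  expect_lt(max(abs(f_ode - f_log)[near5]), 0.04)
})

test_that("predict_competition across dilution rates", {
  p <- default_parent()
  m <- default_mutant()
  # neutral strains: flat at f0 for every D
  twin <- strain_params("twin", p$mu_max, p$K_M, p$yield)
  flat <- predict_competition(p, twin, c(0.2, 0.3), f0 = 0.1, horizon = 100)
  for (fs in flat$series)
    expect_lt(max(abs(fs$fraction - 0.1)), 1e-6)
  # default pair: mutant rises at every D (oracle: selection_rate sign)
  pred <- predict_competition(p, m, c(0.2, 0.3, 0.5), f0 = 0.1)
  for (D in c(0.2, 0.3, 0.5))
    expect_gt(selection_rate(p, m, chemostat_config(D, 25)), 0)
  for (fs in pred$series) {
    expect_equal(fs$fraction[1], 0.1, tolerance = 1e-9)
    expect_true(all(diff(fs$fraction) >= 0))
    expect_gt(tail(fs$fraction, 1), 0.97)
  }
  expect_true(all(is.finite(pred$summary$g50)))
  expect_true(all(pred$summary$g50 < pred$summary$g97))
  # horizon 0: just f0
  p0 <- predict_competition(p, m, 0.3, f0 = 0.1, horizon = 0)
  expect_identical(p0$series[[1]]$fraction, 0.1)
  # washout diagnosis names the limit
  expect_error(predict_competition(p, m, c(0.2, 0.6)),
               class = "chemevol_washout")
})
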