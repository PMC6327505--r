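#' Specification of mutant emergence in a resident population
#'
#' The beneficial variant is introduced deterministically at a single time
#' point, either at an absolute biomass amount or at a population frequency.
#' An optional seeded stochastic mode draws the first-appearance time from
#' an exponential waiting-time (Poisson process) instead; it is off by
#' default because the fitted quantity in wash-in analyses is a single
#' deterministic emergence frequency/time.
#'
#' @param t Time of first appearance, >= 0.
#' @param amount Either an initial frequency in (0,1) (`mode = "frequency"`)
#'   or an absolute biomass added (> 0, `mode = "absolute"`).
#' @param mode `"frequency"` or `"absolute"`.
#' @param unit Unit of `t`: `"generations"` (default) or `"hours"`.
#' @param stochastic If `TRUE`, `t` is the mean of an exponential
#'   first-appearance time; requires a `seed` at simulation time.
#' @return An `emergence_spec` object.
#' @export
emergence_spec <- function(t, amount, mode = c("frequency", "absolute"),
                           unit = c("generations", "hours"),
                           stochastic = FALSE) {
  mode <- match.arg(mode)
  unit <- match.arg(unit)
  assert_scalar_num(t, "t", 0)
  assert_scalar_num(amount, "amount", 0, strict = TRUE)
  if (mode == "frequency" && amount >= 1)
    abort("frequency-mode emergence amount must lie in (0, 1)")
  structure(list(t = t, amount = amount, mode = mode, unit = unit,
                 stochastic = isTRUE(stochastic)),
            class = "emergence_spec")
}

emergence_hours <- function(emergence, D, seed = NULL) {
  t0 <- if (emergence$unit == "generations")
    generations_to_hours(emergence$t, D) else emergence$t
  if (emergence$stochastic) {
    if (is.null(seed)) abort("stochastic emergence requires a seed")
    t0 <- with_seed(seed, stats::rexp(1L, rate = 1 / max(t0, 1e-12)))
  }
  t0
}

#' Variant-frequency time series
#'
#' @param generations Non-decreasing generation indices.
#' @param fraction Variant frequency per index, in \[0, 1\].
#' @param depth Optional read counts per index.
#' @param ci_low,ci_high Optional binomial confidence bounds with
#'   `ci_low <= fraction <= ci_high`.
#' @return A `fraction_series` object.
#' @export
fraction_series <- function(generations, fraction, depth = NULL,
                            ci_low = NULL, ci_high = NULL) {
  if (length(generations) != length(fraction))
    abort("generations and fraction lengths differ")
  if (is.unsorted(generations)) abort("generations must be non-decreasing")
  if (any(fraction < -1e-12 | fraction > 1 + 1e-12, na.rm = TRUE))
    abort("fractions must lie in [0, 1]")
  fraction <- pmin(pmax(fraction, 0), 1)
  if (!is.null(ci_low) && !is.null(ci_high) &&
      any(ci_low > fraction + 1e-9 | ci_high < fraction - 1e-9, na.rm = TRUE))
    abort("require ci_low <= fraction <= ci_high")
  structure(list(generations = as.numeric(generations),
                 fraction = as.numeric(fraction),
                 depth = depth, ci_low = ci_low, ci_high = ci_high),
            class = "fraction_series")
}

#' @export
print.fraction_series <- function(x, ...) {
  cat(sprintf(
    "<fraction_series> %d points, generations [%g, %g], fraction [%.4g, %.4g]\n",
    length(x$generations), min(x$generations), max(x$generations),
    min(x$fraction), max(x$fraction)))
  invisible(x)
}

#' @export
as.data.frame.fraction_series <- function(x, ...) {
  n <- length(x$generations)
  data.frame(generation = x$generations, fraction = x$fraction,
             depth = if (is.null(x$depth)) rep(NA_real_, n) else x$depth,
             ci_low = if (is.null(x$ci_low)) rep(NA_real_, n) else x$ci_low,
             ci_high = if (is.null(x$ci_high)) rep(NA_real_, n) else x$ci_high)
}

#' Per-hour selective rate advantage of a mutant invading a resident
#'
#' With the resident (parent) at its steady state, the residual substrate is
#' \eqn{S^*_{parent}} and a rare mutant grows at
#' \eqn{\mu_{mutant}(S^*_{parent})} while being washed out at rate `D`, so
#' its invasion rate is \eqn{\mu_{mutant}(S^*_{parent}) - D}. Zero for
#' identical strains; depends on the two Monod constants only through
#' their ratio (jointly rescaling both K_M leaves it unchanged).
#'
#' @param parent,mutant [strain_params()] objects.
#' @param config A [chemostat_config()]; requires `0 < D < parent$mu_max`.
#' @return Per-hour rate advantage (can be negative).
#' @export
selection_rate <- function(parent, mutant, config) {
  ss <- steady_state(parent, config)   # signals washout if D >= parent mu_max
  monod_rate(mutant, ss$S) - config$D
}

#' @rdname selection_rate
#' @details `selection_coefficient()` converts the per-hour advantage to a
#'   per-generation selection coefficient via `s_gen = s_hour * ln(2) / D`
#'   (one generation is one doubling at growth rate D).
#' @export
selection_coefficient <- function(parent, mutant, config) {
  selection_rate(parent, mutant, config) * LN2 / config$D
}

#' Simulate mutant wash-in against a resident at steady state
#'
#' The parent runs at its steady state until the emergence time, at which
#' the mutant is introduced (absolute biomass, or a frequency of the
#' resident biomass). The two-strain Monod chemostat is then integrated to
#' `t_end` and the mutant fraction is reported on a generation grid.
#'
#' @param parent,mutant [strain_params()] objects.
#' @param config A [chemostat_config()].
#' @param emergence An [emergence_spec()].
#' @param t_end End of simulation (hours), > emergence time.
#' @param sample_generations Generation grid for the fraction series
#'   (default every 20 generations from 0).
#' @param seed Only used for stochastic emergence.
#' @param rtol,atol Integrator tolerances.
#' @return List with elements `trajectory` (full state) and `fractions`
#'   (a [fraction_series()] of the mutant frequency).
#' @export
simulate_washin <- function(parent, mutant, config, emergence, t_end,
                            sample_generations = NULL, seed = NULL,
                            rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(emergence, "emergence_spec"))
  t_em <- emergence_hours(emergence, config$D, seed)
  if (t_em >= t_end) abort("emergence at %g h is not before t_end = %g h",
                           t_em, t_end)
  ss <- steady_state(parent, config)
  x_p <- unname(ss$x)
  x_m_add <- if (emergence$mode == "absolute") emergence$amount
             else emergence$amount / (1 - emergence$amount) * x_p
  if (is.null(sample_generations)) {
    g_end <- hours_to_generations(t_end, config$D)
    sample_generations <- seq(0, g_end, by = 20)
  }
  times <- sort(unique(c(0, generations_to_hours(sample_generations, config$D))))
  ev <- if (t_em > 0)
    data.frame(time = t_em, strain = mutant$name, amount = x_m_add) else NULL
  init_m <- if (t_em > 0) 0 else x_m_add
  init <- reactor_state(ss$S, setNames(c(x_p, init_m),
                                       c(parent$name, mutant$name)))
  traj <- simulate_chemostat(list(parent, mutant), config, init, t_end,
                             events = ev, times = times,
                             rtol = rtol, atol = atol)
  g <- hours_to_generations(traj$times, config$D)
  tot <- rowSums(traj$x)
  f <- ifelse(tot > 0, traj$x[, 2L] / tot, 0)
  keep <- match_generations(g, sample_generations)
  list(trajectory = traj,
       fractions = fraction_series(sample_generations, f[keep]))
}

match_generations <- function(g, wanted) {
  vapply(wanted, function(w) which.min(abs(g - w)), 1L)
}

#' Closed-form logistic wash-in approximation
#'
#' Under a constant per-generation selection coefficient `s`, the variant
#' frequency follows \eqn{logit f(g) = logit f_0 + s g}. This is the
#' quasi-steady-substrate approximation of the two-strain chemostat model.
#'
#' @param f0 Initial frequency, strictly inside (0, 1).
#' @param s Per-generation selection coefficient.
#' @param g Generations elapsed (vectorised).
#' @return Frequency at `g`.
#' @examples
#' logistic_fraction(0.01, 0.0328, 140) # about 0.5
#' @export
logistic_fraction <- function(f0, s, g) {
  assert_scalar_num(f0, "f0", 0)
  if (f0 <= 0 || f0 >= 1)
    abort("f0 must lie strictly inside (0, 1): a frequency of exactly 0 or 1 cannot leave the boundary")
  inv_logit(logit(f0) + s * g)
}

#' @rdname logistic_fraction
#' @param target Target frequency in (0, 1).
#' @return `time_to_fraction()`: generations until `target` is reached
#'   (`Inf` when `s` points away from the target or is zero).
#' @export
time_to_fraction <- function(f0, s, target) {
  assert_scalar_num(target, "target", 0)
  if (f0 <= 0 || f0 >= 1 || target <= 0 || target >= 1)
    abort("frequencies must lie strictly inside (0, 1)")
  d <- logit(target) - logit(f0)
  if (d == 0) return(0)
  if (s == 0 || sign(d) != sign(s)) return(Inf)
  d / s
}

#' @rdname logistic_fraction
#' @param g1,f1,g2,f2 Two calibration points (generation, frequency).
#' @return `calibrate_logistic()`: list with per-generation `s` and the
#'   back-extrapolated frequency `f0` at generation 0.
#' @examples
#' cal <- calibrate_logistic(70, 0.01, 210, 0.5)
#' logistic_fraction(cal$f0, cal$s, 445) # > 0.97
#' @export
calibrate_logistic <- function(g1, f1, g2, f2) {
  if (g2 == g1) abort("calibration points must differ in generation")
  s <- (logit(f2) - logit(f1)) / (g2 - g1)
  f0 <- inv_logit(logit(f1) - s * g1)
  list(s = s, f0 = f0)
}

#' Predict competition outcomes across dilution rates
#'
#' For each dilution rate, both strains are started from a mixed steady
#' state (total biomass at the parent's steady state, a fraction `f0` of it
#' mutant) and the two-strain model is integrated over `horizon`
#' generations. Reports the generation at which the mutant crosses 50% and
#' 97%, interpolated on the logit scale.
#'
#' @param parent,mutant [strain_params()] objects.
#' @param D_list Dilution rates (h^-1); each must be below both strains'
#'   `mu_max` (the error names which strain would wash out).
#' @param f0 Initial mutant fraction (default 0.1, i.e. ~10% inoculum).
#' @param horizon Generations to simulate (default 445).
#' @param S_in Feed substrate (mM).
#' @param step Generation grid step.
#' @return An object of class `competition_prediction`: list with `series`
#'   (named list of [fraction_series()]) and `summary` (data.frame with
#'   columns `D`, `selection_rate`, `g50`, `g97`).
#' @export
predict_competition <- function(parent, mutant, D_list, f0 = 0.1,
                                horizon = 445, S_in = 25, step = 5) {
  assert_scalar_num(f0, "f0", 0, strict = TRUE)
  if (f0 >= 1) abort("f0 must be < 1")
  assert_scalar_num(horizon, "horizon", 0)
  series <- list()
  summ <- data.frame(D = double(), selection_rate = double(),
                     g50 = double(), g97 = double())
  for (D in D_list) {
    for (st in list(parent, mutant))
      if (D >= st$mu_max)
        abort("washout: D = %g >= mu_max(%s) = %g", D, st$name, st$mu_max,
              class = "chemevol_washout")
    cfg <- chemostat_config(D = D, S_in = S_in)
    srate <- selection_rate(parent, mutant, cfg)
    gens <- seq(0, horizon, by = step)
    if (horizon == 0) gens <- 0
    ss <- steady_state(parent, cfg)
    x_tot <- unname(ss$x)
    init <- reactor_state(ss$S, setNames(c((1 - f0) * x_tot, f0 * x_tot),
                                         c(parent$name, mutant$name)))
    if (horizon == 0) {
      fs <- fraction_series(0, f0)
    } else {
      t_end <- generations_to_hours(horizon, D)
      times <- sort(unique(c(0, generations_to_hours(gens, D))))
      traj <- simulate_chemostat(list(parent, mutant), cfg, init, t_end,
                                 times = times)
      g <- hours_to_generations(traj$times, D)
      f <- traj$x[, 2L] / rowSums(traj$x)
      keep <- match_generations(g, gens)
      fs <- fraction_series(gens, f[keep])
    }
    key <- sprintf("D=%g", D)
    series[[key]] <- fs
    summ <- rbind(summ, data.frame(
      D = D, selection_rate = srate,
      g50 = crossing_generation(fs, 0.5),
      g97 = crossing_generation(fs, 0.97)))
  }
  structure(list(series = series, summary = summ),
            class = "competition_prediction")
}

#' @export
print.competition_prediction <- function(x, ...) {
  cat("<competition_prediction>\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

# first generation at which the series crosses `target`, interpolating
# linearly on the logit scale; NA if never crossed within the horizon
crossing_generation <- function(fs, target) {
  f <- fs$fraction
  g <- fs$generations
  if (f[1] >= target) return(g[1])
  i <- which(f >= target)
  if (!length(i)) return(NA_real_)
  i <- i[1]
  eps <- 1e-12
  l <- logit(pmin(pmax(f, eps), 1 - eps))
  lt <- logit(target)
  g[i - 1] + (lt - l[i - 1]) / (l[i] - l[i - 1]) * (g[i] - g[i - 1])
}
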