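#' Per-strain Monod growth parameters
#'
#' Bundles the three parameters of Monod growth on a single limiting
#' substrate: the maximal specific growth rate \eqn{\mu_{max}} (per hour),
#' the Monod (half-saturation) constant \eqn{K_M} (mM), and the biomass
#' yield on substrate (biomass-unit per mmol). Biomass units are left
#' abstract (OD600, gDW/L, ...); the yield carries the unit conversion.
#'
#' @param name Strain label.
#' @param mu_max Maximal specific growth rate (h^-1), > 0.
#' @param K_M Monod constant for the limiting substrate (mM), > 0.
#' @param yield Biomass formed per substrate consumed (biomass-unit/mmol), > 0.
#' @return An object of class `strain_params`.
#' @examples
#' parent <- strain_params("Genr0", mu_max = 0.7, K_M = 0.1, yield = 0.02)
#' @export
strain_params <- function(name, mu_max, K_M, yield = 1) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name))
    abort("'name' must be a non-empty string")
  assert_scalar_num(mu_max, "mu_max", 0, strict = TRUE)
  assert_scalar_num(K_M, "K_M", 0, strict = TRUE)
  assert_scalar_num(yield, "yield", 0, strict = TRUE)
  structure(list(name = name, mu_max = mu_max, K_M = K_M, yield = yield),
            class = "strain_params")
}

#' @export
print.strain_params <- function(x, ...) {
  cat(sprintf("<strain_params> %s: mu_max = %g /h, K_M = %g mM, yield = %g\n",
              x$name, x$mu_max, x$K_M, x$yield))
  invisible(x)
}

#' Chemostat operating configuration
#'
#' @param D Dilution rate (h^-1), >= 0.
#' @param S_in Feed substrate concentration (mM), > 0. Default 25 mM glucose.
#' @param V Working volume (mL), > 0. Default 60 mL.
#' @return An object of class `chemostat_config`.
#' @export
chemostat_config <- function(D, S_in = 25, V = 60) {
  assert_scalar_num(D, "D", 0)
  assert_scalar_num(S_in, "S_in", 0, strict = TRUE)
  assert_scalar_num(V, "V", 0, strict = TRUE)
  structure(list(D = D, S_in = S_in, V = V), class = "chemostat_config")
}

#' @export
print.chemostat_config <- function(x, ...) {
  cat(sprintf("<chemostat_config> D = %g /h, S_in = %g mM, V = %g mL\n",
              x$D, x$S_in, x$V))
  invisible(x)
}

#' Reactor state: substrate plus per-strain biomass
#'
#' @param S Substrate concentration (mM), >= 0.
#' @param x Named numeric vector of biomass concentrations, one per strain,
#'   all >= 0.
#' @return An object of class `reactor_state`.
#' @export
reactor_state <- function(S, x) {
  assert_scalar_num(S, "S", 0)
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)))
    abort("'x' must be a finite numeric vector of biomass concentrations")
  if (any(x < 0)) abort("biomass concentrations must be >= 0")
  structure(list(S = S, x = x), class = "reactor_state")
}

#' Monod specific growth rate
#'
#' \deqn{\mu(S) = \mu_{max} S / (K_M + S)}
#' Bounded in `[0, mu_max)` and monotone increasing in `S`.
#'
#' @param params A [strain_params()] object.
#' @param S Substrate concentration (mM), >= 0 (vectorised).
#' @return Specific growth rate(s), h^-1.
#' @examples
#' monod_rate(strain_params("p", 0.7, 0.1), S = 0.1) # half-saturation: 0.35
#' @export
monod_rate <- function(params, S) {
  stopifnot(inherits(params, "strain_params"))
  if (!is.numeric(S) || any(!is.finite(S))) abort("'S' must be finite numeric")
  if (any(S < 0)) abort("substrate concentration 'S' must be >= 0")
  params$mu_max * S / (params$K_M + S)
}

#' Single-strain chemostat steady state
#'
#' At steady state the residual substrate is \eqn{S^* = K_M D/(\mu_{max}-D)}
#' and the biomass is \eqn{x^* = Y (S_{in} - S^*)}. Requires
#' `0 < D < mu_max` (otherwise the only steady state is washout) and
#' `S* < S_in` (otherwise the feed cannot sustain growth at D).
#'
#' @param params A [strain_params()] object.
#' @param config A [chemostat_config()] object.
#' @return A [reactor_state()] with `S = S*` and biomass `x*`.
#' @export
steady_state <- function(params, config) {
  stopifnot(inherits(params, "strain_params"),
            inherits(config, "chemostat_config"))
  D <- config$D
  if (D <= 0) abort("steady state requires D > 0")
  if (D >= params$mu_max)
    abort("washout: D = %g >= mu_max = %g, no positive-biomass steady state",
          D, params$mu_max, class = "chemevol_washout")
  S_star <- params$K_M * D / (params$mu_max - D)
  if (S_star >= config$S_in)
    abort("infeasible feed: residual substrate S* = %g mM >= S_in = %g mM",
          S_star, config$S_in, class = "chemevol_infeasible")
  x_star <- params$yield * (config$S_in - S_star)
  reactor_state(S = S_star, x = setNames(x_star, params$name))
}

#' Simulate Monod chemostat dynamics for one or more strains
#'
#' Integrates
#' \deqn{dS/dt = D(S_{in}-S) - \sum_i \mu_i(S) x_i / Y_i, \quad
#'       dx_i/dt = (\mu_i(S)-D) x_i}
#' with an adaptive Dormand-Prince 5(4) solver (compiled). State components
#' are clipped at zero. Timed events add the stated biomass to the stated
#' strain instantaneously.
#'
#' @param strains A [strain_params()] object or list of them.
#' @param config A [chemostat_config()].
#' @param init A [reactor_state()]; `init$x` must have one entry per strain
#'   (matched by position).
#' @param t_end Final time (hours), > 0.
#' @param events Optional data.frame with columns `time`, `strain`
#'   (name or index) and `amount` (biomass added, >= 0).
#' @param times Optional output time grid (hours, starting at 0); default 201
#'   equally spaced points.
#' @param rtol,atol Integrator tolerances.
#' @return A `trajectory`: list with `times`, `S`, `x` (matrix, one column
#'   per strain) and `strain_names`.
#' @export
simulate_chemostat <- function(strains, config, init, t_end,
                               events = NULL, times = NULL,
                               rtol = 1e-8, atol = 1e-10) {
  if (inherits(strains, "strain_params")) strains <- list(strains)
  stopifnot(length(strains) >= 1L,
            all(vapply(strains, inherits, TRUE, "strain_params")),
            inherits(config, "chemostat_config"),
            inherits(init, "reactor_state"))
  assert_scalar_num(t_end, "t_end", 0, strict = TRUE)
  n <- length(strains)
  if (length(init$x) != n)
    abort("init has %d biomass entries but %d strains given", length(init$x), n)
  nm <- vapply(strains, `[[`, "", "name")
  if (is.null(times)) times <- seq(0, t_end, length.out = 201L)
  if (times[1] != 0 || is.unsorted(times, strictly = TRUE))
    abort("'times' must be strictly increasing and start at 0")
  if (max(times) > t_end + 1e-9) abort("'times' must not exceed t_end")

  ev <- validate_events(events, nm, t_end)
  mu_max <- vapply(strains, `[[`, 0, "mu_max")
  km <- vapply(strains, `[[`, 0, "K_M")
  yld <- vapply(strains, `[[`, 0, "yield")

  y <- c(init$S, unname(init$x))
  out <- matrix(NA_real_, length(times), 1L + n)
  out[1, ] <- y
  seg_start <- 1L
  t_cur <- 0
  # integrate piecewise between events
  breaks <- c(ev$time, Inf)
  for (b in seq_along(breaks)) {
    t_next <- min(breaks[b], max(times))
    idx <- which(times > t_cur + 1e-12 & times <= t_next + 1e-12)
    seg_times <- unique(c(t_cur, times[idx],
                          if (is.finite(breaks[b]) && breaks[b] <= max(times))
                            breaks[b]))
    if (length(seg_times) > 1L) {
      res <- tryCatch(
        .chemostat_rk45(seg_times, y, mu_max, km, yld,
                        config$D, config$S_in, rtol, atol),
        error = function(e) abort(
          "integration failed on [%g, %g] h: %s", t_cur, t_next,
          conditionMessage(e), class = "chemevol_integrator"))
      if (length(idx))
        out[idx, ] <- res[match(times[idx], seg_times), , drop = FALSE]
      y <- res[nrow(res), ]
      t_cur <- seg_times[length(seg_times)]
    }
    if (is.finite(breaks[b]) && breaks[b] <= max(times) + 1e-12) {
      j <- ev$strain_idx[b]
      y[1L + j] <- y[1L + j] + ev$amount[b]
      # event exactly on an output point: report post-event state
      hit <- which(abs(times - breaks[b]) < 1e-12)
      if (length(hit)) out[hit, ] <- y
    }
    if (t_cur >= max(times)) break
  }
  new_trajectory(times, out, nm)
}

validate_events <- function(events, strain_names, t_end) {
  if (is.null(events) || NROW(events) == 0L)
    return(list(time = numeric(), strain_idx = integer(), amount = numeric()))
  if (!all(c("time", "strain", "amount") %in% names(events)))
    abort("events need columns time, strain, amount")
  if (any(events$amount < 0)) abort("negative event amounts rejected")
  if (any(events$time < 0 | events$time > t_end))
    abort("event times must lie in [0, t_end]")
  idx <- if (is.numeric(events$strain)) as.integer(events$strain)
         else match(as.character(events$strain), strain_names)
  if (any(is.na(idx)) || any(idx < 1L) || any(idx > length(strain_names)))
    abort("event strain not found")
  o <- order(events$time)
  list(time = events$time[o], strain_idx = idx[o], amount = events$amount[o])
}

new_trajectory <- function(times, mat, strain_names) {
  colnames(mat) <- c("S_mM", strain_names)
  structure(list(times = times, S = mat[, 1L],
                 x = mat[, -1L, drop = FALSE], strain_names = strain_names),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d time points over [%g, %g] h, strains: %s\n",
              length(x$times), min(x$times), max(x$times),
              paste(x$strain_names, collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.trajectory <- function(x, ...) {
  data.frame(time_h = x$times, S_mM = x$S,
             as.data.frame(x$x, check.names = FALSE))
}

#' Generation and volume-change arithmetic
#'
#' One volume change is one reactor volume of throughput
#' (`volume changes = D * t`); one generation is one population doubling
#' (`generations = volume changes / ln 2`). The default rounding mode
#' truncates to an integer generation count, so 309 volume changes map to
#' 445 generations (309/ln 2 = 445.8).
#'
#' @param vc Volume changes, >= 0 (vectorised).
#' @param mode `"truncate"` (integer, default) or `"exact"`.
#' @return Generations.
#' @examples
#' generations_from_volume_changes(309) # 445
#' @export
generations_from_volume_changes <- function(vc, mode = c("truncate", "exact")) {
  mode <- match.arg(mode)
  if (!is.numeric(vc) || any(!is.finite(vc))) abort("'vc' must be finite")
  if (any(vc < 0)) abort("negative volume changes rejected")
  g <- vc / LN2
  if (mode == "truncate") trunc(g) else g
}

#' @rdname generations_from_volume_changes
#' @param D Dilution rate (h^-1), >= 0.
#' @param t Cultivation time (hours), >= 0.
#' @export
volume_changes <- function(D, t) {
  if (!is.numeric(D) || !is.numeric(t) || any(!is.finite(c(D, t))))
    abort("'D' and 't' must be finite numeric")
  if (any(D < 0) || any(t < 0)) abort("negative inputs rejected")
  D * t
}

#' Convert between hours and generations at dilution rate D
#'
#' At steady state the population doubles every `ln(2)/D` hours.
#' @param g Generations.
#' @param t Hours.
#' @param D Dilution rate (h^-1), > 0.
#' @export
generations_to_hours <- function(g, D) {
  assert_scalar_num(D, "D", 0, strict = TRUE)
  g * LN2 / D
}

#' @rdname generations_to_hours
#' @export
hours_to_generations <- function(t, D) {
  assert_scalar_num(D, "D", 0, strict = TRUE)
  t * D / LN2
}
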