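# Calibration layer: measurement container, the deviation objective and its
# seven constraints, importance-factor screening, the staged active-set
# calibration, statistical indicators, and the perturbation study.

#' Measured (or synthetic) gas-flow series
#'
#' @param times Sampling times, days, strictly increasing.
#' @param flows Flow rates, L/day, non-negative.
#' @param kind `"CH4"` or `"biogas"`.
#' @return List of class `ad_measurements` with the mean flow `Q_mean`.
#' @export
measurement_series <- function(times, flows, kind = c("CH4", "biogas")) {
  kind <- match.arg(kind)
  if (length(times) != length(flows) || length(times) < 2) {
    stop("need at least two (time, flow) pairs of equal length")
  }
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (any(flows < 0)) stop("flows must be non-negative")
  qm <- mean(flows)
  if (qm <= 0) stop("mean measured flow must be positive")
  structure(list(times = as.numeric(times), flows = as.numeric(flows),
                 kind = kind, Q_mean = qm),
            class = "ad_measurements")
}

# simulated flow of the measured kind, linearly interpolated onto the
# measurement grid
.sim_on_meas <- function(sim, meas) {
  q <- if (meas$kind == "CH4") sim$Q_CH4 else sim$Q_biogas
  stats::approx(sim$time, q, xout = meas$times, rule = 2)$y
}

.trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + y[-1]) / 2)

#' Calibration deviation objective
#'
#' `psi0 * integral(((Q(t) - Q_exp(t)) / Q_mean)^2 dt)` over the measurement
#' grid (trapezoid rule), with the simulated flow interpolated onto the
#' measurement times.
#'
#' @param sim An `ad_simulation` covering the measurement span.
#' @param meas An `ad_measurements`.
#' @param psi0 Normalization constant.
#' @return Non-negative scalar.
#' @export
g0_cal <- function(sim, meas, psi0 = 1) {
  if (max(sim$time) < max(meas$times) - 1e-9) {
    stop("simulation does not cover the measurement span")
  }
  q <- .sim_on_meas(sim, meas)
  psi0 * .trapz(meas$times, ((q - meas$flows) / meas$Q_mean)^2)
}

#' Calibration configuration
#'
#' Threshold schedule, normalization constants, envelope factors and the
#' prescribed gas-fraction limits of the calibration constraints.
#'
#' @param fT Non-increasing activation-threshold schedule ending in 0.
#' @param psi Named normalization constants `psi0`, `psi4`..`psi7`.
#' @param k_LO,k_UP Envelope factors on the measured flow.
#' @param X_bac_max Maximal allowed initial biomass concentration, g/L.
#' @param phi_CH4 Allowed fractional overshoot of simulated vs measured CH4
#'   volume (Eq-13-style constraint; see the methods vignette for the sign
#'   convention).
#' @param phi_H2_max,phi_H2S_max,phi_NH3_max Maximal fractions of H2, H2S
#'   and NH3 in the produced biogas.
#' @param sens_multiplier Sensitivity sample size as a multiple of the
#'   number of parameters.
#' @param heaviside_k Sharpness of the smoothed step in the envelope
#'   constraints.
#' @param seed RNG seed for the stochastic parts.
#' @return List of class `ad_cal_config`.
#' @export
calibration_config <- function(fT = c(0.2, 0.1, 0.001, 0),
                               psi = c(psi0 = 1, psi4 = 1, psi5 = 1,
                                       psi6 = 1, psi7 = 1),
                               k_LO = 0.5, k_UP = 2.0, X_bac_max = 5,
                               phi_CH4 = 0.5, phi_H2_max = 0.01,
                               phi_H2S_max = 0.02, phi_NH3_max = 0.01,
                               sens_multiplier = 5, heaviside_k = 1,
                               seed = 1L) {
  if (any(diff(fT) > 0) || utils::tail(fT, 1) != 0) {
    stop("fT must be non-increasing and end in 0")
  }
  stopifnot(k_LO > 0, k_UP > k_LO, X_bac_max > 0,
            phi_H2_max > 0, phi_H2_max < 1, phi_H2S_max > 0,
    phi_H2S_max < 1, phi_NH3_max > 0, phi_NH3_max < 1)
  structure(list(fT = fT, psi = psi, k_LO = k_LO, k_UP = k_UP,
                 X_bac_max = X_bac_max, phi_CH4 = phi_CH4,
                 phi_H2_max = phi_H2_max, phi_H2S_max = phi_H2S_max,
                 phi_NH3_max = phi_NH3_max,
                 sens_multiplier = sens_multiplier,
                 heaviside_k = heaviside_k, seed = as.integer(seed)),
            class = "ad_cal_config")
}

#' The seven calibration constraints
#'
#' In the standard `g <= 0` convention: g1 limits the initial biomass
#' concentrations, g2/g3 penalize excursions of the simulated flow below
#' `k_LO` / above `k_UP` times the measured flow (arctan-smoothed step
#' integrals), g4 relates simulated to measured CH4 volume, and g5-g7 cap
#' the H2, H2S and NH3 fractions of the produced biogas.
#'
#' @param sim An `ad_simulation`.
#' @param meas An `ad_measurements`.
#' @param params The `ad_parameters` being evaluated (for the initial
#'   biomass).
#' @param cfg An `ad_cal_config`.
#' @return Named numeric vector `g1`..`g7`.
#' @export
calibration_constraints <- function(sim, meas, params, cfg) {
  Vb <- sim$volumes[["V_biogas"]]
  if (Vb <= 0) stop("V_biogas = 0: fraction constraints undefined")
  g1 <- sum((params$X_init - cfg$X_bac_max) / cfg$X_bac_max)
  q <- .sim_on_meas(sim, meas)
  tt <- max(meas$times) - min(meas$times)
  dlo <- (cfg$k_LO * meas$flows - q) / meas$Q_mean
  g2 <- .trapz(meas$times,
               smooth_heaviside(dlo, cfg$heaviside_k) *
                 (cfg$k_LO * meas$flows - q)) / (tt * meas$Q_mean)
  dup <- (q - cfg$k_UP * meas$flows) / meas$Q_mean
  g3 <- .trapz(meas$times,
               smooth_heaviside(dup, cfg$heaviside_k) *
                 (q - cfg$k_UP * meas$flows)) / (tt * meas$Q_mean)
  V_exp <- .trapz(meas$times, meas$flows)
  g4 <- cfg$psi[["psi4"]] *
    ((sim$volumes[["V_CH4"]] - V_exp) / V_exp - cfg$phi_CH4)
  g5 <- cfg$psi[["psi5"]] * (sim$volumes[["V_H2"]] / Vb - cfg$phi_H2_max)
  g6 <- cfg$psi[["psi6"]] * (sim$volumes[["V_H2S"]] / Vb - cfg$phi_H2S_max)
  g7 <- cfg$psi[["psi7"]] * (sim$volumes[["V_NH3"]] / Vb - cfg$phi_NH3_max)
  c(g1 = g1, g2 = g2, g3 = g3, g4 = unname(g4), g5 = unname(g5),
    g6 = unname(g6), g7 = unname(g7))
}

#' Combined calibration evaluator over the unit design cube
#'
#' Returns a function mapping a normalized 187-vector to
#' `list(f = g0_cal, g = calibration_constraints)` by simulating the model;
#' failed simulations return a large finite objective so screening and
#' optimization remain usable anywhere in the design space.
#'
#' @param config,feed Reactor and feedstock.
#' @param meas Measurement series.
#' @param bounds Parameter bounds table.
#' @param cfg An `ad_cal_config`.
#' @param dt,method,ph_mode Solver settings for the embedded simulations.
#' @param fail_value Objective value assigned to failed simulations.
#' @return `function(x_unit) -> list(f, g)`.
#' @export
make_calibration_evaluator <- function(config, feed, meas, bounds,
                                       cfg = calibration_config(),
                                       dt = 0.02, method = "euler",
                                       ph_mode = "resolve", save_dt = 0.25,
                                       fail_value = 1e6) {
  force(config); force(feed); force(meas); force(bounds); force(cfg)
  function(x) {
    p <- params_from_vector(denormalize_design(x, bounds$lo, bounds$up),
                            bounds, validate = FALSE)
    out <- tryCatch({
      sim <- simulate_ad(p, config, feed, dt = dt, method = method,
                         ph_mode = ph_mode, save_dt = save_dt)
      list(f = g0_cal(sim, meas, cfg$psi[["psi0"]]),
           g = calibration_constraints(sim, meas, p, cfg))
    }, error = function(e) NULL)
    if (is.null(out)) {
      out <- list(f = fail_value, g = rep(0, 7))
    }
    out
  }
}

#' Importance-factor screening of the model parameters
#'
#' Samples uniform random designs in the unit cube, evaluates the deviation
#' functional for each, and scores every parameter by the absolute Pearson
#' correlation between its sampled values and the functional, max-normalized
#' to 1.
#'
#' @param evaluator Combined evaluator (see
#'   [make_calibration_evaluator()]); only `$f` is used.
#' @param n_params Number of design variables.
#' @param n_designs Sample size (default `5 * n_params`).
#' @param seed RNG seed.
#' @return List of class `ad_importance` with `fIM` (in `[0,1]`), `ranking`
#'   (parameter indices, most important first) and `n_designs`.
#' @export
importance_factors <- function(evaluator, n_params,
                               n_designs = 5L * n_params, seed = 1L) {
  if (n_designs < 2) stop("n_designs must be >= 2")
  set.seed(as.integer(seed))
  X <- matrix(stats::runif(n_designs * n_params), n_designs, n_params)
  fval <- vapply(seq_len(n_designs),
                 function(i) evaluator(X[i, ])$f, numeric(1))
  keep <- is.finite(fval)
  if (stats::sd(fval[keep]) == 0) {
    warning("deviation functional constant across the sample; ",
            "all importance factors set to 0")
    fim <- rep(0, n_params)
  } else {
    fim <- abs(suppressWarnings(
      stats::cor(X[keep, , drop = FALSE], fval[keep])))[, 1]
    fim[!is.finite(fim)] <- 0
    if (max(fim) > 0) fim <- fim / max(fim)
  }
  structure(list(fIM = unname(fim), ranking = order(fim, decreasing = TRUE),
                 n_designs = n_designs),
            class = "ad_importance")
}

#' Staged active-set calibration
#'
#' For each threshold `fT[s]` of the schedule, the parameters with
#' importance factor at or above the threshold are activated and optimized
#' (sequential convex approximation) while the passive ones are frozen at
#' their current values; each stage warm-starts from the previous optimum,
#' so the stagewise objective never regresses. The final stage (`fT = 0`)
#' activates all parameters.
#'
#' @param config,feed Reactor and feedstock.
#' @param meas Measurement series.
#' @param bounds Parameter bounds table.
#' @param cfg An `ad_cal_config`.
#' @param init Initial `ad_parameters` (default: interval midpoints).
#' @param importance Optional precomputed `ad_importance` (computed from
#'   `cfg$sens_multiplier` designs otherwise).
#' @param dt,method Solver settings of the embedded simulations.
#' @param maxit_stage Iteration cap per stage (recycled over stages).
#' @param move Optimizer move limit (recycled over stages).
#' @param h Forward-difference step of the stage optimizations.
#' @param verbose Log per-stage lines.
#' @return List of class `ad_calibration`: calibrated `params`, `stages`
#'   (data.frame: fT, n_active, iterations, g0), `importance`, and the
#'   final evaluator value.
#' @export
aso_calibrate <- function(config, feed, meas, bounds,
                          cfg = calibration_config(), init = NULL,
                          importance = NULL, dt = 0.02, method = "euler",
                          save_dt = 0.25, maxit_stage = 25, move = 0.2,
                          h = 1e-4, verbose = FALSE) {
  evaluator <- make_calibration_evaluator(config, feed, meas, bounds, cfg,
                                          dt = dt, method = method,
                                          save_dt = save_dt)
  n <- nrow(bounds)
  if (is.null(importance)) {
    importance <- importance_factors(evaluator, n,
                                     n_designs = cfg$sens_multiplier * n,
                                     seed = cfg$seed)
  }
  x <- if (is.null(init)) rep(0.5, n) else
    normalize_design(params_to_vector(init), bounds$lo, bounds$up)
  x <- pmin(pmax(x, 0), 1)
  v <- evaluator(x)
  maxit_stage <- rep_len(maxit_stage, length(cfg$fT))
  move <- rep_len(move, length(cfg$fT))
  stages <- data.frame(fT = numeric(0), n_active = integer(0),
                       iterations = integer(0), g0 = numeric(0))
  for (s in seq_along(cfg$fT)) {
    active <- which(importance$fIM >= cfg$fT[s])
    if (!length(active)) {
      warning("stage ", s, ": empty active set (fT = ", cfg$fT[s],
              "), skipped")
      stages <- rbind(stages, data.frame(fT = cfg$fT[s], n_active = 0L,
                                         iterations = 0L, g0 = v$f))
      next
    }
    fn_active <- function(xa) {
      xf <- x
      xf[active] <- xa
      evaluator(xf)
    }
    res <- tryCatch(
      approx_solve(opt_problem(fn_active, length(active),
                               maxit = maxit_stage[s], move = move[s],
                               h = h, asy0 = max(2 * move[s], 0.05)),
                   x[active]),
      error = function(e) NULL)
    if (!is.null(res)) {
      x_cand <- x
      x_cand[active] <- res$x
      v_cand <- list(f = res$f, g = res$g)
      # warm-start guarantee: never accept a regression
      if (v_cand$f <= v$f + 1e-12) {
        x <- x_cand
        v <- v_cand
      }
      iters <- res$iterations
    } else {
      warning("stage ", s, " failed; continuing with previous values")
      iters <- 0L
    }
    stages <- rbind(stages, data.frame(fT = cfg$fT[s],
                                       n_active = length(active),
                                       iterations = iters, g0 = v$f))
    if (verbose) {
      message(sprintf("stage %d: fT = %g, active = %d, g0 = %.6g",
                      s, cfg$fT[s], length(active), v$f))
    }
  }
  params <- params_from_vector(denormalize_design(x, bounds$lo, bounds$up),
                               bounds, validate = FALSE)
  structure(list(params = params, x_unit = x, stages = stages,
                 importance = importance, value = v),
            class = "ad_calibration")
}

#' Statistical indicators comparing simulated and measured series
#'
#' Mean absolute error, root mean square error, coefficient of
#' determination `R2 = 1 - SSE/SST`, and the relative index of agreement
#' `IA_rel = 1 - sum(((e - s)/e)^2) / sum(((|s - eb| + |e - eb|)/eb)^2)`
#' with `eb` the measured mean.
#'
#' @param sim_values Simulated series.
#' @param exp_values Measured series (same length, `n >= 2`).
#' @return Named vector `MAE`, `RMSE`, `R2`, `IA_rel`.
#' @export
statistical_indicators <- function(sim_values, exp_values) {
  if (length(sim_values) != length(exp_values) || length(sim_values) < 2) {
    stop("need two equal-length series with n >= 2")
  }
  s <- as.numeric(sim_values); e <- as.numeric(exp_values)
  mae <- mean(abs(s - e))
  rmse <- sqrt(mean((s - e)^2))
  sst <- sum((e - mean(e))^2)
  if (sst == 0) stop("SST = 0: R2 undefined")
  r2 <- 1 - sum((s - e)^2) / sst
  if (any(e == 0)) stop("measured value 0: IA_rel undefined")
  eb <- mean(e)
  ia <- 1 - sum(((e - s) / e)^2) /
    sum(((abs(s - eb) + abs(e - eb)) / eb)^2)
  c(MAE = mae, RMSE = rmse, R2 = r2, IA_rel = ia)
}

#' Perturbation study of calibrated parameters
#'
#' Draws each parameter uniformly in `[p (1 - level), p (1 + level)]`
#' (clipped to the bounds), simulates, and computes the statistical
#' indicators against the measurements; draws are paired across levels by
#' per-replicate seeds.
#'
#' @param params_star Calibrated `ad_parameters`.
#' @param levels Perturbation levels (e.g. `c(0.01, 0.05)`).
#' @param n_reps Replicates per level.
#' @param seed Base seed.
#' @param config,feed,meas,bounds As in [aso_calibrate()].
#' @param dt,method Solver settings.
#' @return data.frame with one row per (level, replicate) and the four
#'   indicators; failed draws are skipped and counted in the
#'   `attr(, "skipped")`.
#' @export
perturbation_study <- function(params_star, levels = c(0.01, 0.05),
                               n_reps = 20, seed = 1L, config, feed, meas,
                               bounds = default_parameter_bounds(),
                               dt = 0.02, method = "euler") {
  stopifnot(n_reps >= 1)
  p0 <- params_to_vector(params_star)
  out <- list()
  skipped <- 0L
  for (lv in levels) {
    for (r in seq_len(n_reps)) {
      set.seed(as.integer(seed) + r)   # paired draws across levels
      u <- stats::runif(length(p0), -1, 1)
      pv <- pmin(pmax(p0 * (1 + lv * u), bounds$lo), bounds$up)
      res <- tryCatch({
        p <- params_from_vector(pv, bounds, validate = FALSE)
        sim <- simulate_ad(p, config, feed, dt = dt, method = method,
                           save_dt = 0.25)
        q <- .sim_on_meas(sim, meas)
        # relative indicators are only defined on positive measured flows
        # (pre-onset samples are zero in a batch)
        pos <- meas$flows > 0
        statistical_indicators(q[pos], meas$flows[pos])
      }, error = function(e) NULL)
      if (is.null(res)) {
        skipped <- skipped + 1L
        next
      }
      out[[length(out) + 1L]] <- data.frame(level = lv, rep = r,
                                            MAE = res[["MAE"]],
                                            RMSE = res[["RMSE"]],
                                            R2 = res[["R2"]],
                                            IA_rel = res[["IA_rel"]])
    }
  }
  res <- do.call(rbind, out)
  attr(res, "skipped") <- skipped
  res
}
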