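# Trace-metal dosage optimization: the eleven-variable design space over
# feedstock metal concentrations and the three optimization cases
# (A: biogas quantity; B: biogas quantity vs H2S; C: CH4 quantity vs H2S
# with gas-quality constraints).

.dosage_tms <- c("Ca", "K", "Mg", "Na", "Fe", "Co", "Cr", "Ni", "Pb", "Cu",
                 "Zn")

#' Trace-metal dosage bounds
#'
#' Eleven rows (Ca, K, Mg, Na, Fe, Co in g/L; Cr, Ni, Pb, Cu, Zn in mg/L)
#' with lower, upper and initial (ID) concentrations in the stated units.
#' The lower bound must equal 10% of the initial concentration (the removal
#' limit of the design space); internal computations use g/L.
#'
#' @param df data.frame with columns `tm`, `lo`, `up`, `init`, `unit`
#'   (`"g/L"` or `"mg/L"`).
#' @param relax_lo Skip the `lo = 0.1 * init` check.
#' @return data.frame of class `ad_tm_bounds` with added SI columns
#'   `lo_g`, `up_g`, `init_g`.
#' @export
tm_bounds <- function(df, relax_lo = FALSE) {
  need <- c("tm", "lo", "up", "init", "unit")
  if (!all(need %in% names(df))) {
    stop("tm bounds need columns: ", paste(need, collapse = ", "))
  }
  if (!identical(sort(df$tm), sort(.dosage_tms))) {
    stop("dosage design space must contain exactly the 11 metals: ",
         paste(.dosage_tms, collapse = ", "))
  }
  if (any(df$lo >= df$up)) stop("tm bounds must satisfy lo < up")
  if (!relax_lo && any(abs(df$lo - 0.1 * df$init) > 1e-9 * pmax(1, df$init))) {
    stop("lower bounds must equal 10% of the initial concentrations")
  }
  f <- ifelse(df$unit == "mg/L", 1e-3, 1)
  df$lo_g <- df$lo * f
  df$up_g <- df$up * f
  df$init_g <- df$init * f
  df <- df[match(.dosage_tms, df$tm), ]
  rownames(df) <- NULL
  class(df) <- c("ad_tm_bounds", "data.frame")
  df
}

#' Reference dosage bounds for bioreactor B1
#'
#' The prescribed lower/upper/initial trace-metal concentrations of the
#' dosage design space for the manure feedstock.
#'
#' @return An `ad_tm_bounds` data.frame.
#' @export
b1_tm_bounds <- function() {
  tm_bounds(data.frame(
    tm = .dosage_tms,
    lo = c(0.30, 0.32, 0.08, 0.03, 0.011, 0.002, 0.30, 0.10, 0.02, 1.0, 5.0),
    up = c(4.0, 4.2, 1.8, 0.80, 5.11, 0.12, 103.0, 101.0, 100.2, 110.0, 150.0),
    init = c(3.0, 3.2, 0.80, 0.30, 0.11, 0.02, 3.0, 1.0, 0.20, 10.0, 50.0),
    unit = c(rep("g/L", 6), rep("mg/L", 5)),
    stringsAsFactors = FALSE
  ))
}

#' Dosage optimization case specification
#'
#' Case A maximizes the time-integrated biogas volume under bound
#' constraints only; Case B additionally penalizes H2S production and caps
#' the H2S fraction; Case C promotes CH4 volume, penalizes H2S, and caps
#' the H2S, H2 and NH3 fractions.
#'
#' @param case `"A"`, `"B"` or `"C"`.
#' @param psi0 Case A objective weight (`NULL`: normalized to the
#'   initial-design magnitude at optimization time).
#' @param psi01,psi02 Weights of the volume and H2S terms in Cases B/C.
#' @param psi1,psi2,psi3 Constraint weights.
#' @param phi_H2S_max,phi_H2_max,phi_NH3_max Maximal gas fractions.
#' @return List of class `ad_case`.
#' @export
case_spec <- function(case = c("A", "B", "C"), psi0 = NULL, psi01 = NULL,
                      psi02 = NULL, psi1 = 1, psi2 = 1, psi3 = 1,
                      phi_H2S_max = 0.02, phi_H2_max = 0.01,
                      phi_NH3_max = 0.01) {
  case <- match.arg(case)
  ws <- c(psi0, psi01, psi02, psi1, psi2, psi3)
  if (any(ws < 0)) stop("weights must be non-negative")
  structure(list(case = case, psi0 = psi0, psi01 = psi01, psi02 = psi02,
                 psi1 = psi1, psi2 = psi2, psi3 = psi3,
                 phi_H2S_max = phi_H2S_max, phi_H2_max = phi_H2_max,
                 phi_NH3_max = phi_NH3_max),
            class = "ad_case")
}

#' Case objective value on a simulation
#'
#' Minimization convention: Case A returns
#' `-psi0 * integral(V_biogas(t) dt)`; Case B
#' `-psi01 * integral(V_biogas(t) dt) + psi02 * V_H2S`; Case C
#' `-psi01 * integral(V_CH4(t) dt) + psi02 * V_H2S`.
#' Unset weights default to 1.
#'
#' @param case An `ad_case`.
#' @param sim An `ad_simulation`.
#' @return Scalar objective value.
#' @export
objective_case <- function(case, sim) {
  if (!inherits(case, "ad_case")) stop("unknown case")
  w <- function(x) if (is.null(x)) 1 else x
  Ib <- .trapz(sim$time, sim$state[, "V_biogas"])
  Ic <- .trapz(sim$time, sim$state[, "V_CH4"])
  vh2s <- sim$volumes[["V_H2S"]]
  switch(case$case,
         A = -w(case$psi0) * Ib,
         B = -w(case$psi01) * Ib + w(case$psi02) * vh2s,
         C = -w(case$psi01) * Ic + w(case$psi02) * vh2s)
}

#' Case constraint values on a simulation
#'
#' Case A has no functional constraints (bounds only); Case B caps the H2S
#' fraction of the produced biogas; Case C caps the H2S, H2 and NH3
#' fractions. Standard `g <= 0` convention.
#'
#' @inheritParams objective_case
#' @return Numeric vector (length 0, 1 or 3).
#' @export
dosage_constraints <- function(case, sim) {
  if (!inherits(case, "ad_case")) stop("unknown case")
  Vb <- sim$volumes[["V_biogas"]]
  if (case$case == "A") return(numeric(0))
  if (Vb <= 0) stop("V_biogas = 0: fraction constraints undefined")
  g1 <- case$psi1 * (sim$volumes[["V_H2S"]] / Vb - case$phi_H2S_max)
  if (case$case == "B") return(c(g_H2S = unname(g1)))
  g2 <- case$psi2 * (sim$volumes[["V_H2"]] / Vb - case$phi_H2_max)
  g3 <- case$psi3 * (sim$volumes[["V_NH3"]] / Vb - case$phi_NH3_max)
  c(g_H2S = unname(g1), g_H2 = unname(g2), g_NH3 = unname(g3))
}

#' Optimize the trace-metal dosage of the feedstock
#'
#' Optimizes the eleven normalized metal concentrations with the sequential
#' convex approximation solver, simulating the calibrated model at every
#' evaluation; the start point is the normalized initial design. Unset
#' objective weights are normalized by the initial-design magnitudes so the
#' objective terms are O(1).
#'
#' @param case An `ad_case`.
#' @param params Calibrated `ad_parameters`.
#' @param bounds An `ad_tm_bounds` table.
#' @param config,feed Reactor and (initial-design) feedstock.
#' @param dt,method Solver settings of the embedded simulations.
#' @param maxit,move Optimizer settings.
#' @param verbose Log optimizer iterations.
#' @return List of class `ad_dosage_report`: `tm_opt` (data.frame in the
#'   stated units with added/removed amounts), `deltas` (percentage changes
#'   of cumulative volumes vs the initial design), `content_deltas`,
#'   `feasible`, `objective`, and the two simulations.
#' @export
optimize_dosage <- function(case, params, bounds, config, feed,
                            dt = 0.02, method = "euler", maxit = 30,
                            move = 0.2, verbose = FALSE) {
  stopifnot(inherits(case, "ad_case"), inherits(bounds, "ad_tm_bounds"))
  feed_with <- function(tm_g) {
    f2 <- feed
    f2$tm[bounds$tm] <- tm_g
    f2
  }
  sim_init <- simulate_ad(params, config, feed_with(bounds$init_g),
                          dt = dt, method = method)
  # normalize unset weights by initial-design magnitudes
  Ib0 <- .trapz(sim_init$time, sim_init$state[, "V_biogas"])
  Ic0 <- .trapz(sim_init$time, sim_init$state[, "V_CH4"])
  vh2s0 <- sim_init$volumes[["V_H2S"]]
  if (is.null(case$psi0)) case$psi0 <- 1 / max(Ib0, 1e-12)
  if (is.null(case$psi01)) {
    case$psi01 <- 1 / max(if (case$case == "C") Ic0 else Ib0, 1e-12)
  }
  if (is.null(case$psi02)) case$psi02 <- 1 / max(vh2s0, 1e-12)

  fn <- function(x) {
    tm_g <- denormalize_design(x, bounds$lo_g, bounds$up_g)
    out <- tryCatch({
      sim <- simulate_ad(params, config, feed_with(tm_g), dt = dt,
                         method = method)
      list(f = objective_case(case, sim), g = dosage_constraints(case, sim))
    }, error = function(e) NULL)
    if (is.null(out)) {
      out <- list(f = 1e6,
                  g = numeric(switch(case$case, A = 0, B = 1, C = 3)))
    }
    out
  }
  x0 <- normalize_design(bounds$init_g, bounds$lo_g, bounds$up_g)
  res <- approx_solve(opt_problem(fn, 11, maxit = maxit, move = move),
                      x0, verbose = verbose)
  tm_opt_g <- denormalize_design(res$x, bounds$lo_g, bounds$up_g)
  sim_opt <- simulate_ad(params, config, feed_with(tm_opt_g), dt = dt,
                         method = method)
  f <- ifelse(bounds$unit == "mg/L", 1e3, 1)
  tm_tab <- data.frame(tm = bounds$tm, unit = bounds$unit,
                       initial = bounds$init, optimal = tm_opt_g * f,
                       added = (tm_opt_g - bounds$init_g) * f)
  perf <- performance_report(sim_opt, sim_init)
  structure(list(case = case$case, tm_opt = tm_tab,
                 deltas = perf$volume_deltas,
                 content_deltas = perf$content_deltas,
                 feasible = res$feasible, objective = res$f,
                 sim_init = sim_init, sim_opt = sim_opt,
                 history = res$history),
            class = "ad_dosage_report")
}

#' Percentage performance deltas between two simulations
#'
#' `100 * (V_opt - V_init) / V_init` for the cumulative biogas, CH4, H2,
#' H2S and NH3 volumes, and the same for the gas content (volume fraction
#' of biogas). Gases with zero initial volume report `NA`.
#'
#' @param sim_opt,sim_init Two `ad_simulation`s on the same configuration.
#' @return List with `volume_deltas` and `content_deltas` (named, percent).
#' @export
performance_report <- function(sim_opt, sim_init) {
  vo <- sim_opt$volumes
  vi <- sim_init$volumes
  pd <- function(a, b) if (b == 0) NA_real_ else 100 * (a - b) / b
  vol <- vapply(names(vo), function(k) pd(vo[[k]], vi[[k]]), numeric(1))
  gs <- c("V_CH4", "V_H2", "V_H2S", "V_NH3")
  co <- vapply(gs, function(k) {
    pd(vo[[k]] / vo[["V_biogas"]], vi[[k]] / vi[["V_biogas"]])
  }, numeric(1))
  names(co) <- sub("V_", "content_", gs)
  list(volume_deltas = vol, content_deltas = co)
}

#' @export
print.ad_dosage_report <- function(x, ...) {
  cat("<ad_dosage_report> Case", x$case,
      if (x$feasible) "(feasible)" else "(least-infeasible)", "\n")
  print(x$tm_opt, digits = 4)
  cat("volume deltas vs initial design (%):\n")
  print(round(x$deltas, 2))
  invisible(x)
}
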