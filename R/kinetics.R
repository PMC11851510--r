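# Biochemical rate laws: enzyme-mediated hydrolysis, Michaelis pH factor,
# linear-tent temperature dependence, Monod growth with non-competitive
# inhibition, and liquid-gas transfer.

#' Enzymatic hydrolysis rate
#'
#' `rate = k_hyd * c_S * c_E / (K_ME0 + c_S) * K_inh_VFA / (K_inh_VFA + c_VFA)`,
#' i.e. first order in the hydrolytic enzyme, Michaelis-Menten in the
#' particulate substrate, and non-competitively inhibited by total VFA.
#'
#' @param c_S Particulate substrate concentration, g/L.
#' @param c_E Enzyme concentration, g/L.
#' @param c_VFA Total VFA concentration, g/L.
#' @param k_hyd Hydrolysis rate constant, 1/day.
#' @param K_ME0 Half-saturation constant, g/L.
#' @param K_inh_VFA VFA inhibition constant, g/L.
#' @return Hydrolysis rate, g/L/day.
#' @export
hydrolysis_rate <- function(c_S, c_E, c_VFA, k_hyd, K_ME0, K_inh_VFA) {
  if (any(c(c_S, c_E, c_VFA, k_hyd, K_ME0, K_inh_VFA) < 0)) {
    stop("hydrolysis_rate: negative input")
  }
  k_hyd * c_S * c_E / (K_ME0 + c_S) * K_inh_VFA / (K_inh_VFA + c_VFA)
}

#' Michaelis pH factor
#'
#' Bell-shaped pH dependence
#' `f = (1 + 2 * 10^(0.5*(pK_lo - pK_up))) / (1 + 10^(pH - pK_up) + 10^(pK_lo - pH))`,
#' equal to its maximum (1) at `pH = (pK_lo + pK_up)/2` and symmetric about
#' it.
#'
#' @param pH The pH.
#' @param pK_lo,pK_up Lower / upper drop-off values (`pK_lo < pK_up`).
#' @return Dimensionless factor in `[0, 1]` (up to rounding).
#' @export
michaelis_ph_factor <- function(pH, pK_lo, pK_up) {
  if (any(pK_lo >= pK_up)) stop("michaelis_ph_factor: pK_lo must be < pK_up")
  (1 + 2 * 10^(0.5 * (pK_lo - pK_up))) /
    (1 + 10^(pH - pK_up) + 10^(pK_lo - pH))
}

#' Temperature dependence of the maximal growth rate
#'
#' Linear tent law: `mu_max(T) = max(0, mu_max_Topt - alpha * |T - T_opt|)`
#' for `T < T_max` and 0 at or above `T_max`.
#'
#' @param T_C Temperature, degrees C.
#' @param mu_max_Topt Maximal growth rate at the optimum, 1/day.
#' @param alpha Linear decline, 1/(degC day).
#' @param T_opt,T_max Optimal and cutoff temperatures, degC (`T_opt < T_max`).
#' @return Maximal growth rate at `T_C`, 1/day.
#' @export
temperature_factor <- function(T_C, mu_max_Topt, alpha, T_opt, T_max) {
  if (any(T_opt >= T_max)) stop("temperature_factor: T_opt must be < T_max")
  mu <- pmax(0, mu_max_Topt - alpha * abs(T_C - T_opt))
  mu[T_C >= T_max] <- 0
  if (length(mu) == 1) mu <- unname(mu)
  mu
}

# substrate pairings behind the 16 Monod constants: for each group, the
# state pools and the matching k_M entries
.growth_monod_map <- list(
  Asu  = list(sub = "su",                    km = "kM_su_Asu"),
  Aaa  = list(sub = "aa",                    km = "kM_aa_Aaa"),
  Agly = list(sub = "gly",                   km = "kM_gly_Agly"),
  Aoa  = list(sub = "oa",                    km = "kM_oa_Aoa"),
  Apro = list(sub = "pro",                   km = "kM_pro_Apro"),
  Abu  = list(sub = "bu",                    km = "kM_bu_Abu"),
  Ava  = list(sub = "va",                    km = "kM_va_Ava"),
  Mac  = list(sub = "ac",                    km = "kM_ac_Mac"),
  Mhyd = list(sub = "H2_liq",                km = "kM_H2_Mhyd"),
  Ss   = list(sub = "Sio_at",                km = "kM_Sat_Ss"),
  Spro = list(sub = c("pro", "Sio_at"),      km = c("kM_pro_Spro", "kM_Sat_Spro")),
  Sac  = list(sub = c("ac", "Sio_at"),       km = c("kM_ac_Sac", "kM_Sat_Sac")),
  Shyd = list(sub = c("H2_liq", "Sio_at"),   km = c("kM_H2_Shyd", "kM_Sat_Shyd"))
)

# growth-inhibitor pairings (25): inhibitor pool -> K_inh entry, per group
.growth_inhibition_map <- list(
  Agly = c(H2 = "Kinh_H2_Agly"),
  Aoa  = c(H2 = "Kinh_H2_Aoa"),
  Apro = c(H2 = "Kinh_H2_Apro", H2S = "Kinh_H2S_Apro"),
  Abu  = c(H2 = "Kinh_H2_Abu", H2S = "Kinh_H2S_Abu",
           Cu = "Kinh_Cu_Abu", Zn = "Kinh_Zn_Abu", Cr = "Kinh_Cr_Abu",
           Pb = "Kinh_Pb_Abu", Ni = "Kinh_Ni_Abu"),
  Ava  = c(H2 = "Kinh_H2_Ava", H2S = "Kinh_H2S_Ava"),
  Mac  = c(H2S = "Kinh_H2S_Mac", NH3 = "Kinh_NH3_Mac",
           Cu = "Kinh_Cu_Mac", Zn = "Kinh_Zn_Mac", Cr = "Kinh_Cr_Mac",
           Pb = "Kinh_Pb_Mac", Ni = "Kinh_Ni_Mac"),
  Mhyd = c(H2S = "Kinh_H2S_Mhyd"),
  Ss   = c(H2S = "Kinh_H2S_Ss"),
  Spro = c(H2S = "Kinh_H2S_Spro"),
  Sac  = c(H2S = "Kinh_H2S_Sac"),
  Shyd = c(H2S = "Kinh_H2S_Shyd")
)

# inhibitor concentrations (g/L on each inhibitor's scale) from a named state
# vector and the speciation fractions
.inhibitor_concs <- function(s, fr) {
  c(H2 = unname(s[["H2_liq"]]),
    H2S = unname(s[["Sio_id"]] * fr[["f_H2S"]]),
    NH3 = unname(s[["Nio"]] * fr[["f_NH3"]]),
    Cu = unname(s[["TM_Cu"]]), Zn = unname(s[["TM_Zn"]]),
    Cr = unname(s[["TM_Cr"]]), Pb = unname(s[["TM_Pb"]]),
    Ni = unname(s[["TM_Ni"]]))
}

#' Specific growth rate of one microbial group
#'
#' Multiplies the temperature-adjusted maximal rate by the group's Monod
#' substrate factor(s), the Michaelis pH factor, inorganic N and P nutrient
#' limitation, and the group's non-competitive inhibition factors
#' (H2, free H2S, free NH3, and ionic Cu/Zn/Cr/Pb/Ni where assigned).
#'
#' @param group One of [microbial_groups()].
#' @param state Named 80-entry state vector (see [state_names()]).
#' @param params An `ad_parameters` object.
#' @param pH Bulk pH.
#' @param T_C Temperature, degC.
#' @param cst Chemistry constants.
#' @return Specific growth rate, 1/day.
#' @export
growth_rate <- function(group, state, params, pH, T_C,
                        cst = chem_constants()) {
  if (!group %in% microbial_groups()) stop("unknown microbial group: ", group)
  if (pH <= 0 || pH >= 14) stop("pH out of (0, 14)")
  mu <- temperature_factor(T_C, params$mu_max_Topt[[group]],
                           params$alpha[[group]], params$T_opt[[group]],
                           params$T_max[[group]])
  mm <- .growth_monod_map[[group]]
  for (i in seq_along(mm$sub)) {
    cs <- max(0, state[[mm$sub[i]]])
    mu <- mu * cs / (params$k_M[[mm$km[i]]] + cs)
  }
  mu <- mu * michaelis_ph_factor(pH, params$pK_lo[[group]],
                                 params$pK_up[[group]])
  cN <- max(0, state[["Nio"]]); cP <- max(0, state[["Pio"]])
  mu <- mu * cN / (params$K_M_nutrient[["K_M_Nio"]] + cN) *
    cP / (params$K_M_nutrient[["K_M_Pio"]] + cP)
  im <- .growth_inhibition_map[[group]]
  if (!is.null(im)) {
    fr <- speciate(pH, state[c("Cio", "Nio", "Sio_id")], cst)$fractions
    ci <- .inhibitor_concs(state, fr)
    for (j in seq_along(im)) {
      K <- params$K_inh[[im[[j]]]]
      mu <- mu * K / (K + max(0, ci[[names(im)[j]]]))
    }
  }
  unname(mu)
}

#' Liquid-gas mass transfer rate
#'
#' `rate = (KLa_a * T + KLa_b) * (c_liq - K_H * p_gas)`; positive rates
#' transfer from liquid to gas.
#'
#' @param gas One of `"CH4"`, `"CO2"`, `"H2"`, `"H2S"`, `"NH3"` (used for
#'   validation only).
#' @param c_liq Transferable (free) liquid concentration, g/L.
#' @param p_gas Partial pressure in the headspace, bar.
#' @param T_C Temperature, degC.
#' @param KLa_a,KLa_b Linear temperature law of the transfer coefficient,
#'   1/(degC day) and 1/day.
#' @param K_H Henry constant, g/(L bar), on the same scale as `c_liq`.
#' @return Transfer rate, g/L/day.
#' @export
gas_transfer_rate <- function(gas, c_liq, p_gas, T_C, KLa_a, KLa_b, K_H) {
  gas <- match.arg(gas, c("CH4", "CO2", "H2", "H2S", "NH3"))
  if (c_liq < 0 || p_gas < 0) stop("gas_transfer_rate: negative input")
  kla <- KLa_a * T_C + KLa_b
  if (kla < 0) stop("gas_transfer_rate: negative transfer coefficient")
  kla * (c_liq - K_H * p_gas)
}

#' Headspace balance at constant total pressure
#'
#' Converts per-gas liquid-to-gas transfer rates into headspace molar
#' derivatives, expelling biogas so that the total pressure never exceeds
#' `p_total`: while the headspace is at `p_total`, the molar outflow equals
#' the net molar inflow and is split across gases by mole fraction, making
#' total moles (hence total pressure) an exact invariant of the integration.
#'
#' @param state Named 80-entry state vector.
#' @param config An `ad_bioreactor`.
#' @param transfer Named per-gas transfer rates, g/L/day, on the tracked
#'   scales (CO2 as g C, H2S as g S, NH3 as g N).
#' @param cst Chemistry constants.
#' @return List with `dGas` (mol/day, per gas), `Q_biogas` (L/day at reactor
#'   T and `p_total`), `p` (partial pressures, bar) and `y` (mole
#'   fractions).
#' @export
gas_phase_balance <- function(state, config, transfer,
                              cst = chem_constants()) {
  stopifnot(config$V_gas > 0)
  gases <- c("CH4", "CO2", "H2", "H2S", "NH3")
  n <- pmax(0, as.numeric(state[paste0("G_", gases)]))
  if (sum(n) <= 0) {
    warning("empty headspace: total pressure cannot be maintained; Q clamped to 0")
    return(list(dGas = stats::setNames(numeric(5), gases), Q_biogas = 0,
                p = stats::setNames(numeric(5), gases),
                y = stats::setNames(rep(NA_real_, 5), gases)))
  }
  RT <- cst$R_bar * (config$T_C + 273.15)
  # mol/day entering the headspace, per gas
  scale_M <- cst$molar_mass[c("CH4", "C", "H2", "S", "N")]
  ndot_in <- as.numeric(transfer[gases]) * config$V_liq / as.numeric(scale_M)
  p <- n * RT / config$V_gas
  y <- n / sum(n)
  at_pressure <- sum(p) >= config$p_total * (1 - 1e-12)
  Q_mol <- if (at_pressure) max(0, sum(ndot_in)) else 0
  dGas <- ndot_in - Q_mol * y
  list(dGas = stats::setNames(dGas, gases),
       Q_biogas = Q_mol * RT / config$p_total,
       p = stats::setNames(p, gases), y = stats::setNames(y, gases))
}
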