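# State enumeration (80 ODE states), reactor/feedstock configuration types,
# and construction of the initial state.

#' Canonical state vector enumeration
#'
#' The 80 ODE states: 13 biomass, 3 enzymes, 4 particulates, 4 monomers,
#' 4 VFA totals, 8 dissolved inorganics, the proton concentration, 2 lumped
#' ions, 13 trace-metal ionic totals, 20 precipitates, 5 gas-phase amounts
#' (mol) and 3 cumulative volumes (L).
#'
#' @return Character vector of length 80.
#' @export
state_names <- function() {
  c(paste0("X_", microbial_groups()),
    paste0("E_", c("ch", "pr", "li")),
    c("ch", "pr", "li", "inert"),
    c("su", "aa", "gly", "oa"),
    c("pro", "bu", "va", "ac"),
    c("Cio", "Nio", "Pio", "Sio_id", "Sio_at", "NO2", "H2_liq", "CH4_liq"),
    "Hplus",
    c("Cat", "An"),
    paste0("TM_", tm_set()),
    paste0("P_", precipitate_species()$name),
    paste0("G_", c("CH4", "CO2", "H2", "H2S", "NH3")),
    c("V_biogas", "V_CH4", "V_H2S"))
}

#' Registry of algebraic intermediates
#'
#' The 54 algebraic quantities evaluated alongside the ODE states: 13 pH
#' factors and 13 temperature factors (one per microbial group), 5 gas
#' transfer coefficients, 5 partial pressures, 14 acid-base speciation
#' fractions, the charge imbalance, the pH, and the biogas and methane flow
#' rates.
#'
#' @return Character vector of length 54.
#' @export
algebraic_registry <- function() {
  g <- microbial_groups()
  gases <- c("CH4", "CO2", "H2", "H2S", "NH3")
  c(paste0("f_pH_", g),
    paste0("f_T_", g),
    paste0("KLa_", gases),
    paste0("p_", gases),
    c("f_pro", "f_bu", "f_va", "f_ac", "f_NH4", "f_HCO3", "f_CO3",
      "f_HSO4", "f_SO4", "f_HS", "f_S2", "f_H2PO4", "f_HPO4", "f_PO4"),
    c("Ch", "pH", "Q_biogas", "Q_CH4"))
}

#' Bioreactor configuration
#'
#' @param pH_init Initial pH (dimensionless, in (0, 14)).
#' @param T_C Operating temperature, degrees C.
#' @param V_liq Liquid volume, L.
#' @param V_gas Headspace volume, L.
#' @param p_total Total headspace pressure, bar.
#' @param t_total Batch duration, days.
#' @param headspace Initial headspace mole fractions of the five tracked
#'   gases (must sum to 1); default pure CO2.
#' @return List of class `ad_bioreactor`.
#' @export
bioreactor_config <- function(pH_init, T_C, V_liq, V_gas, p_total, t_total,
                              headspace = c(CH4 = 0, CO2 = 1, H2 = 0,
                                            H2S = 0, NH3 = 0)) {
  stopifnot(V_liq > 0, V_gas > 0, p_total > 0, t_total > 0,
            pH_init > 0, pH_init < 14)
  headspace <- headspace[c("CH4", "CO2", "H2", "H2S", "NH3")]
  if (abs(sum(headspace) - 1) > 1e-9) stop("headspace fractions must sum to 1")
  structure(list(pH_init = pH_init, T_C = T_C, V_liq = V_liq, V_gas = V_gas,
                 p_total = p_total, t_total = t_total, headspace = headspace),
            class = "ad_bioreactor")
}

#' Feedstock composition
#'
#' Concentrations in g/L: degradable particulates (ch, pr, li), inerts,
#' dissolved inorganic pools (C, N, P, sulfide-S, sulfate-S, NO2), and the
#' thirteen trace-metal ionic totals. Cl and Se default to 0 (they appear in
#' the charge balance but have no measured feed entry).
#'
#' @param ch,pr,li,inert Particulate organics and inerts, g/L.
#' @param Cio,Nio,Pio Inorganic carbon/nitrogen/phosphorus, g element/L.
#' @param Sio_id,Sio_at Inorganic sulfide-S and sulfate-S, g S/L.
#' @param NO2 Nitrite/nitrogen dioxide pool, g/L.
#' @param tm Named numeric vector of trace-metal concentrations (g metal/L);
#'   names among [tm_set()].
#' @return List of class `ad_feedstock`.
#' @export
feedstock_composition <- function(ch = 0, pr = 0, li = 0, inert = 0,
                                  Cio = 0, Nio = 0, Pio = 0,
                                  Sio_id = 0, Sio_at = 0, NO2 = 0,
                                  tm = numeric(0)) {
  tms <- stats::setNames(numeric(13), tm_set())
  if (length(tm)) {
    bad <- setdiff(names(tm), tm_set())
    if (length(bad)) stop("unknown trace metal: ", paste(bad, collapse = ", "))
    tms[names(tm)] <- tm
  }
  vals <- c(ch = ch, pr = pr, li = li, inert = inert, Cio = Cio, Nio = Nio,
            Pio = Pio, Sio_id = Sio_id, Sio_at = Sio_at, NO2 = NO2, tms)
  if (any(vals < 0)) {
    stop("negative feed concentration: ", names(vals)[which(vals < 0)[1]])
  }
  structure(c(as.list(vals[1:10]), list(tm = tms)), class = "ad_feedstock")
}

#' Reference bioreactor B1 configuration
#'
#' Lab-scale batch digester: pH 8.00, 35 C, 1.00 L liquid, 0.10 L headspace,
#' 1.0059 bar.
#'
#' @param t_total Batch duration in days (default 60).
#' @return An `ad_bioreactor` object.
#' @export
b1_bioreactor <- function(t_total = 60) {
  bioreactor_config(pH_init = 8.00, T_C = 35.00, V_liq = 1.00, V_gas = 0.10,
                    p_total = 1.0059, t_total = t_total)
}

#' Reference feedstock composition (manure, bioreactor B1)
#' @return An `ad_feedstock` object.
#' @export
b1_feedstock <- function() {
  feedstock_composition(
    ch = 15.0, pr = 35.0, li = 3.0, inert = 50.0,
    Cio = 2.5, Nio = 2.0, Pio = 2.6, Sio_id = 0.1, Sio_at = 0.5, NO2 = 0.008,
    tm = c(Ca = 3.0, Co = 0.02, Cr = 0.003, Cu = 0.01, Fe = 0.11, K = 3.2,
           Mg = 0.8, Na = 0.3, Ni = 0.001, Pb = 0.0002, Zn = 0.05))
}

#' Build the initial 80-entry state
#'
#' Biomass and enzymes come from the calibratable X_init/cE0 groups; all
#' dissolved and particulate pools from the feedstock; precipitates, soluble
#' intermediates and dissolved gases start at zero. The lumped Cat+/An- ion
#' is set so that the charge balance closes exactly at the configured initial
#' pH, and the headspace starts at p_total with the configured composition.
#'
#' @param params An `ad_parameters` object.
#' @param config An `ad_bioreactor` object.
#' @param feed An `ad_feedstock` object.
#' @param cst Chemistry constants.
#' @return Named numeric vector of length 80.
#' @export
build_initial_state <- function(params, config, feed,
                                cst = chem_constants()) {
  nm <- state_names()
  s <- stats::setNames(numeric(length(nm)), nm)
  s[paste0("X_", microbial_groups())] <- params$X_init
  s[paste0("E_", c("ch", "pr", "li"))] <- params$cE0
  s[c("ch", "pr", "li", "inert")] <- c(feed$ch, feed$pr, feed$li, feed$inert)
  s[c("Cio", "Nio", "Pio", "Sio_id", "Sio_at", "NO2")] <-
    c(feed$Cio, feed$Nio, feed$Pio, feed$Sio_id, feed$Sio_at, feed$NO2)
  s[paste0("TM_", tm_set())] <- feed$tm

  # close the charge balance at the prescribed initial pH with lumped ions
  H0 <- 10^(-config$pH_init)
  s["Hplus"] <- H0
  ch_req <- H0 - cst$Kw / H0
  ch_no_lump <- charge_imbalance_totals(s, config$pH_init, cst)
  gap <- ch_req - ch_no_lump   # eq/L to be supplied by lumped ions
  if (gap > 0) s["An"] <- gap else s["Cat"] <- -gap

  # headspace at p_total: n_total = p V / (R T)
  n_tot <- config$p_total * config$V_gas / (cst$R_bar * (config$T_C + 273.15))
  s[paste0("G_", c("CH4", "CO2", "H2", "H2S", "NH3"))] <-
    n_tot * config$headspace
  s
}
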