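# The 20-species precipitation network. All rate laws share the squared
# supersaturation driving force with a max(0, .) clamp before squaring, so
# rates are exactly zero at and below saturation and precipitates are
# terminal sinks (no dissolution).

#' Sulfide precipitation rate
#'
#' `rho = k_cryst * (max(0, sqrt(c_M * c_S) - sqrt(K_sp)))^2`.
#'
#' @param c_M Metal ion concentration, g/L.
#' @param c_S2 Ionized sulfide concentration, g S/L.
#' @param k_cryst Crystallization rate constant, 1/day.
#' @param K_sp Solubility product on the g/L driving-force scale.
#' @return Precipitation rate, g/L/day (vectorized).
#' @export
precip_rate_sulfide <- function(c_M, c_S2, k_cryst, K_sp) {
  if (any(c(c_M, c_S2, k_cryst, K_sp) < 0)) stop("negative input")
  d <- pmax(0, sqrt(c_M * c_S2) - sqrt(K_sp))
  k_cryst * d * d
}

#' Carbonate precipitation rate
#'
#' Same half-power driving force as the sulfide law, evaluated on the
#' carbonate ion pool.
#'
#' @inheritParams precip_rate_sulfide
#' @param c_CO3 Carbonate ion concentration, g C/L.
#' @return Precipitation rate, g/L/day (vectorized).
#' @export
precip_rate_carbonate <- function(c_M, c_CO3, k_cryst, K_sp) {
  if (any(c(c_M, c_CO3, k_cryst, K_sp) < 0)) stop("negative input")
  d <- pmax(0, sqrt(c_M * c_CO3) - sqrt(K_sp))
  k_cryst * d * d
}

#' Total phosphate precipitation rate
#'
#' Sum of the M3(PO4)2 terms (fifth-root ion product, counted twice per the
#' phosphate stoichiometry), the struvite term and the K-struvite term
#' (cube-root ion products):
#' `rho_PO4 = 2 * sum_i k_i * (max(0, (c_i^3 c_PO4^2)^(1/5) - K_sp_i^(1/5)))^2
#'   + k_struvite * (max(0, (c_Mg c_NH4 c_PO4)^(1/3) - K_sp^(1/3)))^2
#'   + k_kstruvite * (max(0, (c_K c_Mg c_PO4)^(1/3) - K_sp^(1/3)))^2`
#' with i in Ca, Co, Fe, Ni.
#'
#' @param c_M Named metal concentrations with entries `Ca`, `Co`, `Fe`,
#'   `Ni`, g/L.
#' @param c_PO4 Phosphate ion concentration, g P/L.
#' @param c_NH4 Ammonium concentration, g N/L.
#' @param c_K,c_Mg Potassium / magnesium ion concentrations, g/L.
#' @param k_cryst Named rate constants (`Ca3(PO4)2`, ..., `MgNH4PO4`,
#'   `KMgPO4`), 1/day.
#' @param K_sp Named solubility products for the same six phases.
#' @return Phosphate-pool sink rate, g P-equivalent/L/day.
#' @export
precip_rate_phosphate <- function(c_M, c_PO4, c_NH4, c_K, c_Mg,
                                  k_cryst, K_sp) {
  if (any(c(c_M, c_PO4, c_NH4, c_K, c_Mg) < 0)) stop("negative input")
  mp <- paste0(c("Ca", "Co", "Fe", "Ni"), "3(PO4)2")
  d <- pmax(0, (c_M[c("Ca", "Co", "Fe", "Ni")]^3 * c_PO4^2)^(1 / 5) -
              K_sp[mp]^(1 / 5))
  r <- 2 * sum(k_cryst[mp] * d * d)
  ds <- max(0, (c_Mg * c_NH4 * c_PO4)^(1 / 3) - K_sp[["MgNH4PO4"]]^(1 / 3))
  dk <- max(0, (c_K * c_Mg * c_PO4)^(1 / 3) - K_sp[["KMgPO4"]]^(1 / 3))
  unname(r + k_cryst[["MgNH4PO4"]] * ds * ds + k_cryst[["KMgPO4"]] * dk * dk)
}

# per-precipitate growth rates from an ion environment:
# ions = list(tm = named g/L (13), CO3, S, PO4, NH4 as pool-scale g/L)
.precip_rates_all <- function(ions, k_cryst, Ksp) {
  pt <- precipitate_species()
  n <- nrow(pt)
  r <- numeric(n)
  for (i in seq_len(n)) {
    cm <- ions$tm[[pt$metal[i]]]
    r[i] <- switch(pt$type[i],
      carbonate = {
        d <- max(0, sqrt(cm * ions$CO3) - sqrt(Ksp[[pt$name[i]]])); d * d
      },
      sulfide = {
        d <- max(0, sqrt(cm * ions$S) - sqrt(Ksp[[pt$name[i]]])); d * d
      },
      phosphate = {
        d <- max(0, (cm^3 * ions$PO4^2)^(1 / 5) - Ksp[[pt$name[i]]]^(1 / 5)); d * d
      },
      struvite = {
        d <- max(0, (ions$tm[["Mg"]] * ions$NH4 * ions$PO4)^(1 / 3) -
                   Ksp[[pt$name[i]]]^(1 / 3)); d * d
      },
      kstruvite = {
        d <- max(0, (ions$tm[["K"]] * ions$tm[["Mg"]] * ions$PO4)^(1 / 3) -
                   Ksp[[pt$name[i]]]^(1 / 3)); d * d
      })
    r[i] <- r[i] * k_cryst[[pt$name[i]]]
  }
  stats::setNames(r, pt$name)
}

# ion environment from a named state vector at a given pH
.ion_environment <- function(state, pH, cst) {
  sp <- speciate(pH, state[c("Cio", "Nio", "Pio", "Sio_id")], cst)
  fr <- sp$fractions
  s_frac <- if (identical(cst$sulfide_species, "S2")) fr[["f_S2"]] else
    fr[["f_HS"]] + fr[["f_S2"]]
  list(
    tm = stats::setNames(as.list(pmax(0, as.numeric(
      state[paste0("TM_", tm_set())]))), tm_set()),
    CO3 = max(0, state[["Cio"]]) * fr[["f_CO3"]],
    S = max(0, state[["Sio_id"]]) * s_frac,
    PO4 = max(0, state[["Pio"]]) * fr[["f_PO4"]],
    NH4 = max(0, state[["Nio"]]) * fr[["f_NH4"]]
  )
}

#' Growth rates of the twenty precipitates
#'
#' Evaluates every precipitate's `k_cryst * (driving force)^2` rate at the
#' current state and pH. All rates are non-negative, and each is exactly
#' zero at or below its saturation boundary.
#'
#' @param state Named 80-entry state vector.
#' @param params An `ad_parameters` object (supplies `k_cryst`).
#' @param pH Bulk pH.
#' @param cst Chemistry constants (supplies `K_sp` and the sulfide driving
#'   species).
#' @return Named numeric vector of 20 rates, g/L/day.
#' @export
precipitate_derivatives <- function(state, params, pH,
                                    cst = chem_constants()) {
  ions <- .ion_environment(state, pH, cst)
  .precip_rates_all(ions, params$k_cryst, cst$Ksp)
}

#' Precipitation sink of one trace metal's ionic pool
#'
#' Sum of the carbonate, sulfide and (with the factor-3 metal weight) phosphate
#' driving-force terms that apply to the metal; struvite and K-struvite
#' consumption is included in the Mg and K sinks so that elemental
#' conservation holds. Metals with no precipitate in the network (Na, Cr,
#' Cl, Se) have sink 0.
#'
#' @param tm One of [tm_set()].
#' @inheritParams precipitate_derivatives
#' @return Sink rate of the ionic pool, g/L/day.
#' @export
tm_ion_sink <- function(tm, state, params, pH, cst = chem_constants()) {
  if (!tm %in% tm_set()) stop("unknown trace metal: ", tm)
  r <- precipitate_derivatives(state, params, pH, cst)
  pt <- precipitate_species()
  own <- pt$metal == tm
  sink <- sum(pt$nu_metal[own] * r[own])
  if (tm == "K") sink <- sink + r[["KMgPO4"]]
  unname(sink)
}
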