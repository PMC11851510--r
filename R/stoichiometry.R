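# Fixed (non-calibrated) stoichiometric yields. Yields are mass fractions of
# the consumed primary substrate; every reaction closes to total mass 1
# (including an explicit water term), so the table is checkable. CO2 and NH3
# yields are stated in their molecular masses and converted to the element
# scales (g C, g N) when applied to the inorganic pools.

#' Default stoichiometric yield table
#'
#' For each microbial group: the primary substrate, the biomass yield `Y`
#' (g biomass per g substrate), product mass fractions (negative entries are
#' co-consumed compounds), the water closure term, and the sulfate-to-sulfide
#' conversion `s_conv` (g S per g primary substrate) for the sulfate
#' reducers. Also carries the hydrolysis product split, the decay recycle
#' fractions, and the biomass N and P content.
#'
#' @return A list of class `ad_stoichiometry`.
#' @export
default_stoichiometry <- function() {
  grp <- function(sub, Y, products, H2O = 0, s_conv = 0) {
    list(sub = sub, Y = Y, products = products, H2O = H2O, s_conv = s_conv)
  }
  st <- list(
    groups = list(
      Asu  = grp("su", 0.10, c(ac = 0.3647, pro = 0.15, bu = 0.15, H2 = 0.0003,
                               CO2 = 0.235)),
      Aaa  = grp("aa", 0.10, c(ac = 0.3097, pro = 0.15, bu = 0.10, va = 0.10,
                               H2 = 0.0003, CO2 = 0.14, NH3 = 0.10)),
      Agly = grp("gly", 0.10, c(ac = 0.4294, pro = 0.20, H2 = 0.0006,
                                CO2 = 0.27)),
      Aoa  = grp("oa", 0.08, c(ac = 0.6494, H2 = 0.0006, CO2 = 0.27)),
      Apro = grp("pro", 0.06, c(ac = 0.6144, H2 = 0.0006, CO2 = 0.325)),
      Abu  = grp("bu", 0.06, c(ac = 0.7394, H2 = 0.0006, CO2 = 0.20)),
      Ava  = grp("va", 0.06, c(ac = 0.5894, pro = 0.25, H2 = 0.0006,
                               CO2 = 0.10)),
      Mac  = grp("ac", 0.05, c(CH4 = 0.26, CO2 = 0.69)),
      Mhyd = grp("H2_liq", 0.45, c(CH4 = 2.0, CO2 = -5.5), H2O = 4.05),
      Ss   = grp("Sio_at", 0.10, c(ac = -2.0, CO2 = 1.9, Sid = 1.0)),
      Spro = grp("pro", 0.05, c(ac = 0.50, CO2 = 0.45), s_conv = 0.25),
      Sac  = grp("ac", 0.05, c(CO2 = 0.95), s_conv = 0.30),
      Shyd = grp("H2_liq", 0.30, c(Sid = 0), H2O = 0.70, s_conv = 4.0)
    ),
    hydrolysis = list(ch = c(su = 1), pr = c(aa = 1),
                      li = c(gly = 0.05, oa = 0.95)),
    decay_fractions = c(ch = 0.35, pr = 0.55, li = 0.10),
    biomass_N = 0.08,   # g N per g biomass, drawn from the Nio pool
    biomass_P = 0.015   # g P per g biomass, drawn from the Pio pool
  )
  class(st) <- "ad_stoichiometry"
  st
}

#' Check mass closure of a stoichiometry table
#'
#' Every group's reaction must conserve total mass: primary substrate plus
#' co-consumed compounds equals biomass plus products plus water, within
#' `tol` (relative). Hydrolysis splits and decay recycle fractions must sum
#' to 1 (decay may sum to less; the remainder is lysis loss).
#'
#' @param st An `ad_stoichiometry` list.
#' @param tol Relative tolerance.
#' @return Invisibly TRUE; stops naming the offending reaction otherwise.
#' @export
check_stoichiometry <- function(st, tol = 1e-6) {
  # s_conv is an S-neutral pass-through (sulfate-S in, sulfide-S out) and
  # cancels from the closure
  for (g in names(st$groups)) {
    gr <- st$groups[[g]]
    pr <- gr$products
    mass_in <- 1 + sum(-pr[pr < 0])
    mass_out <- gr$Y + sum(pr[pr > 0]) + gr$H2O
    if (abs(mass_in - mass_out) > tol * mass_in) {
      stop("stoichiometry of ", g, " does not close: in ", mass_in,
           " vs out ", mass_out)
    }
  }
  for (h in names(st$hydrolysis)) {
    if (abs(sum(st$hydrolysis[[h]]) - 1) > tol) {
      stop("hydrolysis split of ", h, " does not sum to 1")
    }
  }
  if (sum(st$decay_fractions) > 1 + tol) stop("decay fractions exceed 1")
  invisible(TRUE)
}
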