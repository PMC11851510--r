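# Acid-base speciation, the model's charge balance, and the pH root solve.
# Totals are carried on the model's mass scales (VFAs as the acid, g/L;
# inorganic pools as g element/L; NO2 as g NO2/L); speciated ion
# concentrations are reported in mol/L.

#' Acid-base speciation at a given pH
#'
#' Closed-form ionization fractions for every acid system of the model:
#' the four VFAs, ammonium, carbonate (diprotic), sulfide (diprotic),
#' sulfate (HSO4-/SO42-), phosphate (triprotic) and nitrite.
#'
#' @param pH The pH.
#' @param totals Named numeric vector of totals in g/L with (any of) the
#'   names `pro`, `bu`, `va`, `ac`, `Cio`, `Nio`, `Pio`, `Sio_id`, `Sio_at`,
#'   `NO2`; missing entries are treated as zero.
#' @param cst Chemistry constants.
#' @return List of class `ad_speciation` with elements `pH`, `fractions`
#'   (named, all in `[0,1]`), `mol` (ion concentrations, mol/L) and
#'   `charge_per_g` (signed eq per gram of each total pool, anions
#'   positive).
#' @export
speciate <- function(pH, totals, cst = chem_constants()) {
  tt <- stats::setNames(numeric(10),
                        c("pro", "bu", "va", "ac", "Cio", "Nio", "Pio",
                          "Sio_id", "Sio_at", "NO2"))
  totals <- unlist(totals)
  keep <- intersect(names(totals), names(tt))
  tt[keep] <- totals[keep]
  if (any(tt < 0)) stop("negative total: ", names(tt)[which(tt < 0)[1]])
  H <- 10^(-pH)
  Ka <- cst$Ka
  M <- cst$molar_mass

  f_vfa <- c(pro = Ka$pro, bu = Ka$bu, va = Ka$va, ac = Ka$ac)
  f_vfa <- f_vfa / (f_vfa + H)
  f_NH4 <- H / (H + Ka$NH4)

  Dc <- H * H + H * Ka$CO2[1] + Ka$CO2[1] * Ka$CO2[2]
  f_CO2 <- H * H / Dc
  f_HCO3 <- H * Ka$CO2[1] / Dc
  f_CO3 <- Ka$CO2[1] * Ka$CO2[2] / Dc

  Ds <- H * H + H * Ka$H2S[1] + Ka$H2S[1] * Ka$H2S[2]
  f_H2S <- H * H / Ds
  f_HS <- H * Ka$H2S[1] / Ds
  f_S2 <- Ka$H2S[1] * Ka$H2S[2] / Ds

  f_SO4 <- Ka$SO4 / (Ka$SO4 + H)
  f_HSO4 <- 1 - f_SO4

  Dp <- H^3 + H^2 * Ka$PO4[1] + H * Ka$PO4[1] * Ka$PO4[2] +
    Ka$PO4[1] * Ka$PO4[2] * Ka$PO4[3]
  f_H2PO4 <- H^2 * Ka$PO4[1] / Dp
  f_HPO4 <- H * Ka$PO4[1] * Ka$PO4[2] / Dp
  f_PO4 <- Ka$PO4[1] * Ka$PO4[2] * Ka$PO4[3] / Dp

  f_NO2 <- Ka$NO2 / (Ka$NO2 + H)

  fr <- c(f_pro = unname(f_vfa["pro"]), f_bu = unname(f_vfa["bu"]),
          f_va = unname(f_vfa["va"]), f_ac = unname(f_vfa["ac"]),
          f_NH4 = f_NH4, f_HCO3 = f_HCO3, f_CO3 = f_CO3,
          f_HSO4 = f_HSO4, f_SO4 = f_SO4, f_HS = f_HS, f_S2 = f_S2,
          f_H2PO4 = f_H2PO4, f_HPO4 = f_HPO4, f_PO4 = f_PO4,
          f_NH3 = 1 - f_NH4, f_CO2 = f_CO2, f_H2S = f_H2S, f_NO2 = f_NO2)

  mol_tot <- c(pro = tt[["pro"]] / M[["pro"]], bu = tt[["bu"]] / M[["bu"]],
               va = tt[["va"]] / M[["va"]], ac = tt[["ac"]] / M[["ac"]],
               N = tt[["Nio"]] / M[["N"]], C = tt[["Cio"]] / M[["C"]],
               S_id = tt[["Sio_id"]] / M[["S"]],
               S_at = tt[["Sio_at"]] / M[["S"]],
               P = tt[["Pio"]] / M[["P"]], NO2 = tt[["NO2"]] / M[["NO2"]])
  mol <- c(
    pro = unname(mol_tot["pro"] * f_vfa["pro"]),
    bu = unname(mol_tot["bu"] * f_vfa["bu"]),
    va = unname(mol_tot["va"] * f_vfa["va"]),
    ac = unname(mol_tot["ac"] * f_vfa["ac"]),
    NH4 = unname(mol_tot["N"] * f_NH4),
    HCO3 = unname(mol_tot["C"] * f_HCO3),
    CO3 = unname(mol_tot["C"] * f_CO3),
    HSO4 = unname(mol_tot["S_at"] * f_HSO4),
    SO4 = unname(mol_tot["S_at"] * f_SO4),
    HS = unname(mol_tot["S_id"] * f_HS),
    S2 = unname(mol_tot["S_id"] * f_S2),
    H2PO4 = unname(mol_tot["P"] * f_H2PO4),
    HPO4 = unname(mol_tot["P"] * f_HPO4),
    PO4 = unname(mol_tot["P"] * f_PO4),
    NO2 = unname(mol_tot["NO2"] * f_NO2)
  )
  # signed eq per gram of each pool (anions positive, cations negative)
  cpg <- c(
    pro = unname(f_vfa["pro"]) / M[["pro"]],
    bu = unname(f_vfa["bu"]) / M[["bu"]],
    va = unname(f_vfa["va"]) / M[["va"]],
    ac = unname(f_vfa["ac"]) / M[["ac"]],
    Nio = -f_NH4 / M[["N"]],
    Cio = (f_HCO3 + 2 * f_CO3) / M[["C"]],
    Sio_at = (f_HSO4 + 2 * f_SO4) / M[["S"]],
    Sio_id = (f_HS + 2 * f_S2) / M[["S"]],
    Pio = (f_H2PO4 + 2 * f_HPO4 + 3 * f_PO4) / M[["P"]],
    NO2 = f_NO2 / M[["NO2"]]
  )
  structure(list(pH = pH, fractions = fr, mol = mol, charge_per_g = cpg,
                 totals = tt),
            class = "ad_speciation")
}

#' Charge imbalance of the model's charge balance
#'
#' Sum of ionic charge with the exact signs and stoichiometric weights of the
#' model's charge balance: speciated anions (VFA-, HCO3-, 2 CO32-, HSO4-,
#' 2 SO42-, HS-, 2 S2-, phosphates, NO2-) and the lumped anion count
#' positive; NH4+, the lumped cation and the metal cations negative with
#' their charges; by the model's convention Cl- enters with +1 and Se
#' with -2.
#'
#' @param speciation An `ad_speciation` object.
#' @param tm_mol Named trace-metal concentrations in mol/L (names among
#'   [tm_set()]; missing entries are zero).
#' @param cat,an Lumped cation / anion concentrations, eq/L.
#' @param cst Chemistry constants.
#' @return Charge imbalance `Ch` in eq/L.
#' @export
charge_imbalance <- function(speciation, tm_mol = numeric(0), cat = 0, an = 0,
                             cst = chem_constants()) {
  m <- speciation$mol
  if (any(c(m, cat, an) < 0)) stop("negative ion concentration")
  ch <- m[["pro"]] + m[["bu"]] + m[["va"]] + m[["ac"]] - m[["NH4"]] +
    m[["HCO3"]] + 2 * m[["CO3"]] + m[["HSO4"]] + 2 * m[["SO4"]] +
    m[["HS"]] + 2 * m[["S2"]] + m[["H2PO4"]] + 2 * m[["HPO4"]] +
    3 * m[["PO4"]] + m[["NO2"]] + an - cat
  if (length(tm_mol)) {
    bad <- setdiff(names(tm_mol), tm_set())
    if (length(bad)) stop("unknown trace metal: ", paste(bad, collapse = ", "))
    if (any(tm_mol < 0)) stop("negative trace-metal concentration")
    ch <- ch + sum(cst$tm_charge[names(tm_mol)] * tm_mol)
  }
  unname(ch)
}

# Fast path: Ch from a (partial) state-named vector of g/L totals at a pH.
# Used by the initial-state construction, the pH solver and the RHS.
charge_imbalance_totals <- function(s, pH, cst) {
  sp <- speciate(pH, s[c("pro", "bu", "va", "ac", "Cio", "Nio", "Pio",
                         "Sio_id", "Sio_at", "NO2")], cst)
  tm_g <- s[paste0("TM_", tm_set())]
  tm_mol <- stats::setNames(as.numeric(tm_g) / cst$molar_mass[tm_set()],
                            tm_set())
  charge_imbalance(sp, tm_mol, cat = s[["Cat"]], an = s[["An"]], cst = cst)
}

#' Solve the charge balance for pH
#'
#' Finds the proton concentration such that
#' `[H+] - Kw/[H+] - Ch(pH) = target_Ch`, by safeguarded bisection followed
#' by Newton polishing; the left side is strictly decreasing in pH so the
#' root in `[0, 14]` is unique. The residual of the returned root is below
#' 1e-12 eq/L.
#'
#' @param totals Named g/L totals as in [speciate()].
#' @param tm_g Named trace-metal totals, g metal/L.
#' @param cat,an Lumped ion concentrations, eq/L.
#' @param target_Ch Target imbalance, eq/L (default 0: electroneutrality).
#' @param cst Chemistry constants.
#' @param tol Residual tolerance, eq/L.
#' @return The pH (numeric scalar) with attribute `residual`.
#' @export
solve_ph <- function(totals, tm_g = numeric(0), cat = 0, an = 0,
                     target_Ch = 0, cst = chem_constants(), tol = 1e-13) {
  s <- stats::setNames(numeric(80), state_names())
  totals <- unlist(totals)
  s[names(totals)] <- totals
  if (length(tm_g)) s[paste0("TM_", names(tm_g))] <- tm_g
  s["Cat"] <- cat
  s["An"] <- an
  fun <- function(pH) {
    H <- 10^(-pH)
    H - cst$Kw / H - charge_imbalance_totals(s, pH, cst) - target_Ch
  }
  f_lo <- fun(0)
  f_hi <- fun(14)
  if (f_lo < 0 || f_hi > 0) stop("no charge-balance root in pH [0, 14]")
  lo <- 0; hi <- 14
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    fm <- fun(mid)
    if (abs(fm) < tol) break
    if (fm > 0) lo <- mid else hi <- mid
  }
  pH <- (lo + hi) / 2
  # Newton polish on [H+]
  for (i in 1:8) {
    r <- fun(pH)
    if (abs(r) < tol) break
    h <- 1e-7
    dr <- (fun(pH + h) - r) / h
    step <- r / dr
    pH_new <- pH - step
    if (!is.finite(pH_new) || pH_new < 0 || pH_new > 14) break
    pH <- pH_new
  }
  attr(pH, "residual") <- fun(pH)
  pH
}
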