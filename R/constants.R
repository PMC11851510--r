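# Physico-chemical constants registry: acid-base equilibria, Henry constants,
# solubility products, molar masses, and the precipitate network topology.
# All values are literature-style defaults and are overridable; concentrations
# are handled on element-mass scales (g C/L, g N/L, g P/L, g S/L), trace
# metals as g metal/L, dissolved CH4/H2 as gas mass (g/L).

#' Trace metals considered by the model
#'
#' The thirteen metals that appear in the feedstock, the charge balance and
#' (for nine of them) the precipitation network.
#'
#' @return Character vector of length 13.
#' @export
tm_set <- function() {
  c("Ca", "Co", "Cu", "Cl", "Cr", "Fe", "K", "Mg", "Na", "Ni", "Pb", "Se", "Zn")
}

#' Precipitate species table
#'
#' The twenty mineral phases of the precipitation network, with the metal and
#' anion pool each one draws on and the stoichiometric weights used for
#' elemental bookkeeping (`nu_metal` = 3 and `nu_anion` = 2 for the
#' M3(PO4)2 phases, 1 otherwise; struvite and K-struvite additionally consume
#' one unit of ammonium-N and one unit of K respectively).
#'
#' @return A data.frame with one row per precipitate.
#' @export
precipitate_species <- function() {
  data.frame(
    name = c(
      "CaCO3", "CoCO3", "CuCO3", "FeCO3", "MgCO3", "NiCO3", "PbCO3", "ZnCO3",
      "FeS", "CoS", "CuS", "NiS", "PbS", "ZnS",
      "Ca3(PO4)2", "Co3(PO4)2", "Fe3(PO4)2", "Ni3(PO4)2",
      "MgNH4PO4", "KMgPO4"
    ),
    type = c(
      rep("carbonate", 8), rep("sulfide", 6), rep("phosphate", 4),
      "struvite", "kstruvite"
    ),
    metal = c(
      "Ca", "Co", "Cu", "Fe", "Mg", "Ni", "Pb", "Zn",
      "Fe", "Co", "Cu", "Ni", "Pb", "Zn",
      "Ca", "Co", "Fe", "Ni",
      "Mg", "Mg"
    ),
    nu_metal = c(rep(1, 14), rep(3, 4), 1, 1),
    nu_anion = c(rep(1, 14), rep(2, 4), 1, 1),
    stringsAsFactors = FALSE
  )
}

#' Default chemistry constants
#'
#' Acid dissociation constants (mol/L), the water ion product, Henry
#' constants on the model's tracked concentration scales (g/(L bar)),
#' solubility products for the twenty precipitates (on the g/L driving-force
#' scale of the precipitation kinetics), and molar masses (g/mol).
#'
#' `sulfide_species` selects which ionized sulfide pool drives sulfide
#' precipitation: `"HS_S2"` (default, HS- + S2-) or `"S2"` (free S2- only).
#'
#' @param overrides Optional named list; entries replace defaults (nested
#'   lists are merged one level deep).
#' @return A list of class `ad_constants`.
#' @export
chem_constants <- function(overrides = NULL) {
  cst <- list(
    Kw = 1e-14,
    # monoprotic VFAs (acid form <-> anion)
    Ka = list(
      ac  = 1.74e-5,  # acetic
      pro = 1.32e-5,  # propionic
      bu  = 1.51e-5,  # butyric
      va  = 1.38e-5,  # valeric
      NH4 = 5.62e-10, # ammonium
      CO2 = c(4.45e-7, 4.69e-11),           # carbonic Ka1, Ka2
      H2S = c(1.0e-7, 1.0e-13),             # sulfide Ka1, Ka2
      SO4 = 1.2e-2,                         # HSO4- <-> SO42-
      PO4 = c(7.1e-3, 6.3e-8, 4.5e-13),     # phosphoric Ka1..Ka3
      NO2 = 5.6e-4                          # nitrous
    ),
    # Henry constants, g of tracked species per (L bar):
    # CH4, H2 in gas mass; CO2 as g C; H2S as g S; NH3 as g N.
    # H2S/NH3 are effective values: together with the per-gas transfer
    # bounds they keep the dissolution feedback of the small headspace
    # non-stiff for the fixed-step explicit integrators (see the methods
    # vignette).
    KH = c(CH4 = 0.018, CO2 = 0.33, H2 = 0.0016, H2S = 1.0, NH3 = 2.0),
    molar_mass = c(
      ac = 60.05, pro = 74.08, bu = 88.11, va = 102.13,
      C = 12.011, N = 14.007, P = 30.974, S = 32.06, NO2 = 46.006,
      CH4 = 16.043, H2 = 2.016, CO2 = 44.009, H2S = 34.08, NH3 = 17.031,
      Ca = 40.078, Co = 58.933, Cu = 63.546, Cl = 35.453, Cr = 51.996,
      Fe = 55.845, K = 39.098, Mg = 24.305, Na = 22.990, Ni = 58.693,
      Pb = 207.2, Se = 78.971, Zn = 65.38
    ),
    # signed charge of each metal ion in the balance (by convention Cl
    # enters with +1 as an anion; Se as a divalent cation)
    tm_charge = c(
      Ca = -2, Co = -2, Cu = -2, Cl = +1, Cr = -2, Fe = -2, K = -1,
      Mg = -2, Na = -1, Ni = -2, Pb = -2, Se = -2, Zn = -2
    ),
    # solubility products on the driving-force scale of the rate laws
    Ksp = c(
      "CaCO3" = 1e-4, "CoCO3" = 5e-5, "CuCO3" = 2e-5, "FeCO3" = 5e-5,
      "MgCO3" = 4e-4, "NiCO3" = 5e-5, "PbCO3" = 2e-5, "ZnCO3" = 4e-5,
      "FeS" = 1e-10, "CoS" = 1e-10, "CuS" = 1e-12, "NiS" = 1e-10,
      "PbS" = 1e-12, "ZnS" = 1e-11,
      "Ca3(PO4)2" = 1e-10, "Co3(PO4)2" = 1e-11, "Fe3(PO4)2" = 1e-11,
      "Ni3(PO4)2" = 1e-11,
      "MgNH4PO4" = 1e-7, "KMgPO4" = 1e-7
    ),
    sulfide_species = "HS_S2",
    R_bar = 0.0831446  # L bar / (mol K)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (nm in names(overrides)) {
      if (is.list(cst[[nm]]) && is.list(overrides[[nm]])) {
        for (k in names(overrides[[nm]])) cst[[nm]][[k]] <- overrides[[nm]][[k]]
      } else if (!is.null(names(cst[[nm]])) && !is.null(names(overrides[[nm]])) &&
                 length(overrides[[nm]]) < length(cst[[nm]])) {
        cst[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
      } else {
        cst[[nm]] <- overrides[[nm]]
      }
    }
  }
  stopifnot(all(cst$Ksp > 0), length(cst$Ksp) == 20L)
  class(cst) <- "ad_constants"
  cst
}

#' Write / read the constants registry as YAML
#'
#' Round-trips bit-exactly for the numeric content (values are serialized at
#' full double precision).
#'
#' @param cst An `ad_constants` list.
#' @param path File path.
#' @return `read_constants` returns an `ad_constants` list.
#' @export
write_constants <- function(cst, path) {
  # named atomic vectors serialize as YAML maps so names survive round-trip
  ser <- lapply(unclass(cst), function(x) {
    if (!is.list(x) && !is.null(names(x))) as.list(x) else x
  })
  txt <- yaml::as.yaml(ser, precision = 17L)
  atomic_write(txt, path)
  invisible(path)
}

#' @rdname write_constants
#' @export
read_constants <- function(path) {
  raw <- yaml::read_yaml(path)
  base <- chem_constants()
  for (nm in names(raw)) {
    v <- raw[[nm]]
    if (!is.null(names(base[[nm]])) && !is.list(base[[nm]])) {
      v <- unlist(v)
    } else if (nm == "Ka") {
      v <- lapply(v, unlist)
    }
    base[[nm]] <- v
  }
  class(base) <- "ad_constants"
  base
}

# write-temp-then-rename so interrupted runs never leave corrupt artifacts
atomic_write <- function(txt, path) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(txt, tmp)
  file.rename(tmp, path)
}
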