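# Assembly of the full 80-state right-hand side. A model context is built
# once per simulation: it unpacks parameters, precomputes temperature
# factors and transfer coefficients (T is constant in a batch), assembles
# the stoichiometric mapping matrices, and compiles the hot path into a
# closure over local bindings so evaluation is pure vector arithmetic.

# fixed state layout (validated against state_names() at context build)
.I <- list(
  X = 1:13, E = 14:16, ch = 17L, pr = 18L, li = 19L, inert = 20L,
  su = 21L, aa = 22L, gly = 23L, oa = 24L,
  pro = 25L, bu = 26L, va = 27L, ac = 28L,
  Cio = 29L, Nio = 30L, Pio = 31L, Sio_id = 32L, Sio_at = 33L, NO2 = 34L,
  H2 = 35L, CH4 = 36L, Hplus = 37L, Cat = 38L, An = 39L,
  TM = 40:52, P = 53:72, G = 73:77,
  Vb = 78L, Vch4 = 79L, Vh2s = 80L
)

# builds the compiled right-hand-side closure; all model constants live as
# locals of this function's frame
.make_rhs <- function(params, config, stoich, cst, ph_mode) {
  M <- cst$molar_mass
  # equilibrium constants as scalars
  ka_pro <- cst$Ka$pro; ka_bu <- cst$Ka$bu; ka_va <- cst$Ka$va
  ka_ac <- cst$Ka$ac; ka_nh4 <- cst$Ka$NH4
  ka_c1 <- cst$Ka$CO2[1]; ka_c12 <- cst$Ka$CO2[1] * cst$Ka$CO2[2]
  ka_s1 <- cst$Ka$H2S[1]; ka_s12 <- cst$Ka$H2S[1] * cst$Ka$H2S[2]
  ka_so4 <- cst$Ka$SO4
  ka_p1 <- cst$Ka$PO4[1]; ka_p12 <- ka_p1 * cst$Ka$PO4[2]
  ka_p123 <- prod(cst$Ka$PO4)
  ka_no2 <- cst$Ka$NO2
  Mpro <- M[["pro"]]; Mbu <- M[["bu"]]; Mva <- M[["va"]]; Mac <- M[["ac"]]
  MC <- M[["C"]]; MN <- M[["N"]]; MP <- M[["P"]]; MS <- M[["S"]]
  MNO2 <- M[["NO2"]]
  Kw <- cst$Kw
  RT <- cst$R_bar * (config$T_C + 273.15)
  V_gas <- config$V_gas; V_liq <- config$V_liq; p_total <- config$p_total
  sulfide_HS <- !identical(cst$sulfide_species, "S2")
  resolve_ph <- identical(ph_mode, "resolve")

  # fractions + signed eq/g of the ten speciating pools as a flat 19-vector:
  # 1 f_CO2, 2 f_HCO3, 3 f_CO3, 4 f_H2S, 5 f_HS, 6 f_S2, 7 f_NH4, 8 f_NH3,
  # 9 f_PO4, 10:19 eq/g of pro bu va ac Cio Nio Pio Sio_id Sio_at NO2
  spec_fast <- function(H) {
    Dc <- H * H + H * ka_c1 + ka_c12
    f_CO2 <- H * H / Dc; f_HCO3 <- H * ka_c1 / Dc; f_CO3 <- ka_c12 / Dc
    Ds <- H * H + H * ka_s1 + ka_s12
    f_H2S <- H * H / Ds; f_HS <- H * ka_s1 / Ds; f_S2 <- ka_s12 / Ds
    f_SO4 <- ka_so4 / (ka_so4 + H)
    Dp <- H * H * H + H * H * ka_p1 + H * ka_p12 + ka_p123
    f_H2PO4 <- H * H * ka_p1 / Dp; f_HPO4 <- H * ka_p12 / Dp
    f_PO4 <- ka_p123 / Dp
    f_NH4 <- H / (H + ka_nh4)
    c(f_CO2, f_HCO3, f_CO3, f_H2S, f_HS, f_S2, f_NH4, 1 - f_NH4, f_PO4,
      ka_pro / ((ka_pro + H) * Mpro), ka_bu / ((ka_bu + H) * Mbu),
      ka_va / ((ka_va + H) * Mva), ka_ac / ((ka_ac + H) * Mac),
      (f_HCO3 + 2 * f_CO3) / MC, -f_NH4 / MN,
      (f_H2PO4 + 2 * f_HPO4 + 3 * f_PO4) / MP,
      (f_HS + 2 * f_S2) / MS, (1 + f_SO4) / MS, ka_no2 / ((ka_no2 + H) * MNO2))
  }

  # constant-in-T prefactors
  mu_T <- unname(temperature_factor(config$T_C, params$mu_max_Topt,
                                    params$alpha, params$T_opt,
                                    params$T_max))
  kla <- pmax(0, unname(params$KLa_a * config$T_C + params$KLa_b))
  KH <- unname(cst$KH[c("CH4", "CO2", "H2", "H2S", "NH3")])
  gasM <- c(M[["CH4"]], M[["C"]], M[["H2"]], M[["S"]], M[["N"]])

  # Monod bookkeeping (order = microbial_groups())
  sub1 <- c(.I$su, .I$aa, .I$gly, .I$oa, .I$pro, .I$bu, .I$va, .I$ac,
            .I$H2, .I$Sio_at, .I$pro, .I$ac, .I$H2)
  km1 <- unname(params$k_M[c("kM_su_Asu", "kM_aa_Aaa", "kM_gly_Agly",
                             "kM_oa_Aoa", "kM_pro_Apro", "kM_bu_Abu",
                             "kM_va_Ava", "kM_ac_Mac", "kM_H2_Mhyd",
                             "kM_Sat_Ss", "kM_pro_Spro", "kM_ac_Sac",
                             "kM_H2_Shyd")])
  g2i <- c(11L, 12L, 13L)
  km2 <- unname(params$k_M[c("kM_Sat_Spro", "kM_Sat_Sac", "kM_Sat_Shyd")])

  pK_lo <- unname(params$pK_lo); pK_up <- unname(params$pK_up)
  ph_num <- 1 + 2 * 10^(0.5 * (pK_lo - pK_up))
  KN <- params$K_M_nutrient[["K_M_Nio"]]
  KP <- params$K_M_nutrient[["K_M_Pio"]]

  # inhibition pairings; inhibitor order: H2, H2S, NH3, Cu, Zn, Cr, Pb, Ni
  inames <- c("H2", "H2S", "NH3", "Cu", "Zn", "Cr", "Pb", "Ni")
  inh_g <- integer(0); inh_i <- integer(0); inh_K <- numeric(0)
  for (g in names(.growth_inhibition_map)) {
    im <- .growth_inhibition_map[[g]]
    for (j in seq_along(im)) {
      inh_g <- c(inh_g, match(g, microbial_groups()))
      inh_i <- c(inh_i, match(names(im)[j], inames))
      inh_K <- c(inh_K, params$K_inh[[im[[j]]]])
    }
  }
  stopifnot(length(inh_g) == 25L)
  Kinh_VFA <- params$K_inh[["Kinh_VFA"]]
  k_hyd <- unname(params$k_hyd); K_ME0 <- unname(params$K_ME0)
  b_dec <- unname(params$b_dec)
  dec_mu <- b_dec * mu_T
  df_ch <- stoich$decay_fractions[["ch"]]
  df_pr <- stoich$decay_fractions[["pr"]]
  df_li <- stoich$decay_fractions[["li"]]
  hyd_gly <- unname(stoich$hydrolysis$li["gly"])
  hyd_oa <- unname(stoich$hydrolysis$li["oa"])

  # growth stoichiometry matrix: ds += Sm %*% uptake
  Sm <- matrix(0, 80, 13)
  vrow <- c(ac = .I$ac, pro = .I$pro, bu = .I$bu, va = .I$va,
            H2 = .I$H2, CH4 = .I$CH4)
  Yv <- numeric(13)
  for (j in seq_len(13)) {
    gr <- stoich$groups[[microbial_groups()[j]]]
    Yv[j] <- gr$Y
    si <- match(gr$sub, state_names())
    Sm[si, j] <- Sm[si, j] - 1
    Sm[j, j] <- Sm[j, j] + gr$Y
    for (pn in names(gr$products)) {
      f <- gr$products[[pn]]
      if (pn %in% names(vrow)) {
        Sm[vrow[[pn]], j] <- Sm[vrow[[pn]], j] + f
      } else if (pn == "CO2") {
        Sm[.I$Cio, j] <- Sm[.I$Cio, j] + f * MC / M[["CO2"]]
      } else if (pn == "NH3") {
        Sm[.I$Nio, j] <- Sm[.I$Nio, j] + f * MN / M[["NH3"]]
      } else if (pn == "Sid") {
        Sm[.I$Sio_id, j] <- Sm[.I$Sio_id, j] + f
      } else stop("unknown stoichiometric product: ", pn)
    }
    if (gr$s_conv > 0) {
      Sm[.I$Sio_at, j] <- Sm[.I$Sio_at, j] - gr$s_conv
      Sm[.I$Sio_id, j] <- Sm[.I$Sio_id, j] + gr$s_conv
    }
    Sm[.I$Nio, j] <- Sm[.I$Nio, j] - stoich$biomass_N * gr$Y
    Sm[.I$Pio, j] <- Sm[.I$Pio, j] - stoich$biomass_P * gr$Y
  }
  uptY <- 1 / Yv

  # precipitation bookkeeping
  pt <- precipitate_species()
  prec_metal <- .I$TM[match(pt$metal, tm_set())]
  prec_k <- unname(params$k_cryst[pt$name])
  root <- c(carbonate = 2, sulfide = 2, phosphate = 5, struvite = 3,
            kstruvite = 3)[pt$type]
  prec_Kr <- unname(cst$Ksp[pt$name]^(1 / root))
  i_carb <- which(pt$type == "carbonate")
  i_sulf <- which(pt$type == "sulfide")
  i_phos <- which(pt$type == "phosphate")
  i_str <- which(pt$type == "struvite")
  i_kstr <- which(pt$type == "kstruvite")
  mi_carb <- prec_metal[i_carb]; k_carb <- prec_k[i_carb]
  Kr_carb <- prec_Kr[i_carb]
  mi_sulf <- prec_metal[i_sulf]; k_sulf <- prec_k[i_sulf]
  Kr_sulf <- prec_Kr[i_sulf]
  mi_phos <- prec_metal[i_phos]; k_phos <- prec_k[i_phos]
  Kr_phos <- prec_Kr[i_phos]
  k_str <- prec_k[i_str]; Kr_str <- prec_Kr[i_str]
  k_kstr <- prec_k[i_kstr]; Kr_kstr <- prec_Kr[i_kstr]
  Pm <- matrix(0, 80, 20)
  for (i in seq_len(20)) {
    Pm[.I$P[i], i] <- 1
    Pm[prec_metal[i], i] <- Pm[prec_metal[i], i] - pt$nu_metal[i]
    an_row <- switch(pt$type[i], carbonate = .I$Cio, sulfide = .I$Sio_id,
                     phosphate = .I$Pio, struvite = .I$Pio,
                     kstruvite = .I$Pio)
    Pm[an_row, i] <- Pm[an_row, i] - pt$nu_anion[i]
    if (pt$type[i] == "struvite") Pm[.I$Nio, i] <- -1
    if (pt$type[i] == "kstruvite") Pm[.I$TM[7], i] <- -1
  }

  tm_zM <- unname(cst$tm_charge[tm_set()] / M[tm_set()])
  pool_idx <- c(.I$pro, .I$bu, .I$va, .I$ac, .I$Cio, .I$Nio, .I$Pio,
                .I$Sio_id, .I$Sio_at, .I$NO2)
  iTM <- .I$TM; iG <- .I$G; iX <- .I$X; iE <- .I$E
  i_part <- c(.I$ch, .I$pr, .I$li)
  liq_rows <- c(.I$CH4, .I$Cio, .I$H2, .I$Sio_id, .I$Nio)
  gas_names <- c("CH4", "CO2", "H2", "H2S", "NH3")

  pH_last <- config$pH_init

  ch_from_spec <- function(s, sp) {
    sum(sp[10:19] * s[pool_idx]) + sum(tm_zM * s[iTM]) + s[39L] - s[38L]
  }

  # NOTE: the state passed in is assumed non-negative (the stepper clips
  # after every accepted step and before every RK stage)
  function(s, diagnostics = FALSE) {
    # pH
    if (resolve_ph) {
      pH <- pH_last
      for (it in 1:40) {
        H <- 10^(-pH)
        sp <- spec_fast(H)
        r <- H - Kw / H - ch_from_spec(s, sp)
        if (abs(r) < 1e-12) break
        H2_ <- 10^(-(pH + 1e-5))
        r2 <- H2_ - Kw / H2_ - ch_from_spec(s, spec_fast(H2_))
        stp <- r / ((r2 - r) / 1e-5)
        if (!is.finite(stp)) break
        if (stp > 1) stp <- 1 else if (stp < -1) stp <- -1
        pH <- pH - stp
        if (pH < 0) pH <- 0.5 else if (pH > 14) pH <- 13.5
      }
      pH_last <<- pH
    } else {
      pH <- -log10(max(s[37L], 1e-14))
    }
    H <- 10^(-pH)
    sp <- spec_fast(H)

    ds <- numeric(80)
    # hydrolysis
    vfa <- s[25L] + s[26L] + s[27L] + s[28L]
    vinh <- Kinh_VFA / (Kinh_VFA + vfa)
    cpart <- s[i_part]
    r_h <- k_hyd * cpart * s[iE] / (K_ME0 + cpart) * vinh
    ds[i_part] <- -r_h
    ds[21L] <- r_h[1]
    ds[22L] <- r_h[2]
    ds[23L] <- hyd_gly * r_h[3]
    ds[24L] <- hyd_oa * r_h[3]

    # growth
    c1 <- s[sub1]
    mu <- mu_T * c1 / (km1 + c1)
    cS <- s[33L]
    mu[g2i] <- mu[g2i] * cS / (km2 + cS)
    mu <- mu * ph_num / (1 + 10^(pH - pK_up) + 10^(pK_lo - pH))
    cN <- s[30L]; cP <- s[31L]
    mu <- mu * (cN / (KN + cN)) * (cP / (KP + cP))
    ci <- c(s[35L], s[32L] * sp[4], cN * sp[8],
            s[42L], s[52L], s[44L], s[50L], s[49L])
    fac <- inh_K / (inh_K + ci[inh_i])
    for (k in 1:25) mu[inh_g[k]] <- mu[inh_g[k]] * fac[k]
    cC <- s[29L]; cAc <- s[28L]
    mu[9L] <- mu[9L] * cC / (1e-3 + cC)    # Mhyd draws on inorganic carbon
    mu[10L] <- mu[10L] * cAc / (1e-3 + cAc) # Ss draws on acetate

    X <- s[iX]
    upt <- mu * X * uptY
    ds <- ds + drop(Sm %*% upt)

    # decay, recycled to particulates
    dec <- dec_mu * X
    ds[iX] <- ds[iX] - dec
    dtot <- sum(dec)
    ds[17L] <- ds[17L] + df_ch * dtot
    ds[18L] <- ds[18L] + df_pr * dtot
    ds[19L] <- ds[19L] + df_li * dtot

    # gas transfer and headspace balance
    n <- s[iG]
    n_tot <- sum(n)
    p <- n * (RT / V_gas)
    cfree <- c(s[36L], cC * sp[1], s[35L], s[32L] * sp[4], cN * sp[8])
    tr <- kla * (cfree - KH * p)
    ds[liq_rows] <- ds[liq_rows] - tr
    ndot_in <- tr * (V_liq / gasM)
    at_p <- n_tot * RT / V_gas >= p_total * (1 - 1e-12)
    Q_mol <- if (at_p) max(0, sum(ndot_in)) else 0
    y <- if (n_tot > 0) n / n_tot else numeric(5)
    ds[iG] <- ndot_in - Q_mol * y
    Q <- Q_mol * RT / p_total
    ds[78L] <- Q
    ds[79L] <- Q * y[1]
    ds[80L] <- Q * y[4]

    # precipitation
    co3 <- cC * sp[3]
    ssulf <- s[32L] * (if (sulfide_HS) sp[5] + sp[6] else sp[6])
    po4 <- cP * sp[9]
    nh4 <- cN * sp[7]
    rp <- numeric(20)
    d <- sqrt(s[mi_carb] * co3) - Kr_carb
    d[d < 0] <- 0
    rp[i_carb] <- k_carb * d * d
    d <- sqrt(s[mi_sulf] * ssulf) - Kr_sulf
    d[d < 0] <- 0
    rp[i_sulf] <- k_sulf * d * d
    d <- (s[mi_phos]^3 * po4 * po4)^0.2 - Kr_phos
    d[d < 0] <- 0
    rp[i_phos] <- k_phos * d * d
    cmg <- s[47L]; ck <- s[46L]
    d <- max(0, (cmg * nh4 * po4)^(1 / 3) - Kr_str)
    rp[i_str] <- k_str * d * d
    d <- max(0, (ck * cmg * po4)^(1 / 3) - Kr_kstr)
    rp[i_kstr] <- k_kstr * d * d
    ds <- ds + drop(Pm %*% rp)

    # proton ODE by the chain rule
    dCh <- sum(sp[10:19] * ds[pool_idx]) + sum(tm_zM * ds[iTM]) +
      ds[39L] - ds[38L]
    Hb <- 10^(-(pH + 1e-5))
    spb <- spec_fast(Hb)
    dChdH <- (sum(spb[10:19] * s[pool_idx]) - sum(sp[10:19] * s[pool_idx])) /
      (Hb - H)
    ds[37L] <- dCh / (1 + Kw / (H * H) - dChdH)

    if (!all(is.finite(ds))) {
      bad <- which(!is.finite(ds))[1]
      stop("non-finite derivative in state '", state_names()[bad],
           "'; state dump: ",
           paste(sprintf("%s=%.4g", state_names(), s), collapse = ", "))
    }
    if (diagnostics) {
      return(list(ds = ds, pH = pH, Ch = ch_from_spec(s, sp),
                  Q_biogas = Q, Q_CH4 = Q * y[1],
                  p = stats::setNames(p, gas_names),
                  y = stats::setNames(y, gas_names), mu = mu))
    }
    ds
  }
}

#' Build a model evaluation context
#'
#' Precomputes everything that is constant along a batch trajectory
#' (unpacked parameters, temperature factors, transfer coefficients,
#' stoichiometric mapping matrices, cached equilibrium constants) and
#' compiles the right-hand side into a closure.
#'
#' @param params An `ad_parameters` object.
#' @param config An `ad_bioreactor` object.
#' @param stoich An `ad_stoichiometry` table.
#' @param cst Chemistry constants.
#' @param ph_mode `"resolve"` (default): the charge balance is re-solved for
#'   pH at every evaluation, warm-started; `"ode"`: the pH is read from the
#'   integrated proton state (the chain-rule form of the proton ODE).
#' @return An environment of class `ad_context` with the compiled `$rhs`.
#' @export
build_model_context <- function(params, config,
                                stoich = default_stoichiometry(),
                                cst = chem_constants(),
                                ph_mode = c("resolve", "ode")) {
  ph_mode <- match.arg(ph_mode)
  validate_parameters(params, bounds = NULL)
  check_stoichiometry(stoich)
  stopifnot(identical(state_names()[.I$Hplus], "Hplus"),
            identical(state_names()[.I$TM[1]], "TM_Ca"),
            identical(state_names()[.I$TM[7]], "TM_K"),
            identical(state_names()[.I$P[1]], "P_CaCO3"),
            identical(state_names()[.I$G[1]], "G_CH4"))
  e <- new.env(parent = emptyenv())
  e$params <- params; e$config <- config; e$stoich <- stoich; e$cst <- cst
  e$ph_mode <- ph_mode
  e$rhs <- .make_rhs(params, config, stoich, cst, ph_mode)
  class(e) <- c("ad_context", "environment")
  e
}

# thin wrapper kept for internal call sites
ad_rhs_core <- function(s, ctx, diagnostics = FALSE) {
  ctx$rhs(s, diagnostics)
}

#' Evaluate the assembled right-hand side
#'
#' Combines hydrolysis, growth and decay of the 13 microbial groups, gas
#' transfer, the headspace balance, the precipitation network and the
#' chain-rule proton ODE into one 80-entry derivative. Batch mode: no liquid
#' throughflow, and inert matter has derivative zero.
#'
#' @param state Named 80-entry state vector.
#' @param params An `ad_parameters` object.
#' @param config An `ad_bioreactor` object.
#' @param stoich Stoichiometry table.
#' @param cst Chemistry constants.
#' @param ph_mode See [build_model_context()].
#' @return Named numeric vector of derivatives (per day).
#' @export
assemble_rhs <- function(state, params, config,
                         stoich = default_stoichiometry(),
                         cst = chem_constants(), ph_mode = "resolve") {
  ctx <- build_model_context(params, config, stoich, cst, ph_mode)
  s <- pmax(as.numeric(state[state_names()]), 0)
  stats::setNames(ctx$rhs(s), state_names())
}
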