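test_that("hydrolysis rate follows the enzymatic Michaelis-Menten form", {
  expect_equal(hydrolysis_rate(10, 1, 0, k_hyd = 1, K_ME0 = 10,
                               K_inh_VFA = 5), 0.5)
  expect_equal(hydrolysis_rate(0, 1, 0, 1, 10, 5), 0)
  expect_equal(hydrolysis_rate(10, 0, 0, 1, 10, 5), 0)
  # VFA at K_inh halves the rate
  expect_equal(hydrolysis_rate(10, 1, 5, 1, 10, 5), 0.25)
  expect_error(hydrolysis_rate(-1, 1, 0, 1, 10, 5), "negative")
})

test_that("Michaelis pH factor: closed form, symmetry, tails", {
  expect_equal(michaelis_ph_factor(7, 6, 8), 1.2 / 1.2)
  mid <- (5.5 + 8.5) / 2
  for (d in c(0.3, 1, 2)) {
    expect_equal(michaelis_ph_factor(mid + d, 5.5, 8.5),
                 michaelis_ph_factor(mid - d, 5.5, 8.5))
  }
  expect_lt(michaelis_ph_factor(0.5, 6, 8), 1e-4)
  expect_lt(michaelis_ph_factor(13.5, 6, 8), 1e-4)
  expect_error(michaelis_ph_factor(7, 8, 6), "pK_lo")
})

test_that("temperature law is a linear tent with hard cutoff", {
  expect_equal(temperature_factor(35, 0.4, 0.02, 35, 60), 0.4)
  expect_equal(temperature_factor(30, 0.4, 0.02, 35, 60), 0.3)
  expect_equal(temperature_factor(40, 0.4, 0.02, 35, 60), 0.3)
  expect_equal(temperature_factor(60, 0.4, 0.02, 35, 60), 0)
  expect_equal(temperature_factor(80, 0.4, 0.02, 35, 60), 0)
  expect_error(temperature_factor(35, 0.4, 0.02, 60, 35), "T_opt")
})

test_that("growth rate composes Monod, pH, nutrient and inhibition factors", {
  p <- midpoint_parameters()
  # Asu carries no inhibition terms: saturating substrate and nutrients at
  # the pH/temperature optimum recover the maximal rate exactly
  s <- state_with(su = 1e5, Nio = 1e5, Pio = 1e5)
  pH_opt <- (p$pK_lo[["Asu"]] + p$pK_up[["Asu"]]) / 2
  mu <- growth_rate("Asu", s, p, pH_opt, p$T_opt[["Asu"]])
  expect_equal(mu, p$mu_max_Topt[["Asu"]], tolerance = 1e-3)
  # limiting substrate zero
  expect_equal(growth_rate("Asu", state_with(Nio = 1, Pio = 1), p, 7, 35), 0)
  # a single added inhibitor at its constant halves the rate (Zn on Mac)
  s_mac <- state_with(ac = 1e3, Nio = 5, Pio = 1e3)
  pH_m <- (p$pK_lo[["Mac"]] + p$pK_up[["Mac"]]) / 2
  mu_m <- growth_rate("Mac", s_mac, p, pH_m, p$T_opt[["Mac"]])
  expect_gt(mu_m, 0)
  s_zn <- s_mac
  s_zn["TM_Zn"] <- p$K_inh[["Kinh_Zn_Mac"]]
  expect_equal(growth_rate("Mac", s_zn, p, pH_m, p$T_opt[["Mac"]]) / mu_m,
               0.5, tolerance = 1e-9)
  expect_error(growth_rate("Nope", s, p, 7, 35), "unknown")
})

test_that("gas transfer: equilibrium, linear coefficient, stripping", {
  expect_equal(gas_transfer_rate("CH4", c_liq = 0.0018, p_gas = 0.1,
                                 T_C = 35, KLa_a = 0.1, KLa_b = 1,
                                 K_H = 0.018), 0)
  # overall coefficient 0.1*35 + 1 = 4.5/day
  expect_equal(gas_transfer_rate("CH4", 1, 0, 35, 0.1, 1, 0.018), 4.5)
  expect_gt(gas_transfer_rate("H2", 0.01, 0, 35, 0.1, 1, 0.0016), 0)
  expect_error(gas_transfer_rate("H2", 0.01, 0, 35, -1, 1, 0.0016),
               "negative transfer")
  expect_error(gas_transfer_rate("H2", -0.01, 0, 35, 0.1, 1, 0.0016),
               "negative input")
})

test_that("headspace balance keeps total pressure and normalizes outflow", {
  cfg <- b1_bioreactor(10)
  cst <- chem_constants()
  n_tot <- cfg$p_total * cfg$V_gas / (cst$R_bar * (cfg$T_C + 273.15))
  s <- state_with(G_CH4 = 0.3 * n_tot, G_CO2 = 0.7 * n_tot)
  # zero transfer -> no outflow
  z <- gas_phase_balance(s, cfg, c(CH4 = 0, CO2 = 0, H2 = 0, H2S = 0,
                                   NH3 = 0))
  expect_equal(z$Q_biogas, 0)
  expect_equal(sum(z$p), cfg$p_total, tolerance = 1e-12)
  # with transfer, expelled fractions sum to 1 and total moles are constant
  tr <- c(CH4 = 0.05, CO2 = 0.02, H2 = 0.001, H2S = 0.0005, NH3 = 0.0002)
  g <- gas_phase_balance(s, cfg, tr)
  expect_gt(g$Q_biogas, 0)
  expect_equal(sum(g$y), 1)
  expect_equal(sum(g$dGas), sum(tr * cfg$V_liq /
    cst$molar_mass[c("CH4", "C", "H2", "S", "N")]) - g$Q_biogas *
    cfg$p_total / (cst$R_bar * (cfg$T_C + 273.15)), tolerance = 1e-12)
  expect_equal(sum(g$dGas), 0, tolerance = 1e-12)
  # single-gas headspace at steady transfer: outflow = volumetric inflow
  s1 <- state_with(G_CH4 = n_tot)
  tr1 <- c(CH4 = 0.05, CO2 = 0, H2 = 0, H2S = 0, NH3 = 0)
  g1 <- gas_phase_balance(s1, cfg, tr1)
  q_oracle <- 0.05 * cfg$V_liq / cst$molar_mass[["CH4"]] *
    cst$R_bar * (cfg$T_C + 273.15) / cfg$p_total
  expect_equal(g1$Q_biogas, unname(q_oracle))
  expect_equal(unname(g1$dGas["CH4"]), 0, tolerance = 1e-15)
  expect_warning(gas_phase_balance(state_with(), cfg, tr), "empty headspace")
})
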