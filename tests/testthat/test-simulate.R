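test_that("sterile reactor produces nothing and inerts never degrade", {
  p <- midpoint_parameters()
  v <- params_to_vector(p)
  v[grep("^(X_init|cE0)_", names(v))] <- 0
  p0 <- params_from_vector(v, validate = FALSE)
  sim <- simulate_ad(p0, toy_reactor(6), b1_feedstock(), dt = toy_dt,
                     method = "euler")
  last <- sim$state[nrow(sim$state), ]
  expect_equal(unname(last["ch"]), 15, tolerance = 1e-9)
  expect_equal(unname(last["su"]), 0)
  expect_equal(unname(last["CH4_liq"]), 0)
  expect_equal(sim$volumes[["V_CH4"]], 0)
  # inert matter is non-degradable in any simulation
  sim2 <- toy_sim(t_total = 6)
  expect_true(all(abs(sim2$state[, "inert"] - 50) < 1e-9))
})

test_that("trajectories are non-negative with monotone cumulative volumes", {
  sim <- toy_sim(t_total = 12)
  expect_true(all(sim$state >= 0))
  for (vc in c("V_biogas", "V_CH4", "V_H2S")) {
    expect_true(all(diff(sim$state[, vc]) >= -1e-12))
  }
  expect_true(all(sim$Q_biogas >= 0))
  # gas mole fractions sum to one at every saved time
  expect_true(all(abs(rowSums(sim$y) - 1) < 1e-9))
})

test_that("gas closure: partial pressures sum to p_total whenever Q > 0", {
  sim <- toy_sim(t_total = 12)
  on_flow <- sim$Q_biogas > 1e-12
  expect_true(any(on_flow))
  expect_lt(max(abs(rowSums(sim$p)[on_flow] - sim$config$p_total)), 1e-9)
})

test_that("elemental conservation across ionic and precipitate pools", {
  sim <- simulate_ad(midpoint_parameters(), b1_bioreactor(60),
                     b1_feedstock(), dt = 0.02, method = "euler")
  S <- sim$state
  pt <- precipitate_species()
  for (m in c("Ca", "Co", "Cu", "Fe", "K", "Mg", "Ni", "Pb", "Zn")) {
    tot <- S[, paste0("TM_", m)]
    for (i in seq_len(nrow(pt))) {
      if (pt$metal[i] == m) {
        tot <- tot + pt$nu_metal[i] * S[, paste0("P_", pt$name[i])]
      }
    }
    if (m == "K") tot <- tot + S[, "P_KMgPO4"]
    expect_lt(max(abs(tot - tot[1])) / max(tot[1], 1e-12), 1e-8,
              label = paste("conservation of", m))
  }
})

test_that("chemistry-only closed system conserves S, C, P and N pools", {
  # switch off biology and gas transfer: precipitation is the only process
  v <- params_to_vector(midpoint_parameters())
  v[grep("^(X_init|cE0)_", names(v))] <- 0
  v[grep("^KLa_", names(v))] <- 0
  p0 <- params_from_vector(v, validate = FALSE)
  sim <- simulate_ad(p0, toy_reactor(6), b1_feedstock(), dt = toy_dt,
                     method = "euler")
  S <- sim$state
  pt <- precipitate_species()
  pool <- function(anion_of, col) {
    tot <- S[, col]
    for (i in seq_len(nrow(pt))) {
      if (pt$type[i] %in% anion_of) {
        tot <- tot + pt$nu_anion[i] * S[, paste0("P_", pt$name[i])]
      }
    }
    tot
  }
  tot_S <- pool("sulfide", "Sio_id") + S[, "Sio_at"]
  tot_C <- pool("carbonate", "Cio")
  tot_P <- pool(c("phosphate", "struvite", "kstruvite"), "Pio")
  tot_N <- S[, "Nio"] + S[, "P_MgNH4PO4"]
  for (tot in list(tot_S, tot_C, tot_P, tot_N)) {
    expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-8)
  }
})

test_that("Euler and RK4 agree on the methane flow under step refinement", {
  p <- midpoint_parameters()
  cfg <- toy_reactor(10)
  feed <- b1_feedstock()
  se <- simulate_ad(p, cfg, feed, dt = 0.00625, method = "euler",
                    save_dt = 0.25)
  sr <- simulate_ad(p, cfg, feed, dt = 0.025, method = "rk4",
                    save_dt = 0.25)
  expect_equal(se$time, sr$time)
  # compare after the biogas onset (the onset time itself moves by a step)
  post <- se$time >= 5
  scale <- max(sr$Q_CH4)
  expect_lt(max(abs(se$Q_CH4[post] - sr$Q_CH4[post])) / scale, 0.01)
  expect_lt(abs(se$volumes[["V_CH4"]] - sr$volumes[["V_CH4"]]) /
              sr$volumes[["V_CH4"]], 0.05)
})

test_that("the ODE is autonomous: extending the horizon preserves the past", {
  p <- midpoint_parameters()
  s1 <- simulate_ad(p, toy_reactor(6), b1_feedstock(), dt = toy_dt,
                    method = "euler", save_dt = 0.5)
  s2 <- simulate_ad(p, toy_reactor(12), b1_feedstock(), dt = toy_dt,
                    method = "euler", save_dt = 0.5)
  n <- length(s1$time)
  expect_equal(s2$time[seq_len(n)], s1$time)
  expect_equal(s2$state[seq_len(n), ], s1$state, tolerance = 1e-12)
})

test_that("one-group reduction matches an independent reference integrator", {
  skip_if_not_installed("deSolve")
  p <- one_group_params()
  st <- default_stoichiometry()
  gr <- st$groups$Asu
  # independent reduced model: hydrolysis of ch by E_ch, growth of Asu on
  # su, product accumulation, decay recycle, nutrient drawdown
  oracle_rhs <- function(t, x, parms) {
    with(as.list(c(x, parms)), {
      vfa <- ac + pro + bu
      rh <- k_hyd * ch * E / (K_ME0 + ch) * Kv / (Kv + vfa)
      fpH <- (1 + 2 * 10^(0.5 * (1 - 13))) /
        (1 + 10^(pH - 13) + 10^(1 - pH))
      mu <- mu_max * su / (km + su) * fpH *
        Nio / (KN + Nio) * Pio / (KP + Pio)
      u <- mu * X / Y
      dec <- b_dec * mu_max * X
      list(c(ch = -rh + 0.35 * dec, E = 0, su = rh - u,
             X = Y * u - dec,
             ac = gr$products[["ac"]] * u, pro = gr$products[["pro"]] * u,
             bu = gr$products[["bu"]] * u,
             Nio = -0.08 * Y * u, Pio = -0.015 * Y * u))
    })
  }
  # the reduced run keeps pH near the initial value (chemistry off);
  # read it from the full simulation and hold it fixed in the oracle
  cfg <- toy_reactor(8)
  feed <- b1_feedstock()
  sim <- simulate_ad(p, cfg, feed, dt = 0.0025, method = "rk4",
                     save_dt = 0.5)
  parms <- c(k_hyd = unname(p$k_hyd[["ch"]]), K_ME0 = unname(p$K_ME0[["ch"]]),
             Kv = unname(p$K_inh[["Kinh_VFA"]]),
             mu_max = unname(p$mu_max_Topt[["Asu"]]),
             km = unname(p$k_M[["kM_su_Asu"]]), Y = gr$Y,
             b_dec = unname(p$b_dec[["Asu"]]),
             KN = unname(p$K_M_nutrient[["K_M_Nio"]]),
             KP = unname(p$K_M_nutrient[["K_M_Pio"]]),
             pH = mean(sim$pH))
  x0 <- c(ch = feed$ch, E = 0.1, su = 0, X = 0.1, ac = 0, pro = 0, bu = 0,
          Nio = feed$Nio, Pio = feed$Pio)
  ref <- deSolve::ode(x0, times = sim$time, func = oracle_rhs, parms = parms,
                      method = "lsoda", rtol = 1e-10, atol = 1e-12)
  for (col in c("X_Asu", "su", "ch", "ac")) {
    ocol <- c(X_Asu = "X", su = "su", ch = "ch", ac = "ac")[[col]]
    scale <- max(abs(ref[, ocol]), 1e-8)
    expect_lt(max(abs(sim$state[, col] - ref[, ocol])) / scale, 1e-3,
              label = paste("reference agreement for", col))
  }
})

test_that("integration reports instability instead of silently diverging", {
  expect_error(simulate_ad(midpoint_parameters(), toy_reactor(10),
                           b1_feedstock(), dt = 0.3, method = "euler"),
               "t_total/dt|unstable|smaller dt")
  expect_error(simulate_ad(midpoint_parameters(), toy_reactor(9),
                           b1_feedstock(), dt = 2, method = "euler"),
               "whole number|unstable|smaller")
})

test_that("simulation export writes tidy CSV and a JSON summary", {
  sim <- toy_sim(t_total = 6)
  f <- withr::local_tempfile(fileext = ".csv")
  j <- withr::local_tempfile(fileext = ".json")
  write_simulation_csv(sim, f, j)
  df <- read.csv(f, check.names = FALSE)
  expect_equal(nrow(df), length(sim$time))
  expect_true(all(c("time_day", "Q_CH4", "pH", "TM_Fe") %in% names(df)))
  summ <- jsonlite::read_json(j)
  expect_equal(summ$volumes_L$V_CH4, sim$volumes[["V_CH4"]])
})
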