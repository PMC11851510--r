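test_that("measurement container validates its invariants", {
  m <- measurement_series(1:5, c(0.1, 0.4, 0.5, 0.3, 0.2))
  expect_equal(m$Q_mean, 0.3)
  expect_error(measurement_series(c(1, 1, 2), c(1, 2, 3)), "increasing")
  expect_error(measurement_series(1:3, c(1, -1, 2)), "non-negative")
  expect_error(measurement_series(1:3, c(0, 0, 0)), "positive")
})

test_that("deviation objective: zero at perfect fit, constant-offset value", {
  # fake simulation carrying a known flow curve
  fake_sim <- function(times, q) {
    structure(list(time = times, Q_CH4 = q, Q_biogas = q * 2,
                   volumes = c(V_biogas = 1, V_CH4 = 0.5, V_H2 = 0,
                               V_H2S = 0, V_NH3 = 0)),
              class = "ad_simulation")
  }
  tt <- 0:10
  meas <- measurement_series(1:10, rep(1, 10))
  expect_equal(g0_cal(fake_sim(tt, rep(1, 11)), meas), 0)
  # constant 10% offset: integrand 0.01 over 9 days
  expect_equal(g0_cal(fake_sim(tt, rep(1.1, 11)), meas), 0.01 * 9,
               tolerance = 1e-12)
  expect_equal(g0_cal(fake_sim(tt, rep(1.1, 11)), meas, psi0 = 3),
               3 * 0.01 * 9)
  expect_error(g0_cal(fake_sim(0:3, rep(1, 4)), meas), "cover")
})

test_that("statistical indicators: identities and hand-computed values", {
  s <- c(1, 2, 3); e <- c(1, 2, 4)
  si <- statistical_indicators(s, e)
  expect_equal(unname(si["MAE"]), 1 / 3, tolerance = 1e-4)
  expect_equal(unname(si["RMSE"]), sqrt(1 / 3), tolerance = 1e-4)
  expect_equal(unname(si["R2"]), 1 - 1 / (42 / 9), tolerance = 1e-4)
  ident <- statistical_indicators(e, e)
  expect_equal(unname(ident), c(0, 0, 1, 1))
  # RMSE >= MAE for arbitrary series
  set.seed(3)
  for (i in 1:20) {
    a <- runif(10); b <- runif(10) + 0.1
    si <- statistical_indicators(a, b)
    expect_gte(si[["RMSE"]], si[["MAE"]] - 1e-12)
    expect_lte(si[["R2"]], 1)
    expect_lte(si[["IA_rel"]], 1)
  }
  expect_error(statistical_indicators(1:3, c(2, 2, 2)), "SST")
  expect_error(statistical_indicators(1:3, c(0, 1, 2)), "IA_rel")
})

test_that("calibration constraints hit their stated boundary values", {
  cfg <- calibration_config()
  # all initial biomass at the cap -> g1 = 0
  p <- midpoint_parameters()
  p$X_init[] <- cfg$X_bac_max
  meas <- measurement_series(1:10, rep(1, 10))
  fake <- structure(list(
    time = 0:10, Q_CH4 = rep(1, 11), Q_biogas = rep(2, 11),
    volumes = c(V_biogas = 10, V_CH4 = 9,  # matches the measured volume
                V_H2 = 0.05, V_H2S = 10 * cfg$phi_H2S_max, V_NH3 = 0.05)),
    class = "ad_simulation")
  g <- calibration_constraints(fake, meas, p, cfg)
  expect_equal(unname(g["g1"]), 0)
  # flow inside the [k_LO, k_UP] envelope: g2, g3 at most the smoothing tail
  expect_lt(abs(g[["g2"]]), 0.05)
  expect_lt(abs(g[["g3"]]), 0.05)
  # H2S exactly at the allowed fraction -> g6 = 0
  expect_equal(unname(g["g6"]), 0)
  expect_error(calibration_constraints(
    structure(list(time = 0:10, Q_CH4 = rep(1, 11), Q_biogas = rep(1, 11),
                   volumes = c(V_biogas = 0, V_CH4 = 0, V_H2 = 0, V_H2S = 0,
                               V_NH3 = 0)), class = "ad_simulation"),
    meas, p, cfg), "V_biogas")
})

test_that("importance screening isolates the influential parameter", {
  # two-parameter toy: the functional depends only on parameter 1
  ev <- function(x) list(f = (x[1] - 0.2)^2 + 0.001 * sin(57 * x[1]),
                         g = numeric(0))
  imp <- importance_factors(ev, 2, n_designs = 400, seed = 11)
  expect_equal(imp$ranking[1], 1L)
  expect_equal(max(imp$fIM), 1)
  expect_lt(imp$fIM[2], 0.1)
  # constant functional -> all-zero with a warning
  expect_warning(i0 <- importance_factors(function(x) list(f = 1), 3,
                                          n_designs = 50, seed = 1),
                 "constant")
  expect_equal(i0$fIM, rep(0, 3))
  # reproducibility
  imp2 <- importance_factors(ev, 2, n_designs = 400, seed = 11)
  expect_identical(imp$fIM, imp2$fIM)
})

test_that("active-set schedule: nesting, skipping, warm-start monotonicity", {
  # cheap synthetic evaluator standing in for the full model: quadratic
  # with two influential coordinates out of six
  bounds <- data.frame(name = paste0("p", 1:6), group = "g",
                       lo = rep(0, 6), up = rep(1, 6))
  target <- c(0.3, 0.7, 0.5, 0.5, 0.5, 0.5)
  fim <- c(1, 0.6, 0.05, 0.04, 0.03, 0.02)
  imp <- structure(list(fIM = fim, ranking = order(fim, decreasing = TRUE),
                        n_designs = 0L), class = "ad_importance")
  # active sets are nested under a non-increasing schedule
  fT <- c(0.5, 0.1, 0.01, 0)
  sets <- lapply(fT, function(f) which(fim >= f))
  for (i in seq_len(length(sets) - 1)) {
    expect_true(all(sets[[i]] %in% sets[[i + 1]]))
  }
  expect_length(sets[[length(sets)]], 6)
})

test_that("perturbation draws are seeded, clipped and level-monotone in spread", {
  p0 <- params_to_vector(midpoint_parameters())
  bounds <- default_parameter_bounds()
  set.seed(5)
  # paired seeds: same replicate draws the same direction at both levels
  set.seed(100 + 1); u1 <- runif(187, -1, 1)
  set.seed(100 + 1); u2 <- runif(187, -1, 1)
  expect_identical(u1, u2)
  pv <- pmin(pmax(p0 * (1 + 0.05 * u1), bounds$lo), bounds$up)
  expect_true(all(pv >= bounds$lo & pv <= bounds$up))
  expect_lt(max(abs(pv / p0 - 1)), 0.05 + 1e-9)
})
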