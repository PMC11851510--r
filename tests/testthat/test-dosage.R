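test_that("dosage bounds table: membership, removal limit, unit handling", {
  b <- b1_tm_bounds()
  expect_equal(nrow(b), 11L)
  expect_setequal(b$tm, c("Ca", "K", "Mg", "Na", "Fe", "Co", "Cr", "Ni",
                          "Pb", "Cu", "Zn"))
  # lower bounds are 10% of the initial concentrations
  expect_equal(b$lo, 0.1 * b$init, tolerance = 1e-12)
  # mg/L rows convert to g/L internally
  zn <- b[b$tm == "Zn", ]
  expect_equal(zn$init_g, 0.05)
  expect_equal(zn$up_g, 0.150)
  fe <- b[b$tm == "Fe", ]
  expect_equal(fe$up_g, 5.11)
  # violations are rejected
  bad <- as.data.frame(b)[, c("tm", "lo", "up", "init", "unit")]
  bad$lo[1] <- 0.5 * bad$init[1]
  expect_error(tm_bounds(bad), "10%")
  bad2 <- as.data.frame(b)[, c("tm", "lo", "up", "init", "unit")]
  bad2$tm[1] <- "Se"
  expect_error(tm_bounds(bad2), "11 metals")
})

test_that("case objectives match a quadrature oracle on a fixed simulation", {
  tt <- seq(0, 10, by = 0.5)
  vb <- 0.2 * tt^1.5
  vc <- 0.1 * tt^1.4
  fake <- structure(list(
    time = tt, state = cbind(V_biogas = vb, V_CH4 = vc),
    volumes = c(V_biogas = max(vb), V_CH4 = max(vc), V_H2 = 0.01,
                V_H2S = 0.004, V_NH3 = 0.002)),
    class = "ad_simulation")
  trap <- function(y) sum(diff(tt) * (head(y, -1) + y[-1]) / 2)
  expect_equal(objective_case(case_spec("A", psi0 = 2), fake), -2 * trap(vb))
  expect_equal(objective_case(case_spec("B", psi01 = 1, psi02 = 3), fake),
               -trap(vb) + 3 * 0.004)
  expect_equal(objective_case(case_spec("C", psi01 = 1, psi02 = 3), fake),
               -trap(vc) + 3 * 0.004)
  expect_error(objective_case(list(case = "Z"), fake), "unknown")
  # constraints
  expect_length(dosage_constraints(case_spec("A"), fake), 0L)
  cb <- case_spec("B", phi_H2S_max = 0.004 / max(vb))
  expect_equal(unname(dosage_constraints(cb, fake)), 0)
  cc <- case_spec("C")
  g <- dosage_constraints(cc, fake)
  expect_length(g, 3L)
  # halving H2S at fixed biogas lowers the H2S constraint
  fake2 <- fake
  fake2$volumes[["V_H2S"]] <- 0.002
  expect_lt(dosage_constraints(cc, fake2)[["g_H2S"]],
            g[["g_H2S"]])
})

test_that("performance deltas are plain percentage arithmetic", {
  mk <- function(vb, vc, vh2, vh2s, vnh3) {
    structure(list(volumes = c(V_biogas = vb, V_CH4 = vc, V_H2 = vh2,
                               V_H2S = vh2s, V_NH3 = vnh3)),
              class = "ad_simulation")
  }
  a <- mk(20, 10, 0.5, 0.2, 0.1)
  b <- mk(10, 5, 0.5, 0.4, 0)
  pr <- performance_report(a, b)
  expect_equal(unname(pr$volume_deltas["V_biogas"]), 100)
  expect_equal(unname(pr$volume_deltas["V_CH4"]), 100)
  expect_equal(unname(pr$volume_deltas["V_H2S"]), -50)
  expect_true(is.na(pr$volume_deltas[["V_NH3"]]))  # zero initial volume
  same <- performance_report(a, a)
  expect_true(all(abs(same$volume_deltas) < 1e-12))
  expect_true(all(abs(same$content_deltas) < 1e-12))
})

test_that("strong Zn inhibition of acetoclastic methanogens drives Zn down", {
  p <- midpoint_parameters()
  v <- params_to_vector(p)
  v["Kinh_Zn_Mac"] <- 0.02   # methanogens highly Zn-sensitive
  p_zn <- params_from_vector(v)
  rep <- optimize_dosage(case_spec("A"), p_zn, b1_tm_bounds(),
                         toy_reactor(8), b1_feedstock(), dt = toy_dt,
                         maxit = 8)
  zn <- rep$tm_opt[rep$tm_opt$tm == "Zn", ]
  expect_lt(zn$optimal, zn$initial)
})

test_that("degenerate dosage bounds pin the optimum at the initial design", {
  b <- b1_tm_bounds()
  df <- as.data.frame(b)[, c("tm", "lo", "up", "init", "unit")]
  df$lo <- df$init * (1 - 1e-6)
  df$up <- df$init * (1 + 1e-6)
  bb <- tm_bounds(df, relax_lo = TRUE)
  rep <- optimize_dosage(case_spec("A"), midpoint_parameters(), bb,
                         toy_reactor(6), b1_feedstock(), dt = toy_dt,
                         maxit = 3)
  expect_lt(max(abs(rep$tm_opt$optimal - rep$tm_opt$initial) /
                  rep$tm_opt$initial), 1e-5)
  expect_true(all(abs(rep$deltas) < 0.5, na.rm = TRUE))
})
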