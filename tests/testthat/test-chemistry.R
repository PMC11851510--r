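cst <- chem_constants()

test_that("speciation fractions are proper and consistent per acid system", {
  for (pH in c(2, 5, 7, 9, 12)) {
    sp <- speciate(pH, c(ac = 1, pro = 0.5, Cio = 2, Nio = 1, Pio = 1,
                         Sio_id = 0.2, Sio_at = 0.3, NO2 = 0.01))
    fr <- sp$fractions
    expect_true(all(fr >= 0 & fr <= 1))
    expect_equal(fr[["f_CO2"]] + fr[["f_HCO3"]] + fr[["f_CO3"]], 1)
    expect_equal(fr[["f_H2S"]] + fr[["f_HS"]] + fr[["f_S2"]], 1)
    expect_equal(fr[["f_HSO4"]] + fr[["f_SO4"]], 1)
    expect_equal(fr[["f_NH4"]] + fr[["f_NH3"]], 1)
  }
  expect_error(speciate(7, c(ac = -1)), "negative")
})

test_that("charge imbalance reproduces single-ion hand values", {
  empty <- speciate(7, c())
  expect_equal(charge_imbalance(empty), 0)
  # a lone cation at 0.01 mol/L counts -0.01 eq/L; Na is monovalent
  expect_equal(charge_imbalance(empty, tm_mol = c(Na = 0.01)), -0.01)
  # a lone acetate anion at 0.01 mol/L of ionized acetate counts +0.01
  M_ac <- cst$molar_mass[["ac"]]
  sp <- speciate(12, c(ac = 0.01 * M_ac / speciate(12, c(ac = 1))$fractions[["f_ac"]]))
  expect_equal(sp$mol[["ac"]], 0.01, tolerance = 1e-9)
  expect_equal(charge_imbalance(sp), 0.01, tolerance = 1e-9)
  # divalents count twice, Cl counts +1 by the model convention
  expect_equal(charge_imbalance(empty, tm_mol = c(Ca = 0.01)), -0.02)
  expect_equal(charge_imbalance(empty, tm_mol = c(Se = 0.01)), -0.02)
  expect_equal(charge_imbalance(empty, tm_mol = c(Cl = 0.01)), +0.01)
  expect_error(charge_imbalance(empty, tm_mol = c(Qq = 1)), "unknown")
})

test_that("pH solve: pure water, strong base oracle, residual, monotonicity", {
  ph <- solve_ph(c())
  expect_equal(as.numeric(ph), 7, tolerance = 1e-9)
  expect_lt(abs(attr(ph, "residual")), 1e-12)
  # strong base: [H+] + 0.001 = Kw/[H+] -> bisection oracle on [H+]
  f <- function(h) h + 1e-3 - 1e-14 / h
  lo <- 1e-14; hi <- 1
  for (i in 1:200) {
    mid <- sqrt(lo * hi)
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  ph_oracle <- -log10(sqrt(lo * hi))
  ph2 <- solve_ph(c(), tm_g = c(Na = 1e-3 * cst$molar_mass[["Na"]]))
  expect_equal(as.numeric(ph2), ph_oracle, tolerance = 1e-6)
  expect_lt(abs(attr(ph2, "residual")), 1e-12)
  # adding acetate monotonically lowers pH; adding Na raises it
  phs <- vapply(c(0, 0.5, 1, 2, 4),
                function(a) as.numeric(solve_ph(c(ac = a))), numeric(1))
  expect_true(all(diff(phs) < 0))
  phs2 <- vapply(c(0, 1e-4, 1e-3, 1e-2),
                 function(a) as.numeric(solve_ph(c(), tm_g = c(Na = a))),
                 numeric(1))
  expect_true(all(diff(phs2) > 0))
})

test_that("precipitation rate laws match direct arithmetic and clamp", {
  # sulfide: sqrt driving force, squared
  expect_equal(precip_rate_sulfide(1e-2, 1e-2, 1, (1e-4)^2),
               (1e-2 - 1e-4)^2)
  expect_equal(precip_rate_sulfide(0.01, 0.01, 1, 1e-8), 9.801e-5,
               tolerance = 1e-6)
  expect_equal(precip_rate_sulfide(1e-6, 1e-6, 5, 1e-4), 0)  # undersaturated
  expect_equal(precip_rate_sulfide(2, 2, 3, 4), 0)           # at saturation
  # carbonate: linear in k_cryst
  r1 <- precip_rate_carbonate(0.02, 0.02, 1, 1e-4)
  expect_equal(r1, 1e-4)
  expect_equal(precip_rate_carbonate(0.02, 0.02, 2, 1e-4), 2 * r1)
  # phosphate: struvite-only configuration
  k <- setNames(c(0, 0, 0, 0, 1, 0),
                c(paste0(c("Ca", "Co", "Fe", "Ni"), "3(PO4)2"),
                  "MgNH4PO4", "KMgPO4"))
  Ksp <- setNames(rep(1e-30, 6), names(k))
  cM <- c(Ca = 0, Co = 0, Fe = 0, Ni = 0)
  r <- precip_rate_phosphate(cM, c_PO4 = 1e-2, c_NH4 = 1e-2, c_K = 0,
                             c_Mg = 1e-2, k_cryst = k, K_sp = Ksp)
  expect_equal(r, (1e-2 - 1e-30^(1 / 3))^2, tolerance = 1e-6)
  expect_equal(precip_rate_phosphate(cM, 0, 1, 1, 1, k, Ksp), 0)
})

test_that("metal ion sinks carry the network stoichiometric weights", {
  p <- midpoint_parameters()
  s <- state_with(TM_Fe = 0.5, TM_Na = 1, Cio = 2, Pio = 2, Nio = 1,
                  Sio_id = 0.3, TM_Mg = 0.5, TM_K = 1)
  pH <- 7.5
  r <- precipitate_derivatives(s, p, pH)
  expect_length(r, 20L)
  expect_true(all(r >= 0))
  # Fe sink = FeS + FeCO3 + 3 * Fe3(PO4)2 terms
  fe <- tm_ion_sink("Fe", s, p, pH)
  expect_equal(fe, r[["FeS"]] + r[["FeCO3"]] + 3 * r[["Fe3(PO4)2"]])
  # Mg sink includes both struvites; K sink the K-struvite
  expect_equal(tm_ion_sink("Mg", s, p, pH),
               r[["MgCO3"]] + r[["MgNH4PO4"]] + r[["KMgPO4"]])
  expect_equal(tm_ion_sink("K", s, p, pH), r[["KMgPO4"]])
  expect_equal(tm_ion_sink("Na", s, p, pH), 0)
  expect_equal(tm_ion_sink("Cr", s, p, pH), 0)
  expect_error(tm_ion_sink("Xx", s, p, pH), "unknown")
})

test_that("constants registry round-trips through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  write_constants(cst, f)
  cst2 <- read_constants(f)
  expect_identical(cst2$Ksp, cst$Ksp)
  expect_identical(cst2$Ka$PO4, cst$Ka$PO4)
  expect_identical(cst2$molar_mass, cst$molar_mass)
  expect_identical(cst2$Kw, cst$Kw)
})
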