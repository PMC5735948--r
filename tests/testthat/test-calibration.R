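# Target assembly per crypt-villus unit, progenitor estimates, tied rates.

test_that("literature inputs scale to per-unit targets with their uncertainties", {
  tg <- assemble_cvu_targets()
  expect_equal(tg$values[["TAC"]], 310)
  expect_equal(tg$sigmas[["TAC"]], 10)
  expect_equal(tg$values[["CBC0"]], 10)
  expect_equal(tg$sigmas[["CBC0"]], 2)
  expect_equal(tg$values[["EEC"]], 40)     # 0.01 x N
  expect_equal(tg$values[["TC"]], 16)
  expect_equal(tg$values[["GC"]], 340)
  expect_equal(tg$sigmas[["GC"]], 60)
  expect_equal(tg$values[["PC"]], 80)
  expect_true(is.na(tg$values[["EC"]]))    # filled later

  short <- literature_inputs()[-1, ]
  expect_error(assemble_cvu_targets(short), "CBC0")
})

test_that("the progenitor proportionality constant matches its defining ratio", {
  expect_equal(compute_phi(0.01, 340, 80, 4000), 0.0952, tolerance = 5e-4)
  expect_equal(compute_phi(0, 340, 80, 4000), 0)
  expect_equal(compute_phi(0.02, 340, 80, 4000), 0.190476, tolerance = 1e-5)
  expect_error(compute_phi(0.01, 0, 0, 4000), "positive")
})

test_that("progenitor estimates and the enterocyte closure reproduce the calibration", {
  tg <- assemble_cvu_targets()
  phi <- compute_phi(0.01, 340, 80, 4000)
  tg <- estimate_progenitors(tg, phi)
  expect_equal(tg$values[["GPP"]], 40, tolerance = 1e-10)
  expect_equal(tg$values[["SP"]],
               phi * (40 + 16 + (1 + phi) * 420), tolerance = 1e-12)
  expect_equal(tg$values[["SP"]], 49.14, tolerance = 1e-4)

  tg <- enterocyte_target(tg)
  expect_equal(tg$values[["EC"]], 2844, tolerance = 1 / 2844)
  expect_equal(tg$values[["AP"]], phi * tg$values[["EC"]])

  # phi = 0: no progenitors, enterocytes absorb the remainder exactly
  tg0 <- estimate_progenitors(assemble_cvu_targets(), 0)
  expect_true(all(tg0$values[c("GPP", "SP")] == 0))
  tg0 <- enterocyte_target(tg0)
  expect_equal(tg0$values[["EC"]],
               4000 - sum(tg0$values[c("CBC0", "TAC", "SP", "GPP", "EEC",
                                       "TC", "GC", "PC")]))
  expect_equal(tg0$values[["AP"]], 0)
})

test_that("conservation and linear scaling hold for the assembled targets", {
  tg <- calibrate_targets()
  expect_equal(sum(tg$values), 4000, tolerance = 1e-9)

  # doubling the unit (twice the crypts, twice the villus) doubles every
  # target when the fractional abundances are held fixed
  comp2 <- cvu_composition(cells_per_crypt = 250, villus_cells = 7000,
                           crypts_per_villus = 4)
  tg2 <- calibrate_targets(comp = comp2)
  expect_equal(tg2$values, 2 * tg$values, tolerance = 1e-12)
  expect_equal(sum(tg2$values), 8000, tolerance = 1e-9)
})

test_that("tied rates follow the branch-ratio relations in dependency order", {
  tg <- calibrate_targets()
  tr <- tied_rates(params_baseline(), tg)
  expect_equal(tr[["k7"]], 0.3565 * (16 / 40), tolerance = 1e-12)
  expect_equal(tr[["k7"]], 0.143, tolerance = 3e-3)
  # omega_s must use the freshly tied k7, not a stale one
  omega_s <- 1.67958 + 0.3565 + tr[["k7"]] - 1.75
  expect_equal(tr[["k3"]],
               1.714495 * (omega_s / (3.7112 - 1.75)) *
                 (tg$values[["SP"]] / tg$values[["AP"]]),
               tolerance = 1e-12)
  expect_equal(tr[["k3"]], 0.068, tolerance = 1e-3)
  expect_equal(tr[["k9"]], 0.095, tolerance = 3e-3)

  p0 <- params_baseline()
  p0["k6"] <- 0
  expect_equal(tied_rates(as_rate_parameters(unclass(p0)), tg)[["k7"]], 0)

  trf <- tied_rates(params_fast(), tg)
  expect_equal(trf[["k9"]], 1.326 * (0.0479 / 0.1560) * (80 / 340),
               tolerance = 1e-12)
  expect_equal(trf[["k9"]], 0.096, tolerance = 3e-3)
})

test_that("k9 collapses to lambda5 * PC/GPP when lambda4 closes the goblet branch", {
  # substituting lambda4 = k8 * GPP / GC into the k9 relation removes k8
  tg <- calibrate_targets()
  v <- tg$values
  for (k8 in c(0.5, 1.326, 3.712, 10)) {
    p <- params_baseline()
    p["k8"] <- k8
    p["lambda4"] <- k8 * v[["GPP"]] / v[["GC"]]
    tr <- tied_rates(as_rate_parameters(unclass(p)), tg)
    expect_equal(tr[["k9"]], (1 / 21) * v[["PC"]] / v[["GPP"]],
                 tolerance = 1e-12, info = paste("k8 =", k8))
    expect_equal(tr[["k9"]], 2 / 21, tolerance = 1e-12)
  }
})
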