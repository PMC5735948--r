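# Closed-form solutions, ODE oracle, steady states and renewal times.

test_that("composite rates follow their defining sums and flag degeneracy", {
  om <- composite_rates(params_baseline())
  expect_equal(om[["omega_d"]], 1.714495 + 0.068 - 1.75)
  expect_equal(om[["omega_d"]], 0.032495, tolerance = 1e-12)
  expect_length(attr(om, "nonpositive"), 0)

  om_f <- composite_rates(params_fast())
  expect_equal(om_f[["omega_e"]], 14.875 - 7.512)
  expect_equal(om_f[["omega_e"]], 7.363, tolerance = 1e-12)

  zero <- as_rate_parameters(stats::setNames(rep(0, 19),
                                             cryptkinetics:::RATE_NAMES))
  om0 <- composite_rates(zero)
  expect_equal(unname(om0[["omega_d"]]), 0)
  expect_true("omega_d" %in% attr(om0, "nonpositive"))
  expect_setequal(attr(om0, "nonpositive"),
                  c("omega_d", "omega_e", "omega_s", "omega_m"))
})

test_that("stem pool is stationary and the rhs vanishes at steady state", {
  p <- params_baseline()
  st <- population_state(CBC = 10, TAC = 5, AP = 3, EC = 100, SP = 2,
                         EEC = 1, TC = 1, GPP = 1, GC = 10, PC = 4)
  expect_equal(unname(ode_rhs(st, p)[["CBC"]]), 0)

  ss <- steady_state(p, 10)
  d <- ode_rhs(ss, p)
  expect_true(all(abs(d) < 1e-9 * pmax(unclass(ss), 1)))
})

test_that("closed-form slope matches the rhs by central difference", {
  p <- params_baseline()
  h <- 1e-5
  up <- closed_form_state(p, 10, 2 + h)
  dn <- closed_form_state(p, 10, 2 - h)
  slope <- (unclass(up) - unclass(dn)) / (2 * h)
  rhs <- ode_rhs(closed_form_state(p, 10, 2), p)
  expect_equal(slope, rhs, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("closed form starts empty, hits its long-time limit, and matches the integrator", {
  p <- params_baseline()
  s0 <- closed_form_state(p, 10, 0)
  expect_equal(unname(s0[["CBC"]]), 10)
  expect_true(all(unclass(s0)[-1] == 0))

  om <- composite_rates(p)
  tac_inf <- 1 * 10 / om[["omega_d"]]
  far <- closed_form_state(p, 10, 10000)
  expect_equal(unname(far[["TAC"]]), unname(tac_inf), tolerance = 1e-3)

  grid <- c(1, 5, 20, 100)
  num <- integrate_ode(p, 10, grid)
  cf <- closed_form_timecourse(p, 10, grid)
  for (nm in cryptkinetics:::POP_NAMES)
    expect_true(all(abs(num[[nm]] - cf[[nm]]) <= 1e-6 * (1 + abs(cf[[nm]]))),
                info = nm)
})

test_that("integrator handles the trivial and the non-steady stem regimes", {
  # all rates zero except a self-renewing stem pool: nothing moves
  p0 <- as_rate_parameters(c(stats::setNames(rep(0, 19),
                                             cryptkinetics:::RATE_NAMES),
                             k1 = 1, alpha = 1)[cryptkinetics:::RATE_NAMES])
  out <- integrate_ode(p0, 10, c(0, 10, 50))
  expect_equal(out$CBC, rep(10, 3), tolerance = 1e-9)
  expect_equal(out$total, rep(10, 3), tolerance = 1e-9)

  # k1 != alpha decays the stem pool exponentially
  pn <- params_baseline()
  pn["alpha"] <- 0.5
  pn <- as_rate_parameters(unclass(pn), steady_state_mode = FALSE)
  out2 <- integrate_ode(pn, 10, c(0, 1, 2))
  expect_equal(out2$CBC, 10 * exp(-0.5 * c(0, 1, 2)), tolerance = 1e-7)
  expect_error(closed_form_state(pn, 10, 1), "k1 == alpha")
})

test_that("total population rises monotonically for both published sets", {
  grid <- seq(0, 200, by = 0.1)
  for (p in list(params_baseline(), params_fast())) {
    tc <- closed_form_timecourse(p, 10, grid)
    for (nm in c(cryptkinetics:::POP_NAMES, "total"))
      expect_true(all(diff(tc[[nm]]) > -1e-9), info = nm)
  }
})

test_that("steady state inverts the calibration ratio and prunes an unfed branch", {
  # omega_d chosen so the transit-amplifying pool lands on its target
  p <- params_baseline()
  p["k2"] <- 1.75 + 10 / 310 - p[["k3"]]  # omega_d = k1*CBC0/310
  p <- as_rate_parameters(unclass(p))
  expect_equal(unname(steady_state(p, 10)[["TAC"]]), 310, tolerance = 1e-9)

  # k3 = 0 starves the whole secretory limb (its flux folded into k2 so the
  # transit-amplifying clearance stays positive)
  ps <- params_baseline()
  ps["k2"] <- ps[["k2"]] + ps[["k3"]]
  ps["k3"] <- 0
  ps <- as_rate_parameters(unclass(ps))
  ss <- steady_state(ps, 10)
  expect_true(all(unclass(ss)[c("SP", "EEC", "TC", "GPP", "GC", "PC")] == 0))
  expect_true(all(unclass(ss)[c("TAC", "AP", "EC")] > 0))

  # long-time closed form converges to the steady state
  ss_b <- steady_state(params_baseline(), 10)
  cf <- closed_form_state(params_baseline(), 10, 1e5)
  expect_equal(unclass(cf), unclass(ss_b), tolerance = 1e-6,
               ignore_attr = TRUE)

  # no finite steady state when a composite rate is non-positive
  bad <- params_baseline()
  bad["k5"] <- 1  # omega_e = 1 - 1.75 < 0
  bad <- as_rate_parameters(unclass(bad))
  expect_error(steady_state(bad, 10), "non-positive")
})

test_that("branch-ratio identities hold at steady state", {
  for (p in list(params_baseline(), params_fast(), {
    set.seed(11); draw_valid_params()
  })) {
    ss <- unclass(steady_state(p, 10))
    x <- unclass(p)
    expect_equal(ss[["EEC"]] / ss[["TC"]],
                 (x[["k6"]] * x[["lambda3"]]) / (x[["k7"]] * x[["lambda2"]]),
                 tolerance = 1e-10)
    expect_equal(ss[["GC"]] / ss[["PC"]],
                 (x[["k8"]] * x[["lambda5"]]) / (x[["k9"]] * x[["lambda4"]]),
                 tolerance = 1e-10)
  }
})

test_that("renewal time finds the 95% crossing of the total population", {
  p <- params_baseline()
  # populations start empty: a tiny fraction is reached almost immediately
  expect_lt(renewal_time(p, 10, "TAC", fraction = 1e-9), 1e-3)

  t95 <- renewal_time(p, 10, "total", 0.95)
  expect_equal(t95, 96.8, tolerance = 0.02)

  # dense-grid scan oracle
  grid <- seq(90, 105, by = 0.001)
  tc <- closed_form_timecourse(p, 10, grid)
  target <- 0.95 * sum(steady_state(p, 10))
  t_scan <- grid[which(tc$total >= target)[1]]
  expect_equal(t95, t_scan, tolerance = 0.01 / t_scan)

  expect_error(renewal_time(p, 10, "total", 0.95, horizon = 10),
               "does not reach")
  expect_error(renewal_time(p, 10, "total", 1.5), "fraction")
})

test_that("near-coincident decay rates are perturbed, warned about, and stay accurate", {
  p <- params_baseline()
  p["lambda1"] <- unname(composite_rates(p)[["omega_e"]])  # lambda1 == omega_e
  p <- as_rate_parameters(unclass(p))
  expect_warning(cf <- closed_form_state(p, 10, 5), "near-coincident")
  num <- integrate_ode(p, 10, 5)
  expect_equal(unname(unclass(cf)[["EC"]]), num$EC[1], tolerance = 1e-5)
})
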