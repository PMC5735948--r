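# Scenario fits, uncertainty estimation and identifiability.

baseline_fit <- suppressWarnings(
  fit_scenario(scenario_config("baseline"), calibrated))

test_that("residuals vanish at an exact solution and stay small at the published values", {
  cfg <- scenario_config("baseline")
  expect_true(all(abs(baseline_fit$residuals) < 1e-6))

  # published values reproduce every target to printed-rounding accuracy
  fv <- unclass(params_baseline())[cfg$free]
  r <- residual_vector(fv, cfg, calibrated)
  rel <- abs(r[seq_along(cfg$target_set)]) /
    calibrated$values[cfg$target_set]
  expect_true(all(rel < 0.01))

  # perturbing k2 off the solution leaves a visible residual
  fv2 <- baseline_fit$par
  fv2["k2"] <- fv2["k2"] + 0.1
  expect_gt(sum(residual_vector(fv2, cfg, calibrated)^2), 1)

  # infeasible composite rates return finite penalty residuals
  fv3 <- baseline_fit$par
  fv3["k5"] <- 0.1  # omega_e < 0
  pen <- residual_vector(fv3, cfg, calibrated)
  expect_true(all(is.finite(pen)) && all(pen >= 1e4))
})

test_that("the baseline fit reproduces every steady-state target", {
  ss <- unclass(steady_state(baseline_fit$params, 10))
  v <- calibrated$values
  # all nine targets, including tuft and Paneth cells satisfied through the
  # tied rates
  for (nm in c("TAC", "AP", "EC", "SP", "EEC", "TC", "GPP", "GC", "PC"))
    expect_equal(ss[[nm]], v[[nm]], tolerance = 1e-3, info = nm)
  expect_equal(ss[["TAC"]], 310, tolerance = 1e-6)
  expect_equal(sum(ss), 4000, tolerance = 1e-6)
})

test_that("curvature sigmas follow the quadratic law", {
  expect_equal(curvature_sigma(function(d) 2 * d^2, step = 0.1), 0.5)
  expect_equal(curvature_sigma(function(d) 5000 * d^2), 0.01,
               tolerance = 1e-6)
  expect_true(is.na(curvature_sigma(function(d) -d^2)))

  sig <- curvature_uncertainty(baseline_fit)
  expect_named(sig, baseline_fit$config$free)
  # fitted one-at-a-time sigmas sit far below the literature 0.25/day
  expect_lt(sig[["k2"]], 0.01)
  expect_true(all(sig < 0.25, na.rm = TRUE))
})

test_that("tied-rate errors propagate in quadrature of relative errors", {
  expect_equal(propagate_tied_uncertainty(0.14, c(1, 2), c(0, 0)), 0)
  expect_equal(propagate_tied_uncertainty(0.4, 2, 0.2), 0.04)
  k7 <- 0.14
  fac <- c(0.3565, 0.43673, 0.43673, 16, 40)
  sg <- c(0.0002, 0.00005, 0.00005, 1.6, 4)
  expect_equal(propagate_tied_uncertainty(k7, fac, sg),
               k7 * sqrt(sum((sg / fac)^2)), tolerance = 1e-12)
  expect_error(propagate_tied_uncertainty(1, c(1, 0), c(0, 0)), "zero factor")

  ts <- tied_rate_uncertainty(baseline_fit)
  expect_named(ts, c("k3", "k7", "k9"))
  expect_true(all(is.finite(ts) & ts >= 0))
})

test_that("identifiability: a two-parameter toy problem is full rank", {
  tg <- generate_targets(params_baseline(), 10, noise_model("none"))
  fixed <- unclass(params_baseline())
  fixed <- fixed[setdiff(names(fixed), c("k5", "lambda1", "k3", "k7", "k9"))]
  cfg <- scenario_config("custom", free = c("k5", "lambda1"), fixed = fixed)
  fit <- fit_scenario(cfg, tg)
  expect_equal(fit$identifiability$rank, 2)
  expect_equal(ncol(fit$identifiability$null_space), 0)
})

test_that("the baseline scenario has one flat direction touching k2 and k4", {
  id <- baseline_fit$identifiability
  expect_equal(id$rank, 6)
  expect_equal(id$n_free, 7)
  expect_equal(ncol(id$null_space), 1)
  v <- id$null_space[, 1]
  expect_gt(abs(v[["k2"]]), 0.05)
  expect_gt(abs(v[["k4"]]), 0.05)
})

test_that("moving along the flat direction leaves SSR and the invariants unchanged", {
  id <- baseline_fit$identifiability
  v <- id$null_space[, 1]
  eps <- 1e-4
  shifted <- baseline_fit$par + eps * v
  r <- residual_vector(shifted, baseline_fit$config, calibrated)
  expect_lt(abs(sum(r^2) - baseline_fit$ssr), 1e-8)
  # individual parameters moved ...
  expect_gt(max(abs(shifted - baseline_fit$par)), eps / 10)
  # ... but the identifiable combinations did not
  c0 <- identifiable_combinations(baseline_fit$params)
  c1 <- identifiable_combinations(
    cryptkinetics:::materialize_parameters(shifted, baseline_fit$config,
                                           calibrated))
  expect_equal(c1, c0, tolerance = 1e-6)
})

test_that("reproduction mode pins the manifold and recovers the published table", {
  fit <- fit_scenario(scenario_config("baseline", pin = c(k2 = 1.714495)),
                      calibrated)
  expect_equal(fit$identifiability$rank, 6)
  expect_equal(fit$identifiability$n_free, 6)
  p <- unclass(fit$params)
  pub <- unclass(params_baseline())
  for (nm in c("k4", "k5", "k6", "k8", "lambda1", "lambda2"))
    expect_equal(p[[nm]], pub[[nm]], tolerance = 0.01, info = nm)
})

test_that("the fast fit meets the 5-day enterocyte renewal constraint", {
  fit <- suppressWarnings(fit_scenario(scenario_config("fast"), calibrated))
  ss <- steady_state(fit$params, 10)
  ec5 <- unclass(closed_form_state(fit$params, 10, 5))[["EC"]]
  expect_equal(ec5 / ss[["EC"]], 0.95, tolerance = 1e-4)
  expect_equal(renewal_time(fit$params, 10, "EC", 0.95), 5, tolerance = 0.01)
  # steady targets still met
  expect_equal(unname(ss[["TAC"]]), 310, tolerance = 1e-4)
  expect_equal(sum(ss), 4000, tolerance = 1e-4)
  # underdetermined: more free parameters than independent constraints
  expect_lt(fit$identifiability$rank, fit$identifiability$n_free)
})

test_that("noise-free synthetic targets return the true identifiable combinations", {
  tg <- generate_targets(params_baseline(), 10, noise_model("none"))
  fit <- suppressWarnings(fit_scenario(scenario_config("baseline"), tg))
  truth <- identifiable_combinations(params_baseline())
  est <- identifiable_combinations(fit$params)
  expect_equal(est, truth, tolerance = 1e-4)
})
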