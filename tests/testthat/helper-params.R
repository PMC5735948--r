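# Shared fixtures: random valid parameter draws and the calibrated targets.

# Draw a rate set with positive, mutually well-separated clearance rates so
# the generic (non-confluent) branch of the closed forms is exercised.
draw_valid_params <- function() {
  repeat {
    prolif <- stats::runif(4, 0.2, 2)      # beta, gamma, delta, zeta
    om <- stats::runif(4, 0.05, 2.5)       # omega_d, omega_e, omega_s, omega_m
    lam <- stats::runif(5, 0.05, 3)
    decay <- c(om, lam)
    gaps <- abs(outer(decay, decay, `-`))
    if (min(gaps[upper.tri(gaps)]) < 0.05 * max(decay)) next
    k1 <- stats::runif(1, 0.5, 2)
    u <- stats::runif(1, 0.1, 0.9)
    w <- stats::runif(3, 0.1, 1); w <- w / sum(w)
    v <- stats::runif(1, 0.2, 0.8)
    return(rate_parameters(
      k1 = k1, k2 = u * (prolif[1] + om[1]), k3 = (1 - u) * (prolif[1] + om[1]),
      k4 = w[1] * (prolif[3] + om[3]), k5 = prolif[2] + om[2],
      k6 = w[2] * (prolif[3] + om[3]), k7 = w[3] * (prolif[3] + om[3]),
      k8 = v * (prolif[4] + om[4]), k9 = (1 - v) * (prolif[4] + om[4]),
      alpha = k1, beta = prolif[1], gamma = prolif[2], delta = prolif[3],
      zeta = prolif[4], lambda1 = lam[1], lambda2 = lam[2], lambda3 = lam[3],
      lambda4 = lam[4], lambda5 = lam[5]))
  }
}

# Calibrated literature targets, built once per test file.
calibrated <- calibrate_targets()
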