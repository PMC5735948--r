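# Kinetic rate parameterization of the ten-compartment epithelial cascade.

# canonical orderings used throughout the package
RATE_NAMES <- c("k1", "k2", "k3", "k4", "k5", "k6", "k7", "k8", "k9",
                "alpha", "beta", "gamma", "delta", "zeta",
                "lambda1", "lambda2", "lambda3", "lambda4", "lambda5")
POP_NAMES <- c("CBC", "TAC", "AP", "EC", "SP", "EEC", "TC", "GPP", "GC", "PC")

#' Kinetic rate parameters
#'
#' Bundle the nineteen first-order rate constants of the intestinal
#' epithelial lineage cascade: nine differentiation rates `k1..k9`, five
#' proliferation rates (`alpha` for crypt-based columnar stem cells, `beta`
#' for transit-amplifying cells, `gamma`, `delta`, `zeta` for the absorptive,
#' secretory and goblet/Paneth progenitors) and five terminal loss rates
#' `lambda1..lambda5` (enterocytes, enteroendocrine, tuft, goblet and Paneth
#' cells). All rates are per day and must be non-negative.
#'
#' A constant stem-cell pool requires `k1 == alpha` (the stem compartment
#' loses cells to differentiation exactly as fast as it divides); this
#' steady-state mode is the default and is enforced when
#' `steady_state_mode = TRUE`.
#'
#' @param k1,k2,k3,k4,k5,k6,k7,k8,k9 differentiation rates (day^-1).
#' @param alpha,beta,gamma,delta,zeta proliferation rates (day^-1).
#' @param lambda1,lambda2,lambda3,lambda4,lambda5 loss rates (day^-1).
#' @param steady_state_mode logical; require `k1 == alpha`.
#' @return an object of class `rate_parameters` (named numeric vector).
#' @export
rate_parameters <- function(k1, k2, k3, k4, k5, k6, k7, k8, k9,
                            alpha, beta, gamma, delta, zeta,
                            lambda1, lambda2, lambda3, lambda4, lambda5,
                            steady_state_mode = TRUE) {
  x <- c(k1 = k1, k2 = k2, k3 = k3, k4 = k4, k5 = k5, k6 = k6, k7 = k7,
         k8 = k8, k9 = k9, alpha = alpha, beta = beta, gamma = gamma,
         delta = delta, zeta = zeta, lambda1 = lambda1, lambda2 = lambda2,
         lambda3 = lambda3, lambda4 = lambda4, lambda5 = lambda5)
  if (!is.numeric(x) || anyNA(x))
    stop("all rates must be finite numerics", call. = FALSE)
  if (any(x < 0))
    stop("all rates must be >= 0; negative: ",
         paste(names(x)[x < 0], collapse = ", "), call. = FALSE)
  if (steady_state_mode && !isTRUE(all.equal(unname(k1), unname(alpha))))
    stop("steady-state mode requires k1 == alpha (constant stem-cell pool)",
         call. = FALSE)
  structure(x, class = "rate_parameters")
}

#' Coerce a named vector or list to rate parameters
#'
#' @param x named numeric vector or list carrying all nineteen rates.
#' @param steady_state_mode logical; require `k1 == alpha`.
#' @return a `rate_parameters` object.
#' @export
as_rate_parameters <- function(x, steady_state_mode = TRUE) {
  x <- unlist(x)
  missing <- setdiff(RATE_NAMES, names(x))
  if (length(missing))
    stop("missing rates: ", paste(missing, collapse = ", "), call. = FALSE)
  do.call(rate_parameters,
          c(as.list(x[RATE_NAMES]), steady_state_mode = steady_state_mode))
}

#' @export
print.rate_parameters <- function(x, ...) {
  cat("Kinetic rate parameters (day^-1):\n")
  print(signif(unclass(x), 6))
  invisible(x)
}

#' Published baseline-scenario parameter set
#'
#' The fitted and constrained rates of the baseline scenario: stem-cell
#' turnover fixed at the literature value (`k1 = alpha = 1`/day), all
#' progenitor proliferation rates at the transit-amplifying literature rate
#' (1.75/day), Paneth-cell loss at 1/21 per day, secretory loss rates shared,
#' and the remaining rates at their reported fitted values.
#'
#' @return a `rate_parameters` object.
#' @export
params_baseline <- function() {
  rate_parameters(
    k1 = 1, k2 = 1.714495, k3 = 0.068, k4 = 1.67958, k5 = 3.7112,
    k6 = 0.3565, k7 = 0.14, k8 = 3.712, k9 = 0.095,
    alpha = 1, beta = 1.75, gamma = 1.75, delta = 1.75, zeta = 1.75,
    lambda1 = 0.35364, lambda2 = 0.43673, lambda3 = 0.43673,
    lambda4 = 0.43673, lambda5 = 1 / 21)
}

#' Published fast-scenario parameter set
#'
#' The reported rates of the fast scenario, in which every non-tied rate was
#' freed so the enterocyte pool reaches 95% of its steady state by day 5.
#' These values are one point on an underdetermined solution manifold, not a
#' unique optimum.
#'
#' @return a `rate_parameters` object.
#' @export
params_fast <- function() {
  rate_parameters(
    k1 = 24.025, k2 = 6.4369, k3 = 0.125, k4 = 0.798, k5 = 14.875,
    k6 = 0.1050, k7 = 0.052, k8 = 1.326, k9 = 0.096,
    alpha = 24.025, beta = 5.7868, gamma = 7.512, delta = 0.096,
    zeta = 0.523, lambda1 = 1.4154, lambda2 = 0.1182, lambda3 = 0.148,
    lambda4 = 0.1560, lambda5 = 0.0479)
}

#' Published per-rate uncertainties
#'
#' One-standard-deviation uncertainties attached to each rate: curvature
#' (fit) uncertainties for the fitted rates, literature uncertainties for the
#' constrained ones (0.25/day for the stem and progenitor proliferation
#' rates), and quadrature-propagated uncertainties for the tied rates
#' `k3`, `k7`, `k9`. The Paneth loss rate carries no published uncertainty in
#' the baseline set.
#'
#' @return named numeric vector over the nineteen rates (day^-1).
#' @export
baseline_sigmas <- function() {
  c(k1 = 0.25, k2 = 0.000008, k3 = 0.06, k4 = 0.00005, k5 = 0.0009,
    k6 = 0.0002, k7 = 0.10, k8 = 0.008, k9 = 0.045,
    alpha = 0.25, beta = 0.25, gamma = 0.25, delta = 0.25, zeta = 0.25,
    lambda1 = 0.00007, lambda2 = 0.00005, lambda3 = 0.00005,
    lambda4 = 0.00005, lambda5 = 0)
}

#' @rdname baseline_sigmas
#' @export
fast_sigmas <- function() {
  c(k1 = 0.006, k2 = 0.0002, k3 = 0.108, k4 = 0.001, k5 = 0.004,
    k6 = 0.0002, k7 = 0.037, k8 = 0.004, k9 = 0.041,
    alpha = 0.006, beta = 0.0002, gamma = 0.002, delta = 0.001,
    zeta = 0.002, lambda1 = 0.0004, lambda2 = 0.0002, lambda3 = 0.004,
    lambda4 = 0.0004, lambda5 = 0.0009)
}

#' Net compartment clearance rates
#'
#' The four composite rates governing the proliferating compartments: each is
#' the sum of the outgoing differentiation rates minus the compartment's own
#' proliferation rate. `omega_d = k2 + k3 - beta` (transit-amplifying),
#' `omega_e = k5 - gamma` (absorptive progenitor),
#' `omega_s = k4 + k6 + k7 - delta` (secretory progenitor),
#' `omega_m = k8 + k9 - zeta` (goblet/Paneth progenitor). A finite steady
#' state exists only when all four are positive; non-positive values are
#' flagged, not treated as errors, because transient analysis may still be
#' meaningful.
#'
#' @param params a [rate_parameters()] object.
#' @return object of class `composite_rates`: named numeric vector
#'   `omega_d`, `omega_e`, `omega_s`, `omega_m` with a `nonpositive`
#'   attribute naming any flagged entries.
#' @export
composite_rates <- function(params) {
  p <- as.list(unclass(params))
  om <- c(omega_d = p$k2 + p$k3 - p$beta,
          omega_e = p$k5 - p$gamma,
          omega_s = p$k4 + p$k6 + p$k7 - p$delta,
          omega_m = p$k8 + p$k9 - p$zeta)
  structure(om, nonpositive = names(om)[om <= 0], class = "composite_rates")
}

#' @export
print.composite_rates <- function(x, ...) {
  cat("Composite clearance rates (day^-1):\n")
  print(signif(unclass(x), 6))
  np <- attr(x, "nonpositive")
  if (length(np))
    cat("non-positive (no finite steady state through):",
        paste(np, collapse = ", "), "\n")
  invisible(x)
}
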