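# Constrained least-squares estimation of the kinetic rates.

#' Scenario configuration for rate fitting
#'
#' Declares which rates are free, fixed or tied for a fit:
#'
#' * `"baseline"` — stem turnover and all proliferation rates held at their
#'   literature values (`k1 = alpha = 1`, `beta = gamma = delta = zeta =
#'   1.75`, `lambda5 = 1/21`/day), secretory loss rates shared
#'   (`lambda3 = lambda4 = lambda2`), seven free rates
#'   (`k2, k4, k5, k6, k8, lambda1, lambda2`) and no timescale constraint.
#' * `"fast"` — every non-tied rate free (15 parameters), `alpha` tracking
#'   `k1`, plus the renewal constraint that enterocytes reach 95% of their
#'   steady state at 5 days.
#' * `"custom"` — caller supplies the pieces.
#'
#' In both built-in scenarios `k3`, `k7` and `k9` are tied through the
#' branch-ratio relations ([tied_rates()]) and recomputed at every residual
#' evaluation. `pin` fixes selected otherwise-free rates at given values
#' (e.g. `pin = c(k2 = 1.714495)` reproduces the published baseline table,
#' removing the one-dimensional solution manifold).
#'
#' @param scenario `"baseline"`, `"fast"` or `"custom"`.
#' @param free character vector of free rate names (custom only).
#' @param fixed named numeric of fixed rates (custom only).
#' @param shared named character: each entry's rate copies another, e.g.
#'   `c(lambda3 = "lambda2")`.
#' @param target_set populations entering the residual; tuft and Paneth
#'   cells are satisfied identically through the tied rates and are omitted
#'   by default.
#' @param weights optional named weights for the target residuals.
#' @param timescale list with `enabled`, `selector`, `fraction`, `time`
#'   (days) and `weight` for the renewal constraint residual.
#' @param pin named numeric of free rates to hold at given values.
#' @param CBC0 stem-cell count per crypt-villus unit.
#' @param optimizer list of optimizer settings: `start` (named numeric or
#'   NULL for the built-in initializer), `lower`, `maxiter`, `ftol`, `ptol`.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(scenario = c("baseline", "fast", "custom"),
                            free = NULL, fixed = NULL, shared = NULL,
                            target_set = NULL, weights = NULL,
                            timescale = NULL, pin = NULL, CBC0 = 10,
                            optimizer = list()) {
  scenario <- match.arg(scenario)
  lit <- c(k1 = 1, alpha = 1, beta = 1.75, gamma = 1.75, delta = 1.75,
           zeta = 1.75, lambda5 = 1 / 21)
  if (scenario == "baseline") {
    free <- c("k2", "k4", "k5", "k6", "k8", "lambda1", "lambda2")
    fixed <- lit
    shared <- c(lambda3 = "lambda2", lambda4 = "lambda2")
    ts <- list(enabled = FALSE, selector = "EC", fraction = 0.95,
               time = 5, weight = 1)
  } else if (scenario == "fast") {
    free <- c("k1", "k2", "k4", "k5", "k6", "k8", "beta", "gamma", "delta",
              "zeta", "lambda1", "lambda2", "lambda3", "lambda4", "lambda5")
    fixed <- numeric(0)
    shared <- c(alpha = "k1")
    ts <- list(enabled = TRUE, selector = "EC", fraction = 0.95,
               time = 5, weight = 1)
  } else {
    if (is.null(free)) stop("custom scenario needs `free`", call. = FALSE)
    ts <- list(enabled = FALSE, selector = "EC", fraction = 0.95,
               time = 5, weight = 1)
  }
  if (!is.null(timescale)) ts[names(timescale)] <- timescale
  if (is.null(target_set))
    target_set <- c("TAC", "AP", "SP", "GPP", "EEC", "GC", "EC")
  opt <- list(start = NULL, lower = 1e-8, maxiter = 1000,
              ftol = 1e-12, ptol = 1e-12)
  opt[names(optimizer)] <- optimizer
  if (!is.null(pin)) {
    unknown <- setdiff(names(pin), free)
    if (length(unknown))
      stop("pin refers to non-free rate(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    free <- setdiff(free, names(pin))
    fixed <- c(fixed, pin)
  }
  # literature sigmas for fixed/constrained rates, used by error propagation
  fixed_sigmas <- c(k1 = 0.25, alpha = 0.25, beta = 0.25, gamma = 0.25,
                    delta = 0.25, zeta = 0.25, lambda5 = 0)
  structure(list(scenario = scenario, free = free, fixed = fixed,
                 shared = shared, tied = c("k3", "k7", "k9"),
                 target_set = target_set, weights = weights,
                 timescale = ts, CBC0 = CBC0, optimizer = opt,
                 fixed_sigmas = fixed_sigmas),
            class = "scenario_config")
}

# Full 19-rate vector from the free values, with fixed, shared and tied
# entries resolved. No validation: the optimizer may propose transiently
# infeasible points that the penalty residuals handle.
materialize_parameters <- function(free_values, config, targets) {
  p <- stats::setNames(rep(NA_real_, length(RATE_NAMES)), RATE_NAMES)
  p[names(config$fixed)] <- config$fixed
  p[config$free] <- free_values
  for (nm in names(config$shared)) p[nm] <- p[config$shared[nm]]
  p[config$tied] <- 0
  pp <- structure(p, class = "rate_parameters")
  tr <- tryCatch(tied_rates(pp, targets), error = function(e) NULL)
  if (!is.null(tr)) pp[names(tr)] <- tr
  pp
}

#' Residual vector for a scenario
#'
#' Model steady states minus targets over the configured target set, with
#' the tied rates recomputed from the current free values at every call.
#' When the timescale constraint is on, one extra residual
#' `weight * (P(t) - fraction * P_inf)` is appended for the selected
#' population. If any composite or loss rate is non-positive (no finite
#' steady state) every residual is replaced by a large finite penalty that
#' grows with the infeasibility, so gradient-based optimizers can recover.
#' The vector is zero-padded to at least the number of free parameters
#' (required by the Levenberg-Marquardt backend; the padding does not change
#' the objective).
#'
#' @param free_values named numeric of the free rates.
#' @param config a [scenario_config()].
#' @param targets a completed `steady_state_targets` object.
#' @return numeric residual vector (cells).
#' @export
residual_vector <- function(free_values, config, targets) {
  n_out <- max(length(config$target_set) + config$timescale$enabled,
               length(config$free))
  pp <- materialize_parameters(free_values, config, targets)
  p <- as.list(unclass(pp))
  rates <- c(p$k2 + p$k3 - p$beta, p$k5 - p$gamma,
             p$k4 + p$k6 + p$k7 - p$delta, p$k8 + p$k9 - p$zeta,
             p$lambda1, p$lambda2, p$lambda3, p$lambda4, p$lambda5)
  deficit <- sum(pmax(0, 1e-4 - rates))
  if (deficit > 0 || anyNA(rates))
    return(rep(1e4 * (1 + deficit), n_out))
  ss <- steady_state(pp, config$CBC0)
  res <- unclass(ss)[config$target_set] - targets$values[config$target_set]
  if (!is.null(config$weights))
    res <- res * config$weights[config$target_set]
  if (config$timescale$enabled) {
    ts <- config$timescale
    at_t <- .closed_form_matrix(pp, config$CBC0, ts$time,
                                quiet = TRUE)[1, ts$selector]
    res <- c(res, ts$weight * (at_t - ts$fraction * ss[[ts$selector]]))
  }
  res <- unname(res)
  if (length(res) < n_out) res <- c(res, rep(0, n_out - length(res)))
  res
}

# Chained steady-state initializer: inverts the t->infinity ratio relations
# target by target. Exact for self-consistent targets; for noisy targets it
# lands near the optimum. k2 is the manifold coordinate and defaults to the
# transit-amplifying proliferation rate unless pinned.
.chain_start <- function(config, targets) {
  v <- targets$values
  fx <- config$fixed
  grab <- function(nm, default) if (nm %in% names(fx)) fx[[nm]] else default
  k1 <- grab("k1", 1)
  beta <- grab("beta", 1.75)
  gamma <- grab("gamma", 1.75)
  delta <- grab("delta", 1.75)
  zeta <- grab("zeta", 1.75)
  lambda5 <- grab("lambda5", 1 / 21)
  od <- k1 * config$CBC0 / v[["TAC"]]
  k2 <- grab("k2", beta)
  k3 <- max(beta + od - k2, 1e-3)
  oe <- k2 * v[["TAC"]] / v[["AP"]]
  k5 <- oe + gamma
  lambda1 <- k5 * v[["AP"]] / v[["EC"]]
  os <- k3 * oe * v[["AP"]] / (k2 * v[["SP"]])
  r_tc <- v[["TC"]] / v[["EEC"]]
  lambda2 <- (os + delta + zeta * v[["GPP"]] / v[["SP"]] -
                lambda5 * v[["PC"]] / v[["SP"]]) /
    ((v[["GC"]] + (1 + r_tc) * v[["EEC"]]) / v[["SP"]])
  lambda2 <- max(lambda2, 1e-3)
  k6 <- lambda2 * v[["EEC"]] / v[["SP"]]
  k8 <- lambda2 * v[["GC"]] / v[["GPP"]]
  k4 <- max(os + delta - k6 * (1 + r_tc), 1e-3)
  start <- c(k1 = k1, k2 = k2, k4 = k4, k5 = unname(k5), k6 = unname(k6),
             k8 = unname(k8), beta = beta, gamma = gamma, delta = delta,
             zeta = zeta, lambda1 = unname(lambda1),
             lambda2 = unname(lambda2), lambda3 = unname(lambda2),
             lambda4 = unname(lambda2), lambda5 = lambda5)
  start <- start[intersect(names(start), config$free)]
  if (config$timescale$enabled) {
    # steady states depend only on rate ratios, so rescaling every rate by c
    # leaves them unchanged while compressing time by c: scale the start so
    # the constrained population meets its renewal target.
    pp <- materialize_parameters(start, config, targets)
    t0 <- tryCatch(
      renewal_time(pp, config$CBC0, config$timescale$selector,
                   config$timescale$fraction, tol = 1e-4),
      error = function(e) NA_real_)
    if (is.finite(t0) && t0 > 0) start <- start * t0 / config$timescale$time
  }
  pmax(start, 1e-6)
}

#' Fit a scenario to steady-state targets
#'
#' Bounded Levenberg-Marquardt least squares (`minpack.lm::nls.lm`) on
#' [residual_vector()], started from the chained steady-state initializer
#' (or `config$optimizer$start`). Reports the materialized parameter set,
#' the sum of squared residuals, convergence metadata and an
#' identifiability diagnosis; a warning is emitted when the residual
#' Jacobian is rank-deficient at the solution (the solution then lies on a
#' manifold and individual parameter values are solver-dependent).
#'
#' @inheritParams residual_vector
#' @return object of class `fit_result`: fields `par` (free rates),
#'   `params` ([rate_parameters()] with tied values materialized), `ssr`
#'   (cells^2), `residuals`, `identifiability`, `convergence`, `scenario`,
#'   `config`, `targets`.
#' @export
fit_scenario <- function(config, targets) {
  start <- config$optimizer$start
  if (is.null(start)) start <- .chain_start(config, targets)
  start <- start[config$free]
  if (anyNA(start))
    stop("no start value for: ",
         paste(config$free[is.na(start)], collapse = ", "), call. = FALSE)
  ctrl <- minpack.lm::nls.lm.control(
    maxiter = min(config$optimizer$maxiter, 1024),
    ftol = config$optimizer$ftol, ptol = config$optimizer$ptol)
  fit <- minpack.lm::nls.lm(
    par = start, lower = rep(config$optimizer$lower, length(start)),
    fn = function(p) residual_vector(stats::setNames(p, config$free),
                                     config, targets),
    control = ctrl)
  if (fit$info == 0)
    stop("optimizer reported improper input", call. = FALSE)
  if (fit$info == 5)
    stop("fit did not converge within ", ctrl$maxiter, " iterations",
         call. = FALSE)
  par <- stats::setNames(fit$par, config$free)
  params <- materialize_parameters(par, config, targets)
  res <- residual_vector(par, config, targets)
  out <- structure(list(par = par, params = params,
                        ssr = sum(res^2), residuals = res,
                        convergence = list(info = fit$info,
                                           message = fit$message,
                                           iterations = fit$niter),
                        scenario = config$scenario, config = config,
                        targets = targets),
                   class = "fit_result")
  out$identifiability <- identifiability(out)
  if (out$identifiability$rank < length(par))
    warning(sprintf(
      "rank-deficient fit (rank %d of %d free parameters): the solution ",
      out$identifiability$rank, length(par)),
      "lies on a manifold; individual values are solver-dependent",
      call. = FALSE)
  out
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("%s scenario fit: SSR = %.4g cells^2 (%d iterations)\n",
              x$scenario, x$ssr, x$convergence$iterations))
  cat(sprintf("identifiability: rank %d of %d free parameters\n",
              x$identifiability$rank, length(x$par)))
  print(x$params)
  invisible(x)
}

#' One-at-a-time curvature standard deviation
#'
#' Fits the increase of an objective around its minimum to a quadratic
#' `SSR(d) = SSR0 + a d^2` from evaluations at `d = 0, +step, -step`; the
#' quadratic coefficient is the reciprocal of twice the variance, so
#' `sigma = sqrt(1 / (2a))`. Non-positive curvature yields `NA`.
#'
#' @param ssr_fun function of a scalar offset returning the objective.
#' @param step evaluation offset.
#' @return estimated sigma (`NA` if the curvature is not positive).
#' @export
curvature_sigma <- function(ssr_fun, step = 1e-6) {
  s0 <- ssr_fun(0)
  a <- (ssr_fun(step) + ssr_fun(-step) - 2 * s0) / (2 * step^2)
  if (!is.finite(a) || a <= 0) return(NA_real_)
  sqrt(1 / (2 * a))
}

#' Curvature uncertainties of the free parameters
#'
#' Applies [curvature_sigma()] to each free parameter in turn, holding the
#' others at their fitted values. The step is absolute by default (as the
#' published analysis used); `relative = TRUE` scales it by the parameter
#' magnitude, which is preferable for rates much larger than 1/day.
#'
#' @param fit a [fit_scenario()] result.
#' @param step offset (day^-1, or relative fraction if `relative`).
#' @param relative logical; scale `step` by `max(|value|, 1)`.
#' @return named numeric of sigmas; `NA` flags non-positive curvature.
#' @export
curvature_uncertainty <- function(fit, step = 1e-6, relative = FALSE) {
  config <- fit$config
  targets <- fit$targets
  vapply(seq_along(fit$par), function(j) {
    h <- if (relative) step * max(abs(fit$par[j]), 1) else step
    curvature_sigma(function(d) {
      p <- fit$par
      p[j] <- p[j] + d
      sum(residual_vector(p, config, targets)^2)
    }, step = h)
  }, numeric(1)) |> stats::setNames(names(fit$par))
}

#' Quadrature propagation of relative errors
#'
#' For a rate defined as a product/quotient of factors, the relative error
#' is the root-sum-square of the component relative errors:
#' `sigma = |value| * sqrt(sum((sigma_i / x_i)^2))`.
#'
#' @param value the derived quantity.
#' @param factors component values (all nonzero).
#' @param sigmas component standard deviations, same length.
#' @return propagated sigma.
#' @export
propagate_tied_uncertainty <- function(value, factors, sigmas) {
  stopifnot(length(factors) == length(sigmas))
  if (any(factors == 0))
    stop("zero factor value in error propagation", call. = FALSE)
  abs(value) * sqrt(sum((sigmas / factors)^2))
}

#' Uncertainties of the tied rates
#'
#' Propagates the free-parameter curvature sigmas, the literature sigmas of
#' the constrained rates and the target-count sigmas through the
#' branch-ratio expressions for `k3`, `k7` and `k9` by quadrature of
#' relative errors. Composite-rate sigmas are quadrature sums of their
#' additive components.
#'
#' @param fit a [fit_scenario()] result.
#' @param free_sigmas named sigmas of the free rates (defaults to
#'   [curvature_uncertainty()] of the fit).
#' @return named numeric `c(k3, k7, k9)`.
#' @export
tied_rate_uncertainty <- function(fit, free_sigmas = NULL) {
  if (is.null(free_sigmas)) free_sigmas <- curvature_uncertainty(fit)
  p <- as.list(unclass(fit$params))
  v <- fit$targets$values
  sv <- fit$targets$sigmas
  sig <- function(nm) {
    if (nm %in% names(free_sigmas)) return(free_sigmas[[nm]])
    sh <- fit$config$shared
    if (nm %in% names(sh)) return(sig(sh[[nm]]))
    fs <- fit$config$fixed_sigmas
    if (nm %in% names(fs)) return(fs[[nm]])
    0
  }
  om <- composite_rates(fit$params)
  s_oe <- sqrt(sig("k5")^2 + sig("gamma")^2)
  s_k7 <- propagate_tied_uncertainty(
    p$k7, c(p$k6, p$lambda3, p$lambda2, v[["TC"]], v[["EEC"]]),
    c(sig("k6"), sig("lambda3"), sig("lambda2"), sv[["TC"]], sv[["EEC"]]))
  s_os <- sqrt(sig("k4")^2 + sig("k6")^2 + s_k7^2 + sig("delta")^2)
  s_k3 <- propagate_tied_uncertainty(
    p$k3, c(p$k2, om[["omega_s"]], om[["omega_e"]], v[["SP"]], v[["AP"]]),
    c(sig("k2"), s_os, s_oe, sv[["SP"]], sv[["AP"]]))
  s_k9 <- propagate_tied_uncertainty(
    p$k9, c(p$k8, p$lambda5, p$lambda4, v[["PC"]], v[["GC"]]),
    c(sig("k8"), sig("lambda5"), sig("lambda4"), sv[["PC"]], sv[["GC"]]))
  c(k3 = s_k3, k7 = s_k7, k9 = s_k9)
}

# Numerical Jacobian of the residual vector in the free parameters.
.residual_jacobian <- function(par, config, targets, step = 1e-6) {
  n <- length(residual_vector(par, config, targets))
  J <- matrix(0, n, length(par), dimnames = list(NULL, names(par)))
  for (j in seq_along(par)) {
    h <- step * max(1, abs(par[j]))
    up <- dn <- par
    up[j] <- up[j] + h
    dn[j] <- max(dn[j] - h, 0)
    J[, j] <- (residual_vector(up, config, targets) -
                 residual_vector(dn, config, targets)) / (up[j] - dn[j])
  }
  J
}

#' Identifiability diagnosis at a fitted solution
#'
#' Singular-value decomposition of the numerical residual Jacobian at the
#' solution. The rank (at tolerance `tol` times the largest singular value)
#' counts the independently constrained parameter directions; right singular
#' vectors beyond the rank span the null space, i.e. directions along which
#' the parameters can move without changing any residual.
#'
#' @param fit a [fit_scenario()] result.
#' @param tol relative singular-value tolerance for the rank.
#' @return list with `rank`, `n_free`, `singular_values`, `null_space`
#'   (matrix, one column per flat direction) and `jacobian`.
#' @export
identifiability <- function(fit, tol = 1e-8) {
  J <- .residual_jacobian(fit$par, fit$config, fit$targets)
  sv <- svd(J)
  rank <- sum(sv$d > tol * sv$d[1])
  null_space <- sv$v[, seq_len(ncol(J)) > rank, drop = FALSE]
  rownames(null_space) <- names(fit$par)
  list(rank = rank, n_free = length(fit$par), singular_values = sv$d,
       null_space = null_space, jacobian = J)
}

#' Identifiable parameter combinations
#'
#' The steady-state constraints determine only certain combinations of the
#' rates, each the ratio controlling one compartment's steady level:
#' `omega_d` (via the transit-amplifying count), `k2/omega_e` (absorptive
#' progenitor), `k4/omega_m` (goblet/Paneth progenitor), `k6/lambda2`
#' (enteroendocrine), `k8/lambda4` (goblet) and `lambda1/k5` (enterocyte).
#' These six are invariant along the baseline solution manifold even though
#' individual rates — and the composite rates `omega_e`, `omega_s`,
#' `omega_m` themselves — are not: the manifold trades `k2` against
#' `omega_e` (and so on down the cascade) at fixed ratios.
#'
#' @param params a [rate_parameters()] object.
#' @return named numeric of the six combinations.
#' @export
identifiable_combinations <- function(params) {
  p <- as.list(unclass(params))
  om <- composite_rates(params)
  c(omega_d = om[["omega_d"]],
    k2_over_omega_e = p$k2 / om[["omega_e"]],
    k4_over_omega_m = p$k4 / om[["omega_m"]],
    k6_over_lambda2 = p$k6 / p$lambda2,
    k8_over_lambda4 = p$k8 / p$lambda4,
    lambda1_over_k5 = p$lambda1 / p$k5)
}

# Moore-Penrose pseudo-inverse via SVD.
.pinv <- function(A, tol = 1e-10) {
  s <- svd(A)
  keep <- s$d > tol * s$d[1]
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Delta-method uncertainty of the identifiable combinations
#'
#' Propagates the target-count uncertainties through the least-squares
#' estimator to the identifiable combinations:
#' `Cov = P J' S J P` with `P = (J'J)^+` the pseudo-inverse on the
#' identifiable subspace and `S` the diagonal of squared target sigmas, then
#' `sigma_g = sqrt(g' Cov g)` for each combination gradient `g`. Because the
#' combinations lie in the identified subspace, the pseudo-inverse is exact
#' for them despite the manifold.
#'
#' @param fit a [fit_scenario()] result.
#' @param target_sigmas named sigmas of the targets (defaults to the
#'   sigmas stored in the fit's targets).
#' @return named numeric sigma per combination.
#' @export
combination_uncertainty <- function(fit, target_sigmas = NULL) {
  if (is.null(target_sigmas))
    target_sigmas <- fit$targets$sigmas[fit$config$target_set]
  J <- fit$identifiability$jacobian
  sig <- rep(0, nrow(J))
  sig[seq_along(fit$config$target_set)] <-
    target_sigmas[fit$config$target_set]
  combo_of <- function(par) {
    identifiable_combinations(
      materialize_parameters(par, fit$config, fit$targets))
  }
  base <- combo_of(fit$par)
  G <- sapply(seq_along(fit$par), function(j) {
    h <- 1e-6 * max(1, abs(fit$par[j]))
    up <- dn <- fit$par
    up[j] <- up[j] + h
    dn[j] <- dn[j] - h
    (combo_of(up) - combo_of(dn)) / (2 * h)
  })  # n_combo x p
  P <- .pinv(crossprod(J))
  Cov <- P %*% t(J) %*% diag(sig^2) %*% J %*% P
  stats::setNames(sqrt(pmax(diag(G %*% Cov %*% t(G)), 0)), names(base))
}
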