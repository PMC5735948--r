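# Time courses, steady states and renewal times of the linear cascade.

#' Population state of the ten compartments
#'
#' Cell counts per crypt-villus unit for the ten compartments, optionally
#' tagged with the time (days) at which they hold. Counts are real-valued
#' (compartment averages), not integers.
#'
#' @param CBC,TAC,AP,EC,SP,EEC,TC,GPP,GC,PC non-negative cell counts.
#' @param t optional time tag (days).
#' @return object of class `population_state` (named numeric vector with a
#'   `t` attribute).
#' @export
population_state <- function(CBC, TAC, AP, EC, SP, EEC, TC, GPP, GC, PC,
                             t = NA_real_) {
  x <- c(CBC = CBC, TAC = TAC, AP = AP, EC = EC, SP = SP, EEC = EEC,
         TC = TC, GPP = GPP, GC = GC, PC = PC)
  if (anyNA(x) || any(x < 0))
    stop("all compartment counts must be non-negative", call. = FALSE)
  structure(x, t = t, class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  t <- attr(x, "t")
  cat("Cell counts per crypt-villus unit",
      if (!is.na(t)) sprintf("(t = %g days)", t), "\n")
  print(signif(unclass(x), 6))
  cat("total:", signif(sum(x), 6), "\n")
  invisible(x)
}

#' Right-hand side of the compartment ODE system
#'
#' Instantaneous rates of change (cells/day) of the ten compartments. The
#' stem compartment obeys `dCBC/dt = -(k1 - alpha) CBC`, so with
#' `k1 = alpha` the stem pool is constant; each downstream compartment gains
#' from its parent at the parent's differentiation rate and clears at its
#' composite (or terminal loss) rate.
#'
#' @param state a [population_state()] (or named numeric over the ten
#'   compartments).
#' @param params a [rate_parameters()] object.
#' @return named numeric vector of the ten derivatives (cells/day).
#' @export
ode_rhs <- function(state, params) {
  y <- as.list(unclass(state)[POP_NAMES])
  p <- as.list(unclass(params))
  with(c(y, p), c(
    CBC = -(k1 - alpha) * CBC,
    TAC = -(k2 + k3 - beta) * TAC + k1 * CBC,
    AP  = k2 * TAC - (k5 - gamma) * AP,
    EC  = k5 * AP - lambda1 * EC,
    SP  = k3 * TAC - (k4 + k6 + k7 - delta) * SP,
    EEC = k6 * SP - lambda2 * EEC,
    TC  = k7 * SP - lambda3 * TC,
    GPP = k4 * SP - (k8 + k9 - zeta) * GPP,
    GC  = k8 * GPP - lambda4 * GC,
    PC  = k9 * GPP - lambda5 * PC))
}

# Decay-rate chain for each downstream compartment, and the product of
# transfer rates feeding it. Each population is the terminal member of a
# linear cascade driven by the constant source k1 * CBC0.
.chains <- function(p, om) {
  list(
    TAC = list(trans = 1,                  mu = c(om[["omega_d"]])),
    AP  = list(trans = p$k2,               mu = c(om[["omega_d"]], om[["omega_e"]])),
    EC  = list(trans = p$k2 * p$k5,        mu = c(om[["omega_d"]], om[["omega_e"]], p$lambda1)),
    SP  = list(trans = p$k3,               mu = c(om[["omega_d"]], om[["omega_s"]])),
    EEC = list(trans = p$k3 * p$k6,        mu = c(om[["omega_d"]], om[["omega_s"]], p$lambda2)),
    TC  = list(trans = p$k3 * p$k7,        mu = c(om[["omega_d"]], om[["omega_s"]], p$lambda3)),
    GPP = list(trans = p$k3 * p$k4,        mu = c(om[["omega_d"]], om[["omega_s"]], om[["omega_m"]])),
    GC  = list(trans = p$k3 * p$k4 * p$k8, mu = c(om[["omega_d"]], om[["omega_s"]], om[["omega_m"]], p$lambda4)),
    PC  = list(trans = p$k3 * p$k4 * p$k9, mu = c(om[["omega_d"]], om[["omega_s"]], om[["omega_m"]], p$lambda5)))
}

# Perturb near-coincident (or near-zero) decay rates so the partial-fraction
# denominators stay finite. The relative error introduced is bounded by the
# bump size and is checked against the numerical integrator in the tests.
.separate_rates <- function(mu, rel_tol = 1e-9, bump = 1e-7, quiet = FALSE) {
  bumped <- FALSE
  eps0 <- 1e-12
  if (any(abs(mu) < eps0)) {
    mu[abs(mu) < eps0] <- eps0
    bumped <- TRUE
  }
  repeat {
    done <- TRUE
    for (i in seq_along(mu)) for (j in seq_along(mu)) {
      if (j <= i) next
      big <- max(abs(mu[i]), abs(mu[j]))
      if (abs(mu[i] - mu[j]) < rel_tol * big) {
        mu[j] <- mu[j] + bump * max(big, 1)
        bumped <- TRUE
        done <- FALSE
      }
    }
    if (done) break
  }
  if (bumped && !quiet)
    warning("near-coincident decay rates perturbed to evaluate the ",
            "closed-form solution; accuracy bounded by the perturbation",
            call. = FALSE)
  mu
}

# Constant-source cascade: population of the last compartment of a chain
# with decay rates mu, fed at constant rate `inflow` through the chain.
.cascade <- function(inflow, mu, t) {
  s <- rep(1 / prod(mu), length(t))
  for (i in seq_along(mu)) {
    denom <- mu[i] * prod(mu[-i] - mu[i])
    s <- s - exp(-mu[i] * t) / denom
  }
  inflow * s
}

.closed_form_matrix <- function(params, CBC0, t, quiet = FALSE) {
  p <- as.list(unclass(params))
  if (abs(p$k1 - p$alpha) > 1e-12 * max(p$k1, 1))
    stop("closed-form solution requires k1 == alpha (constant stem pool); ",
         "use integrate_ode() for a non-steady stem compartment",
         call. = FALSE)
  om <- composite_rates(params)
  chains <- .chains(p, om)
  source_rate <- p$k1 * CBC0
  out <- matrix(0, nrow = length(t), ncol = 10,
                dimnames = list(NULL, POP_NAMES))
  out[, "CBC"] <- CBC0
  for (nm in names(chains)) {
    mu <- .separate_rates(chains[[nm]]$mu, quiet = quiet)
    out[, nm] <- .cascade(source_rate * chains[[nm]]$trans, mu, t)
  }
  out[t == 0, setdiff(POP_NAMES, "CBC")] <- 0  # exact, kills round-off
  # guard tiny negative round-off
  out[out < 0 & out > -1e-9] <- 0
  out
}

#' Closed-form population state at a time point
#'
#' Evaluates the analytic solution of the cascade (integrating-factor /
#' partial-fraction form) at time `t`. All compartments except the stem pool
#' start at zero; the stem pool is constant at `CBC0`. Requires
#' `k1 == alpha`.
#'
#' Near-coincident decay rates make the partial-fraction denominators
#' vanish; such rates are perturbed by a relative 1e-7 with a warning, which
#' bounds the error well below the integrator cross-check tolerance.
#'
#' @param params a [rate_parameters()] object.
#' @param CBC0 initial (and constant) stem-cell count per crypt-villus unit.
#' @param t time in days (scalar, >= 0).
#' @param quiet suppress the confluent-rate warning.
#' @return a [population_state()] at time `t`.
#' @export
closed_form_state <- function(params, CBC0 = 10, t, quiet = FALSE) {
  stopifnot(length(t) == 1)
  if (is.na(t) || t < 0) stop("t must be >= 0", call. = FALSE)
  m <- .closed_form_matrix(params, CBC0, t, quiet = quiet)
  do.call(population_state, c(as.list(m[1, ]), t = t))
}

#' Closed-form time course over a grid
#'
#' @inheritParams closed_form_state
#' @param t_grid sorted non-negative times (days).
#' @return data.frame with columns `t`, the ten compartments, and `total`.
#' @export
closed_form_timecourse <- function(params, CBC0 = 10, t_grid, quiet = FALSE) {
  if (is.unsorted(t_grid) || any(t_grid < 0))
    stop("t_grid must be sorted and non-negative", call. = FALSE)
  m <- .closed_form_matrix(params, CBC0, t_grid, quiet = quiet)
  data.frame(t = t_grid, m, total = rowSums(m))
}

#' Numerical integration of the compartment ODEs
#'
#' Solves the ten-compartment system with `deSolve::ode` (lsoda) from the
#' canonical initial state (all compartments zero except the stem pool at
#' `CBC0`). Serves as the numerical oracle for the closed forms and covers
#' the non-steady stem mode (`k1 != alpha`).
#'
#' @inheritParams closed_form_timecourse
#' @param rtol,atol integrator tolerances.
#' @return data.frame with columns `t`, the ten compartments, and `total`.
#' @export
integrate_ode <- function(params, CBC0 = 10, t_grid, rtol = 1e-9,
                          atol = 1e-12) {
  if (is.unsorted(t_grid) || any(t_grid < 0))
    stop("t_grid must be sorted and non-negative", call. = FALSE)
  y0 <- c(CBC = CBC0, TAC = 0, AP = 0, EC = 0, SP = 0, EEC = 0, TC = 0,
          GPP = 0, GC = 0, PC = 0)
  times <- t_grid
  prepend <- FALSE
  if (times[1] > 0) {  # deSolve needs the initial time on the grid
    times <- c(0, times)
    prepend <- TRUE
  }
  deriv <- function(t, y, parms) list(unname(ode_rhs(y, params)))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed", call. = FALSE)
  m <- as.data.frame(sol)
  if (prepend) m <- m[-1, , drop = FALSE]
  rownames(m) <- NULL
  names(m)[1] <- "t"
  m$total <- rowSums(m[POP_NAMES])
  m
}

#' Steady-state populations
#'
#' The long-time limits of the cascade: each compartment is the product of
#' its feed rate and the reciprocal of its clearance rate, chained from the
#' constant stem pool, e.g. `TAC = (k1/omega_d) CBC0`,
#' `EC = (k5/lambda1) AP`. Requires all four composite rates and all loss
#' rates to be positive.
#'
#' @inheritParams closed_form_state
#' @return a [population_state()] (time tag `Inf`).
#' @export
steady_state <- function(params, CBC0 = 10) {
  p <- as.list(unclass(params))
  om <- composite_rates(params)
  lam <- unlist(p[c("lambda1", "lambda2", "lambda3", "lambda4", "lambda5")])
  if (any(om <= 0) || any(lam <= 0))
    stop("no finite steady state: non-positive clearance rate(s): ",
         paste(c(attr(om, "nonpositive"), names(lam)[lam <= 0]),
               collapse = ", "), call. = FALSE)
  TAC <- p$k1 / om[["omega_d"]] * CBC0
  AP  <- p$k2 / om[["omega_e"]] * TAC
  EC  <- p$k5 / p$lambda1 * AP
  SP  <- p$k3 / om[["omega_s"]] * TAC
  EEC <- p$k6 / p$lambda2 * SP
  TC  <- p$k7 / p$lambda3 * SP
  GPP <- p$k4 / om[["omega_m"]] * SP
  GC  <- p$k8 / p$lambda4 * GPP
  PC  <- p$k9 / p$lambda5 * GPP
  population_state(CBC = CBC0, TAC = TAC, AP = AP, EC = EC, SP = SP,
                   EEC = EEC, TC = TC, GPP = GPP, GC = GC, PC = PC, t = Inf)
}

#' Time to reach a fraction of steady state
#'
#' Smallest time at which a selected population (or the total across all ten
#' compartments) first reaches `fraction` of its steady-state value, located
#' by bisection on the closed-form solution. Populations rise monotonically
#' from zero (the total from `CBC0`), so the first crossing is well defined;
#' if the fraction is already met at `t = 0`, zero is returned.
#'
#' @inheritParams closed_form_state
#' @param selector one of the compartment names or `"total"`.
#' @param fraction target fraction of the steady-state value, in (0, 1).
#' @param horizon search horizon (days).
#' @param tol bisection tolerance (days).
#' @return time in days.
#' @export
renewal_time <- function(params, CBC0 = 10, selector = "total",
                         fraction = 0.95, horizon = 10000, tol = 1e-3) {
  selector <- match.arg(selector, c("total", POP_NAMES))
  if (fraction <= 0 || fraction >= 1)
    stop("fraction must lie in (0, 1)", call. = FALSE)
  inf <- steady_state(params, CBC0)
  target <- fraction * if (selector == "total") sum(inf) else inf[[selector]]
  value_at <- function(t) {
    m <- .closed_form_matrix(params, CBC0, t, quiet = TRUE)
    if (selector == "total") sum(m[1, ]) else m[1, selector]
  }
  if (value_at(0) >= target) return(0)
  if (value_at(horizon) < target)
    stop(sprintf("%s does not reach %.3g of steady state within %g days",
                 selector, fraction, horizon), call. = FALSE)
  lo <- 0
  hi <- horizon
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (value_at(mid) >= target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}
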