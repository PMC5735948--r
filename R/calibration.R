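# Assembly of steady-state calibration targets per crypt-villus unit.

#' Crypt-villus unit composition
#'
#' Accounting unit for cell counts: one villus plus its average share of the
#' surrounding crypts. In murine ileum a hexagonal crypt/villus packing
#' gives each villus, on average, two complete crypt contributions.
#'
#' @param cells_per_crypt cells in one crypt.
#' @param villus_cells cells on one villus.
#' @param crypts_per_villus average complete crypts contributing per villus.
#' @return object of class `cvu_composition` with fields `N_c` (crypt cells
#'   per unit), `N_v` (villus cells per unit) and `N = N_c + N_v`.
#' @export
cvu_composition <- function(cells_per_crypt = 250, villus_cells = 3500,
                            crypts_per_villus = 2) {
  stopifnot(cells_per_crypt > 0, villus_cells > 0, crypts_per_villus > 0)
  N_c <- cells_per_crypt * crypts_per_villus
  structure(list(N_c = N_c, N_v = villus_cells, N = N_c + villus_cells,
                 crypts_per_villus = crypts_per_villus),
            class = "cvu_composition")
}

#' Literature inputs for the measured cell populations
#'
#' The measured abundances that calibrate the model, in their native units:
#' stem cells, transit-amplifying cells and Paneth cells are reported per
#' crypt (converted with the crypts-per-villus factor); enteroendocrine,
#' tuft and goblet cells as fractions of the total cell count per unit.
#' Uncertainties are one standard deviation where the source reports one,
#' and zero otherwise.
#'
#' @return data.frame with columns `population`, `value`, `uncertainty`,
#'   `basis` (`"per_crypt"` or `"fraction"`).
#' @export
literature_inputs <- function() {
  data.frame(
    population  = c("CBC0", "TAC", "EEC", "TC", "GC", "PC"),
    value       = c(5, 155, 0.01, 0.004, 0.085, 40),
    uncertainty = c(1, 5, 0, 0, 0.015, 10),
    basis       = c("per_crypt", "per_crypt", "fraction", "fraction",
                    "fraction", "per_crypt"),
    stringsAsFactors = FALSE)
}

.new_targets <- function(values, sigmas, phi = NA_real_, N = NA_real_) {
  structure(list(values = values, sigmas = sigmas, phi = phi, N = N),
            class = "steady_state_targets")
}

#' @export
print.steady_state_targets <- function(x, ...) {
  cat("Steady-state targets (cells per crypt-villus unit):\n")
  df <- data.frame(value = x$values, uncertainty = x$sigmas)
  print(signif(df, 6))
  if (!is.na(x$phi)) cat("phi:", signif(x$phi, 6), "\n")
  if (!is.na(x$N)) cat("N:", x$N, "\n")
  invisible(x)
}

#' Assemble steady-state targets per crypt-villus unit
#'
#' Converts literature inputs to cells per crypt-villus unit: per-crypt
#' values are multiplied by the crypts-per-villus factor, fractional
#' abundances by the total cell count `N`. Uncertainties scale identically.
#' Progenitor compartments (AP, SP, GPP) and enterocytes remain unfilled
#' until [estimate_progenitors()] and [enterocyte_target()] run.
#'
#' @param inputs data.frame as returned by [literature_inputs()].
#' @param comp a [cvu_composition()].
#' @return object of class `steady_state_targets` holding named `values` and
#'   `sigmas` vectors (cells per crypt-villus unit) and `N`.
#' @export
assemble_cvu_targets <- function(inputs = literature_inputs(),
                                 comp = cvu_composition()) {
  required <- c("CBC0", "TAC", "EEC", "TC", "GC", "PC")
  missing <- setdiff(required, inputs$population)
  if (length(missing))
    stop("missing required population(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  scale <- ifelse(inputs$basis == "per_crypt", comp$crypts_per_villus,
                  ifelse(inputs$basis == "fraction", comp$N, 1))
  values <- inputs$value * scale
  sigmas <- inputs$uncertainty * scale
  names(values) <- names(sigmas) <- inputs$population
  full <- c("CBC0", "TAC", "AP", "EC", "SP", "EEC", "TC", "GPP", "GC", "PC")
  v <- s <- stats::setNames(rep(NA_real_, length(full)), full)
  v[names(values)] <- values
  s[names(values)] <- sigmas
  .new_targets(v, s, N = comp$N)
}

#' Progenitor proportionality constant
#'
#' Each unobserved progenitor pool is assumed proportional to the total
#' steady-state population of its progeny, with one shared proportionality
#' constant `phi` anchored to the observed goblet/Paneth progenitor
#' abundance: `phi = f_GPP * N / (GC + PC)`.
#'
#' @param f_GPP goblet/Paneth progenitor abundance as a fraction of `N`.
#' @param GC_inf,PC_inf goblet and Paneth steady-state counts per unit.
#' @param N total cells per crypt-villus unit.
#' @return `phi` (dimensionless).
#' @export
compute_phi <- function(f_GPP, GC_inf, PC_inf, N) {
  if (GC_inf + PC_inf <= 0)
    stop("GC_inf + PC_inf must be positive", call. = FALSE)
  f_GPP * N / (GC_inf + PC_inf)
}

#' Fill in the unobserved progenitor targets
#'
#' `GPP = phi (GC + PC)`; the secretory progenitor feeds the
#' enteroendocrine, tuft and goblet/Paneth branches, so
#' `SP = phi [EEC + TC + (1 + phi)(GC + PC)]`. The absorptive progenitor
#' (`AP = phi EC`) is filled by [enterocyte_target()] once the enterocyte
#' count is known.
#'
#' @param targets a `steady_state_targets` object with the measured fields.
#' @param phi proportionality constant from [compute_phi()].
#' @return the targets with `GPP` and `SP` filled (and their `phi` stored).
#' @export
estimate_progenitors <- function(targets, phi) {
  v <- targets$values
  need <- c("EEC", "TC", "GC", "PC")
  if (anyNA(v[need]))
    stop("EEC, TC, GC and PC targets must be present", call. = FALSE)
  v[["GPP"]] <- phi * (v[["GC"]] + v[["PC"]])
  v[["SP"]]  <- phi * (v[["EEC"]] + v[["TC"]] +
                         (1 + phi) * (v[["GC"]] + v[["PC"]]))
  targets$values <- v
  s <- targets$sigmas
  gp2 <- s[["GC"]]^2 + s[["PC"]]^2
  targets$sigmas[["GPP"]] <- phi * sqrt(gp2)
  targets$sigmas[["SP"]] <- phi * sqrt(s[["EEC"]]^2 + s[["TC"]]^2 +
                                         (1 + phi)^2 * gp2)
  targets$phi <- phi
  targets
}

#' Enterocyte steady-state target by cell-count closure
#'
#' Enterocytes take up whatever the total `N` leaves after all other
#' compartments; eliminating `AP = phi EC` from the closure gives
#' `EC = [N - (CBC0 + TAC + SP + GPP + EEC + TC + GC + PC)] / (1 + phi)`.
#' The absorptive progenitor target is then `AP = phi EC`, and the ten
#' compartments sum exactly to `N`.
#'
#' @param targets a `steady_state_targets` object with all non-enterocyte
#'   fields except AP filled.
#' @param phi proportionality constant (defaults to the one stored by
#'   [estimate_progenitors()]).
#' @return the targets with `EC` and `AP` filled.
#' @export
enterocyte_target <- function(targets, phi = targets$phi) {
  v <- targets$values
  need <- c("CBC0", "TAC", "SP", "GPP", "EEC", "TC", "GC", "PC")
  if (anyNA(v[need]))
    stop("all non-enterocyte targets must be present", call. = FALSE)
  EC <- (targets$N - sum(v[need])) / (1 + phi)
  if (EC <= 0)
    stop("non-positive enterocyte target; inputs exceed N", call. = FALSE)
  v[["EC"]] <- EC
  v[["AP"]] <- phi * EC
  targets$values <- v
  targets$sigmas[c("EC", "AP")] <- c(0, 0)
  targets
}

#' One-shot calibration from literature inputs
#'
#' Assembles per-unit targets, computes `phi` from the goblet/Paneth
#' progenitor abundance, fills the progenitor estimates and closes the
#' enterocyte count.
#'
#' @inheritParams assemble_cvu_targets
#' @param f_GPP goblet/Paneth progenitor fractional abundance.
#' @param ec_sigma optional uncertainty to attach to the enterocyte target
#'   (quadrature of the component count uncertainties if `NULL`).
#' @return a completed `steady_state_targets` object.
#' @export
calibrate_targets <- function(inputs = literature_inputs(),
                              comp = cvu_composition(), f_GPP = 0.01,
                              ec_sigma = NULL) {
  tg <- assemble_cvu_targets(inputs, comp)
  phi <- compute_phi(f_GPP, tg$values[["GC"]], tg$values[["PC"]], comp$N)
  tg <- estimate_progenitors(tg, phi)
  tg <- enterocyte_target(tg)
  if (is.null(ec_sigma)) {
    comp_sig <- tg$sigmas[c("CBC0", "TAC", "SP", "GPP", "EEC", "TC",
                            "GC", "PC")]
    ec_sigma <- sqrt(sum(comp_sig^2)) / (1 + phi)
  }
  tg$sigmas[["EC"]] <- ec_sigma
  tg$sigmas[["AP"]] <- phi * ec_sigma
  tg
}

#' Tied rate constants from branching ratios
#'
#' At every branch point of the cascade the higher-subscripted rate is
#' expressed through the lower one and the steady-state ratio of the two
#' branch products: `k7 = k6 (lambda3/lambda2)(TC/EEC)`,
#' `k3 = k2 (omega_s/omega_e)(SP/AP)` and
#' `k9 = k8 (lambda5/lambda4)(PC/GC)`. Because `omega_s` contains `k7`,
#' `k7` is evaluated first.
#'
#' @param params a [rate_parameters()] object supplying the free rates
#'   (its `k3`, `k7`, `k9` entries are ignored and recomputed).
#' @param targets a completed `steady_state_targets` object.
#' @return named numeric vector `c(k3, k7, k9)` (day^-1).
#' @export
tied_rates <- function(params, targets) {
  p <- as.list(unclass(params))
  v <- targets$values
  if (anyNA(v[c("SP", "AP", "TC", "EEC", "PC", "GC")]))
    stop("targets must include SP, AP, TC, EEC, PC and GC", call. = FALSE)
  if (p$lambda2 <= 0 || p$lambda4 <= 0 || v[["EEC"]] <= 0 || v[["GC"]] <= 0)
    stop("zero denominator in tied-rate expressions", call. = FALSE)
  k7 <- p$k6 * (p$lambda3 / p$lambda2) * (v[["TC"]] / v[["EEC"]])
  omega_e <- p$k5 - p$gamma
  if (omega_e == 0) stop("omega_e must be nonzero", call. = FALSE)
  omega_s <- p$k4 + p$k6 + k7 - p$delta
  k3 <- p$k2 * (omega_s / omega_e) * (v[["SP"]] / v[["AP"]])
  k9 <- p$k8 * (p$lambda5 / p$lambda4) * (v[["PC"]] / v[["GC"]])
  c(k3 = k3, k7 = k7, k9 = k9)
}
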