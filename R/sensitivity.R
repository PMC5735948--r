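# Local sensitivity of the steady-state populations to the rate inputs.

#' Derivative matrix of steady-state populations
#'
#' Central-difference partial derivatives of the nine downstream
#' steady-state populations with respect to each of the nineteen rates,
#' every rate perturbed alone (the tied rates are treated as independent
#' inputs carrying their own uncertainty, not chain-ruled through their
#' defining relations). Step is `step * max(|r_j|, 1)` per input.
#'
#' @param params a [rate_parameters()] object with a finite steady state.
#' @param CBC0 stem-cell count per crypt-villus unit.
#' @param step relative central-difference step.
#' @return matrix `S` (9 populations x 19 rates), units cells per day^-1.
#' @export
sensitivity_matrix <- function(params, CBC0 = 10, step = 1e-6) {
  outputs <- setdiff(POP_NAMES, "CBC")
  base <- unclass(params)
  S <- matrix(NA_real_, length(outputs), length(RATE_NAMES),
              dimnames = list(outputs, RATE_NAMES))
  ss_of <- function(x) {
    pp <- structure(x, class = "rate_parameters")
    unclass(steady_state(pp, CBC0))[outputs]
  }
  for (j in RATE_NAMES) {
    h <- step * max(abs(base[[j]]), 1)
    up <- dn <- base
    up[[j]] <- up[[j]] + h
    dn[[j]] <- dn[[j]] - h
    f_up <- tryCatch(ss_of(up), error = function(e) NULL)
    f_dn <- tryCatch(ss_of(dn), error = function(e) NULL)
    if (is.null(f_up) || is.null(f_dn))
      stop("perturbing ", j, " destroys the steady state; reduce `step`",
           call. = FALSE)
    S[, j] <- (f_up - f_dn) / (2 * h)
  }
  S
}

#' Variance matrix from sensitivities and input uncertainties
#'
#' Element-wise `V_ij = S_ij^2 * sigma_j^2`: the contribution of input `j`'s
#' uncertainty to the variance of output `i`. Computed literally from the
#' derivative matrix; no normalization is applied, so the entries carry
#' cells^2 even though rankings within a row are unit-free.
#'
#' @param S derivative matrix from [sensitivity_matrix()].
#' @param sigma_r named numeric of per-rate uncertainties (day^-1), e.g.
#'   [baseline_sigmas()].
#' @return matrix `V`, same shape as `S`.
#' @export
variance_matrix <- function(S, sigma_r) {
  if (!all(colnames(S) %in% names(sigma_r)))
    stop("sigma_r must name every column of S", call. = FALSE)
  sig <- sigma_r[colnames(S)]
  V <- sweep(S^2, 2, sig^2, `*`)
  if (any(V < 0)) stop("negative variance element", call. = FALSE)
  V
}

#' Rank the inputs driving one output
#'
#' Inputs sorted by decreasing variance-matrix element in the row of the
#' requested output; ties are broken by the canonical rate order (`k1..k9`,
#' proliferation rates, loss rates).
#'
#' @param V variance matrix from [variance_matrix()].
#' @param output one of the nine downstream population names.
#' @return character vector of the input names, most influential first.
#' @export
rank_inputs <- function(V, output) {
  if (!output %in% rownames(V))
    stop("unknown output: ", output, call. = FALSE)
  row <- V[output, ]
  ord <- order(-row, match(names(row), RATE_NAMES))
  names(row)[ord]
}

#' Full sensitivity report
#'
#' Bundles the derivative matrix, variance matrix and per-output input
#' rankings at one parameter set.
#'
#' @inheritParams sensitivity_matrix
#' @param sigma_r per-rate uncertainties (day^-1).
#' @return object of class `sensitivity_report` with fields `S`, `V`,
#'   `sigma_r`, `rankings` (named list of character vectors).
#' @export
sensitivity_report <- function(params, CBC0 = 10,
                               sigma_r = baseline_sigmas(), step = 1e-6) {
  S <- sensitivity_matrix(params, CBC0, step)
  V <- variance_matrix(S, sigma_r)
  rankings <- lapply(stats::setNames(nm = rownames(V)),
                     function(out) rank_inputs(V, out))
  structure(list(S = S, V = V, sigma_r = sigma_r, rankings = rankings),
            class = "sensitivity_report")
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat("Sensitivity report: top-3 inputs per steady-state population\n")
  for (nm in names(x$rankings))
    cat(sprintf("  %-4s %s\n", nm,
                paste(x$rankings[[nm]][1:3], collapse = " > ")))
  invisible(x)
}
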