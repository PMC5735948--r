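# Flat-file interfaces: time-course CSV, parameter and target configs.

#' Write / read a time-course table
#'
#' CSV with fixed column order `t`, the ten compartments, `total`; one row
#' per grid point. Round-trips bit-identically through [read_timecourse()].
#'
#' @param tc data.frame as produced by [closed_form_timecourse()],
#'   [integrate_ode()] or [generate_timecourse()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_timecourse <- function(tc, path) {
  cols <- c("t", POP_NAMES, "total")
  stopifnot(all(cols %in% names(tc)))
  utils::write.csv(format(tc[cols], digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  utils::read.csv(path, colClasses = "numeric")
}

#' Write / read a rate-parameter configuration
#'
#' Flat YAML key-value file with keys `k1..k9`, `alpha`, `beta`, `gamma`,
#' `delta`, `zeta`, `lambda1..lambda5` and `CBC0`.
#'
#' @param params a [rate_parameters()] object.
#' @param CBC0 stem-cell count per crypt-villus unit.
#' @param path file path.
#' @return `path` invisibly (write); list with `params` and `CBC0` (read).
#' @export
write_parameters <- function(params, CBC0 = 10, path) {
  x <- c(as.list(unclass(params)), list(CBC0 = CBC0))
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_parameters
#' @param steady_state_mode logical; require `k1 == alpha` on read.
#' @export
read_parameters <- function(path, steady_state_mode = TRUE) {
  x <- yaml::read_yaml(path)
  CBC0 <- x$CBC0
  x$CBC0 <- NULL
  list(params = as_rate_parameters(x, steady_state_mode = steady_state_mode),
       CBC0 = CBC0)
}

#' Write / read calibrated steady-state targets
#'
#' JSON carrying the per-compartment values and uncertainties (cells per
#' crypt-villus unit), the progenitor constant `phi` and the total `N`.
#'
#' @param targets a `steady_state_targets` object.
#' @param path file path.
#' @return `path` invisibly (write); the targets object (read).
#' @export
write_targets <- function(targets, path) {
  jsonlite::write_json(
    list(values = as.list(targets$values), sigmas = as.list(targets$sigmas),
         phi = targets$phi, N = targets$N),
    path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_targets
#' @export
read_targets <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  .new_targets(unlist(x$values), unlist(x$sigmas),
               phi = if (is.null(x$phi)) NA_real_ else x$phi,
               N = if (is.null(x$N)) NA_real_ else x$N)
}

#' Read a literature-input configuration
#'
#' YAML mirror of the measured-abundance table: one entry per population
#' with `value`, `uncertainty`, `basis` (`per_crypt` or `fraction`) and an
#' optional `source` tag.
#'
#' @param path file path.
#' @return data.frame in the schema of [literature_inputs()].
#' @export
read_input_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(rbind, lapply(names(x), function(nm) {
    e <- x[[nm]]
    if (is.null(e$value) || is.null(e$basis))
      stop("input entry ", nm, " needs `value` and `basis`", call. = FALSE)
    data.frame(population = nm, value = e$value,
               uncertainty = if (is.null(e$uncertainty)) 0 else e$uncertainty,
               basis = e$basis, stringsAsFactors = FALSE)
  }))
}
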