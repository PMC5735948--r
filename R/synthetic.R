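# Synthetic calibration targets and time courses from known parameters.

#' Observation noise model
#'
#' @param kind `"none"`, `"multiplicative"` (gaussian, relative spread `cv`)
#'   or `"poisson"` (count noise, spread `sqrt(value)`).
#' @param cv coefficient of variation for multiplicative noise.
#' @param seed integer seed; identical seeds reproduce identical draws.
#' @return object of class `noise_model`.
#' @export
noise_model <- function(kind = c("none", "multiplicative", "poisson"),
                        cv = 0, seed = NULL) {
  kind <- match.arg(kind)
  if (cv < 0) stop("cv must be >= 0", call. = FALSE)
  structure(list(kind = kind, cv = cv, seed = seed), class = "noise_model")
}

# Apply the noise model to a vector of positive values; redraw any
# non-positive result (bounded attempts) to keep counts physical without
# silent truncation.
.apply_noise <- function(values, noise, max_attempts = 100) {
  if (noise$kind == "none") return(values)
  draw <- function(v) {
    switch(noise$kind,
           multiplicative = v * (1 + noise$cv * stats::rnorm(length(v))),
           poisson = stats::rpois(length(v), v))
  }
  out <- stats::setNames(draw(values), names(values))
  attempt <- 1
  while (any(out <= 0)) {
    if (attempt >= max_attempts)
      stop("could not draw positive targets in ", max_attempts,
           " attempts; reduce the noise level", call. = FALSE)
    bad <- out <= 0
    out[bad] <- draw(values[bad])
    attempt <- attempt + 1
  }
  out
}

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", globalenv())) {
      old <- get(".Random.seed", globalenv())
      on.exit(assign(".Random.seed", old, globalenv()))
    }
    set.seed(seed)
  }
  force(expr)
}

#' Generate synthetic steady-state targets
#'
#' Steady states of a known parameter set, perturbed by the noise model, in
#' the same container the calibration pipeline produces — so every fitting
#' and uncertainty stage can be exercised against a known truth. Reported
#' per-target uncertainty is `cv * value` (multiplicative) or `sqrt(value)`
#' (poisson). The generating truth is attached as attribute `truth`.
#'
#' @param true_params a [rate_parameters()] object (defaults to the
#'   published baseline set, a realistic regime).
#' @param CBC0 stem-cell count per crypt-villus unit.
#' @param noise a [noise_model()].
#' @return a `steady_state_targets` object with attribute `truth`.
#' @export
generate_targets <- function(true_params = params_baseline(), CBC0 = 10,
                             noise = noise_model("none")) {
  ss <- steady_state(true_params, CBC0)
  values <- unclass(ss)
  names(values)[names(values) == "CBC"] <- "CBC0"
  noisy <- .with_seed(noise$seed, .apply_noise(values, noise))
  sigmas <- switch(noise$kind,
                   none = values * 0,
                   multiplicative = noise$cv * values,
                   poisson = sqrt(values))
  tg <- .new_targets(noisy, sigmas, N = sum(values))
  attr(tg, "truth") <- list(params = true_params, CBC0 = CBC0,
                            noise = noise, clean = values)
  tg
}

#' Generate a synthetic time course
#'
#' Closed-form trajectories sampled on a grid with per-point noise, in the
#' same table schema as [closed_form_timecourse()].
#'
#' @inheritParams generate_targets
#' @param t_grid sorted non-negative times (days).
#' @return data.frame with columns `t`, the ten compartments, `total`, and
#'   attribute `truth`.
#' @export
generate_timecourse <- function(true_params = params_baseline(), CBC0 = 10,
                                t_grid, noise = noise_model("none")) {
  tc <- closed_form_timecourse(true_params, CBC0, t_grid)
  m <- as.matrix(tc[POP_NAMES])
  noisy <- .with_seed(noise$seed, {
    out <- m
    pos <- m > 0
    out[pos] <- .apply_noise(m[pos], noise)
    out
  })
  res <- data.frame(t = t_grid, noisy, total = rowSums(noisy))
  attr(res, "truth") <- list(params = true_params, CBC0 = CBC0,
                             noise = noise)
  res
}
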