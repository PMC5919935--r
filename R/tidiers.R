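#' Tidy an inversion result
#'
#' One row per free parameter: posterior mean on the natural scale, the
#' transformed-scale estimate and its approximate posterior sd.
#'
#' @param x An `inversion_result`.
#' @param ... Unused.
#' @return A tibble with columns `parameter`, `estimate`, `transformed`,
#'   `std_error`.
#' @export
tidy.inversion_result <- function(x, ...) {
  x$estimate[c("parameter", "estimate", "transformed", "std_error")]
}

#' One-row summary of an inversion result
#'
#' @inheritParams tidy.inversion_result
#' @return Tibble with `log_evidence`, `log_joint`, `n_params`, `n_obs`,
#'   `converged`.
#' @export
glance.inversion_result <- function(x, ...) {
  tibble::tibble(
    log_evidence = x$log_evidence,
    log_joint = x$log_joint,
    n_params = nrow(x$estimate),
    n_obs = x$n_obs,
    converged = isTRUE(x$diagnostics$converged)
  )
}

#' Tidy a Bayesian model selection result
#'
#' @param x A `bms_result`.
#' @param ... Unused.
#' @return The underlying tibble (`model`, `alpha`, `expected_frequency`,
#'   `exceedance_probability`).
#' @export
tidy.bms_result <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "bms_result")
  out
}

#' One-row summary of a Bayesian model selection result
#'
#' @inheritParams tidy.bms_result
#' @return Tibble with `n_models`, `n_agents`, `n_samples`, `best_model`,
#'   `best_xp`.
#' @export
glance.bms_result <- function(x, ...) {
  i <- which.max(x$exceedance_probability)
  tibble::tibble(
    n_models = nrow(x),
    n_agents = attr(x, "n_agents"),
    n_samples = attr(x, "n_samples"),
    best_model = x$model[i],
    best_xp = x$exceedance_probability[i]
  )
}

#' Tidy fitted NPM weights
#'
#' @param x An `npm_weights` object.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std_error`, `p_value`.
#' @export
tidy.npm_weights <- function(x, ...) x$coefficients
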