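#' Default priors for a model's parameters
#'
#' Each parameter gets an invertible transform to an unconstrained scale --
#' `log` for positives (`sigma`, `R`, `obs_sd`), `logit` for unit-interval
#' parameters (`gamma`, `c_g`, `c_l`), identity otherwise -- and a Gaussian
#' prior on that transformed scale (weakly informative: mean 0, sd 3).
#'
#' @param spec A [mood_spec()] or [choice_spec()].
#' @param mean,sd Prior mean and sd applied to every parameter on the
#'   transformed scale.
#' @return A tibble (class `prior_spec`) with columns `parameter`, `mean`,
#'   `sd`, `transform`, `fixed` (logical), `fixed_value`.
#' @export
default_priors <- function(spec, mean = 0, sd = 3) {
  pars <- if (inherits(spec, "mood_spec")) {
    mood_param_names(spec)
  } else if (inherits(spec, "choice_spec")) {
    choice_param_names(spec)
  } else {
    stop("spec must be a mood_spec or choice_spec", call. = FALSE)
  }
  out <- tibble::tibble(
    parameter = pars,
    mean = mean,
    sd = sd,
    transform = purrr::map_chr(pars, param_transform),
    fixed = FALSE,
    fixed_value = NA_real_
  )
  class(out) <- c("prior_spec", class(out))
  out
}

param_transform <- function(name) {
  if (name %in% c("sigma", "R", "obs_sd")) return("log")
  if (name %in% c("gamma", "c_g", "c_l")) return("logit")
  "identity"
}

#' Fix parameters at known values in a prior specification
#'
#' Fixed parameters are removed from the optimization and pinned at
#' `fixed_value` on the natural scale (useful for conjugate cross-checks and
#' profiling).
#'
#' @param priors A [default_priors()] tibble.
#' @param ... Named natural-scale values, e.g. `obs_sd = 1`.
#' @return The updated prior tibble.
#' @export
fix_params <- function(priors, ...) {
  vals <- list(...)
  for (nm in names(vals)) {
    i <- which(priors$parameter == nm)
    if (!length(i)) stop("unknown parameter: ", nm, call. = FALSE)
    priors$fixed[i] <- TRUE
    priors$fixed_value[i] <- vals[[nm]]
  }
  priors
}

to_unconstrained <- function(value, transform) {
  switch(transform,
         identity = value,
         log = log(value),
         logit = stats::qlogis(pmin(pmax(value, 1e-12), 1 - 1e-12)))
}

to_natural <- function(value, transform) {
  switch(transform,
         identity = value,
         log = exp(value),
         logit = stats::plogis(value))
}
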