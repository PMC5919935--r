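#' Subjective probability of hitting the force-target window
#'
#' The produced peak force is modelled as Gaussian around the required 25%
#' of maximal force with subjective sd `sigma`; the success probability is
#' the Gaussian mass inside the window `0.25 +/- size/2`:
#' `p_s = Phi((size/2)/sigma) - Phi(-(size/2)/sigma)`. Strictly increasing in
#' `size`, strictly decreasing in `sigma`.
#'
#' @param sigma Subjective motor sd (> 0); may be a vector (recycled).
#' @param size Target-window width, fraction of maximal force (> 0).
#' @return Success probability in (0, 1).
#' @export
#' @examples
#' prob_success(0.05, 0.10)  # ~0.6827
prob_success <- function(sigma, size) {
  if (any(sigma <= 0)) stop("sigma must be positive", call. = FALSE)
  z <- (size / 2) / sigma
  stats::pnorm(z) - stats::pnorm(-z)
}

#' Expected utility of accepting a prospect
#'
#' `U(accept) = p_s * k_g * Gain^c_g - (1 - p_s) * k_l * Loss^c_l`, with unit
#' exponents unless the spec includes curvature.
#'
#' @param params Named parameter list.
#' @param gain,loss Prospect amounts in euro.
#' @param p_s Success probability for the trial's target size.
#' @param spec A [choice_spec()] (normative family).
#' @param k_g,k_l Optional per-trial effective weights overriding
#'   `params$k_g` / `params$k_l` (used for neural-proxy modulation).
#' @return Numeric utility.
#' @export
utility_accept <- function(params, gain, loss, p_s, spec,
                           k_g = NULL, k_l = NULL) {
  if (is.null(k_g)) k_g <- params[["k_g"]]
  if (is.null(k_l)) k_l <- params[["k_l"]]
  if (isTRUE(spec$curvature)) {
    gain <- gain^params[["c_g"]]
    loss <- loss^params[["c_l"]]
  }
  p_s * k_g * gain - (1 - p_s) * k_l * loss
}

#' Expected utility of declining a prospect
#'
#' Same functional form as [utility_accept()] with gain and loss replaced by
#' the constant minimal stakes of 0.5 euro, using the trial's success
#' probability. Returns 0 when the spec omits the decline utility (it is then
#' absorbed by the constant bias `k0`).
#'
#' @inheritParams utility_accept
#' @param size Target-window width (used for `p_s` when not supplied).
#' @param p_s Optional precomputed success probability.
#' @return Numeric utility (0 when `include_decline_utility` is unset).
#' @export
utility_decline <- function(params, size, spec, p_s = NULL,
                            k_g = NULL, k_l = NULL) {
  if (!isTRUE(spec$include_decline_utility)) return(0 * size)
  if (is.null(p_s)) p_s <- prob_success(params[["sigma"]], size)
  utility_accept(params, gain = 0.5, loss = 0.5, p_s = p_s, spec = spec,
                 k_g = k_g, k_l = k_l)
}

#' Descriptive (regression-style) utility of a prospect
#'
#' A linear combination of the included regressors among the main effects
#' G, L, S and their products GL, GS, LS, GLS, with one free weight each
#' (raw, unstandardized products).
#'
#' @param params Named parameter list with a `w_<regressor>` weight for each
#'   included regressor (e.g. `w_g`, `w_gl`).
#' @param gain,loss,size Prospect dimensions.
#' @param spec A [choice_spec()] (descriptive family).
#' @return Numeric utility (0 for the empty regressor set).
#' @export
descriptive_utility <- function(params, gain, loss, size, spec) {
  terms <- list(G = gain, L = loss, S = size, GL = gain * loss,
                GS = gain * size, LS = loss * size, GLS = gain * loss * size)
  extra <- setdiff(grep("^w_", names(params), value = TRUE),
                   paste0("w_", tolower(spec$regressors)))
  if (length(extra)) {
    stop("weight(s) supplied for excluded regressor(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  u <- 0 * gain
  for (r in spec$regressors) {
    u <- u + params[[paste0("w_", tolower(r))]] * terms[[r]]
  }
  u
}

#' Apply neural-proxy modulation to choice parameters
#'
#' For each active modulation the effective per-trial parameter is scaled:
#' `k_g'(t) = k_g * (1 + k_mg * NPM(t))`, likewise `k_l'` and `sigma'`
#' (`sigma'` clamped to a floor of 1e-6); the additive modulation adds
#' `k_m0 * NPM(t)` to the utility difference.
#'
#' @param params Named parameter list.
#' @param npm Per-trial neural proxy for mood (finite numeric vector).
#' @param spec A [choice_spec()].
#' @return List with per-trial vectors `k_g`, `k_l`, `sigma`, `additive`.
#' @export
modulate_params <- function(params, npm, spec) {
  if (any(!is.finite(npm))) stop("npm must be finite", call. = FALSE)
  n <- length(npm)
  out <- list(k_g = rep(params[["k_g"]] %||% NA_real_, n),
              k_l = rep(params[["k_l"]] %||% NA_real_, n),
              sigma = rep(params[["sigma"]] %||% NA_real_, n),
              additive = rep(0, n))
  mods <- spec$modulations
  if ("gain" %in% mods) out$k_g <- out$k_g * (1 + params[["k_mg"]] * npm)
  if ("loss" %in% mods) out$k_l <- out$k_l * (1 + params[["k_ml"]] * npm)
  if ("sigma" %in% mods) {
    out$sigma <- pmax(out$sigma * (1 + params[["k_msigma"]] * npm), 1e-6)
  }
  if ("additive" %in% mods) out$additive <- params[["k_m0"]] * npm
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Acceptance probability of the motor challenge
#'
#' Softmax of the utility difference with constant bias and time drift:
#' `p(accept, t) = 1 / (1 + exp(-(U_accept - U_decline + k_t * t + k0)))`.
#' Neural-proxy modulations are applied per trial when the spec includes
#' them (then `npm` is required).
#'
#' @param table Trial table (or single-prospect tibble) with columns `gain`,
#'   `loss`, `size`, `trial`.
#' @param spec A [choice_spec()].
#' @param params Named parameter list.
#' @param npm Per-trial neural proxy for mood (required iff the spec has
#'   modulations).
#' @param k_g_series,k_l_series Optional per-trial effective weights used by
#'   the simulator's generative modulation path.
#' @param check Validate parameters against the spec (default TRUE; internal
#'   hot paths disable it).
#' @return Numeric vector of acceptance probabilities, strictly in (0, 1).
#' @export
accept_probability <- function(table, spec, params, npm = NULL,
                               k_g_series = NULL, k_l_series = NULL,
                               check = TRUE) {
  if (check) check_choice_params(spec, params)
  tt <- as.numeric(table$trial)
  additive <- 0
  sigma <- params[["sigma"]]
  kg <- k_g_series
  kl <- k_l_series
  if (length(spec$modulations)) {
    if (is.null(npm)) {
      stop("spec includes modulations but no npm series was supplied",
           call. = FALSE)
    }
    eff <- modulate_params(params, npm, spec)
    if (is.null(kg)) kg <- eff$k_g
    if (is.null(kl)) kl <- eff$k_l
    sigma <- eff$sigma
    additive <- eff$additive
  }
  if (spec$family == "normative") {
    p_s <- prob_success(sigma, table$size)
    ua <- utility_accept(params, table$gain, table$loss, p_s, spec,
                         k_g = kg, k_l = kl)
    ud <- utility_decline(params, table$size, spec, p_s = p_s,
                          k_g = kg, k_l = kl)
  } else {
    ua <- descriptive_utility(params, table$gain, table$loss, table$size, spec)
    ud <- 0
  }
  stats::plogis(ua - ud + additive + params[["k_t"]] * tt + params[["k0"]])
}

# utility of the option actually chosen (decline = 0.5 EUR stakes)
chosen_utility <- function(table, spec, params, choice) {
  p_s <- if (spec$family == "normative") {
    prob_success(params[["sigma"]], table$size)
  } else NULL
  if (spec$family == "normative") {
    ua <- utility_accept(params, table$gain, table$loss, p_s, spec)
    ud <- utility_accept(params, gain = 0.5, loss = 0.5, p_s = p_s, spec = spec)
  } else {
    ua <- descriptive_utility(params, table$gain, table$loss, table$size, spec)
    ud <- descriptive_utility(params, 0.5, 0.5, table$size, spec)
  }
  ifelse(choice == 1, ua, ud)
}

#' Bernoulli log-likelihood of observed accept/decline choices
#'
#' `sum(y log p + (1 - y) log(1 - p))` with probabilities from
#' [accept_probability()], clipped to `[eps, 1 - eps]` (default
#' `eps = 1e-10`) for numerical safety. Trials with missing choices are
#' skipped.
#'
#' @inheritParams accept_probability
#' @param eps Clipping bound away from 0 and 1.
#' @return Scalar log-likelihood.
#' @export
choice_loglik <- function(table, spec, params, npm = NULL, eps = 1e-10) {
  y <- table$choice
  ok <- !is.na(y)
  if (!any(ok)) return(0)
  p <- accept_probability(table, spec, params, npm = npm)
  p <- pmin(pmax(p, eps), 1 - eps)
  sum(y[ok] * log(p[ok]) + (1 - y[ok]) * log(1 - p[ok]))
}
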