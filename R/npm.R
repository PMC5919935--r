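#' Orthogonalize a signal with respect to nuisance series
#'
#' Returns the OLS residual of `signal` regressed on the nuisance columns
#' plus an intercept; the residual has (numerically) zero sample correlation
#' with every nuisance column. Rank-deficient nuisance columns are dropped
#' with a message. An empty nuisance set just removes the mean.
#'
#' @param signal Numeric vector.
#' @param nuisance Numeric vector, matrix, or data frame of nuisance series
#'   (may be NULL/empty).
#' @return Numeric residual vector of the same length.
#' @export
orthogonalize <- function(signal, nuisance = NULL) {
  n <- length(signal)
  X <- matrix(1, n, 1)
  if (!is.null(nuisance)) {
    Z <- as.matrix(nuisance)
    if (nrow(Z) != n) stop("signal and nuisance lengths differ", call. = FALSE)
    X <- cbind(X, Z)
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    message("dropping ", ncol(X) - qr_x$rank,
            " rank-deficient nuisance column(s)")
  }
  as.numeric(qr.resid(qr_x, signal))
}

#' Fit the neural-proxy-for-mood (NPM) weights
#'
#' Regresses the theoretical mood level on the two ROI baseline series in a
#' single multiple regression, after residualizing: TML is orthogonalized
#' with respect to the trial index, and each ROI series with respect to the
#' global (whole-brain mean) signal. Optionally all three series are
#' additionally orthogonalized with respect to the previous trial's feedback
#' (+1/-1), the robustness variant that rules out feedback-evoked responses.
#'
#' @param table Trial table with `trial`, `vmpfc`, `ains`, `global`,
#'   `feedback` columns.
#' @param tml Per-trial theoretical mood level (from the best mood model).
#' @param orthogonalize_last_feedback Apply the last-feedback
#'   orthogonalization to TML and both ROI series? (default FALSE)
#' @return Object of class `npm_weights`: list with `beta_vmpfc`,
#'   `beta_ains`, the fitted `lm` summary tibble, and the recipe applied.
#' @export
fit_npm_weights <- function(table, tml,
                            orthogonalize_last_feedback = FALSE) {
  stopifnot(length(tml) == nrow(table))
  v <- orthogonalize(table$vmpfc, table$global)
  a <- orthogonalize(table$ains, table$global)
  y <- orthogonalize(tml, table$trial)
  recipe <- c("tml ~ resid(trial)", "roi ~ resid(global)")
  if (orthogonalize_last_feedback) {
    last_fb <- dplyr::lag(table$feedback, default = 0)
    v <- orthogonalize(v, last_fb)
    a <- orthogonalize(a, last_fb)
    y <- orthogonalize(y, last_fb)
    recipe <- c(recipe, "all ~ resid(last feedback)")
  }
  xtx_cond <- tryCatch(kappa(cbind(v, a), exact = TRUE), error = function(e) Inf)
  if (is.finite(xtx_cond) && xtx_cond > 1e6) {
    warning("ROI regressors are nearly collinear (condition number ",
            format(xtx_cond, digits = 3), ")", call. = FALSE)
  }
  if (stats::sd(a) == 0) {
    beta_a <- 0
    beta_v <- unname(stats::coef(stats::lm(y ~ v))[2])
    coefs <- tibble::tibble(term = c("vmpfc", "ains"),
                            estimate = c(beta_v, 0),
                            std_error = NA_real_, p_value = NA_real_)
  } else {
    fit <- stats::lm(y ~ v + a)
    sm <- summary(fit)$coefficients
    beta_v <- unname(sm["v", "Estimate"])
    beta_a <- unname(sm["a", "Estimate"])
    coefs <- tibble::tibble(
      term = c("vmpfc", "ains"),
      estimate = c(beta_v, beta_a),
      std_error = sm[c("v", "a"), "Std. Error"],
      p_value = sm[c("v", "a"), "Pr(>|t|)"]
    )
  }
  structure(list(beta_vmpfc = beta_v, beta_ains = beta_a, coefficients = coefs,
                 recipe = recipe),
            class = "npm_weights")
}

#' @export
print.npm_weights <- function(x, ...) {
  cat("<npm_weights> beta_vmpfc = ", format(x$beta_vmpfc, digits = 4),
      ", beta_ains = ", format(x$beta_ains, digits = 4), "\n", sep = "")
  invisible(x)
}

#' Construct the per-trial neural proxy for mood
#'
#' `NPM(t) = beta_vmpfc * vmpfc(t) + beta_ains * ains(t)`: a linear read-out
#' of mood from the two ROI baselines.
#'
#' @param weights An [fit_npm_weights()] result (or a list with
#'   `beta_vmpfc`, `beta_ains`).
#' @param vmpfc,ains Per-trial ROI baseline series.
#' @return Numeric NPM series.
#' @export
compute_npm <- function(weights, vmpfc, ains) {
  weights$beta_vmpfc * vmpfc + weights$beta_ains * ains
}

#' Regress the residual error of choice on a covariate, per agent
#'
#' The residual error of the fitted choice model (actual choice minus
#' predicted acceptance probability) is regressed on a per-trial covariate
#' (mood rating or NPM) separately per agent; the slopes are then tested at
#' the group level with [group_param_test()] (summary-statistics approach).
#'
#' @param tables List of trial tables.
#' @param spec,params_list Choice model and per-agent fitted parameter lists.
#' @param covariates List of per-trial covariate vectors (NA allowed; such
#'   trials are skipped).
#' @param npm_list Optional per-agent NPM series for the model predictions
#'   (modulated specs).
#' @return List with `slopes` tibble (`agent`, `slope`, `note`) and `test`
#'   (group-level test row).
#' @export
residual_choice_regression <- function(tables, spec, params_list, covariates,
                                       npm_list = NULL) {
  slopes <- purrr::map_dfr(seq_along(tables), function(a) {
    tab <- tables[[a]]
    npm <- if (!is.null(npm_list)) npm_list[[a]] else NULL
    p <- accept_probability(tab, spec, params_list[[a]], npm = npm)
    resid <- tab$choice - p
    x <- covariates[[a]]
    ok <- !is.na(x) & !is.na(resid)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0) {
      return(tibble::tibble(agent = a, slope = NA_real_,
                            note = "constant or insufficient covariate"))
    }
    tibble::tibble(agent = a,
                   slope = unname(stats::coef(stats::lm(resid[ok] ~ x[ok]))[2]),
                   note = NA_character_)
  })
  ok <- !is.na(slopes$slope)
  test <- if (sum(ok) >= 2) {
    group_param_test(slopes$slope)
  } else {
    tibble::tibble(n = sum(ok), mean = mean(slopes$slope[ok]), t = NA_real_,
                   df = NA_real_, p_t = NA_real_, v_wilcoxon = NA_real_,
                   p_wilcoxon = NA_real_,
                   note = "fewer than 2 agents with a defined slope")
  }
  list(slopes = slopes, test = test)
}

#' Fit neural-proxy-modulated choice models and compare them
#'
#' Inverts each modulation variant of the base choice model on every agent,
#' driven by the supplied per-agent proxy series (the NPM, or a single ROI's
#' baseline), then runs random-effects model selection over the variants and
#' group tests on the modulation weights of the full-modulation variant.
#'
#' @param tables List of trial tables.
#' @param base_spec Unmodulated base [choice_spec()].
#' @param proxy_list List of per-agent per-trial proxy series.
#' @param modulation_sets List of character vectors, one per candidate
#'   model, each a subset of `c("gain","loss","sigma","additive")`; default
#'   all 16 subsets.
#' @param seed Base seed.
#' @param ... Passed to [invert_model()].
#' @return List with `evidence` (long tibble incl. fits), `bms`, `winner`,
#'   and `group_tests` on every modulation weight that appears in any model
#'   (taken from the richest fitted variant containing it).
#' @export
fit_modulated_models <- function(tables, base_spec, proxy_list,
                                 modulation_sets = NULL, seed = 1L, ...) {
  if (is.null(modulation_sets)) {
    modulation_sets <- enumerate_npm_models(base_spec)$modulations
  }
  specs <- purrr::map(modulation_sets, function(m) {
    s <- base_spec
    s$modulations <- m
    s
  })
  models <- tibble::tibble(
    model = purrr::map_chr(specs, choice_model_label),
    spec = specs
  )
  evidence <- fit_cohort(tables, models, npm_list = proxy_list, seed = seed, ...)
  bms <- group_bms(evidence[c("agent", "model", "log_evidence")], seed = seed)
  winner <- bms$model[which.max(bms$exceedance_probability)]

  mod_par <- c(gain = "k_mg", loss = "k_ml", sigma = "k_msigma",
               additive = "k_m0")
  sizes <- purrr::map_int(modulation_sets, length)
  group_tests <- purrr::map_dfr(unique(unlist(modulation_sets)), function(m) {
    cand <- which(purrr::map_lgl(modulation_sets, ~ m %in% .x))
    pick <- cand[which.max(sizes[cand])]
    fits <- evidence$fit[evidence$model == models$model[[pick]]]
    vals <- purrr::map_dbl(fits, ~ posterior_params(.x)[[mod_par[[m]]]])
    dplyr::mutate(group_param_test(vals),
                  parameter = mod_par[[m]], from_model = models$model[[pick]],
                  .before = 1)
  })
  list(evidence = evidence, bms = bms, winner = winner,
       group_tests = group_tests, models = models)
}

#' Covariate effect on acceptance, on all trials and on uncertain trials
#'
#' Splits trials into `n_bins` covariate bins and reports the acceptance-rate
#' difference between the top and bottom bin, computed on all trials and
#' again restricted to trials whose model-predicted acceptance probability
#' lies inside `band` (default `[1/6, 5/6]`, i.e. trials not strongly
#' determined by the task factors).
#'
#' @param table Trial table with `choice`.
#' @param spec,params Fitted base choice model used for the band restriction.
#' @param covariate Per-trial covariate (e.g. NPM or mood rating).
#' @param band Acceptance-probability band for the restricted analysis.
#' @param n_bins Number of covariate bins (default 3, i.e. tertiles).
#' @return One-row tibble: `effect_all`, `effect_restricted`, `n_all`,
#'   `n_restricted` (effects are top-minus-bottom-bin acceptance rates; NA
#'   with a message when a band is empty).
#' @export
restricted_trial_effect <- function(table, spec, params, covariate,
                                    band = c(1 / 6, 5 / 6), n_bins = 3) {
  p <- accept_probability(table, spec, params)
  eff <- function(keep) {
    x <- covariate[keep]; y <- table$choice[keep]
    if (sum(keep) < n_bins || length(unique(x)) < n_bins) return(NA_real_)
    bins <- cut(x, breaks = stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1)),
                include.lowest = TRUE, labels = FALSE)
    mean(y[bins == n_bins]) - mean(y[bins == 1])
  }
  all_keep <- !is.na(covariate) & !is.na(table$choice)
  restr <- all_keep & p >= band[1] & p <= band[2]
  if (!any(restr)) message("restricted band is empty; effect not computable")
  tibble::tibble(
    effect_all = eff(all_keep),
    effect_restricted = eff(restr),
    n_all = sum(all_keep),
    n_restricted = sum(restr)
  )
}

#' Check for non-linear coupling between mood level and an ROI signal
#'
#' Regresses the ROI series on a polynomial expansion of TML (orthogonal
#' polynomials) and, separately, compares the linear slopes fitted above and
#' below the median TML (interaction test). Under a purely linear coupling
#' the higher-order terms and the slope difference are both null.
#'
#' @param tml Per-trial theoretical mood level.
#' @param roi Per-trial ROI series.
#' @param degree Polynomial degree (default 3).
#' @return List with `polynomial` (tidy coefficient tibble) and
#'   `median_split` (one-row tibble: slopes below/above the median and the
#'   interaction p-value).
#' @export
nonlinearity_check <- function(tml, roi, degree = 3) {
  stopifnot(length(tml) == length(roi))
  fit <- stats::lm(roi ~ stats::poly(tml, degree))
  sm <- summary(fit)$coefficients
  polynomial <- tibble::tibble(
    order = 0:degree,
    estimate = unname(sm[, "Estimate"]),
    std_error = unname(sm[, "Std. Error"]),
    p_value = unname(sm[, "Pr(>|t|)"])
  )
  hi <- tml > stats::median(tml)
  fit2 <- stats::lm(roi ~ tml * hi)
  co <- summary(fit2)$coefficients
  slope_lo <- unname(co["tml", "Estimate"])
  slope_hi <- slope_lo + unname(co["tml:hiTRUE", "Estimate"])
  median_split <- tibble::tibble(
    slope_below = slope_lo,
    slope_above = slope_hi,
    difference = slope_hi - slope_lo,
    p_difference = unname(co["tml:hiTRUE", "Pr(>|t|)"])
  )
  list(polynomial = polynomial, median_split = median_split)
}
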