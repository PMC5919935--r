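#' Fit a set of models to every agent in a cohort
#'
#' Runs [invert_model()] for each agent x model combination and collects the
#' log evidences (and, optionally, the full inversion objects).
#'
#' @param tables List of trial tables, one per agent.
#' @param models Tibble with columns `model` and `spec` (as produced by
#'   [enumerate_mood_models()], [enumerate_choice_models()], or
#'   [enumerate_npm_models()]), or a single spec object.
#' @param npm_list Optional list of per-agent NPM series (for modulated
#'   choice models).
#' @param keep_fits Keep the full `inversion_result` objects? (default TRUE)
#' @param seed Base seed; agent/model inversions use offsets of it.
#' @param ... Passed to [invert_model()] (e.g. `n_starts`, `ratings`).
#' @return Tibble with columns `agent`, `model`, `log_evidence`,
#'   `converged`, and (if kept) a `fit` list-column.
#' @export
fit_cohort <- function(tables, models, npm_list = NULL, keep_fits = TRUE,
                       seed = 1L, ...) {
  if (!is.data.frame(models)) {
    lab <- if (inherits(models, "mood_spec")) mood_model_label(models)
           else choice_model_label(models)
    models <- tibble::tibble(model = lab, spec = list(models))
  }
  rows <- list()
  for (a in seq_along(tables)) {
    npm <- if (!is.null(npm_list)) npm_list[[a]] else NULL
    for (m in seq_len(nrow(models))) {
      spec <- models$spec[[m]]
      use_npm <- if (inherits(spec, "choice_spec") &&
                     length(spec$modulations)) npm else NULL
      fit <- invert_model(tables[[a]], spec, npm = use_npm,
                          seed = seed + 1000L * a + m, ...)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        agent = a, model = models$model[[m]],
        log_evidence = fit$log_evidence,
        converged = fit$diagnostics$converged,
        fit = if (keep_fits) list(fit) else list(NULL)
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  if (!keep_fits) out$fit <- NULL
  out
}

#' Parameter- and model-recovery study on synthetic cohorts
#'
#' Simulates a cohort from a known generating model, fits every model in
#' `models` to every agent, runs random-effects model selection, and
#' summarises (i) which model wins and with what exceedance probability and
#' (ii) how well the generating model's parameters are recovered
#' (truth-vs-estimate correlation and bias per parameter, plus group sign
#' tests).
#'
#' @param config A [task_config()].
#' @param truth_template An [agent_truth()] with population-mean parameters.
#' @param models Model tibble including the generating model.
#' @param n_agents Cohort size.
#' @param mood_sd,choice_sd Population sds passed to [gen_cohort()].
#' @param target `"mood"` or `"choice"`: which generative model is being
#'   recovered.
#' @param seed Integer seed for the whole study.
#' @param interpolate,zscore Rating preparation for mood fits.
#' @param ... Passed to [fit_cohort()] / [invert_model()].
#' @return List with `evidence` (long tibble), `bms` ([group_bms()] result),
#'   `winner`, `params` (truth vs estimate per agent for the generating
#'   model), `recovery` (per-parameter correlation and bias),
#'   `group_tests` (per-parameter [group_param_test()] rows), and `cohort`.
#' @export
recovery_study <- function(config, truth_template, models, n_agents = 23,
                           mood_sd = NULL, choice_sd = NULL,
                           target = c("mood", "choice"), seed = 1L,
                           interpolate = TRUE, zscore = TRUE, ...) {
  target <- match.arg(target)
  cohort <- gen_cohort(config, n_agents, truth_template,
                       mood_sd = mood_sd, choice_sd = choice_sd, seed = seed)
  gen_spec <- if (target == "mood") truth_template$mood_spec
              else truth_template$choice_spec
  gen_label <- if (target == "mood") mood_model_label(gen_spec)
               else choice_model_label(gen_spec)
  if (!gen_label %in% models$model) {
    stop("models must include the generating model (", gen_label, ")",
         call. = FALSE)
  }
  ratings_list <- if (target == "mood") {
    purrr::map(cohort$tables, prepare_ratings,
               interpolate = interpolate, zscore = zscore)
  } else NULL

  evidence <- if (target == "mood") {
    rows <- list()
    for (a in seq_along(cohort$tables)) {
      for (m in seq_len(nrow(models))) {
        fit <- invert_model(cohort$tables[[a]], models$spec[[m]],
                            ratings = ratings_list[[a]],
                            seed = seed + 1000L * a + m, ...)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          agent = a, model = models$model[[m]],
          log_evidence = fit$log_evidence,
          converged = fit$diagnostics$converged, fit = list(fit))
      }
    }
    dplyr::bind_rows(rows)
  } else {
    fit_cohort(cohort$tables, models, seed = seed, ...)
  }

  bms <- group_bms(evidence[c("agent", "model", "log_evidence")], seed = seed)
  winner <- bms$model[which.max(bms$exceedance_probability)]

  gen_fits <- evidence[evidence$model == gen_label, ]
  est <- purrr::map(gen_fits$fit, posterior_params)
  truth_params <- purrr::map(cohort$truths, function(tr) {
    if (target == "mood") tr$mood_params else tr$choice_params
  })
  par_names <- names(truth_params[[1]])
  params <- purrr::map_dfr(seq_len(n_agents), function(a) {
    tibble::tibble(agent = a, parameter = par_names,
                   truth = unlist(truth_params[[a]][par_names]),
                   estimate = unlist(est[[a]][par_names]))
  })
  recovery <- params |>
    dplyr::group_by(.data$parameter) |>
    dplyr::summarise(
      correlation = if (stats::sd(.data$truth) > 0 && stats::sd(.data$estimate) > 0)
        stats::cor(.data$truth, .data$estimate) else NA_real_,
      bias = mean(.data$estimate - .data$truth),
      .groups = "drop")
  group_tests <- params |>
    dplyr::group_by(.data$parameter) |>
    dplyr::reframe(group_param_test(.data$estimate))

  list(evidence = evidence, bms = bms, winner = winner,
       generating_model = gen_label, params = params, recovery = recovery,
       group_tests = group_tests, cohort = cohort, seed = seed)
}
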