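trial_columns_required <- c(
  "session", "trial", "trial_in_session", "difficulty", "accuracy_mean",
  "correct", "feedback", "gain", "loss", "size", "choice"
)
trial_columns_optional <- c(
  "mood_rating", "confidence_rating", "vmpfc", "ains", "global",
  "tml_true", "p_accept_true", "ev_choice"
)

#' Write / read a trial table as CSV
#'
#' The schema is a fixed, documented column order (required columns first,
#' then whichever optional columns are present); missing values are written
#' as empty fields. The round trip is lossless.
#'
#' @param table Trial table tibble.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the validated tibble.
#' @export
write_trials <- function(table, path) {
  missing <- setdiff(trial_columns_required, names(table))
  if (length(missing)) {
    stop("trial table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  cols <- c(trial_columns_required,
            intersect(trial_columns_optional, names(table)))
  readr::write_csv(table[cols], path, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  spec <- readr::cols(
    session = readr::col_integer(),
    trial = readr::col_integer(),
    trial_in_session = readr::col_integer(),
    difficulty = readr::col_character(),
    accuracy_mean = readr::col_double(),
    correct = readr::col_integer(),
    feedback = readr::col_integer(),
    gain = readr::col_double(),
    loss = readr::col_double(),
    size = readr::col_double(),
    choice = readr::col_integer(),
    .default = readr::col_double()
  )
  tab <- readr::read_csv(path, col_types = spec, na = "",
                         show_col_types = FALSE)
  probs <- readr::problems(tab)
  if (nrow(probs)) {
    stop("malformed trial table at line(s) ",
         paste(utils::head(unique(probs$row), 5), collapse = ", "),
         " of ", path, call. = FALSE)
  }
  missing <- setdiff(trial_columns_required, names(tab))
  if (length(missing)) {
    stop("trial table lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (is.unsorted(tab$trial, strictly = TRUE)) {
    stop("trial index must be strictly increasing", call. = FALSE)
  }
  if (any(tab$correct == 1 & tab$feedback == -1, na.rm = TRUE)) {
    stop("inconsistent rows: correct = 1 with negative feedback", call. = FALSE)
  }
  tab
}

#' Run the full analysis pipeline on a synthetic (or loaded) cohort
#'
#' Executes the stages in their scientific order: (1) simulate or load the
#' cohort; (2) fit the mood-model set to the (interpolated, z-scored) mood
#' ratings of every agent and select the best model by random-effects BMS;
#' (3) generate each agent's TML trajectory by applying the group-mean
#' posterior parameters of the winning mood model to that agent's own
#' feedback history; (4) fit the choice-model set and select the best choice
#' model; (5) NPM analysis: fit the NPM weights per agent from the ROI
#' proxies, build the NPM series, run the residual-choice regression and the
#' modulated-model comparison. Deterministic given the seeds in `config`.
#'
#' @param config List with elements `task` (a [task_config()]), `n_agents`,
#'   `truth` (an [agent_truth()] template used when simulating),
#'   `mood_models` / `choice_models` (model tibbles; defaults to the full
#'   families), `mood_sd` / `choice_sd` (population sds), `seed`, and
#'   logical toggles `fit_mood`, `fit_choice`, `npm_analysis`,
#'   `interpolate`, `zscore`, `orthogonalize_last_feedback`.
#' @param tables Optional list of pre-loaded trial tables (skips
#'   simulation).
#' @param ... Passed to [invert_model()] (e.g. `n_starts`).
#' @return A run report: list with one element per executed stage, the
#'   config, a config hash, and the package version. Skipped stages are
#'   absent.
#' @export
run_pipeline <- function(config, tables = NULL, ...) {
  defaults <- list(n_agents = 23, seed = 1L, fit_mood = TRUE,
                   fit_choice = TRUE, npm_analysis = TRUE,
                   interpolate = TRUE, zscore = TRUE,
                   orthogonalize_last_feedback = FALSE,
                   mood_sd = NULL, choice_sd = NULL)
  config <- utils::modifyList(defaults, config)
  report <- list(
    config = config[setdiff(names(config), c("truth", "mood_models",
                                             "choice_models", "task"))],
    config_hash = rlang::hash(config),
    version = as.character(utils::packageVersion("moodchoice"))
  )
  seed <- config$seed

  if (is.null(tables)) {
    if (is.null(config$task) || is.null(config$truth)) {
      stop("stage simulate: config needs `task` and `truth` (or pass tables)",
           call. = FALSE)
    }
    cohort <- gen_cohort(config$task, config$n_agents, config$truth,
                         mood_sd = config$mood_sd,
                         choice_sd = config$choice_sd, seed = seed)
    tables <- cohort$tables
    report$simulate <- list(n_agents = length(tables),
                            n_trials = nrow(tables[[1]]),
                            params = cohort$params)
  }
  n_agents <- length(tables)

  best_mood <- NULL
  tml_list <- NULL
  if (isTRUE(config$fit_mood)) {
    mood_models <- config$mood_models %||% enumerate_mood_models()
    ratings_list <- purrr::map(tables, prepare_ratings,
                               interpolate = config$interpolate,
                               zscore = config$zscore)
    rows <- list()
    for (a in seq_len(n_agents)) {
      for (m in seq_len(nrow(mood_models))) {
        fit <- invert_model(tables[[a]], mood_models$spec[[m]],
                            ratings = ratings_list[[a]],
                            seed = seed + 1000L * a + m, ...)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          agent = a, model = mood_models$model[[m]],
          log_evidence = fit$log_evidence, fit = list(fit))
      }
    }
    mood_evidence <- dplyr::bind_rows(rows)
    mood_bms <- group_bms(mood_evidence[c("agent", "model", "log_evidence")],
                          seed = seed)
    best_label <- mood_bms$model[which.max(mood_bms$exceedance_probability)]
    best_mood <- mood_models$spec[[match(best_label, mood_models$model)]]
    # group-mean posterior parameters, applied to each agent's own history
    best_fits <- mood_evidence$fit[mood_evidence$model == best_label]
    post <- purrr::map(best_fits, posterior_params)
    mean_params <- purrr::map(purrr::set_names(names(post[[1]])),
                              function(nm) mean(purrr::map_dbl(post, nm)))
    tml_list <- purrr::map(tables,
                           ~ compute_tml(.x, best_mood, mean_params)$tml)
    report$mood <- list(evidence = mood_evidence[c("agent", "model",
                                                   "log_evidence")],
                        bms = mood_bms, best_model = best_label,
                        group_mean_params = mean_params)
  }

  best_choice <- NULL
  choice_params_list <- NULL
  if (isTRUE(config$fit_choice)) {
    choice_models <- config$choice_models %||% enumerate_choice_models()
    choice_evidence <- fit_cohort(tables, choice_models, seed = seed + 7L, ...)
    choice_bms <- group_bms(
      choice_evidence[c("agent", "model", "log_evidence")], seed = seed)
    best_label <- choice_bms$model[which.max(choice_bms$exceedance_probability)]
    best_choice <- choice_models$spec[[match(best_label, choice_models$model)]]
    best_fits <- choice_evidence$fit[choice_evidence$model == best_label]
    choice_params_list <- purrr::map(best_fits, posterior_params)
    report$choice <- list(evidence = choice_evidence[c("agent", "model",
                                                       "log_evidence")],
                          bms = choice_bms, best_model = best_label,
                          params = choice_params_list)
  }

  if (isTRUE(config$npm_analysis)) {
    if (is.null(best_choice) || is.null(tml_list)) {
      stop("stage npm: requires the mood and choice stages", call. = FALSE)
    }
    if (!all(c("vmpfc", "ains") %in% names(tables[[1]])) ||
        all(is.na(tables[[1]]$vmpfc))) {
      report$npm <- list(skipped = "no ROI columns in the data")
    } else {
      weights <- purrr::map2(tables, tml_list, fit_npm_weights,
                             orthogonalize_last_feedback =
                               config$orthogonalize_last_feedback)
      npm_list <- purrr::map2(tables, weights,
                              ~ compute_npm(.y, .x$vmpfc, .x$ains))
      resid_reg <- residual_choice_regression(tables, best_choice,
                                              choice_params_list, npm_list)
      modulated <- fit_modulated_models(tables, best_choice, npm_list,
                                        seed = seed + 13L, ...)
      report$npm <- list(weights = weights, resid_regression = resid_reg,
                         modulated_bms = modulated$bms,
                         modulation_tests = modulated$group_tests)
    }
  }
  class(report) <- "moodchoice_report"
  report
}

#' @export
print.moodchoice_report <- function(x, ...) {
  cat("<moodchoice_report> stages:",
      paste(intersect(c("simulate", "mood", "choice", "npm"), names(x)),
            collapse = ", "), "\n")
  if (!is.null(x$mood)) cat("  best mood model:  ", x$mood$best_model, "\n")
  if (!is.null(x$choice)) cat("  best choice model:", x$choice$best_model, "\n")
  invisible(x)
}
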