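#' Task configuration for the quiz + choice paradigm
#'
#' Builds and validates the configuration describing one experiment:
#' session structure, quiz difficulty/bias plan, prospect levels, and the
#' sparse rating schedule. The default design mirrors the fMRI-style
#' experiment: sessions of 32 trials whose 18 middle trials form a biased
#' easy or hard episode, flanked by 7 unbiased medium-difficulty trials on
#' each side; gains and losses in 1--5 euro; target-window widths as
#' fractions of maximal force, centred on 25% of maximal force; one mood
#' (and confidence) rating every third trial.
#'
#' @param n_sessions Number of sessions.
#' @param trials_per_session Trials per session (default 32).
#' @param gain_levels Gain prospect levels in euro (default 1:5).
#' @param loss_levels Loss prospect levels in euro (default 1:5).
#' @param size_levels Target-window widths (fraction of maximal force).
#'   Must be positive; windows are centred on 0.25 of maximal force.
#' @param bias_plan Tibble with columns `session`, `difficulty`
#'   (`"easy"|"medium"|"hard"`, applied to the middle trials) and `bias`
#'   (proportion of wrong answers that nevertheless receive positive
#'   feedback, in `[0, 0.5]`). Defaults to alternating easy (bias 0.4) and
#'   hard (bias 0.1) sessions.
#' @param accuracy_means Named numeric vector giving the cohort mean correct
#'   rate per difficulty level; used both to draw correct answers and as the
#'   expectation entering `EV_quiz = 2 * accuracy - 1`.
#' @param edge_unbiased Number of leading and trailing trials per session
#'   that are always medium difficulty with zero feedback bias (default 7).
#' @param rating_period Trials between successive ratings (default 3).
#' @param first_rated_trial Within-session index of the first rated trial
#'   (default 2).
#'
#' @return An object of class `task_config` (a named list).
#' @export
#' @examples
#' cfg <- task_config(n_sessions = 4)
#' cfg$trials_per_session
task_config <- function(n_sessions = 8,
                        trials_per_session = 32,
                        gain_levels = 1:5,
                        loss_levels = 1:5,
                        size_levels = seq(0.05, 0.25, length.out = 5),
                        bias_plan = NULL,
                        accuracy_means = c(easy = 0.8, medium = 0.6, hard = 0.35),
                        edge_unbiased = 7,
                        rating_period = 3,
                        first_rated_trial = 2) {
  stopifnot(n_sessions >= 1, trials_per_session >= 1)
  if (any(gain_levels <= 0) || any(loss_levels <= 0)) {
    stop("gain and loss levels must be positive", call. = FALSE)
  }
  if (any(size_levels <= 0)) {
    stop("target-window sizes must be positive", call. = FALSE)
  }
  if (is.null(bias_plan)) {
    bias_plan <- default_bias_plan(n_sessions)
  }
  bias_plan <- tibble::as_tibble(bias_plan)
  needed <- c("session", "difficulty", "bias")
  if (!all(needed %in% names(bias_plan))) {
    stop("bias_plan needs columns: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  if (any(bias_plan$bias < 0 | bias_plan$bias > 0.5)) {
    stop("biased-feedback proportion must lie in [0, 0.5]", call. = FALSE)
  }
  if (!all(bias_plan$difficulty %in% names(accuracy_means))) {
    stop("every bias_plan difficulty needs an entry in accuracy_means", call. = FALSE)
  }
  if (nrow(bias_plan) != n_sessions) {
    stop("bias_plan must have one row per session", call. = FALSE)
  }
  if (2 * edge_unbiased > trials_per_session) {
    stop("edge_unbiased trials exceed the session length", call. = FALSE)
  }
  structure(
    list(
      n_sessions = as.integer(n_sessions),
      trials_per_session = as.integer(trials_per_session),
      gain_levels = as.numeric(gain_levels),
      loss_levels = as.numeric(loss_levels),
      size_levels = as.numeric(size_levels),
      bias_plan = bias_plan,
      accuracy_means = accuracy_means,
      edge_unbiased = as.integer(edge_unbiased),
      rating_period = as.integer(rating_period),
      first_rated_trial = as.integer(first_rated_trial)
    ),
    class = "task_config"
  )
}

#' Default session-level difficulty and feedback-bias plan
#'
#' Alternates easy and hard episodes across sessions, with more feedback bias
#' in easy sessions (the easier the questions, the more biased the feedback),
#' so that sessions form clearly positive and clearly negative mood-induction
#' episodes.
#'
#' @param n_sessions Number of sessions.
#' @return Tibble with columns `session`, `difficulty`, `bias`.
#' @export
default_bias_plan <- function(n_sessions) {
  difficulty <- rep(c("easy", "hard"), length.out = n_sessions)
  tibble::tibble(
    session = seq_len(n_sessions),
    difficulty = difficulty,
    bias = ifelse(difficulty == "easy", 0.4, 0.1)
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> ", x$n_sessions, " sessions x ", x$trials_per_session,
      " trials (", x$n_sessions * x$trials_per_session, " total)\n", sep = "")
  cat("  gains: ", paste(x$gain_levels, collapse = ", "),
      " EUR; losses: ", paste(x$loss_levels, collapse = ", "), " EUR\n", sep = "")
  cat("  sizes: ", paste(signif(x$size_levels, 3), collapse = ", "),
      " (fraction of max force)\n", sep = "")
  cat("  rating every ", x$rating_period, " trials from within-session trial ",
      x$first_rated_trial, "\n", sep = "")
  invisible(x)
}
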