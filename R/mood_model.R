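#' Code objective feedback, allowing asymmetric impact of wins
#'
#' Positive feedback is coded as `R` (a free positive magnitude) when the
#' model is asymmetric, otherwise as 1; negative feedback is always -1.
#'
#' @param feedback Vector of +1/-1 objective feedback.
#' @param spec A [mood_spec()].
#' @param params Named parameter list (needs `R` when asymmetric).
#' @return Numeric vector of coded feedback.
#' @export
code_feedback <- function(feedback, spec, params) {
  if (!all(feedback %in% c(-1, 1))) {
    stop("feedback must be +1 or -1", call. = FALSE)
  }
  pos <- if (isTRUE(spec$asymmetric)) params[["R"]] else 1
  ifelse(feedback > 0, pos, -1)
}

#' Subjective perception of feedback under reciprocal mood influence
#'
#' `F(t) = coded_feedback(t) + delta * TML(t-1)`: a better prior mood makes
#' any feedback feel better ("rosy outlook"); the effect is additive so a
#' negative feedback is not perceived as worse in a good mood.
#'
#' @param coded Coded feedback value(s).
#' @param tml_prev TML carried from the previous trial, before updating.
#' @param params Named parameter list with `delta` (0 disables the effect).
#' @return Numeric subjective feedback F.
#' @export
subjective_feedback <- function(coded, tml_prev, params) {
  delta <- params[["delta"]]
  if (is.null(delta)) delta <- 0
  coded + delta * tml_prev
}

#' Compute the theoretical mood level (TML) trajectory
#'
#' Implements the leaky-integration mood model
#' \deqn{TML(t) = \omega_0 + \omega_{q1} \sum_{j=1}^{t} \gamma^{t-j} EV_{quiz}(j)
#'  + \omega_{q2} \sum_{j=1}^{t} \gamma^{t-j} RPE_{quiz}(j)
#'  + \omega_p \sum_{j=1}^{t} \gamma^{t-j} EV_{choice}(j) + \omega_t t}
#' with `EV_quiz = 2 * accuracy_mean - 1`,
#' `RPE_quiz(t) = F(t) - EV_quiz(t)` and subjective feedback
#' `F(t) = coded_feedback(t) + delta * TML(t-1)` (TML(0) = 0). The simplified
#' variant collapses the two quiz terms into `omega_f * sum gamma^(t-j) F(j)`.
#' Decaying sums are evaluated by the linear recursion
#' `S(t) = gamma * S(t-1) + x(t)` (via [stats::filter()]), which equals the
#' explicit weighted sum.
#'
#' @param table Trial table with columns `trial`, `feedback`, and
#'   `accuracy_mean` (quiz sources) / `ev_choice` (choice sources).
#' @param spec A [mood_spec()].
#' @param params Named parameter list (see [mood_param_names()]).
#' @return Tibble (mood trace) with columns `trial`, `ev_quiz`, `rpe_quiz`,
#'   `ev_choice`, `f`, `tml`; class `mood_trace`.
#' @export
compute_tml <- function(table, spec, params) {
  check_mood_params(spec, params)
  compute_tml_impl(table, spec, params)
}

compute_tml_impl <- function(table, spec, params) {
  n <- nrow(table)
  tt <- as.numeric(table$trial)
  ev_choice <- rep(NA_real_, n)
  if (mood_uses_choice(spec)) {
    if (is.null(table$ev_choice)) {
      stop("source includes the choice task but the table has no ev_choice ",
           "column (see add_ev_choice())", call. = FALSE)
    }
    ev_choice <- as.numeric(table$ev_choice)
  }
  ev_quiz <- rep(NA_real_, n)
  feedback <- NULL
  if (mood_uses_quiz(spec)) {
    if (is.null(table$accuracy_mean) || anyNA(table$accuracy_mean)) {
      stop("quiz source requires an accuracy_mean column without missing values",
           call. = FALSE)
    }
    ev_quiz <- 2 * as.numeric(table$accuracy_mean) - 1
    feedback <- table$feedback
    if (!all(feedback %in% c(-1, 1))) {
      stop("feedback must be +1 or -1", call. = FALSE)
    }
  }
  tml <- tml_vector(tt, feedback, ev_quiz, ev_choice, spec, params)
  f <- rep(NA_real_, n)
  rpe <- rep(NA_real_, n)
  if (mood_uses_quiz(spec)) {
    coded <- code_feedback(feedback, spec, params)
    delta <- if (isTRUE(spec$reciprocal)) params[["delta"]] else 0
    f <- coded + delta * c(0, tml[-n])
    rpe <- f - ev_quiz
  }
  new_mood_trace(tt, ev_quiz, rpe, ev_choice, f, tml)
}

# fast vector core: TML only, no validation, no tibbles
tml_vector <- function(tt, feedback, ev_quiz, ev_choice, spec, params) {
  n <- length(tt)
  g <- function(nm) {
    v <- params[[nm]]
    if (is.null(v)) 0 else v
  }
  base <- g("omega0") + g("omega_t") * tt
  gamma <- g("gamma")
  wp <- g("omega_p")

  # choice-utility decaying sum: independent of TML, computable up front
  s_p <- if (mood_uses_choice(spec)) decaying_sum(ev_choice, gamma) else rep(0, n)

  if (!mood_uses_quiz(spec)) {
    return(base + wp * s_p)
  }
  pos <- if (isTRUE(spec$asymmetric)) g("R") else 1
  coded <- rep(-1, n)
  coded[feedback > 0] <- pos
  delta <- if (isTRUE(spec$reciprocal)) g("delta") else 0
  base_prev <- c(0, base[-n])           # TML(0) = 0
  s_p_prev <- c(0, s_p[-n])

  if (isTRUE(spec$simplified)) {
    wf <- g("omega_f")
    # S_F(t) = gamma S_F(t-1) + F(t), F(t) = coded(t) + delta TML(t-1)
    # TML(t-1) = base(t-1) + wf S_F(t-1) + wp S_P(t-1)  ==>
    # S_F(t) = (gamma + delta wf) S_F(t-1) + coded(t) + delta (base + wp S_P)(t-1)
    u <- coded + delta * (base_prev + wp * s_p_prev)
    s_f <- decaying_sum(u, gamma + delta * wf)
    base + wf * s_f + wp * s_p
  } else {
    w1 <- g("omega_q1"); w2 <- g("omega_q2")
    s_ev <- decaying_sum(ev_quiz, gamma)
    s_ev_prev <- c(0, s_ev[-n])
    # RPE(t) = F(t) - EV(t); S_R(t) = gamma S_R(t-1) + RPE(t)
    # TML(t-1) = base + w1 S_EV + w2 S_R + wp S_P (all at t-1)  ==>
    # S_R(t) = (gamma + delta w2) S_R(t-1)
    #        + coded(t) - EV(t) + delta (base + w1 S_EV + wp S_P)(t-1)
    u <- coded - ev_quiz + delta * (base_prev + w1 * s_ev_prev + wp * s_p_prev)
    s_r <- decaying_sum(u, gamma + delta * w2)
    base + w1 * s_ev + w2 * s_r + wp * s_p
  }
}

# S(t) = a * S(t-1) + x(t), S(0) = 0
decaying_sum <- function(x, a) {
  if (length(x) == 0) return(numeric(0))
  if (a == 0) return(as.numeric(x))
  .decay_filter(as.numeric(x), a)
}

new_mood_trace <- function(trial, ev_quiz, rpe_quiz, ev_choice, f, tml) {
  out <- tibble::tibble(trial = trial, ev_quiz = ev_quiz, rpe_quiz = rpe_quiz,
                        ev_choice = ev_choice, f = f, tml = tml)
  class(out) <- c("mood_trace", class(out))
  out
}

#' Append the chosen-option utility to a trial table
#'
#' `ev_choice(t)` is the expected utility of the option the agent actually
#' chose: the accept utility for accepted trials and the decline utility
#' (same form, 0.5 euro stakes) for declined ones. This is the quantity a
#' choice-source mood model integrates.
#'
#' @param table Trial table with `gain`, `loss`, `size`, `choice`.
#' @param choice_spec,choice_params The choice model generating the utility.
#' @return The table with an `ev_choice` column added.
#' @export
add_ev_choice <- function(table, choice_spec, choice_params) {
  table$ev_choice <- chosen_utility(table, choice_spec, choice_params,
                                    table$choice)
  table
}

#' Linearly interpolate sparse ratings to one value per trial
#'
#' Ratings between rated trials are linearly interpolated; before the first
#' and after the last rating the series is held constant. Original rated
#' values are preserved exactly.
#'
#' @param table Trial table with `trial` and a rating column.
#' @param column Name of the rating column (default `"mood_rating"`).
#' @return Numeric vector with one value per trial.
#' @export
interpolate_ratings <- function(table, column = "mood_rating") {
  y <- table[[column]]
  ok <- !is.na(y)
  if (sum(ok) < 2) {
    stop("need at least 2 rated trials to interpolate", call. = FALSE)
  }
  stats::approx(x = table$trial[ok], y = y[ok], xout = table$trial,
                method = "linear", rule = 2)$y
}

#' Prepare the rating series a mood model is fitted to
#'
#' Optionally interpolates ratings to one point per trial and z-scores the
#' resulting series (the default analysis path); with `interpolate = FALSE`
#' only the actually rated trials enter the likelihood (robustness path).
#'
#' @inheritParams interpolate_ratings
#' @param interpolate Interpolate to all trials? (default TRUE)
#' @param zscore Z-score the series? (default TRUE)
#' @return Numeric vector per trial, `NA` on trials excluded from the fit.
#' @export
prepare_ratings <- function(table, column = "mood_rating",
                            interpolate = TRUE, zscore = TRUE) {
  y <- if (interpolate) interpolate_ratings(table, column) else table[[column]]
  if (zscore) {
    mu <- mean(y, na.rm = TRUE)
    sd <- stats::sd(y, na.rm = TRUE)
    if (!is.na(sd) && sd > 0) y <- (y - mu) / sd else y <- y - mu
  }
  y
}

#' Gaussian log-likelihood of ratings under a mood model
#'
#' Ratings (raw or interpolated, typically z-scored) are modelled as TML plus
#' independent Gaussian observation noise of sd `obs_sd`; trials without a
#' rating value contribute nothing.
#'
#' @param table Trial table.
#' @param spec A [mood_spec()].
#' @param params Named parameter list including `obs_sd > 0`.
#' @param ratings Optional precomputed rating series (per trial, NA allowed);
#'   defaults to [prepare_ratings()] of the table.
#' @return Scalar log-likelihood.
#' @export
mood_loglik <- function(table, spec, params, ratings = NULL) {
  obs_sd <- params[["obs_sd"]]
  if (is.null(obs_sd) || obs_sd <= 0) stop("obs_sd must be positive", call. = FALSE)
  if (is.null(ratings)) ratings <- prepare_ratings(table)
  ok <- !is.na(ratings)
  if (!any(ok)) return(0)
  tml <- compute_tml(table, spec, params)$tml
  sum(stats::dnorm(ratings[ok], mean = tml[ok], sd = obs_sd, log = TRUE))
}
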