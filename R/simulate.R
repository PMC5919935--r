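#' Generate the quiz schedule: difficulty episodes, answers and biased feedback
#'
#' Draws, for every trial, a difficulty label, the cohort mean accuracy for
#' that difficulty, a simulated correct/incorrect answer, and the (possibly
#' biased) feedback. The first and last `edge_unbiased` trials of each session
#' are medium difficulty with zero bias; middle trials follow the session's
#' `bias_plan` row. Feedback is always positive after a correct answer; after
#' a wrong answer it is positive with the session's bias proportion.
#'
#' @param config A [task_config()].
#' @param seed Optional integer seed for reproducibility.
#' @return Tibble with one row per trial: `session`, `trial` (1-based global
#'   index), `trial_in_session`, `difficulty`, `accuracy_mean`, `correct`
#'   (0/1), `feedback` (+1/-1).
#' @export
gen_quiz_schedule <- function(config, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  nt <- config$trials_per_session
  edge <- config$edge_unbiased
  per_session <- purrr::map(seq_len(config$n_sessions), function(s) {
    row <- config$bias_plan[config$bias_plan$session == s, ]
    idx <- seq_len(nt)
    is_edge <- idx <= edge | idx > nt - edge
    difficulty <- ifelse(is_edge, "medium", row$difficulty)
    bias <- ifelse(is_edge, 0, row$bias)
    acc <- unname(config$accuracy_means[difficulty])
    correct <- as.integer(stats::runif(nt) < acc)
    # wrong answers flip to positive feedback with the episode's bias rate
    lucky <- stats::runif(nt) < bias
    feedback <- ifelse(correct == 1L, 1L, ifelse(lucky, 1L, -1L))
    tibble::tibble(
      session = s, trial_in_session = idx, difficulty = difficulty,
      accuracy_mean = acc, correct = correct, feedback = as.integer(feedback)
    )
  })
  out <- dplyr::bind_rows(per_session)
  out$trial <- seq_len(nrow(out))
  dplyr::relocate(out, "session", "trial", "trial_in_session")
}

#' Generate orthogonalized prospect sequences (gain, loss, target size)
#'
#' Each dimension uses a balanced sequence (every level equally often, up to
#' rounding) shuffled independently, then reshuffled until all pairwise
#' Pearson correlations among gain, loss, size -- and with quiz difficulty
#' when supplied -- are below `max_abs_r`. With fewer trials than levels a
#' warning is emitted and plain random draws are used.
#'
#' @param config A [task_config()].
#' @param n_trials Number of trials (defaults to the full experiment length).
#' @param difficulty Optional per-trial difficulty labels to decorrelate from.
#' @param max_abs_r Orthogonality threshold on |Pearson r| (default 0.1).
#' @param max_tries Reshuffle attempts before giving up with a warning.
#' @param seed Optional integer seed.
#' @return Tibble with columns `gain`, `loss`, `size`.
#' @export
gen_prospects <- function(config, n_trials = NULL, difficulty = NULL,
                          max_abs_r = 0.1, max_tries = 200, seed = NULL) {
  stopifnot(inherits(config, "task_config"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(n_trials)) n_trials <- config$n_sessions * config$trials_per_session
  levs <- list(gain = config$gain_levels, loss = config$loss_levels,
               size = config$size_levels)
  if (n_trials == 1L) {
    return(tibble::tibble(gain = sample(levs$gain, 1), loss = sample(levs$loss, 1),
                          size = sample(levs$size, 1)))
  }
  if (n_trials < max(lengths(levs))) {
    warning("fewer trials than levels; falling back to random draws",
            call. = FALSE)
    return(tibble::as_tibble(purrr::map(levs, sample, size = n_trials,
                                        replace = TRUE)))
  }
  balanced <- function(levels) {
    base <- rep(levels, length.out = n_trials)
    sample(base, n_trials)
  }
  diff_num <- if (!is.null(difficulty)) {
    as.numeric(factor(difficulty, levels = c("easy", "medium", "hard")))
  } else NULL
  for (i in seq_len(max_tries)) {
    draw <- purrr::map(levs, balanced)
    m <- cbind(gain = draw$gain, loss = draw$loss, size = draw$size)
    r <- stats::cor(m)
    ok <- all(abs(r[upper.tri(r)]) < max_abs_r)
    if (ok && !is.null(diff_num) && stats::sd(diff_num) > 0) {
      ok <- all(abs(stats::cor(m, diff_num)) < max_abs_r)
    }
    if (ok) return(tibble::as_tibble(draw))
  }
  warning("orthogonality target not reached after ", max_tries,
          " shuffles; returning last draw", call. = FALSE)
  tibble::as_tibble(draw)
}

#' Ground-truth description of one simulated agent
#'
#' Bundles the generative mood model (spec + parameters, including the rating
#' observation noise `obs_sd`), the generative choice model, the confidence
#' rating noise, the coupling of the two region-of-interest (ROI) baseline
#' proxies to mood, and optional trial-wise modulation of the choice weights
#' by the ROI signals themselves.
#'
#' ROI proxies are per-trial scalars emulating baseline activity at prospect
#' onset: `vmpfc = b_v * TML + global + noise` and
#' `ains = -b_a * TML + global + noise` share a global fluctuation. When
#' `mod_gain` is nonzero the gain weight on trial t becomes
#' `k_g * (1 + mod_gain * (vmpfc - global))`; `mod_loss` acts on `k_l`
#' through the anterior-insula proxy in the same way, so a positive
#' `mod_loss` means loss aversion grows with insula activity, i.e. falls
#' with mood.
#'
#' @param mood_spec,mood_params Generative mood model (see [mood_spec()]).
#' @param choice_spec,choice_params Generative choice model (see
#'   [choice_spec()]).
#' @param confidence_sd Noise sd of the (feedback-independent) confidence
#'   ratings.
#' @param confidence_trend Linear drift per trial of confidence ratings.
#' @param b_v,b_a Positive coupling strengths of the vmPFC and aIns proxies
#'   to the theoretical mood level.
#' @param global_sd Sd of the shared global signal.
#' @param roi_noise_sd Sd of the ROI-specific noise.
#' @param mod_gain,mod_loss Modulation coefficients of `k_g` by the vmPFC
#'   proxy and of `k_l` by the aIns proxy (default 0 = no modulation).
#' @return An object of class `agent_truth`.
#' @export
agent_truth <- function(mood_spec, mood_params, choice_spec, choice_params,
                        confidence_sd = 0.5, confidence_trend = 0,
                        b_v = 0.8, b_a = 0.8, global_sd = 0.5,
                        roi_noise_sd = 0.5, mod_gain = 0, mod_loss = 0) {
  stopifnot(inherits(mood_spec, "mood_spec"), inherits(choice_spec, "choice_spec"))
  if (confidence_sd <= 0 || global_sd <= 0 || roi_noise_sd <= 0) {
    stop("noise sds must be positive", call. = FALSE)
  }
  if (b_v <= 0 || b_a <= 0) stop("ROI couplings b_v, b_a must be positive", call. = FALSE)
  check_mood_params(mood_spec, mood_params)
  check_choice_params(choice_spec, choice_params)
  structure(
    list(mood_spec = mood_spec, mood_params = mood_params,
         choice_spec = choice_spec, choice_params = choice_params,
         confidence_sd = confidence_sd, confidence_trend = confidence_trend,
         b_v = b_v, b_a = b_a, global_sd = global_sd,
         roi_noise_sd = roi_noise_sd, mod_gain = mod_gain, mod_loss = mod_loss),
    class = "agent_truth"
  )
}

#' Simulate one agent's full trial table
#'
#' Generates a quiz schedule and prospect sequence, computes the theoretical
#' mood level (TML) from the agent's generative mood model, emits sparse mood
#' ratings (TML plus Gaussian noise of sd `obs_sd` on scheduled trials) and
#' feedback-independent confidence ratings, simulates ROI baseline proxies
#' linearly coupled to TML, and draws accept/decline choices from the
#' generative choice model, optionally with its weights modulated trial-wise
#' by the ROI signals.
#'
#' @param config A [task_config()].
#' @param truth An [agent_truth()].
#' @param seed Integer seed; the whole table is reproducible from it.
#' @return A trial-table tibble with columns `session`, `trial`,
#'   `trial_in_session`, `difficulty`, `accuracy_mean`, `correct`, `feedback`,
#'   `gain`, `loss`, `size`, `choice`, `mood_rating`, `confidence_rating`,
#'   `vmpfc`, `ains`, `global`, plus the latent `tml` as an attribute-free
#'   ordinary column `tml_true` for validation work.
#' @export
simulate_agent <- function(config, truth, seed = 1L) {
  stopifnot(inherits(config, "task_config"), inherits(truth, "agent_truth"))
  set.seed(seed)
  quiz <- gen_quiz_schedule(config)
  pros <- gen_prospects(config, difficulty = quiz$difficulty)
  tab <- dplyr::bind_cols(quiz, pros)
  n <- nrow(tab)

  if (mood_uses_choice(truth$mood_spec)) {
    # choice utilities feed back into mood: simulate trial-sequentially
    tab <- simulate_agent_sequential(tab, truth)
  } else {
    trace <- compute_tml(tab, truth$mood_spec, truth$mood_params)
    tab$tml_true <- trace$tml
    glob <- stats::rnorm(n, 0, truth$global_sd)
    tab$global <- glob
    tab$vmpfc <- truth$b_v * tab$tml_true + glob + stats::rnorm(n, 0, truth$roi_noise_sd)
    tab$ains <- -truth$b_a * tab$tml_true + glob + stats::rnorm(n, 0, truth$roi_noise_sd)
    p <- generative_accept_prob(tab, truth)
    tab$choice <- as.integer(stats::runif(n) < p)
    tab$p_accept_true <- p
    # chosen-option utility under the generative choice model, so that
    # choice-source mood models are fittable on simulated tables
    tab <- add_ev_choice(tab, truth$choice_spec, truth$choice_params)
  }

  rated <- rating_schedule(config)
  obs_sd <- truth$mood_params[["obs_sd"]]
  if (is.null(obs_sd)) obs_sd <- 0
  tab$mood_rating <- NA_real_
  tab$mood_rating[rated] <- tab$tml_true[rated] +
    if (obs_sd > 0) stats::rnorm(sum(rated), 0, obs_sd) else 0
  tab$confidence_rating <- NA_real_
  tab$confidence_rating[rated] <- truth$confidence_trend * tab$trial[rated] +
    stats::rnorm(sum(rated), 0, truth$confidence_sd)
  tab
}

# choice weights possibly modulated per trial by the ROI-specific components
generative_accept_prob <- function(tab, truth) {
  params <- truth$choice_params
  n <- nrow(tab)
  kg <- rep(params[["k_g"]], n)
  kl <- rep(params[["k_l"]], n)
  if (truth$mod_gain != 0) kg <- kg * (1 + truth$mod_gain * (tab$vmpfc - tab$global))
  if (truth$mod_loss != 0) kl <- kl * (1 + truth$mod_loss * (tab$ains - tab$global))
  p2 <- params
  accept_probability(tab, truth$choice_spec, p2, k_g_series = kg, k_l_series = kl)
}

simulate_agent_sequential <- function(tab, truth) {
  n <- nrow(tab)
  spec <- truth$mood_spec
  params <- truth$mood_params
  glob <- stats::rnorm(n, 0, truth$global_sd)
  tml <- numeric(n); ev_choice <- numeric(n)
  vmpfc <- numeric(n); ains <- numeric(n); choice <- integer(n)
  p_acc <- numeric(n)
  for (t in seq_len(n)) {
    # pre-choice TML: choice utilities known up to t - 1
    tab_t <- tab[seq_len(t), ]
    tab_t$ev_choice <- c(ev_choice[seq_len(t - 1)], 0)[seq_len(t)]
    tml[t] <- compute_tml(tab_t, spec, params)$tml[t]
    vmpfc[t] <- truth$b_v * tml[t] + glob[t] + stats::rnorm(1, 0, truth$roi_noise_sd)
    ains[t] <- -truth$b_a * tml[t] + glob[t] + stats::rnorm(1, 0, truth$roi_noise_sd)
    kg <- truth$choice_params[["k_g"]] *
      (1 + truth$mod_gain * (vmpfc[t] - glob[t]))
    kl <- truth$choice_params[["k_l"]] *
      (1 + truth$mod_loss * (ains[t] - glob[t]))
    p <- accept_probability(tab[t, ], truth$choice_spec, truth$choice_params,
                            k_g_series = kg, k_l_series = kl)
    choice[t] <- as.integer(stats::runif(1) < p)
    p_acc[t] <- p
    ev_choice[t] <- chosen_utility(tab[t, ], truth$choice_spec,
                                   truth$choice_params, choice[t])
  }
  tab$tml_true <- tml
  tab$global <- glob
  tab$vmpfc <- vmpfc
  tab$ains <- ains
  tab$choice <- choice
  tab$p_accept_true <- p_acc
  tab$ev_choice <- ev_choice
  tab
}

# logical vector: which global trials carry a rating
rating_schedule <- function(config) {
  nt <- config$trials_per_session
  within <- seq(config$first_rated_trial, nt, by = config$rating_period)
  rated <- rep(FALSE, config$n_sessions * nt)
  for (s in seq_len(config$n_sessions)) {
    rated[(s - 1L) * nt + within] <- TRUE
  }
  rated
}

#' Draw a cohort of simulated agents from a population distribution
#'
#' Agent-level generative parameters are drawn from independent Gaussians
#' with the supplied population means and sds (parameters with natural
#' constraints are truncated: `gamma` to `[0.01, 0.99]`, positive parameters
#' to a small positive floor). Everything is reproducible from `seed`.
#'
#' @param config A [task_config()].
#' @param n_agents Number of agents (>= 1).
#' @param truth_template An [agent_truth()] holding the population-mean
#'   parameters and the structural specs.
#' @param mood_sd,choice_sd Named numeric vectors of population sds for the
#'   mood and choice parameters (parameters not named get sd 0, i.e. are
#'   fixed across agents).
#' @param seed Integer seed.
#' @return A list with `tables` (list of trial tables), `truths` (list of
#'   per-agent [agent_truth()] objects) and `params` (tibble of the drawn
#'   ground-truth parameter values, one row per agent).
#' @export
gen_cohort <- function(config, n_agents, truth_template,
                       mood_sd = NULL, choice_sd = NULL, seed = 1L) {
  stopifnot(n_agents >= 1, inherits(truth_template, "agent_truth"))
  if (any(c(mood_sd, choice_sd) < 0)) {
    stop("population sds must be non-negative", call. = FALSE)
  }
  set.seed(seed)
  agent_seeds <- sample.int(.Machine$integer.max, n_agents)
  draw_params <- function(means, sds) {
    out <- means
    for (nm in names(out)) {
      s <- if (!is.null(sds) && nm %in% names(sds)) sds[[nm]] else 0
      v <- stats::rnorm(1, means[[nm]], s)
      v <- truncate_param(nm, v)
      out[[nm]] <- v
    }
    out
  }
  truths <- vector("list", n_agents)
  tables <- vector("list", n_agents)
  rows <- vector("list", n_agents)
  for (i in seq_len(n_agents)) {
    mp <- draw_params(truth_template$mood_params, mood_sd)
    cp <- draw_params(truth_template$choice_params, choice_sd)
    tr <- truth_template
    tr$mood_params <- mp
    tr$choice_params <- cp
    truths[[i]] <- tr
    tables[[i]] <- simulate_agent(config, tr, seed = agent_seeds[i])
    rows[[i]] <- tibble::tibble(
      agent = i,
      parameter = c(names(mp), names(cp)),
      value = c(unlist(mp), unlist(cp)),
      model = rep(c("mood", "choice"), c(length(mp), length(cp)))
    )
  }
  list(tables = tables, truths = truths,
       params = dplyr::bind_rows(rows), seed = seed, agent_seeds = agent_seeds)
}

#' Canonical synthetic study conditions
#'
#' The package's reference ground truth for recovery studies: the winning
#' mood model (quiz feedback only, single weight, asymmetric coding,
#' reciprocal mood-on-feedback influence) with a forgetting factor of 0.77,
#' positive feedback weight, positive reciprocity and a slow negative time
#' drift; and the winning choice model (expected utility with distinct
#' gain/loss weights, no curvature, explicit 0.5-euro decline utility).
#' `default_population_sd()` gives the matching between-agent sds.
#'
#' @param mod_gain,mod_loss Optional generative ROI modulations of the
#'   choice weights (see [agent_truth()]).
#' @return An [agent_truth()] object.
#' @export
default_agent_truth <- function(mod_gain = 0, mod_loss = 0) {
  agent_truth(
    mood_spec = mood_spec("quiz_only", simplified = TRUE, asymmetric = TRUE,
                          reciprocal = TRUE),
    mood_params = list(omega0 = 0, omega_t = -0.005, gamma = 0.77,
                       omega_f = 0.4, R = 1.5, delta = 0.3, obs_sd = 0.3),
    choice_spec = choice_spec("normative", include_decline_utility = TRUE),
    choice_params = list(k_g = 1, k_l = 1, sigma = 0.08, k_t = -0.002,
                         k0 = 0.5),
    mod_gain = mod_gain, mod_loss = mod_loss
  )
}

#' @rdname default_agent_truth
#' @export
default_population_sd <- function() {
  list(
    mood = c(omega0 = 0.2, omega_t = 0.002, gamma = 0.05, omega_f = 0.15,
             R = 0.3, delta = 0.1, obs_sd = 0.05),
    choice = c(k_g = 0.25, k_l = 0.25, sigma = 0.02, k_t = 0.001, k0 = 0.3)
  )
}

# keep drawn parameters inside their natural domains
truncate_param <- function(name, value) {
  if (name == "gamma") return(min(max(value, 0.01), 0.99))
  if (name %in% c("sigma", "obs_sd", "R")) return(max(value, 1e-3))
  if (name %in% c("c_g", "c_l")) return(min(max(value, 0.01), 1))
  value
}
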