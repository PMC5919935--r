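# Shared fixtures: small task configs, canonical specs, and independent
# brute-force oracles used across test files.

small_config <- function(n_sessions = 2) task_config(n_sessions = n_sessions)

best_mood_spec <- function() {
  mood_spec("quiz_only", simplified = TRUE, asymmetric = TRUE,
            reciprocal = TRUE)
}

best_choice_spec <- function() {
  choice_spec("normative", include_decline_utility = TRUE)
}

quick_truth <- function(...) default_agent_truth(...)

# minimal quiz-side trial table built by hand
toy_table <- function(feedback, accuracy = 0.5) {
  n <- length(feedback)
  tibble::tibble(
    session = 1L, trial = seq_len(n), trial_in_session = seq_len(n),
    difficulty = "medium", accuracy_mean = rep(accuracy, length.out = n),
    correct = as.integer(feedback > 0), feedback = as.integer(feedback),
    gain = rep(3, n), loss = rep(3, n), size = rep(0.15, n),
    choice = rep(1L, n)
  )
}

# Independent brute-force TML oracle: explicit double sum with sequential
# subjective-feedback computation; deliberately loop-based.
brute_force_tml <- function(table, spec, params) {
  n <- nrow(table)
  g <- function(nm) if (is.null(params[[nm]])) 0 else params[[nm]]
  gamma <- g("gamma")
  uses_quiz <- spec$source %in% c("quiz_only", "both")
  uses_choice <- spec$source %in% c("choice_only", "both")
  ev <- if (uses_quiz) 2 * table$accuracy_mean - 1 else rep(0, n)
  evc <- if (uses_choice) table$ev_choice else rep(0, n)
  pos <- if (isTRUE(spec$asymmetric)) g("R") else 1
  delta <- if (isTRUE(spec$reciprocal)) g("delta") else 0
  tml <- numeric(n)
  f <- numeric(n)
  for (t in seq_len(n)) {
    tml_prev <- if (t > 1) tml[t - 1] else 0
    coded <- if (table$feedback[t] > 0) pos else -1
    f[t] <- coded + delta * tml_prev
    val <- g("omega0") + g("omega_t") * table$trial[t]
    if (uses_quiz) {
      for (j in seq_len(t)) {
        w <- gamma^(t - j)
        if (isTRUE(spec$simplified)) {
          val <- val + g("omega_f") * w * f[j]
        } else {
          val <- val + g("omega_q1") * w * ev[j] +
            g("omega_q2") * w * (f[j] - ev[j])
        }
      }
    }
    if (uses_choice) {
      for (j in seq_len(t)) val <- val + g("omega_p") * gamma^(t - j) * evc[j]
    }
    tml[t] <- val
  }
  tml
}

# closed-form log marginal likelihood of y = X beta + noise(sd), with a
# Gaussian prior beta ~ N(m0, S0): y ~ N(X m0, sd^2 I + X S0 X')
conjugate_log_marginal <- function(y, X, m0, S0, sd) {
  n <- length(y)
  V <- sd^2 * diag(n) + X %*% S0 %*% t(X)
  r <- y - as.numeric(X %*% m0)
  -0.5 * (n * log(2 * pi) + determinant(V, logarithm = TRUE)$modulus[1] +
            sum(r * solve(V, r)))
}
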