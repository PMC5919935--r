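#' Invert a model on one agent's data (MAP + Laplace evidence)
#'
#' Finds the maximum-a-posteriori estimate of the model's parameters on the
#' unconstrained transformed scale by multi-start quasi-Newton optimization
#' of the log-joint (log-likelihood plus Gaussian log-prior), then
#' approximates the log model evidence with the Laplace approximation
#' \deqn{\log p(y) \approx \log p(y, \hat\theta) + \tfrac{d}{2}\log(2\pi)
#'   - \tfrac12 \log\det H,}
#' where `H` is the negative Hessian of the log-joint at the mode
#' (central finite differences, step 1e-4; ridge jitter added and recorded
#' if it is not positive definite). This evidence realises the usual
#' accuracy-minus-complexity trade-off. The whole procedure is deterministic
#' given `seed`.
#'
#' @param table Trial table for one agent.
#' @param spec A [mood_spec()] or [choice_spec()]; dispatch picks
#'   [mood_loglik()] or [choice_loglik()].
#' @param priors Prior specification, default [default_priors()] of the spec.
#' @param npm Per-trial neural proxy series (choice models with modulations).
#' @param ratings Optional precomputed rating series (mood models); defaults
#'   to interpolated, z-scored mood ratings.
#' @param n_starts Number of random starts drawn from the prior (default 8).
#' @param seed Integer seed for the starts.
#' @param maxit Maximum BFGS iterations per start.
#' @param hessian_step Finite-difference step on the transformed scale.
#' @return An object of class `inversion_result`: parameter estimates
#'   (natural and transformed scale), posterior covariance (transformed
#'   scale), `log_evidence`, and convergence diagnostics. Non-convergence is
#'   flagged in `diagnostics`, never silent.
#' @export
invert_model <- function(table, spec, priors = default_priors(spec),
                         npm = NULL, ratings = NULL,
                         n_starts = 8, seed = 1L, maxit = 500,
                         hessian_step = 1e-4) {
  free <- priors[!priors$fixed, ]
  fixed <- priors[priors$fixed, ]
  d <- nrow(free)
  fixed_list <- stats::setNames(as.list(fixed$fixed_value), fixed$parameter)

  ll_fun <- build_loglik(table, spec, npm = npm, ratings = ratings)
  n_obs <- attr(ll_fun, "n_obs")

  idx_log <- which(free$transform == "log")
  idx_logit <- which(free$transform == "logit")
  par_names <- free$parameter
  prior_mean <- free$mean
  prior_sd <- free$sd
  prior_const <- -sum(log(prior_sd)) - d / 2 * log(2 * pi)
  make_params <- function(theta) {
    nat <- theta
    if (length(idx_log)) nat[idx_log] <- exp(theta[idx_log])
    if (length(idx_logit)) nat[idx_logit] <- stats::plogis(theta[idx_logit])
    c(stats::setNames(as.list(nat), par_names), fixed_list)
  }
  log_joint <- function(theta) {
    ll <- ll_fun(make_params(theta))
    if (!is.finite(ll)) return(-Inf)
    z <- (theta - prior_mean) / prior_sd
    ll + prior_const - 0.5 * sum(z * z)
  }
  objective <- function(theta) {
    v <- -log_joint(theta)
    if (!is.finite(v)) 1e10 else v
  }

  if (d == 0) {
    lj <- log_joint(numeric(0))
    return(new_inversion_result(spec, free, fixed_list, numeric(0),
                                matrix(0, 0, 0), lj, lj,
                                diagnostics = list(converged = TRUE,
                                                   n_starts = 0, jitter = 0),
                                n_obs = n_obs))
  }

  set.seed(seed)
  # first start at the prior mean (a well-behaved region of every model);
  # the remaining starts are random prior draws
  starts <- matrix(stats::rnorm(n_starts * d, rep(free$mean, each = n_starts),
                                rep(free$sd, each = n_starts)),
                   nrow = n_starts)
  starts[1, ] <- free$mean
  fits <- vector("list", n_starts)
  for (i in seq_len(n_starts)) {
    fits[[i]] <- tryCatch(
      stats::optim(starts[i, ], objective, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-10)),
      error = function(e) {
        stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                     control = list(maxit = 2000))
      })
  }
  vals <- purrr::map_dbl(fits, "value")
  norms <- purrr::map_dbl(fits, ~ sqrt(sum(.x$par^2)))
  # best log-joint wins; ties broken by lowest parameter norm
  best <- order(vals, norms)[1]
  fit <- fits[[best]]
  converged <- fit$convergence == 0
  if (!converged) {
    warning("optimizer did not fully converge (code ", fit$convergence,
            "); best-found values returned", call. = FALSE)
  }
  theta_hat <- fit$par
  lj_hat <- -fit$value

  H <- fd_hessian(objective, theta_hat, hessian_step)
  reg <- regularize_spd(H)
  logdet <- determinant(reg$H, logarithm = TRUE)$modulus[1]
  log_evidence <- lj_hat + d / 2 * log(2 * pi) - 0.5 * logdet
  post_cov <- tryCatch(solve(reg$H), error = function(e) {
    diag(Inf, d)
  })
  dimnames(post_cov) <- list(free$parameter, free$parameter)

  new_inversion_result(spec, free, fixed_list, theta_hat, post_cov,
                       log_evidence, lj_hat,
                       diagnostics = list(converged = converged,
                                          n_starts = n_starts,
                                          best_start = best,
                                          jitter = reg$jitter,
                                          optim_counts = fit$counts,
                                          seed = seed),
                       n_obs = n_obs)
}

# fast per-spec likelihood closure; data columns extracted once
build_loglik <- function(table, spec, npm = NULL, ratings = NULL) {
  if (inherits(spec, "mood_spec")) {
    if (is.null(ratings)) {
      ratings <- if (nrow(table) == 0) numeric(0) else prepare_ratings(table)
    }
    ok <- !is.na(ratings)
    y <- ratings[ok]
    tt <- as.numeric(table$trial)
    feedback <- if (mood_uses_quiz(spec)) table$feedback else NULL
    ev_quiz <- if (mood_uses_quiz(spec)) {
      if (is.null(table$accuracy_mean) || anyNA(table$accuracy_mean)) {
        stop("quiz source requires an accuracy_mean column without missing ",
             "values", call. = FALSE)
      }
      2 * as.numeric(table$accuracy_mean) - 1
    } else rep(NA_real_, nrow(table))
    ev_choice <- if (mood_uses_choice(spec)) {
      if (is.null(table$ev_choice)) {
        stop("source includes the choice task but the table has no ev_choice ",
             "column (see add_ev_choice())", call. = FALSE)
      }
      as.numeric(table$ev_choice)
    } else rep(NA_real_, nrow(table))
    n_y <- length(y)
    log2pi_term <- n_y * 0.5 * log(2 * pi)
    f <- function(params) {
      if (!n_y) return(0)
      tml <- tml_vector(tt, feedback, ev_quiz, ev_choice, spec, params)[ok]
      if (any(!is.finite(tml))) return(-Inf)
      sd <- params[["obs_sd"]]
      r <- (y - tml) / sd
      -0.5 * sum(r * r) - n_y * log(sd) - log2pi_term
    }
    attr(f, "n_obs") <- n_y
  } else if (inherits(spec, "choice_spec")) {
    y_all <- if (nrow(table)) table$choice else integer(0)
    ok <- !is.na(y_all)
    y <- y_all[ok]
    if (length(spec$modulations) && is.null(npm)) {
      stop("spec includes modulations but no npm series was supplied",
           call. = FALSE)
    }
    gain <- table$gain[ok]; loss <- table$loss[ok]
    half_size <- table$size[ok] / 2
    tt <- as.numeric(table$trial)[ok]
    npm_ok <- if (!is.null(npm)) npm[ok] else NULL
    mods <- spec$modulations
    normative <- spec$family == "normative"
    curv <- isTRUE(spec$curvature)
    decl <- isTRUE(spec$include_decline_utility)
    regs <- spec$regressors
    reg_terms <- if (!normative) {
      terms <- list(G = gain, L = loss, S = 2 * half_size,
                    GL = gain * loss, GS = gain * 2 * half_size,
                    LS = loss * 2 * half_size,
                    GLS = gain * loss * 2 * half_size)
      terms[regs]
    } else NULL
    eps <- 1e-10
    f <- function(params) {
      if (!length(y)) return(0)
      kg <- params[["k_g"]]; kl <- params[["k_l"]]
      sigma <- params[["sigma"]]
      additive <- 0
      if (length(mods)) {
        if ("gain" %in% mods) kg <- kg * (1 + params[["k_mg"]] * npm_ok)
        if ("loss" %in% mods) kl <- kl * (1 + params[["k_ml"]] * npm_ok)
        if ("sigma" %in% mods) {
          sigma <- pmax(sigma * (1 + params[["k_msigma"]] * npm_ok), 1e-6)
        }
        if ("additive" %in% mods) additive <- params[["k_m0"]] * npm_ok
      }
      if (normative) {
        p_s <- 2 * stats::pnorm(half_size / sigma) - 1
        if (curv) {
          ua <- p_s * kg * gain^params[["c_g"]] -
            (1 - p_s) * kl * loss^params[["c_l"]]
          ud <- if (decl) {
            p_s * kg * 0.5^params[["c_g"]] - (1 - p_s) * kl * 0.5^params[["c_l"]]
          } else 0
        } else {
          ua <- p_s * kg * gain - (1 - p_s) * kl * loss
          ud <- if (decl) 0.5 * (p_s * kg - (1 - p_s) * kl) else 0
        }
      } else {
        ua <- 0
        for (i in seq_along(reg_terms)) {
          ua <- ua + params[[paste0("w_", tolower(regs[i]))]] * reg_terms[[i]]
        }
        ud <- 0
      }
      x <- ua - ud + additive + params[["k_t"]] * tt + params[["k0"]]
      if (any(!is.finite(x))) return(-Inf)
      p <- pmin(pmax(stats::plogis(x), eps), 1 - eps)
      sum(y * log(p) + (1 - y) * log(1 - p))
    }
    attr(f, "n_obs") <- sum(ok)
  } else {
    stop("spec must be a mood_spec or choice_spec", call. = FALSE)
  }
  f
}

new_inversion_result <- function(spec, free, fixed_list, theta_hat, post_cov,
                                 log_evidence, log_joint, diagnostics, n_obs) {
  estimate <- tibble::tibble(
    parameter = free$parameter,
    transformed = theta_hat,
    estimate = purrr::map2_dbl(theta_hat, free$transform, to_natural),
    std_error = if (nrow(post_cov)) sqrt(pmax(diag(post_cov), 0)) else numeric(0)
  )
  structure(
    list(spec = spec, estimate = estimate, fixed = fixed_list,
         posterior_cov = post_cov, log_evidence = log_evidence,
         log_joint = log_joint, diagnostics = diagnostics, n_obs = n_obs),
    class = "inversion_result"
  )
}

#' Extract posterior means (natural scale) as a named list
#' @param x An `inversion_result`.
#' @return Named list of parameter values (free and fixed).
#' @export
posterior_params <- function(x) {
  stopifnot(inherits(x, "inversion_result"))
  c(stats::setNames(as.list(x$estimate$estimate), x$estimate$parameter),
    x$fixed)
}

#' @export
print.inversion_result <- function(x, ...) {
  lab <- if (inherits(x$spec, "mood_spec")) mood_model_label(x$spec)
         else choice_model_label(x$spec)
  cat("<inversion_result> ", lab, "\n", sep = "")
  cat("  log evidence: ", format(x$log_evidence, digits = 6),
      " (n = ", x$n_obs, ")\n", sep = "")
  print(x$estimate)
  invisible(x)
}

# central finite-difference Hessian of f at x
fd_hessian <- function(f, x, h = 1e-4) {
  d <- length(x)
  H <- matrix(0, d, d)
  f0 <- f(x)
  for (i in seq_len(d)) {
    ei <- replace(numeric(d), i, h)
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h^2
    if (i < d) for (j in seq((i + 1), d)) {
      ej <- replace(numeric(d), j, h)
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h^2)
    }
  }
  (H + t(H)) / 2
}

# add escalating ridge jitter until positive definite
regularize_spd <- function(H) {
  jitter <- 0
  d <- nrow(H)
  for (k in 0:12) {
    Hj <- H + diag(jitter, d)
    ok <- tryCatch({chol(Hj); TRUE}, error = function(e) FALSE)
    if (ok) return(list(H = Hj, jitter = jitter))
    jitter <- if (jitter == 0) 1e-8 else jitter * 10
  }
  list(H = H + diag(jitter, d), jitter = jitter)
}
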