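test_that("Laplace evidence matches the conjugate closed form (linear-Gaussian)", {
  # null mood model with fixed obs_sd: TML = omega0 + omega_t * t is linear
  # in its two free parameters, so the marginal likelihood has a closed form
  set.seed(21)
  n <- 40
  tab <- toy_table(sample(c(-1, 1), n, replace = TRUE))
  sp <- mood_spec("null")
  sd_obs <- 0.8
  y <- 0.5 - 0.02 * (1:n) + rnorm(n, 0, sd_obs)
  priors <- fix_params(default_priors(sp), obs_sd = sd_obs)
  fit <- invert_model(tab, sp, priors = priors, ratings = y, seed = 2)
  X <- cbind(1, 1:n)
  oracle <- conjugate_log_marginal(y, X, m0 = c(0, 0), S0 = diag(9, 2),
                                   sd = sd_obs)
  expect_lt(abs(fit$log_evidence - oracle), 1e-3)
  # posterior mode matches the conjugate posterior mean
  S0i <- diag(1 / 9, 2)
  post_mean <- solve(S0i + crossprod(X) / sd_obs^2,
                     crossprod(X, y) / sd_obs^2)
  expect_equal(fit$estimate$estimate, as.numeric(post_mean), tolerance = 1e-4)
})

test_that("with no data the posterior is the prior and evidence is zero", {
  sp <- mood_spec("null")
  tab <- toy_table(integer(0))
  fit <- invert_model(tab, sp, seed = 3)
  expect_equal(fit$estimate$transformed, rep(0, 3), tolerance = 1e-6)
  expect_equal(fit$log_evidence, 0, tolerance = 1e-4)
})

test_that("noiseless simulated ratings recover generating parameters", {
  tr <- quick_truth()
  tr$mood_params$obs_sd <- 0.01
  cfg <- task_config(n_sessions = 8)
  tab <- simulate_agent(cfg, tr, seed = 22)
  # rated trials only, raw scale: the target equals true TML almost exactly
  y <- prepare_ratings(tab, interpolate = FALSE, zscore = FALSE)
  fit <- invert_model(tab, best_mood_spec(), ratings = y, seed = 4)
  est <- posterior_params(fit)
  expect_lt(abs(est$gamma - tr$mood_params$gamma), 0.05)
  expect_lt(abs(est$omega_f - tr$mood_params$omega_f), 0.1)
  expect_lt(abs(est$R - tr$mood_params$R), 0.3)
  expect_lt(abs(est$delta - tr$mood_params$delta), 0.1)
})

test_that("inversion is deterministic under a fixed seed", {
  tr <- quick_truth()
  tab <- simulate_agent(small_config(), tr, seed = 23)
  f1 <- invert_model(tab, best_choice_spec(), seed = 11)
  f2 <- invert_model(tab, best_choice_spec(), seed = 11)
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$log_evidence, f2$log_evidence)
})

test_that("evidence penalizes unneeded complexity on nested models", {
  # data from the plain quiz model: richer variants should not win on average
  tr <- quick_truth()
  tr$mood_spec <- mood_spec("quiz_only", simplified = TRUE)
  tr$mood_params <- list(omega0 = 0, omega_t = -0.005, gamma = 0.77,
                         omega_f = 0.5, obs_sd = 0.3)
  cfg <- task_config(n_sessions = 4)
  rich <- best_mood_spec()
  d <- purrr::map_dbl(1:4, function(i) {
    tab <- simulate_agent(cfg, tr, seed = 30 + i)
    y <- prepare_ratings(tab)
    f_simple <- invert_model(tab, tr$mood_spec, ratings = y, seed = 5)
    f_rich <- invert_model(tab, rich, ratings = y, seed = 5)
    f_simple$log_evidence - f_rich$log_evidence
  })
  expect_gt(mean(d), 0)
})

test_that("uniform evidences give uniform exceedance probabilities", {
  le <- matrix(0, nrow = 6, ncol = 4,
               dimnames = list(NULL, paste0("m", 1:4)))
  fit <- group_bms(le, seed = 31)
  expect_equal(sum(fit$exceedance_probability), 1, tolerance = 1e-12)
  expect_true(all(abs(fit$exceedance_probability - 0.25) < 0.01))
  expect_equal(sum(fit$expected_frequency), 1, tolerance = 1e-12)
})

test_that("two-model exceedance matches the exact Beta computation", {
  # every agent favors model 1 by 3 log-evidence units
  le <- cbind(m1 = rep(3, 10), m2 = rep(0, 10))
  fit <- group_bms(le, n_samples = 1e5, seed = 32)
  expect_gt(fit$exceedance_probability[1], 0.99)
  # oracle: P(r1 > 1/2) under Dirichlet(a1, a2) = 1 - pbeta(1/2, a1, a2)
  exact <- 1 - stats::pbeta(0.5, fit$alpha[1], fit$alpha[2])
  expect_lt(abs(fit$exceedance_probability[1] - exact), 0.005)
  # single agent, equal evidence: uninformative
  fit1 <- group_bms(cbind(a = 0, b = 0), seed = 33)
  expect_lt(abs(fit1$exceedance_probability[1] - 0.5), 0.01)
})

test_that("group BMS rejects non-finite evidence with a named message", {
  le <- cbind(m1 = c(0, NA), m2 = c(0, 0))
  expect_error(group_bms(le), "agent 2.*m1")
})

test_that("family aggregation preserves symmetry and dominance", {
  # two equal families of identical models
  le <- matrix(0, 5, 4, dimnames = list(NULL, paste0("m", 1:4)))
  fam <- family_bms(le, list(A = c("m1", "m2"), B = c("m3", "m4")),
                    seed = 34)
  expect_true(all(abs(fam$exceedance_probability - 0.5) < 0.01))
  expect_equal(sum(fam$expected_frequency), 1, tolerance = 1e-6)
  # a family holding one dominant model inherits its dominance
  le2 <- cbind(m1 = rep(4, 8), m2 = 0, m3 = 0, m4 = 0)
  fam2 <- family_bms(le2, list(A = c("m1", "m2"), B = c("m3", "m4")),
                     seed = 35)
  expect_gt(fam2$exceedance_probability[1], 0.95)
  expect_error(family_bms(le2, list(A = c("m1", "m2"), B = c("m2", "m3"))),
               "overlap")
  expect_error(family_bms(le2, list(A = c("m1", "m2"), B = "m3")), "cover")
})

test_that("npm modulation family splits 8/8 on any one dimension", {
  fam <- enumerate_npm_models(best_choice_spec())
  le <- matrix(0, 3, 16, dimnames = list(NULL, fam$model))
  on <- fam$model[purrr::map_lgl(fam$modulations, ~ "loss" %in% .x)]
  split <- family_bms(le, list(loss_on = on,
                               loss_off = setdiff(fam$model, on)), seed = 36)
  expect_equal(length(on), 8)
  expect_true(all(abs(split$exceedance_probability - 0.5) < 0.01))
})

test_that("group parameter test matches the textbook t formula", {
  set.seed(37)
  x <- rnorm(15, 0.4, 1)
  res <- group_param_test(x)
  t_oracle <- mean(x) / (stats::sd(x) / sqrt(15))
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, 14)
  expect_equal(res$p_t, 2 * stats::pt(-abs(t_oracle), 14), tolerance = 1e-12)
  # constant non-zero signal with tiny jitter: strongly positive
  res2 <- group_param_test(c(1, 1, 1, 1) + rnorm(4, 0, 1e-6))
  expect_gt(res2$t, 100)
  # all-zero data: t undefined, reported not errored
  res3 <- group_param_test(rep(0, 5))
  expect_true(is.na(res3$t))
  expect_match(res3$note, "undefined")
  expect_error(group_param_test(1), "at least 2")
})
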