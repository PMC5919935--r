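test_that("orthogonalization removes exactly the nuisance subspace", {
  set.seed(41)
  n <- 100
  z <- rnorm(n)
  s <- rnorm(n)
  r <- orthogonalize(s, z)
  expect_lt(abs(stats::cor(r, z)), 1e-10)
  expect_lt(abs(mean(r)), 1e-12)
  # signal equal to nuisance: residual identically zero
  expect_lt(max(abs(orthogonalize(z, z))), 1e-12)
  # signal already orthogonal: unchanged up to mean removal
  s2 <- s - sum(s * z) / sum(z * z) * z
  expect_equal(orthogonalize(s2, z), s2 - mean(s2) -
                 (sum((s2 - mean(s2)) * (z - mean(z))) /
                    sum((z - mean(z))^2)) * (z - mean(z)),
               tolerance = 1e-10)
  # random case vs explicit projection-matrix computation
  Z <- cbind(1, z, rnorm(n))
  P <- diag(n) - Z %*% solve(crossprod(Z)) %*% t(Z)
  expect_equal(orthogonalize(s, Z[, -1]), as.numeric(P %*% s),
               tolerance = 1e-10)
  # duplicated nuisance columns are dropped with a message
  expect_message(orthogonalize(s, cbind(z, z)), "rank-deficient")
})

test_that("NPM weights recover opposite-signed ROI couplings", {
  set.seed(42)
  n <- 500
  tml <- as.numeric(arima.sim(list(ar = 0.8), n))
  glob <- rnorm(n)
  tab <- tibble::tibble(
    trial = 1:n, feedback = sample(c(-1L, 1L), n, TRUE),
    vmpfc = 0.7 * tml + glob + rnorm(n, 0, 0.4),
    ains = -0.6 * tml + glob + rnorm(n, 0, 0.4),
    global = glob
  )
  w <- fit_npm_weights(tab, tml)
  expect_gt(w$beta_vmpfc, 0)
  expect_lt(w$beta_ains, 0)
  # absent second regressor: simple-regression slope, beta_ains = 0
  tab0 <- tab
  tab0$ains <- 0
  w0 <- fit_npm_weights(tab0, tml)
  expect_equal(w0$beta_ains, 0)
  v <- orthogonalize(tab0$vmpfc, tab0$global)
  y <- orthogonalize(tml, tab0$trial)
  expect_equal(w0$beta_vmpfc, unname(stats::coef(stats::lm(y ~ v))[2]),
               tolerance = 1e-10)
  # last-feedback orthogonalization leaves signs intact here
  wlf <- fit_npm_weights(tab, tml, orthogonalize_last_feedback = TRUE)
  expect_gt(wlf$beta_vmpfc, 0)
  expect_lt(wlf$beta_ains, 0)
})

test_that("fitted beta signs match generating signs across replications", {
  hits <- purrr::map_lgl(1:20, function(i) {
    set.seed(100 + i)
    n <- 128
    tml <- as.numeric(arima.sim(list(ar = 0.8), n))
    glob <- rnorm(n)
    tab <- tibble::tibble(
      trial = 1:n, feedback = sample(c(-1L, 1L), n, TRUE),
      vmpfc = 0.8 * tml + glob + rnorm(n, 0, 0.5),
      ains = -0.8 * tml + glob + rnorm(n, 0, 0.5),
      global = glob
    )
    w <- fit_npm_weights(tab, tml)
    w$beta_vmpfc > 0 && w$beta_ains < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("the neural proxy is an exact linear read-out", {
  w <- list(beta_vmpfc = 0.098, beta_ains = -0.083)
  expect_equal(compute_npm(w, 1, 1), 0.015)
  expect_equal(compute_npm(list(beta_vmpfc = 0, beta_ains = 0), 2, 3), 0)
  v1 <- rnorm(10); a1 <- rnorm(10); v2 <- rnorm(10); a2 <- rnorm(10)
  expect_equal(compute_npm(w, v1 + v2, a1 + a2),
               compute_npm(w, v1, a1) + compute_npm(w, v2, a2))
})

test_that("residual-choice regression recovers a constructed slope", {
  sp <- best_choice_spec()
  pars <- list(k_g = 1, k_l = 1, sigma = 0.08, k_t = 0, k0 = 0)
  tabs <- purrr::map(1:4, function(a) {
    set.seed(50 + a)
    tab <- tibble::tibble(gain = sample(1:5, 60, TRUE),
                          loss = sample(1:5, 60, TRUE),
                          size = runif(60, 0.05, 0.25), trial = 1:60)
    tab$choice <- 0L
    tab
  })
  covs <- purrr::map(tabs, ~ rnorm(60))
  # construct choices so that residual = 0.2 * covariate exactly:
  # choice = p + 0.2 * cov must be 0/1, so build a synthetic "choice" column
  for (a in 1:4) {
    p <- accept_probability(tabs[[a]], sp, pars)
    tabs[[a]]$choice <- p + 0.2 * covs[[a]]
  }
  res <- residual_choice_regression(tabs, sp, purrr::map(1:4, ~ pars), covs)
  expect_equal(res$slopes$slope, rep(0.2, 4), tolerance = 1e-10)
  # independent covariate: group slope ~ 0
  set.seed(60)
  tabs2 <- purrr::map(1:6, function(a) {
    tab <- tibble::tibble(gain = sample(1:5, 400, TRUE),
                          loss = sample(1:5, 400, TRUE),
                          size = runif(400, 0.05, 0.25), trial = 1:400)
    tab$choice <- as.integer(runif(400) < accept_probability(tab, sp, pars))
    tab
  })
  covs2 <- purrr::map(1:6, ~ rnorm(400))
  res2 <- residual_choice_regression(tabs2, sp, purrr::map(1:6, ~ pars), covs2)
  expect_gt(res2$test$p_t, 0.05)
  # constant covariate reported, not errored
  res3 <- residual_choice_regression(tabs2[1], sp, list(pars),
                                     list(rep(1, 400)))
  expect_true(is.na(res3$slopes$slope[1]))
})

test_that("restricted-band effect computation handles bands correctly", {
  sp <- best_choice_spec()
  pars <- list(k_g = 1, k_l = 1, sigma = 0.08, k_t = 0, k0 = 0)
  set.seed(61)
  tab <- tibble::tibble(gain = sample(1:5, 600, TRUE),
                        loss = sample(1:5, 600, TRUE),
                        size = runif(600, 0.05, 0.25), trial = 1:600)
  cov <- rnorm(600)
  p <- accept_probability(tab, sp, pars)
  tab$choice <- as.integer(runif(600) < p)
  # null covariate: both effects near zero
  eff0 <- restricted_trial_effect(tab, sp, pars, cov)
  expect_lt(abs(eff0$effect_all), 0.12)
  expect_lt(abs(eff0$effect_restricted), 0.15)
  # band [0, 1] equals the all-trials computation
  eff1 <- restricted_trial_effect(tab, sp, pars, cov, band = c(0, 1))
  expect_equal(eff1$effect_all, eff1$effect_restricted)
  expect_equal(eff1$n_all, eff1$n_restricted)
})

test_that("a generative covariate effect is amplified in the uncertain band", {
  sp <- best_choice_spec()
  pars <- list(k_g = 1, k_l = 1, sigma = 0.08, k_t = 0, k0 = 0)
  set.seed(62)
  n <- 6000
  tab <- tibble::tibble(gain = sample(1:5, n, TRUE),
                        loss = sample(1:5, n, TRUE),
                        size = runif(n, 0.05, 0.25), trial = 1:n)
  cov <- rnorm(n)
  # covariate shifts the decision value additively at generation
  x <- stats::qlogis(accept_probability(tab, sp, pars)) + 0.8 * cov
  tab$choice <- as.integer(runif(n) < stats::plogis(x))
  eff <- restricted_trial_effect(tab, sp, pars, cov)
  expect_gt(eff$effect_restricted, eff$effect_all)
  expect_gt(eff$effect_all, 0)
})

test_that("nonlinearity check distinguishes linear from quadratic coupling", {
  set.seed(63)
  n <- 400
  tml <- rnorm(n)
  roi_lin <- 0.5 * tml + rnorm(n, 0, 0.3)
  lin <- nonlinearity_check(tml, roi_lin)
  expect_true(all(lin$polynomial$p_value[lin$polynomial$order >= 2] > 0.01))
  expect_gt(lin$median_split$p_difference, 0.01)
  roi_quad <- 0.5 * tml + 0.6 * tml^2 + rnorm(n, 0, 0.3)
  quad <- nonlinearity_check(tml, roi_quad)
  expect_lt(quad$polynomial$p_value[quad$polynomial$order == 2], 1e-6)
})
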