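test_that("success probability agrees with numerical quadrature", {
  expect_equal(prob_success(0.05, 0.10), 0.6826895, tolerance = 1e-5)
  # oracle: adaptive quadrature of the Gaussian over the target window
  quad <- function(sigma, size) {
    stats::integrate(function(x) stats::dnorm(x, 0.25, sigma),
                     0.25 - size / 2, 0.25 + size / 2,
                     rel.tol = 1e-12)$value
  }
  for (sigma in c(0.02, 0.05, 0.1, 0.2)) {
    for (size in c(0.01, 0.05, 0.15, 0.3)) {
      expect_lt(abs(prob_success(sigma, size) - quad(sigma, size)), 1e-8)
    }
  }
  expect_gt(prob_success(0.01, 1), 1 - 1e-10)
  expect_lt(prob_success(0.1, 1e-9), 1e-6)
  expect_error(prob_success(-0.1, 0.1), "positive")
})

test_that("success probability is monotone in size and sigma", {
  sizes <- seq(0.02, 0.3, length.out = 10)
  expect_true(all(diff(prob_success(0.08, sizes)) > 0))
  sigmas <- seq(0.02, 0.3, length.out = 10)
  expect_true(all(diff(prob_success(sigmas, 0.15)) < 0))
})

test_that("accept/decline utilities follow the expected-utility form", {
  sp <- choice_spec("normative")
  pars <- list(k_g = 1, k_l = 1, sigma = 0.05, k_t = 0, k0 = 0)
  expect_equal(utility_accept(pars, 5, 1, 0.68269, sp), 3.0962,
               tolerance = 1e-3)
  expect_equal(utility_accept(pars, 4, 4, 0.5, sp), 0)
  # unit curvatures reproduce the plain value exactly
  spc <- choice_spec("normative", curvature = TRUE)
  parsc <- c(pars, c_g = 1, c_l = 1)
  expect_equal(utility_accept(parsc, 5, 2, 0.7, spc),
               utility_accept(pars, 5, 2, 0.7, sp))
  # decline: 0.5 EUR stakes, same p_s
  spd <- choice_spec("normative", include_decline_utility = TRUE)
  expect_equal(utility_decline(list(k_g = 1, k_l = 1, sigma = 0.05), 0.1,
                               spd, p_s = 0.5), 0)
  expect_equal(utility_decline(list(k_g = 2, k_l = 1, sigma = 0.05), 0.1,
                               spd, p_s = 0.8), 0.7)
  expect_equal(utility_decline(pars, 0.1, sp, p_s = 0.8), 0)
})

test_that("acceptance probability is the softmax of net utility", {
  sp <- choice_spec("normative")
  tab <- tibble::tibble(gain = 5, loss = 1, size = 0.1, trial = 1)
  pars <- list(k_g = 1, k_l = 1, sigma = 0.05, k_t = 0, k0 = 0)
  expect_equal(accept_probability(tab, sp, pars), 0.9567, tolerance = 1e-3)
  # zero net utility (p_s = 1/2, equal stakes): softmax midpoint
  tab0 <- tibble::tibble(gain = 3, loss = 3, size = 0.1, trial = 4)
  sigma_half <- 0.05 / stats::qnorm(0.75)  # gives p_s exactly 1/2
  pars0 <- list(k_g = 1, k_l = 1, sigma = sigma_half, k_t = 0, k0 = 0)
  expect_equal(accept_probability(tab0, sp, pars0), 0.5, tolerance = 1e-12)
  # saturation under a huge bias
  pars_sat <- list(k_g = 1, k_l = 1, sigma = 0.05, k_t = 0, k0 = 100)
  expect_gt(accept_probability(tab, sp, pars_sat), 1 - 1e-10)
})

test_that("acceptance is monotone in gain, loss and motor noise", {
  sp <- choice_spec("normative")
  pars <- list(k_g = 1, k_l = 1, sigma = 0.08, k_t = 0, k0 = 0)
  tab_g <- tibble::tibble(gain = 1:5, loss = 3, size = 0.15, trial = 1)
  expect_true(all(diff(accept_probability(tab_g, sp, pars)) > 0))
  tab_l <- tibble::tibble(gain = 3, loss = 1:5, size = 0.15, trial = 1)
  expect_true(all(diff(accept_probability(tab_l, sp, pars)) < 0))
  tab_s <- tibble::tibble(gain = 5, loss = 1, size = seq(0.05, 0.3, 0.05),
                          trial = 1)
  expect_true(all(diff(accept_probability(tab_s, sp, pars)) > 0))
  p_lo <- accept_probability(tab_g, sp, pars)
  pars$sigma <- 0.2
  p_hi <- accept_probability(tab_g, sp, pars)
  expect_true(all(p_hi[tab_g$gain > 3] < p_lo[tab_g$gain > 3]))
})

test_that("descriptive utility matches an independent polynomial oracle", {
  sp1 <- choice_spec("descriptive", regressors = "G")
  expect_equal(descriptive_utility(list(w_g = 2), 3, 1, 0.1, sp1), 6)
  sp0 <- choice_spec("descriptive")
  expect_equal(descriptive_utility(list(), 3, 1, 0.1, sp0), 0)
  full <- choice_spec("descriptive",
                      regressors = c("G", "L", "S", "GL", "GS", "LS", "GLS"))
  w <- list(w_g = 0.5, w_l = -0.8, w_s = 2, w_gl = 0.1, w_gs = -0.2,
            w_ls = 0.3, w_gls = 0.05)
  set.seed(11)
  for (i in 1:5) {
    G <- sample(1:5, 1); L <- sample(1:5, 1); S <- runif(1, 0.03, 0.3)
    oracle <- w$w_g * G + w$w_l * L + w$w_s * S + w$w_gl * G * L +
      w$w_gs * G * S + w$w_ls * L * S + w$w_gls * G * L * S
    expect_equal(descriptive_utility(w, G, L, S, full), oracle)
  }
  expect_error(descriptive_utility(list(w_g = 1, w_l = 1), 3, 1, 0.1, sp1),
               "excluded")
})

test_that("neural-proxy modulation scales parameters as specified", {
  sp <- choice_spec("normative", modulations = c("gain", "loss", "sigma",
                                                 "additive"))
  pars <- list(k_g = 1, k_l = 2, sigma = 0.1, k_t = 0, k0 = 0,
               k_mg = 0.5, k_ml = -0.3, k_msigma = 0.2, k_m0 = 0.4)
  eff0 <- modulate_params(pars, 0, sp)
  expect_equal(eff0$k_g, 1)
  expect_equal(eff0$k_l, 2)
  expect_equal(eff0$sigma, 0.1)
  expect_equal(eff0$additive, 0)
  eff1 <- modulate_params(pars, 1, sp)
  expect_equal(eff1$k_g, 1.5)
  expect_lt(eff1$k_l, 2)  # negative loss modulation with positive proxy
  expect_equal(eff1$additive, 0.4)
  # sigma floor under extreme negative modulation
  effx <- modulate_params(pars, -100, sp)
  expect_gte(effx$sigma, 1e-6)
  expect_error(modulate_params(pars, NaN, sp), "finite")
})

test_that("modulation with zero weights reproduces the base model exactly", {
  base <- best_choice_spec()
  modded <- base
  modded$modulations <- c("gain", "loss", "sigma", "additive")
  tab <- tibble::tibble(gain = c(1, 5, 3), loss = c(2, 2, 4),
                        size = c(0.1, 0.2, 0.15), trial = 1:3)
  pars <- list(k_g = 1.2, k_l = 0.8, sigma = 0.07, k_t = -0.01, k0 = 0.3)
  parsm <- c(pars, k_mg = 0, k_ml = 0, k_msigma = 0, k_m0 = 0)
  npm <- c(-1, 0.5, 2)
  expect_identical(accept_probability(tab, modded, parsm, npm = npm),
                   accept_probability(tab, base, pars))
  expect_error(accept_probability(tab, modded, parsm), "npm")
})

test_that("choice family enumerates 132 models (128 descriptive)", {
  fam <- enumerate_choice_models()
  expect_equal(nrow(fam), 132)
  expect_equal(sum(fam$family == "descriptive"), 128)
  expect_equal(sum(fam$family == "normative"), 4)
  expect_equal(anyDuplicated(fam$model), 0)
  expect_true("normative+decline" %in% fam$model)
  expect_true("descriptive{}" %in% fam$model)
})

test_that("npm variants enumerate all 16 modulation subsets", {
  base <- best_choice_spec()
  fam <- enumerate_npm_models(base)
  expect_equal(nrow(fam), 16)
  expect_equal(anyDuplicated(fam$model), 0)
  expect_identical(fam$spec[[1]]$modulations, character())
  with_gain <- purrr::map_lgl(fam$modulations, ~ "gain" %in% .x)
  expect_equal(sum(with_gain), 8)
  expect_error(enumerate_npm_models(fam$spec[[2]]), "unmodulated")
})

test_that("choice log-likelihood matches direct Bernoulli computation", {
  sp <- choice_spec("normative")
  # chance-level model: -n log 2
  tab <- tibble::tibble(gain = rep(3, 20), loss = 3, size = 0.1,
                        trial = 1:20, choice = rep(c(0L, 1L), 10))
  pars <- list(k_g = 0, k_l = 0, sigma = 0.08, k_t = 0, k0 = 0)
  expect_equal(choice_loglik(tab, sp, pars), -20 * log(2))
  # single trial
  tab1 <- tibble::tibble(gain = 5, loss = 1, size = 0.1, trial = 1,
                         choice = 1L)
  pars1 <- list(k_g = 1, k_l = 1, sigma = 0.05, k_t = 0, k0 = 0)
  expect_equal(choice_loglik(tab1, sp, pars1),
               log(accept_probability(tab1, sp, pars1)))
  # large self-generated sample: per-trial loglik ~ negative binary entropy
  set.seed(12)
  n <- 10000
  tabn <- tibble::tibble(gain = sample(1:5, n, TRUE),
                         loss = sample(1:5, n, TRUE),
                         size = runif(n, 0.03, 0.3), trial = 1:n)
  parsn <- list(k_g = 0.8, k_l = 0.8, sigma = 0.08, k_t = 0, k0 = 0)
  p <- accept_probability(tabn, sp, parsn)
  tabn$choice <- as.integer(runif(n) < p)
  ent <- mean(p * log(p) + (1 - p) * log(1 - p))
  expect_lt(abs(choice_loglik(tabn, sp, parsn) / n - ent), 0.02)
})
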