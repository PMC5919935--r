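#' Group-level random-effects Bayesian model selection
#'
#' Treats the model identity as a random effect across agents: model
#' frequencies `r` get a Dirichlet prior (`alpha0 = 1` per model) and the
#' posterior `Dirichlet(alpha)` is obtained by the standard variational
#' update (iterating agent-wise model responsibilities
#' `u_nk proportional to exp(log-evidence_nk + digamma(alpha_k) -
#' digamma(sum alpha))`). Exceedance probabilities -- the posterior
#' probability that each model is the most frequent in the population -- are
#' estimated by Monte-Carlo sampling of the Dirichlet posterior with a fixed
#' seed and recorded sample count.
#'
#' @param log_evidence Numeric matrix, agents x models (column names used as
#'   model labels), or a tibble with columns `agent`, `model`,
#'   `log_evidence`.
#' @param alpha0 Dirichlet prior count per model (default 1).
#' @param n_samples Monte-Carlo samples for exceedance probabilities
#'   (default 1e5).
#' @param seed Seed for the Dirichlet sampling.
#' @param max_iter,tol Variational-update iteration controls.
#' @return A tibble of class `bms_result` with columns `model`, `alpha`,
#'   `expected_frequency`, `exceedance_probability`; attributes record
#'   `n_agents`, `n_samples`, `seed`, and the responsibility matrix `u`.
#' @export
group_bms <- function(log_evidence, alpha0 = 1, n_samples = 1e5, seed = 1L,
                      max_iter = 500, tol = 1e-8) {
  le <- as_evidence_matrix(log_evidence)
  if (any(!is.finite(le))) {
    bad <- which(!is.finite(le), arr.ind = TRUE)[1, ]
    stop("non-finite log evidence for agent ", bad[1], ", model ",
         colnames(le)[bad[2]], call. = FALSE)
  }
  K <- ncol(le)
  if (K < 2) stop("need at least 2 models", call. = FALSE)
  alpha <- rep(alpha0, K)
  u <- NULL
  for (it in seq_len(max_iter)) {
    w <- sweep(le, 2, digamma(alpha) - digamma(sum(alpha)), "+")
    w <- w - apply(w, 1, max)
    u <- exp(w)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  xp <- dirichlet_exceedance(alpha, n_samples = n_samples, seed = seed)
  out <- tibble::tibble(
    model = colnames(le),
    alpha = alpha,
    expected_frequency = alpha / sum(alpha),
    exceedance_probability = xp
  )
  attr(out, "n_agents") <- nrow(le)
  attr(out, "n_samples") <- n_samples
  attr(out, "seed") <- seed
  attr(out, "u") <- u
  class(out) <- c("bms_result", class(out))
  out
}

as_evidence_matrix <- function(log_evidence) {
  if (is.matrix(log_evidence)) {
    le <- log_evidence
    if (is.null(colnames(le))) {
      colnames(le) <- paste0("model", seq_len(ncol(le)))
    }
    return(le)
  }
  if (is.data.frame(log_evidence)) {
    wide <- tidyr::pivot_wider(log_evidence[c("agent", "model", "log_evidence")],
                               names_from = "model",
                               values_from = "log_evidence")
    le <- as.matrix(wide[setdiff(names(wide), "agent")])
    rownames(le) <- wide$agent
    return(le)
  }
  stop("log_evidence must be a matrix or a tibble", call. = FALSE)
}

# P(r_k is the largest component), by Monte-Carlo Dirichlet sampling
dirichlet_exceedance <- function(alpha, n_samples = 1e5, seed = 1L) {
  set.seed(seed)
  K <- length(alpha)
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              nrow = n_samples)
  win <- max.col(g, ties.method = "random")
  tabulate(win, nbins = K) / n_samples
}

#' Family-level Bayesian model selection
#'
#' Aggregates a model-level random-effects analysis over a disjoint,
#' exhaustive partition of the model space: family frequencies are sums of
#' member frequencies (so the family posterior is the aggregated Dirichlet),
#' and family exceedance probabilities are computed from the same posterior
#' by Monte Carlo.
#'
#' @inheritParams group_bms
#' @param partition Named list of character/integer vectors assigning every
#'   model (column) to exactly one family.
#' @return A `bms_result` tibble at family level.
#' @export
family_bms <- function(log_evidence, partition, alpha0 = 1, n_samples = 1e5,
                       seed = 1L) {
  le <- as_evidence_matrix(log_evidence)
  idx <- purrr::map(partition, function(m) {
    if (is.character(m)) match(m, colnames(le)) else as.integer(m)
  })
  all_idx <- as.integer(sort(unname(unlist(idx))))
  if (anyDuplicated(all_idx)) stop("families overlap", call. = FALSE)
  if (!identical(all_idx, seq_len(ncol(le)))) {
    stop("partition must cover every model exactly once", call. = FALSE)
  }
  fit <- group_bms(le, alpha0 = alpha0, n_samples = n_samples, seed = seed)
  alpha <- fit$alpha
  fam_alpha <- purrr::map_dbl(idx, ~ sum(alpha[.x]))
  set.seed(seed)
  K <- length(alpha)
  g <- matrix(stats::rgamma(n_samples * K, shape = rep(alpha, each = n_samples)),
              nrow = n_samples)
  r <- g / rowSums(g)
  fam_r <- vapply(idx, function(i) rowSums(r[, i, drop = FALSE]),
                  numeric(n_samples))
  win <- max.col(fam_r, ties.method = "random")
  xp <- tabulate(win, nbins = length(idx)) / n_samples
  out <- tibble::tibble(
    model = names(partition),
    alpha = fam_alpha,
    expected_frequency = fam_alpha / sum(alpha),
    exceedance_probability = xp
  )
  attr(out, "n_agents") <- nrow(le)
  attr(out, "n_samples") <- n_samples
  attr(out, "seed") <- seed
  attr(out, "model_level") <- fit
  class(out) <- c("bms_result", class(out))
  out
}

#' Group-level test of fitted parameter values
#'
#' One-sample two-tailed t-test of the per-agent posterior means against
#' zero, with the Wilcoxon signed-rank test as the non-parametric
#' alternative; both are always reported. Zero-variance input yields an
#' undefined t, reported as such rather than an error.
#'
#' @param values Numeric vector of per-agent estimates (one per agent).
#' @param mu Null value (default 0).
#' @return One-row tibble: `n`, `mean`, `t`, `df`, `p_t`, `v_wilcoxon`,
#'   `p_wilcoxon`, `note`.
#' @export
group_param_test <- function(values, mu = 0) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 2) stop("need at least 2 agents", call. = FALSE)
  # treat numerically constant samples as zero-variance (t undefined)
  if (stats::sd(values) <= 1e-12 * (1 + abs(mean(values)))) {
    w <- tryCatch(stats::wilcox.test(values, mu = mu, exact = FALSE),
                  error = function(e) NULL)
    return(tibble::tibble(
      n = n, mean = mean(values), t = NA_real_, df = n - 1, p_t = NA_real_,
      v_wilcoxon = if (is.null(w)) NA_real_ else unname(w$statistic),
      p_wilcoxon = if (is.null(w)) NA_real_ else w$p.value,
      note = "zero variance: t undefined"
    ))
  }
  tt <- stats::t.test(values, mu = mu)
  w <- stats::wilcox.test(values, mu = mu, exact = FALSE)
  tibble::tibble(
    n = n, mean = mean(values), t = unname(tt$statistic),
    df = unname(tt$parameter), p_t = tt$p.value,
    v_wilcoxon = unname(w$statistic), p_wilcoxon = w$p.value,
    note = NA_character_
  )
}
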