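#' Structural specification of a choice model
#'
#' Two families map a prospect (gain, loss, target size) to an acceptance
#' probability through a softmax with constant bias `k0` and linear time
#' drift `k_t`:
#' * `normative`: expected utility
#'   `U(accept) = p_s * k_g * Gain^c_g - (1 - p_s) * k_l * Loss^c_l` with the
#'   success probability `p_s` inferred from the target size; optional
#'   curvatures (prospect-theory style) and an optional explicit decline
#'   utility (same form with 0.5 euro stakes).
#' * `descriptive`: a linear combination of any subset of
#'   \{G, L, S, GL, GS, LS, GLS\} (no decline utility).
#'
#' Neural-proxy modulations (`"gain"`, `"loss"`, `"sigma"`, `"additive"`)
#' scale `k_g`, `k_l`, `sigma` by `(1 + k_m * NPM(t))` or add `k_m0 * NPM(t)`
#' to the utility.
#'
#' @param family `"normative"` or `"descriptive"`.
#' @param include_decline_utility Normative flag: model the decline option's
#'   utility explicitly (otherwise it is absorbed into `k0`).
#' @param curvature Normative flag: free exponents `c_g`, `c_l` in `[0, 1]`.
#' @param regressors Descriptive only: character subset of
#'   `c("G","L","S","GL","GS","LS","GLS")` (may be empty).
#' @param modulations Character subset of
#'   `c("gain","loss","sigma","additive")`.
#' @return An object of class `choice_spec`.
#' @export
#' @examples
#' best <- choice_spec("normative", include_decline_utility = TRUE)
#' choice_param_names(best)
choice_spec <- function(family = c("normative", "descriptive"),
                        include_decline_utility = FALSE,
                        curvature = FALSE,
                        regressors = character(),
                        modulations = character()) {
  family <- match.arg(family)
  all_regs <- c("G", "L", "S", "GL", "GS", "LS", "GLS")
  all_mods <- c("gain", "loss", "sigma", "additive")
  if (!all(regressors %in% all_regs)) {
    stop("unknown regressor(s): ",
         paste(setdiff(regressors, all_regs), collapse = ", "), call. = FALSE)
  }
  if (!all(modulations %in% all_mods)) {
    stop("unknown modulation(s): ",
         paste(setdiff(modulations, all_mods), collapse = ", "), call. = FALSE)
  }
  if (family == "descriptive" && (include_decline_utility || curvature)) {
    stop("decline utility and curvature are normative-family options",
         call. = FALSE)
  }
  if (family == "normative" && length(regressors)) {
    stop("regressors are a descriptive-family option", call. = FALSE)
  }
  structure(
    list(family = family,
         include_decline_utility = include_decline_utility,
         curvature = curvature,
         regressors = regressors[order(match(regressors, all_regs))],
         modulations = modulations[order(match(modulations, all_mods))]),
    class = "choice_spec"
  )
}

#' @export
print.choice_spec <- function(x, ...) {
  cat("<choice_spec>", choice_model_label(x), "\n")
  invisible(x)
}

#' Short label for a choice model
#' @param spec A [choice_spec()].
#' @return Character scalar.
#' @export
choice_model_label <- function(spec) {
  lab <- if (spec$family == "normative") {
    paste0("normative",
           if (spec$include_decline_utility) "+decline" else "",
           if (spec$curvature) "+curvature" else "")
  } else {
    paste0("descriptive{",
           paste(spec$regressors, collapse = ","), "}")
  }
  if (length(spec$modulations)) {
    lab <- paste0(lab, " mod{", paste(spec$modulations, collapse = ","), "}")
  }
  lab
}

#' Free parameters required by a choice model
#' @param spec A [choice_spec()].
#' @return Character vector of parameter names.
#' @export
choice_param_names <- function(spec) {
  p <- if (spec$family == "normative") {
    c("k_g", "k_l", "sigma",
      if (spec$curvature) c("c_g", "c_l"))
  } else {
    if (length(spec$regressors)) paste0("w_", tolower(spec$regressors)) else character()
  }
  p <- c(p, "k_t", "k0")
  mods <- spec$modulations
  if ("gain" %in% mods) p <- c(p, "k_mg")
  if ("loss" %in% mods) p <- c(p, "k_ml")
  if ("sigma" %in% mods) p <- c(p, "k_msigma")
  if ("additive" %in% mods) p <- c(p, "k_m0")
  p
}

check_choice_params <- function(spec, params) {
  missing <- setdiff(choice_param_names(spec), names(params))
  if (length(missing)) {
    stop("missing choice parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (spec$family == "normative" && params[["sigma"]] <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  for (cc in c("c_g", "c_l")) {
    if (!is.null(params[[cc]]) && (params[[cc]] < 0 || params[[cc]] > 1)) {
      stop(cc, " must lie in [0, 1]", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Enumerate the full choice-model family
#'
#' Four pseudo-normative models (decline-utility x curvature) plus all
#' 2^7 = 128 descriptive regressor subsets (including the empty subset):
#' 132 models.
#'
#' @return Tibble with `model`, `spec` (list-column), `family`, `n_params`.
#' @export
#' @examples
#' nrow(enumerate_choice_models())  # 132
enumerate_choice_models <- function() {
  norm <- purrr::pmap(
    expand.grid(include_decline_utility = c(FALSE, TRUE),
                curvature = c(FALSE, TRUE)),
    function(include_decline_utility, curvature) {
      choice_spec("normative",
                  include_decline_utility = include_decline_utility,
                  curvature = curvature)
    })
  all_regs <- c("G", "L", "S", "GL", "GS", "LS", "GLS")
  subsets <- purrr::map(0:127, function(bits) {
    all_regs[bitwAnd(bits, 2^(0:6)) > 0]
  })
  desc <- purrr::map(subsets, ~ choice_spec("descriptive", regressors = .x))
  specs <- c(norm, desc)
  tibble::tibble(
    model = purrr::map_chr(specs, choice_model_label),
    spec = specs,
    family = purrr::map_chr(specs, "family"),
    n_params = purrr::map_int(specs, ~ length(choice_param_names(.x)))
  )
}

#' Enumerate the neural-proxy modulation variants of a base choice model
#'
#' All 2^4 = 16 subsets of the modulations
#' \{gain, loss, sigma, additive\} applied to the selected base model.
#'
#' @param base A [choice_spec()] without modulations.
#' @return Tibble with `model`, `spec` (list-column), `modulations`
#'   (list-column of character vectors).
#' @export
#' @examples
#' nrow(enumerate_npm_models(choice_spec("normative",
#'                                       include_decline_utility = TRUE)))
enumerate_npm_models <- function(base) {
  stopifnot(inherits(base, "choice_spec"))
  if (length(base$modulations)) {
    stop("base model must be unmodulated", call. = FALSE)
  }
  all_mods <- c("gain", "loss", "sigma", "additive")
  subsets <- purrr::map(0:15, function(bits) all_mods[bitwAnd(bits, 2^(0:3)) > 0])
  specs <- purrr::map(subsets, function(m) {
    s <- base
    s$modulations <- m
    s
  })
  tibble::tibble(
    model = purrr::map_chr(specs, choice_model_label),
    spec = specs,
    modulations = subsets
  )
}
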