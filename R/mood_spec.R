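#' Structural specification of a mood model
#'
#' A mood model integrates task events into a theoretical mood level (TML)
#' with exponential forgetting. Structural options: which task feeds mood
#' (`source`); `simplified` replaces the separate weights on quiz expected
#' value and prediction error by a single feedback weight `omega_f`
#' (algebraically, `omega_f = omega_q1 = omega_q2`); `asymmetric` codes
#' positive feedback as a free magnitude `R > 0` instead of 1; `reciprocal`
#' lets mood bias the subjective perception of feedback,
#' `F(t) = feedback(t) + delta * TML(t-1)`. The last three options only apply
#' when quiz feedback is among the sources.
#'
#' @param source One of `"null"`, `"quiz_only"`, `"choice_only"`, `"both"`.
#' @param simplified,asymmetric,reciprocal Logical structural flags.
#' @return An object of class `mood_spec`.
#' @export
#' @examples
#' best <- mood_spec("quiz_only", simplified = TRUE, asymmetric = TRUE,
#'                   reciprocal = TRUE)
#' mood_param_names(best)
mood_spec <- function(source = c("quiz_only", "both", "choice_only", "null"),
                      simplified = FALSE, asymmetric = FALSE,
                      reciprocal = FALSE) {
  source <- match.arg(source)
  quiz <- source %in% c("quiz_only", "both")
  if (!quiz && (simplified || asymmetric || reciprocal)) {
    stop("simplified/asymmetric/reciprocal require quiz feedback in the source",
         call. = FALSE)
  }
  structure(
    list(source = source, simplified = simplified,
         asymmetric = asymmetric, reciprocal = reciprocal),
    class = "mood_spec"
  )
}

mood_uses_quiz <- function(spec) spec$source %in% c("quiz_only", "both")
mood_uses_choice <- function(spec) spec$source %in% c("choice_only", "both")

#' @export
print.mood_spec <- function(x, ...) {
  cat("<mood_spec>", mood_model_label(x), "\n")
  invisible(x)
}

#' Short human-readable label for a mood model
#' @param spec A [mood_spec()].
#' @return Character scalar.
#' @export
mood_model_label <- function(spec) {
  flags <- c(if (spec$simplified) "simplified",
             if (spec$asymmetric) "asymmetric",
             if (spec$reciprocal) "reciprocal")
  paste0(spec$source,
         if (length(flags)) paste0(" + ", paste(flags, collapse = "+")) else "")
}

#' Free parameters required by a mood model
#'
#' Every model carries a constant `omega0`, a linear time weight `omega_t`
#' and the rating observation noise `obs_sd`. Models with any task source add
#' the forgetting factor `gamma`; quiz sources add either `omega_f`
#' (simplified) or `omega_q1`/`omega_q2`, plus `R` (asymmetric) and `delta`
#' (reciprocal) when flagged; choice sources add `omega_p`.
#'
#' @param spec A [mood_spec()].
#' @return Character vector of parameter names.
#' @export
mood_param_names <- function(spec) {
  p <- c("omega0", "omega_t")
  if (spec$source != "null") p <- c(p, "gamma")
  if (mood_uses_quiz(spec)) {
    p <- c(p, if (spec$simplified) "omega_f" else c("omega_q1", "omega_q2"))
    if (spec$asymmetric) p <- c(p, "R")
    if (spec$reciprocal) p <- c(p, "delta")
  }
  if (mood_uses_choice(spec)) p <- c(p, "omega_p")
  c(p, "obs_sd")
}

check_mood_params <- function(spec, params) {
  missing <- setdiff(mood_param_names(spec), names(params))
  if (length(missing)) {
    stop("missing mood parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(params[["gamma"]]) &&
      (params[["gamma"]] < 0 || params[["gamma"]] > 1)) {
    stop("gamma must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(params[["R"]]) && params[["R"]] <= 0) {
    stop("R must be positive", call. = FALSE)
  }
  if (!is.null(params[["obs_sd"]]) && params[["obs_sd"]] <= 0) {
    stop("obs_sd must be positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' Enumerate the full mood-model family
#'
#' One null model (mood a linear function of trial index only), one
#' choice-only model, and all 16 combinations of
#' source in \{quiz_only, both\} x simplified x asymmetric x reciprocal:
#' 18 distinct models in total.
#'
#' @return Tibble with one row per model: `model` (label), `spec`
#'   (list-column of [mood_spec()] objects), `n_params`.
#' @export
#' @examples
#' nrow(enumerate_mood_models())  # 18
enumerate_mood_models <- function() {
  specs <- list(mood_spec("null"), mood_spec("choice_only"))
  grid <- expand.grid(source = c("quiz_only", "both"),
                      simplified = c(FALSE, TRUE),
                      asymmetric = c(FALSE, TRUE),
                      reciprocal = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  specs <- c(specs, purrr::pmap(grid, function(source, simplified, asymmetric,
                                               reciprocal) {
    mood_spec(source, simplified = simplified, asymmetric = asymmetric,
              reciprocal = reciprocal)
  }))
  tibble::tibble(
    model = purrr::map_chr(specs, mood_model_label),
    spec = specs,
    n_params = purrr::map_int(specs, ~ length(mood_param_names(.x)))
  )
}
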