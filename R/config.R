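#' Coach configuration
#'
#' Bundles every tunable of the decision engine with its default. All
#' behavioural knobs of the coach are configuration, not code: the wait
#' brackets between interventions, the veto cap of the acceptance model,
#' its warm-up threshold, the feature-selection cadence, and the difficulty
#' suggestion thresholds.
#'
#' @param wait_brackets data.frame with columns `min_score` and `wait_min`;
#'   the wait imposed after the previous delivery is the `wait_min` of the
#'   first row whose `min_score` the selected item's priority score reaches.
#'   Rows must be in decreasing `min_score` order. Default: score >= 1.1
#'   waits 0 min, >= 0.6 waits 15 min, anything lower waits 45 min.
#' @param max_vetoes maximum number of consecutive deliveries the acceptance
#'   model may cancel (default 3).
#' @param warm_threshold labelled outcomes required before the model's
#'   predictions are used at all; below it `predict` returns 0.5 exactly and
#'   the veto is disabled (default 20).
#' @param veto_threshold predicted acceptance probability below which the
#'   model counts as predicting a rejection (default 0.5).
#' @param learning_rate SGD step size of the online logistic classifier.
#' @param selection_period new labelled samples between feature-selection
#'   refits (default 50).
#' @param top_k number of features kept by each feature-selection refit.
#' @param harder_frac,easier_frac difficulty-suggestion thresholds: overall
#'   completion at or above `harder_frac` of the summed weekly maxima
#'   suggests a harder level; below `easier_frac` of the summed weekly
#'   minima suggests an easier one.
#' @param insight_effect_sd user-model insights require the last-7-day mean
#'   of the tracked series to exceed the last-30-day mean by this many
#'   pooled standard deviations (default 0.5).
#' @param vocab named list of categorical feature vocabularies used by the
#'   acceptance model's one-hot encoding; see [feature_vocabularies()].
#' @param ... overrides stored verbatim.
#'
#' @return an object of class `coach_config` (a named list).
#' @export
coach_config <- function(wait_brackets = data.frame(
                           min_score = c(1.1, 0.6, -Inf),
                           wait_min = c(0, 15, 45)),
                         max_vetoes = 3L,
                         warm_threshold = 20L,
                         veto_threshold = 0.5,
                         learning_rate = 0.05,
                         selection_period = 50L,
                         top_k = 8L,
                         harder_frac = 0.8,
                         easier_frac = 0.5,
                         insight_effect_sd = 0.5,
                         vocab = feature_vocabularies(),
                         ...) {
  stopifnot(is.data.frame(wait_brackets),
            all(c("min_score", "wait_min") %in% names(wait_brackets)),
            !is.unsorted(rev(wait_brackets$min_score)))
  cfg <- list(wait_brackets = wait_brackets,
              max_vetoes = as.integer(max_vetoes),
              warm_threshold = as.integer(warm_threshold),
              veto_threshold = veto_threshold,
              learning_rate = learning_rate,
              selection_period = as.integer(selection_period),
              top_k = as.integer(top_k),
              harder_frac = harder_frac,
              easier_frac = easier_frac,
              insight_effect_sd = insight_effect_sd,
              vocab = vocab)
  extra <- list(...)
  cfg[names(extra)] <- extra
  structure(cfg, class = "coach_config")
}

#' Read a coach configuration from a YAML file
#'
#' Every default of [coach_config()] can be overridden from a YAML document;
#' unknown keys are kept (forward compatible). `wait_brackets` may be given
#' as a list of `{min_score, wait_min}` mappings.
#'
#' @param path path to a YAML file.
#' @return a `coach_config`.
#' @export
read_coach_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$wait_brackets)) {
    wb <- do.call(rbind, lapply(raw$wait_brackets, function(r) {
      data.frame(min_score = as.numeric(r$min_score),
                 wait_min = as.numeric(r$wait_min))
    }))
    raw$wait_brackets <- wb[order(-wb$min_score), , drop = FALSE]
  }
  do.call(coach_config, raw)
}

#' @export
print.coach_config <- function(x, ...) {
  cat("Coach configuration\n")
  cat(sprintf("  wait brackets: %s\n",
              paste(sprintf(">=%.2f: %gmin", x$wait_brackets$min_score,
                            x$wait_brackets$wait_min), collapse = ", ")))
  cat(sprintf("  veto: cap %d consecutive, threshold %.2f, warm after %d outcomes\n",
              x$max_vetoes, x$veto_threshold, x$warm_threshold))
  cat(sprintf("  learner: lr %.3f, feature selection every %d samples, top %d\n",
              x$learning_rate, x$selection_period, x$top_k))
  invisible(x)
}

wait_for_score <- function(score, cfg) {
  wb <- cfg$wait_brackets
  wb$wait_min[match(TRUE, score >= wb$min_score)]
}
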