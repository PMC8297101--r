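#' Incremental accept/reject model
#'
#' A per-participant online classifier predicting whether an intervention
#' offered in the current context will be accepted. It learns one labelled
#' example at a time (no refit per update), and periodically — when enough
#' new samples have accumulated — re-ranks all features by mutual
#' information with the label and keeps the top k, re-initialising the
#' classifier on the new subset and replaying the stored samples. The
#' classifier is an online logistic regression over one-hot encoded
#' categorical features.
#'
#' @name acceptance_model
NULL

#' Default categorical feature vocabularies
#'
#' Declares the levels of every feature of the context vector. Values
#' outside a vocabulary (and absent optional fields) encode as "unknown".
#'
#' @return named list of character vectors.
#' @export
feature_vocabularies <- function() {
  list(
    hour_of_day = as.character(0:23),
    day_of_week = as.character(1:7),
    minutes_since_last = c("none", "lt15", "lt30", "lt60", "lt120", "ge120"),
    room = c("living_room", "kitchen", "bedroom", "bathroom", "hall"),
    posture = c("sitting", "standing", "walking", "lying"),
    emotion = c("positive", "negative", "neutral"),
    interacting_object = c("none", "sofa", "fridge", "table", "tv"),
    weather = c("sunny", "cloudy", "rainy"),
    tool_type = c("quiz", "physical_trainer", "cognitive_game",
                  "recipe_recommender", "social_recommender"),
    rejections_today = c("0", "1", "2", "3plus"),
    consecutive_rejections = c("0", "1", "2", "3plus"),
    last_outcome_tool = c("none", "accepted", "rejected"))
}

encode_level <- function(value, vocab) {
  v <- as.character(value)
  if (length(v) != 1L || is.na(v) || !v %in% vocab) "unknown" else v
}

bin_count <- function(n) {
  if (n >= 3L) "3plus" else as.character(n)
}

bin_minutes <- function(m) {
  if (is.null(m) || is.na(m)) "none"
  else if (m < 15) "lt15" else if (m < 30) "lt30"
  else if (m < 60) "lt60" else if (m < 120) "lt120" else "ge120"
}

#' Delivery-history summary for feature extraction
#'
#' @param log the event log.
#' @param tool_type candidate tool.
#' @param clock POSIXct now.
#' @return list with `minutes_since_last`, `rejections_today`,
#'   `consecutive_rejections` and `last_outcome_tool`.
#' @export
history_from_log <- function(log, tool_type, clock) {
  date <- clock_date(clock)
  if (nrow(log) == 0L)
    return(list(minutes_since_last = NA_real_, rejections_today = 0L,
                consecutive_rejections = 0L, last_outcome_tool = "none"))
  minutes_since_last <- as.numeric(difftime(clock, max(log$time),
                                            units = "mins"))
  rejections_today <- sum(log$date == date & log$outcome == "rejected")
  run <- 0L
  for (i in rev(seq_len(nrow(log)))) {
    if (log$outcome[i] == "rejected") run <- run + 1L else break
  }
  tool_rows <- which(log$tool_type == tool_type)
  last_outcome_tool <- if (length(tool_rows) == 0L) "none"
  else if (log$outcome[max(tool_rows)] == "completed") "accepted"
  else "rejected"
  list(minutes_since_last = minutes_since_last,
       rejections_today = rejections_today, consecutive_rejections = run,
       last_outcome_tool = last_outcome_tool)
}

#' Extract the context feature vector for a candidate delivery
#'
#' Deterministic symbolic encoding of participant status (room, posture,
#' emotion, interacting object), timing (hour of day, day of week, minutes
#' since the last delivery), rejection history and environment (weather),
#' plus the candidate tool type. Missing optional fields map to explicit
#' "unknown"/"none" codes, never an error.
#'
#' @param p a `participant_state`.
#' @param e an `environment_state`.
#' @param clock POSIXct now.
#' @param history a list as returned by [history_from_log()].
#' @param tool_type candidate tool type.
#' @param vocab feature vocabularies; see [feature_vocabularies()].
#' @return named character vector of class `feature_vector`.
#' @export
extract_features <- function(p, e, clock, history, tool_type,
                             vocab = feature_vocabularies()) {
  x <- c(
    hour_of_day = as.character(minute_of_day(clock) %/% 60L),
    day_of_week = as.character(iso_wday(clock_date(clock))),
    minutes_since_last = bin_minutes(history$minutes_since_last),
    room = encode_level(p$room, vocab$room),
    posture = encode_level(p$posture, vocab$posture),
    emotion = encode_level(p$emotion, vocab$emotion),
    interacting_object = if (is.na(p$interacting_object)) "none"
      else encode_level(p$interacting_object, vocab$interacting_object),
    weather = encode_level(e$weather, vocab$weather),
    tool_type = encode_level(tool_type, vocab$tool_type),
    rejections_today = bin_count(history$rejections_today),
    consecutive_rejections = bin_count(history$consecutive_rejections),
    last_outcome_tool = encode_level(history$last_outcome_tool,
                                     vocab$last_outcome_tool))
  structure(x, class = "feature_vector")
}

#' Create an empty acceptance model
#'
#' @param cfg a [coach_config()]; supplies the learning rate, warm-up
#'   threshold, feature-selection period and subset size.
#' @return an `acceptance_model` with all features selected, zero weights
#'   and an empty sample store.
#' @export
acceptance_model <- function(cfg = coach_config()) {
  structure(list(weights = c(`(bias)` = 0),
                 selected_features = names(cfg$vocab),
                 samples = list(), n_samples = 0L,
                 n_since_selection = 0L, cfg = cfg),
            class = "acceptance_model")
}

#' @export
print.acceptance_model <- function(x, ...) {
  cat(sprintf("Acceptance model: %d labelled outcome(s) (%s), %d/%d features selected\n",
              x$n_samples,
              if (model_is_warm(x, x$cfg)) "warm" else "cold",
              length(x$selected_features), length(x$cfg$vocab)))
  cat("  selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Is the model past its warm-up?
#' @param m an `acceptance_model`.
#' @param cfg a [coach_config()].
#' @return logical.
#' @export
model_is_warm <- function(m, cfg = m$cfg) m$n_samples >= cfg$warm_threshold

active_columns <- function(m, x) {
  feats <- intersect(names(x), m$selected_features)
  paste0(feats, "=", unname(x[feats]))
}

linear_score <- function(m, x) {
  cols <- active_columns(m, x)
  w <- m$weights[cols]
  w[is.na(w)] <- 0
  m$weights[["(bias)"]] + sum(w)
}

#' Predict the acceptance probability of a candidate delivery
#'
#' An un-warm model (fewer labelled outcomes than the warm-up threshold)
#' returns 0.5 exactly; a warm model returns the logistic score over the
#' currently selected features only.
#'
#' @param object an `acceptance_model`.
#' @param x a [extract_features()] vector.
#' @param ... unused.
#' @return probability of acceptance in `[0, 1]`.
#' @export
predict.acceptance_model <- function(object, x, ...) {
  if (!model_is_warm(object, object$cfg)) return(0.5)
  stats::plogis(linear_score(object, x))
}

sgd_step <- function(m, x, accepted) {
  p <- stats::plogis(linear_score(m, x))
  grad <- p - as.numeric(accepted)
  lr <- m$cfg$learning_rate
  cols <- active_columns(m, x)
  missing_cols <- setdiff(cols, names(m$weights))
  if (length(missing_cols) > 0L) {
    new <- rep(0, length(missing_cols)); names(new) <- missing_cols
    m$weights <- c(m$weights, new)
  }
  m$weights[cols] <- m$weights[cols] - lr * grad
  m$weights[["(bias)"]] <- m$weights[["(bias)"]] - lr * grad
  m
}

#' Learn from one labelled outcome
#'
#' Single-example incremental update (one SGD step on the logistic loss
#' over the selected features); the sample is appended to the store and the
#' feature-selection counter advances. O(1) in the stored history.
#'
#' @param object an `acceptance_model`.
#' @param x the [extract_features()] vector at delivery time.
#' @param accepted logical outcome label.
#' @param ... unused.
#' @return the updated model.
#' @export
update.acceptance_model <- function(object, x, accepted, ...) {
  object <- sgd_step(object, x, accepted)
  object$samples[[length(object$samples) + 1L]] <-
    list(x = unclass(x), y = isTRUE(accepted))
  object$n_samples <- object$n_samples + 1L
  object$n_since_selection <- object$n_since_selection + 1L
  object
}

# Empirical mutual information (nats) between a categorical feature and
# the binary label.
mutual_information <- function(f, y) {
  tab <- table(f, y)
  n <- sum(tab)
  if (n == 0L) return(0)
  pxy <- tab / n
  px <- rowSums(pxy); py <- colSums(pxy)
  mi <- 0
  for (i in seq_along(px)) for (j in seq_along(py)) {
    if (pxy[i, j] > 0)
      mi <- mi + pxy[i, j] * log(pxy[i, j] / (px[i] * py[j]))
  }
  mi
}

#' Periodically re-fit the feature selection
#'
#' No-op until `cfg$selection_period` new samples have accumulated since
#' the last refit. Then every feature is scored by the mutual information
#' between its (categorical) values and the accept/reject label over the
#' whole sample store; the top `cfg$top_k` become the selected subset (all
#' features when k exceeds the feature count), the classifier weights are
#' re-initialised on that subset and the stored samples are replayed in
#' order.
#'
#' @param m an `acceptance_model`.
#' @param cfg a [coach_config()]; defaults to the model's own.
#' @return the (possibly refreshed) model.
#' @export
refresh_feature_selection <- function(m, cfg = m$cfg) {
  if (m$n_since_selection < cfg$selection_period) return(m)
  y <- vapply(m$samples, function(s) s$y, TRUE)
  feats <- names(cfg$vocab)
  mi <- vapply(feats, function(f) {
    vals <- vapply(m$samples, function(s) s$x[[f]], "")
    mutual_information(vals, y)
  }, 0)
  k <- min(cfg$top_k, length(feats))
  selected <- feats[order(-mi, feats)][seq_len(k)]
  m$selected_features <- selected
  m$weights <- c(`(bias)` = 0)
  for (s in m$samples) m <- sgd_step(m, s$x, s$y)
  m$n_since_selection <- 0L
  m$feature_scores <- mi
  m
}

#' Serialize / restore the model state
#'
#' The full state (weights, selected features, stored samples, counters)
#' round-trips through a single JSON document, so a coach can save and
#' resume mid-stream with an identical subsequent trace.
#'
#' @param m an `acceptance_model`.
#' @param path output path.
#' @return `path` invisibly (`write`), the restored model (`read`).
#' @export
write_acceptance_model <- function(m, path) {
  doc <- list(weights = as.list(m$weights),
              selected_features = m$selected_features,
              samples = lapply(m$samples, function(s)
                list(x = as.list(s$x), y = s$y)),
              n_samples = m$n_samples,
              n_since_selection = m$n_since_selection)
  writeLines(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE,
                                           digits = NA)), path)
  invisible(path)
}

#' @rdname write_acceptance_model
#' @param cfg the [coach_config()] to attach to the restored model.
#' @export
read_acceptance_model <- function(path, cfg = coach_config()) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  m <- acceptance_model(cfg)
  m$weights <- unlist(doc$weights)
  m$selected_features <- unlist(doc$selected_features)
  m$samples <- lapply(doc$samples, function(s)
    list(x = unlist(s$x), y = isTRUE(s$y)))
  m$n_samples <- as.integer(doc$n_samples)
  m$n_since_selection <- as.integer(doc$n_since_selection)
  m
}
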