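#' Symbolic participant state
#'
#' The aggregated view of the sensed person that the momentary planner and
#' the acceptance model consume: presence, room, posture/activity, the
#' object being interacted with, the recognised emotion and the last speech
#' command. `room_since` / `posture_since` carry the onset times needed by
#' duration-based trigger conditions ("sitting for more than 30 min").
#'
#' @param present logical.
#' @param room room name; must be `NA` when not present.
#' @param posture posture/activity label (e.g. "sitting", "standing").
#' @param interacting_object object currently touched, or `NA`.
#' @param emotion categorical emotion label, or `NA` when unavailable.
#' @param last_speech_command recognised command, or `NA`.
#' @param timestamp POSIXct.
#' @param room_since,posture_since POSIXct onset of the current room /
#'   posture; default `timestamp`.
#' @return a `participant_state`.
#' @export
participant_state <- function(present, room = NA_character_,
                              posture = NA_character_,
                              interacting_object = NA_character_,
                              emotion = NA_character_,
                              last_speech_command = NA_character_,
                              timestamp = Sys.time(),
                              room_since = timestamp,
                              posture_since = timestamp) {
  if (!present && !is.na(room))
    stop("room must be unset when the participant is not present")
  structure(list(present = isTRUE(present), room = room, posture = posture,
                 interacting_object = interacting_object, emotion = emotion,
                 last_speech_command = last_speech_command,
                 timestamp = timestamp, room_since = room_since,
                 posture_since = posture_since),
            class = "participant_state")
}

#' Symbolic environment state
#'
#' @param weather categorical weather label (e.g. "sunny").
#' @param timestamp POSIXct.
#' @return an `environment_state`.
#' @export
environment_state <- function(weather, timestamp = Sys.time()) {
  structure(list(weather = weather, timestamp = timestamp),
            class = "environment_state")
}

#' Trigger condition expression
#'
#' A conjunction of symbolic predicates over the participant/environment
#' state, each an equality test on one field with an optional minimum
#' duration (supported for `room` and `posture`, whose onsets are tracked).
#' Serializes naturally to/from the plugin JSON.
#'
#' @param ... predicates, each a list with `field`, `value` and optionally
#'   `min_duration_min`.
#' @return a `condition_expr`.
#' @examples
#' # sitting for at least 30 minutes
#' condition_expr(list(field = "posture", value = "sitting",
#'                     min_duration_min = 30))
#' # touching the fridge
#' condition_expr(list(field = "interacting_object", value = "fridge"))
#' @export
condition_expr <- function(...) {
  preds <- list(...)
  if (length(preds) == 1L && is.null(preds[[1]]$field) &&
      is.list(preds[[1]][[1]]))
    preds <- preds[[1]]  # accept a single list-of-predicates
  for (p in preds)
    stopifnot(is.character(p$field), !is.null(p$value))
  structure(list(all = preds), class = "condition_expr")
}

condition_fields <- c("room", "posture", "interacting_object", "emotion",
                      "last_speech_command", "weather")

#' Evaluate a trigger condition
#'
#' Total over well-formed states: unknown fields and absent state values
#' evaluate to `FALSE`, never an error.
#'
#' @param cond a `condition_expr` (or `NULL`, which is vacuously true).
#' @param p a `participant_state`.
#' @param e an `environment_state`.
#' @param clock POSIXct now.
#' @return logical scalar.
#' @export
eval_condition <- function(cond, p, e, clock) {
  if (is.null(cond)) return(TRUE)
  for (pred in cond$all) {
    val <- if (pred$field == "weather") e$weather else p[[pred$field]]
    if (is.null(val) || is.na(val) || !identical(as.character(val),
                                                 as.character(pred$value)))
      return(FALSE)
    if (!is.null(pred$min_duration_min)) {
      since <- switch(pred$field, room = p$room_since,
                      posture = p$posture_since, NULL)
      if (is.null(since)) return(FALSE)
      held <- as.numeric(difftime(clock, since, units = "mins"))
      if (held < pred$min_duration_min) return(FALSE)
    }
  }
  TRUE
}
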