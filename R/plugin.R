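#' SMART goal plugins
#'
#' A SMART goal plugin is a self-contained care plan: a specific,
#' measurable, achievable, relevant, time-limited objective in one of the
#' four coaching dimensions (cognitive, physical, social, nutritional),
#' broken into 4-8 weekly plans per difficulty level. Each weekly plan lists
#' intervention requirements: an abstract tool type with minimum and maximum
#' weekly counts, an optional within-day time window and an optional
#' symbolic trigger condition. Plugins also carry awareness tips and the
#' mandatory fallback motivational messages that guarantee the day-insight
#' generator is total.
#'
#' @name goal_plugin
NULL

goal_dimensions <- c("cognitive", "physical", "social", "nutritional")

#' Construct an intervention requirement
#'
#' @param tool_type registered abstract tool name (e.g. "quiz",
#'   "physical_trainer", "recipe_recommender").
#' @param min_count,max_count non-negative weekly counts, `min_count <=
#'   max_count`.
#' @param time_window optional [time_window()].
#' @param trigger_condition optional [condition_expr()].
#' @param tool_payload opaque configuration passed to the tool; kept
#'   verbatim.
#' @return an `intervention_requirement`.
#' @export
intervention_requirement <- function(tool_type, min_count, max_count,
                                     time_window = NULL,
                                     trigger_condition = NULL,
                                     tool_payload = NULL) {
  structure(list(tool_type = tool_type,
                 min_count = as.integer(min_count),
                 max_count = as.integer(max_count),
                 time_window = time_window,
                 trigger_condition = trigger_condition,
                 tool_payload = tool_payload),
            class = "intervention_requirement")
}

#' Construct a difficulty level
#'
#' @param level_name unique name within the plugin.
#' @param duration_weeks plan length, 4-8 weeks.
#' @param weekly_plans list of length `duration_weeks`; element `w` is the
#'   list of [intervention_requirement()]s for week `w`.
#' @return a `difficulty_level`.
#' @export
difficulty_level <- function(level_name, duration_weeks, weekly_plans) {
  structure(list(level_name = level_name,
                 duration_weeks = as.integer(duration_weeks),
                 weekly_plans = weekly_plans),
            class = "difficulty_level")
}

#' Construct a goal plugin in code
#'
#' @param plugin_id stable identifier.
#' @param title human-readable title.
#' @param dimension one of cognitive, physical, social, nutritional.
#' @param description free text shown in the catalogue.
#' @param requirements free-text joining requirements (display only; the
#'   engine never evaluates them).
#' @param difficulty_levels list of [difficulty_level()]s.
#' @param awareness_tips goal-based insight messages.
#' @param fallback_messages plain general messages; at least one is
#'   mandatory so a day insight can always be produced.
#' @param extra unknown fields preserved from a loaded file.
#' @return a `goal_plugin` (not validated; see [validate_goal_plugin()]).
#' @export
goal_plugin <- function(plugin_id, title, dimension, description = "",
                        requirements = character(), difficulty_levels = list(),
                        awareness_tips = character(),
                        fallback_messages = character(), extra = list()) {
  structure(list(plugin_id = plugin_id, title = title, dimension = dimension,
                 description = description,
                 requirements = as.character(requirements),
                 difficulty_levels = difficulty_levels,
                 awareness_tips = as.character(awareness_tips),
                 fallback_messages = as.character(fallback_messages),
                 extra = extra),
            class = "goal_plugin")
}

#' @export
print.goal_plugin <- function(x, ...) {
  cat(sprintf("SMART goal plugin '%s' (%s): %s\n", x$plugin_id, x$dimension,
              x$title))
  for (lv in x$difficulty_levels)
    cat(sprintf("  level '%s': %d weeks\n", lv$level_name, lv$duration_weeks))
  cat(sprintf("  %d awareness tip(s), %d fallback message(s)\n",
              length(x$awareness_tips), length(x$fallback_messages)))
  invisible(x)
}

violation <- function(code, path, message) {
  data.frame(code = code, path = path, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a goal plugin
#'
#' Checks every structural invariant of the plugin format and reports all
#' violations, not just the first. Validation never throws.
#'
#' @param plugin a `goal_plugin`.
#' @return a data.frame with columns `code`, `path`, `message`; zero rows
#'   iff the plugin is valid.
#' @export
validate_goal_plugin <- function(plugin) {
  v <- list()
  add <- function(code, path, msg) v[[length(v) + 1L]] <<- violation(code, path, msg)

  if (!is.character(plugin$plugin_id) || !nzchar(plugin$plugin_id))
    add("ID_REQUIRED", "plugin_id", "plugin_id must be a non-empty string")
  if (!plugin$dimension %in% goal_dimensions)
    add("DIMENSION_INVALID", "dimension",
        sprintf("dimension must be one of %s",
                paste(goal_dimensions, collapse = ", ")))
  if (length(plugin$fallback_messages) < 1L)
    add("FALLBACK_REQUIRED", "fallback_messages",
        "at least one fallback message must accompany every goal configuration")
  if (length(plugin$difficulty_levels) < 1L)
    add("LEVELS_REQUIRED", "difficulty_levels",
        "at least one difficulty level is required")
  lnames <- vapply(plugin$difficulty_levels, function(l) l$level_name, "")
  if (anyDuplicated(lnames))
    add("LEVEL_NAMES_UNIQUE", "difficulty_levels",
        "difficulty level names must be unique")

  for (i in seq_along(plugin$difficulty_levels)) {
    lv <- plugin$difficulty_levels[[i]]
    lp <- sprintf("difficulty_levels[%d]", i)
    if (lv$duration_weeks < 4L || lv$duration_weeks > 8L)
      add("DURATION_RANGE", paste0(lp, ".duration_weeks"),
          sprintf("duration_weeks is %d; plans must span 4-8 weeks",
                  lv$duration_weeks))
    if (length(lv$weekly_plans) != lv$duration_weeks)
      add("WEEKLY_PLANS_COVERAGE", paste0(lp, ".weekly_plans"),
          sprintf("expected one weekly plan per week 1..%d, found %d",
                  lv$duration_weeks, length(lv$weekly_plans)))
    for (w in seq_along(lv$weekly_plans)) {
      for (j in seq_along(lv$weekly_plans[[w]])) {
        req <- lv$weekly_plans[[w]][[j]]
        rp <- sprintf("%s.weekly_plans[%d][%d]", lp, w, j)
        if (req$min_count < 0L)
          add("COUNT_NEGATIVE", paste0(rp, ".min_count"),
              "min_count must be non-negative")
        if (req$min_count > req$max_count)
          add("MIN_GT_MAX", paste0(rp, ".min_count"),
              sprintf("min_count (%d) exceeds max_count (%d)",
                      req$min_count, req$max_count))
        if (!is.null(req$time_window) &&
            !(req$time_window$start < req$time_window$end))
          add("WINDOW_INVALID", paste0(rp, ".time_window"),
              "time_window start must precede end within one day")
      }
    }
  }
  if (length(v) == 0L)
    return(data.frame(code = character(), path = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, v)
}

# ---- JSON (de)serialization -------------------------------------------------

req_to_json <- function(req) {
  out <- list(tool_type = req$tool_type, min_count = req$min_count,
              max_count = req$max_count)
  if (!is.null(req$time_window))
    out$time_window <- list(start = format_hm(req$time_window$start),
                            end = format_hm(req$time_window$end))
  if (!is.null(req$trigger_condition))
    out$trigger_condition <- list(all = req$trigger_condition$all)
  if (!is.null(req$tool_payload)) out$tool_payload <- req$tool_payload
  out
}

req_from_json <- function(x) {
  tw <- if (!is.null(x$time_window))
    time_window(x$time_window$start, x$time_window$end)
  tc <- if (!is.null(x$trigger_condition))
    condition_expr(x$trigger_condition$all)
  intervention_requirement(x$tool_type, x$min_count, x$max_count,
                           time_window = tw, trigger_condition = tc,
                           tool_payload = x$tool_payload)
}

plugin_known_fields <- c("format_version", "plugin_id", "title", "dimension",
                         "description", "requirements", "difficulty_levels",
                         "awareness_tips", "fallback_messages")

#' Load a goal plugin from a JSON file
#'
#' The on-disk format is one plugin per JSON document with an explicit
#' `"format_version": "1"`; unknown fields are preserved but ignored
#' (forward compatible, for third-party plugin authors). The file is
#' validated on load and a schema error lists every violated invariant.
#'
#' @param path path to a plugin JSON file.
#' @return a valid `goal_plugin`.
#' @seealso [write_goal_plugin()], [validate_goal_plugin()]
#' @export
load_goal_plugin <- function(path) {
  if (!file.exists(path)) stop("plugin file not found: ", path)
  raw <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e) stop("malformed plugin file ", path,
                                           ": ", conditionMessage(e)))
  levels <- lapply(raw$difficulty_levels, function(lv) {
    difficulty_level(lv$level_name, lv$duration_weeks,
                     lapply(lv$weekly_plans, function(wk)
                       lapply(wk, req_from_json)))
  })
  plugin <- goal_plugin(
    plugin_id = raw$plugin_id, title = raw$title, dimension = raw$dimension,
    description = if (is.null(raw$description)) "" else raw$description,
    requirements = unlist(raw$requirements),
    difficulty_levels = levels,
    awareness_tips = unlist(raw$awareness_tips),
    fallback_messages = unlist(raw$fallback_messages),
    extra = raw[setdiff(names(raw), plugin_known_fields)])
  bad <- validate_goal_plugin(plugin)
  if (nrow(bad) > 0L)
    stop("invalid plugin ", path, ":\n",
         paste(sprintf("  %s %s %s", bad$code, bad$path, bad$message),
               collapse = "\n"))
  plugin
}

#' Write a goal plugin to canonical JSON
#'
#' Canonical formatting (pretty-printed, stable key order) so that
#' write-load-write round-trips are byte identical.
#'
#' @param plugin a `goal_plugin`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_goal_plugin <- function(plugin, path) {
  doc <- c(list(format_version = "1",
                plugin_id = plugin$plugin_id,
                title = plugin$title,
                dimension = plugin$dimension,
                description = plugin$description,
                requirements = as.list(plugin$requirements),
                difficulty_levels = lapply(plugin$difficulty_levels, function(lv)
                  list(level_name = lv$level_name,
                       duration_weeks = lv$duration_weeks,
                       weekly_plans = lapply(lv$weekly_plans, function(wk)
                         lapply(wk, req_to_json)))),
                awareness_tips = as.list(plugin$awareness_tips),
                fallback_messages = as.list(plugin$fallback_messages)),
           plugin$extra)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = 2, null = "null",
                           digits = NA)
  writeLines(json, path)
  invisible(path)
}

# ---- instances --------------------------------------------------------------

#' Enrol a participant in a goal at a chosen difficulty
#'
#' Creates an active goal instance anchored to calendar weeks starting
#' Monday: a goal started mid-week treats the remainder of that calendar
#' week as week 1 with its min/max counts pro-rated by
#' `ceiling(count * remaining_days / 7)`.
#'
#' @param plugin a valid `goal_plugin`.
#' @param level_name one of the plugin's difficulty level names.
#' @param start_date a `Date`.
#' @param instance_id optional stable id; defaults to
#'   `<plugin_id>#<start_date>`.
#' @return a `goal_instance` (carries the plugin and chosen level).
#' @export
instantiate_goal <- function(plugin, level_name, start_date,
                             instance_id = NULL) {
  lnames <- vapply(plugin$difficulty_levels, function(l) l$level_name, "")
  idx <- match(level_name, lnames)
  if (is.na(idx))
    stop(sprintf("unknown difficulty level '%s' (available: %s)", level_name,
                 paste(lnames, collapse = ", ")))
  start_date <- as.Date(start_date)
  if (is.null(instance_id))
    instance_id <- sprintf("%s#%s", plugin$plugin_id, format(start_date))
  structure(list(instance_id = instance_id,
                 plugin_id = plugin$plugin_id,
                 plugin = plugin,
                 level = plugin$difficulty_levels[[idx]],
                 level_name = level_name,
                 start_date = start_date,
                 status = "active"),
            class = "goal_instance")
}

#' @export
print.goal_instance <- function(x, ...) {
  cat(sprintf("Goal instance %s: '%s' at level '%s', started %s (%s)\n",
              x$instance_id, x$plugin$title, x$level_name,
              format(x$start_date), x$status))
  cat(sprintf("  weeks %d, ends %s\n", x$level$duration_weeks,
              format(goal_end_date(x))))
  invisible(x)
}

#' Change the status of a goal instance
#'
#' Only `active -> completed` and `active -> dropped` are legal.
#' @param goal a `goal_instance`.
#' @param status new status.
#' @return the updated instance.
#' @export
set_goal_status <- function(goal, status) {
  stopifnot(status %in% c("completed", "dropped"))
  if (goal$status != "active")
    stop(sprintf("illegal status transition %s -> %s", goal$status, status))
  goal$status <- status
  goal
}

# Last covered date: Sunday of week duration_weeks (weeks are calendar weeks
# counted from the week containing start_date).
#' @keywords internal
goal_end_date <- function(goal) {
  week_monday(goal$start_date) + goal$level$duration_weeks * 7L - 1L
}

# 1-based goal week index of `date`, or NA outside the active duration
#' @keywords internal
goal_week_index <- function(goal, date) {
  if (date < goal$start_date || date > goal_end_date(goal)) return(NA_integer_)
  as.integer((as.integer(date - week_monday(goal$start_date))) %/% 7L) + 1L
}

# Weekly requirements of `goal` for the week containing `date`, with the
# partial first week pro-rated: ceiling(count * remaining_days / 7).
#' @keywords internal
goal_week_requirements <- function(goal, date) {
  w <- goal_week_index(goal, date)
  if (is.na(w)) return(list())
  reqs <- goal$level$weekly_plans[[w]]
  if (w == 1L) {
    remaining <- 7L - (iso_wday(goal$start_date) - 1L)
    if (remaining < 7L) {
      reqs <- lapply(reqs, function(r) {
        r$min_count <- as.integer(ceiling(r$min_count * remaining / 7))
        r$max_count <- as.integer(ceiling(r$max_count * remaining / 7))
        r
      })
    }
  }
  reqs
}
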