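# Participant registry, study phases, device links, withdrawals.
# The append-only event log is the source of truth; the in-memory registry
# is a cached view that replay_events() can rebuild from scratch.

#' Study phases in funnel order
#'
#' The screening funnel is a total order; `withdrawn` and `ineligible` are
#' terminal states reachable from any phase and are not part of the order.
#'
#' @return character vector of funnel phases, in order.
#' @export
study_phases <- function() {
  c("phase1_screen", "phase2_screen", "phase3_screen",
    "baseline", "randomized", "completed")
}

.terminal_phases <- c("withdrawn", "ineligible")

.event_kinds <- c(
  "registered", "submitted_questionnaire", "eligible", "ineligible",
  "advanced", "randomized", "assessed", "withdrawn", "paid",
  "device_linked", "device_unlinked"
)

#' Study configuration
#'
#' @param study_prefix prefix for generated study IDs.
#' @param id_width zero-padding width of the numeric part of study IDs.
#' @param required_demographics profile fields that must be present at
#'   registration; `email` is always required (duplicate detection).
#' @param salt salt mixed into the contact-email hash used as the duplicate
#'   detection key.
#' @param timezone study timezone; day boundaries for daily metrics and pull
#'   windows are taken in this zone.
#' @param arms treatment arm labels (equal target allocation).
#' @param feedback_arm the arm receiving tailored feedback messages.
#' @param messages_per_day tailored messages scheduled per participant-day
#'   in the feedback arm.
#' @return a `wt_config` list.
#' @export
wt_config <- function(study_prefix = "SMT",
                      id_width = 4,
                      required_demographics = c("email"),
                      salt = "weartrial-salt",
                      timezone = "America/New_York",
                      arms = c("SM", "SM+feedback"),
                      feedback_arm = "SM+feedback",
                      messages_per_day = 3) {
  assert_that(length(arms) >= 2, "need at least two arms")
  assert_that(feedback_arm %in% arms, "feedback_arm must be one of arms")
  structure(list(
    study_prefix = study_prefix, id_width = id_width,
    required_demographics = union(required_demographics, "email"),
    salt = salt, timezone = timezone, arms = arms,
    feedback_arm = feedback_arm, messages_per_day = messages_per_day
  ), class = "wt_config")
}

#' Create an empty study
#'
#' A study holds the append-only event log, the derived participant
#' registry, device links, published questionnaires, and collected
#' responses. It has reference semantics: operations append events in
#' place.
#'
#' @param config a [wt_config()].
#' @return a `wt_study` object.
#' @export
wt_study <- function(config = wt_config()) {
  s <- new.env(parent = emptyenv())
  s$config <- config
  s$ev <- new.env(parent = emptyenv())  # hashed event slots (O(1) append)
  s$n_events <- 0L
  s$registry <- list()      # study_id -> participant
  s$email_hashes <- character(0)
  s$links <- list()         # "study_id::vendor" -> link
  s$questionnaires <- list()
  s$tokens <- list()
  s$responses <- list()
  s$next_id <- 1L
  s$last_ts <- new.env(parent = emptyenv())  # per-participant event-time cache
  class(s) <- "wt_study"
  s
}

#' @export
print.wt_study <- function(x, ...) {
  cat(sprintf("<wt_study> %d participants, %d events, %d responses\n",
              length(x$registry), x$n_events, length(x$responses)))
  invisible(x)
}

hash_email <- function(email, salt) {
  rlang::hash(paste0(salt, "\x1f", tolower(trimws(email))))
}

new_study_id <- function(study) {
  id <- sprintf(paste0("%s%0", study$config$id_width, "d"),
                study$config$study_prefix, study$next_id)
  study$next_id <- study$next_id + 1L
  id
}

last_event_time <- function(study, study_id) {
  get0(study_id, envir = study$last_ts, ifnotfound = -Inf)
}

append_event <- function(study, study_id, kind, timestamp, payload = list()) {
  assert_that(kind %in% .event_kinds, paste("unknown event kind:", kind))
  timestamp <- as_time(timestamp, tz = study$config$timezone)
  if (as.numeric(timestamp) < last_event_time(study, study_id)) {
    wt_stop(sprintf("event for %s is earlier than an existing event", study_id),
            "weartrial_event_order")
  }
  n <- study$n_events + 1L
  assign(sprintf("e%09d", n), list(
    study_id = study_id, event_kind = kind,
    timestamp = timestamp, payload = payload
  ), envir = study$ev)
  study$n_events <- n
  assign(study_id, as.numeric(timestamp), envir = study$last_ts)
  invisible(study)
}

#' The append-only event log of a study
#'
#' @param study a [wt_study()].
#' @return list of event records, in append order.
#' @export
event_log <- function(study) {
  n <- study$n_events
  if (n == 0L) return(list())
  unname(mget(sprintf("e%09d", seq_len(n)), envir = study$ev))
}

#' Register a participant
#'
#' Assigns a fresh study-specific ID, places the participant in the first
#' screening phase, and appends a `registered` event. Re-registration with
#' the same contact email (matched on a salted hash) is rejected.
#'
#' @param study a [wt_study()].
#' @param profile named list of demographics; must contain every field in
#'   `config$required_demographics` (at minimum `email`).
#' @param date enrollment date (registration date).
#' @return the new participant record (a named list), invisibly usable via
#'   its `study_id`.
#' @export
register_participant <- function(study, profile, date = Sys.Date()) {
  req <- study$config$required_demographics
  missing_fields <- setdiff(req, names(profile))
  assert_that(length(missing_fields) == 0L,
              paste("profile missing required fields:",
                    paste(missing_fields, collapse = ", ")))
  eh <- hash_email(profile$email, study$config$salt)
  if (eh %in% study$email_hashes) {
    wt_stop("a participant with this contact email is already registered",
            "weartrial_duplicate")
  }
  id <- new_study_id(study)
  p <- list(
    study_id = id,
    enrollment_date = as_date(date),
    phase = "phase1_screen",
    arm = NULL,
    factor_levels = list(),
    withdrawal = NULL,
    email_hash = eh
  )
  study$registry[[id]] <- p
  study$email_hashes <- c(study$email_hashes, eh)
  append_event(study, id, "registered", as_date(date),
               payload = list(email_hash = eh,
                              enrollment_date = format(as_date(date))))
  p
}

#' Look up a participant
#'
#' @param study a [wt_study()].
#' @param study_id participant identifier.
#' @return participant record.
#' @export
get_participant <- function(study, study_id) {
  p <- study$registry[[study_id]]
  if (is.null(p)) wt_stop(paste("unknown study_id:", study_id),
                          "weartrial_unknown_id")
  p
}

#' Record a withdrawal
#'
#' Marks the participant withdrawn (terminal), stores date and reason, and
#' appends a `withdrawn` event. Withdrawn participants are excluded from
#' alert scans and from retention denominators of later assessments.
#'
#' @param study a [wt_study()].
#' @param study_id participant identifier.
#' @param date withdrawal date.
#' @param reason free-text reason.
#' @return the updated participant record.
#' @export
record_withdrawal <- function(study, study_id, date, reason = "") {
  p <- get_participant(study, study_id)
  if (identical(p$phase, "withdrawn")) {
    wt_stop(paste(study_id, "is already withdrawn"), "weartrial_double_withdrawal")
  }
  p$withdrawal <- list(date = as_date(date), reason = reason)
  p$phase <- "withdrawn"
  study$registry[[study_id]] <- p
  append_event(study, study_id, "withdrawn", as_date(date),
               payload = list(date = format(as_date(date)), reason = reason))
  p
}

#' Link a device-vendor account
#'
#' Stores an active vendor link so the sync scheduler includes the account.
#' A participant may hold at most one active link per vendor; the stored
#' token never appears in the event log or any report.
#'
#' @param study a [wt_study()].
#' @param study_id participant identifier; must be in `phase3_screen` or a
#'   later funnel phase (the phase-3 food-diary review requires a link).
#' @param vendor one of `"wearable_vendor"`, `"scale_vendor"`, `"mock"`.
#' @param token opaque secret used by the connector.
#' @param date link date.
#' @return the link record (token included; callers must not log it).
#' @export
link_device <- function(study, study_id, vendor, token, date = Sys.Date()) {
  vendor <- match.arg(vendor, c("wearable_vendor", "scale_vendor", "mock"))
  p <- get_participant(study, study_id)
  ord <- match(p$phase, study_phases())
  assert_that(!is.na(ord) && ord >= match("phase3_screen", study_phases()),
              paste(study_id, "must reach phase3_screen before linking devices"))
  key <- paste0(study_id, "::", vendor)
  existing <- study$links[[key]]
  if (!is.null(existing) && isTRUE(existing$active)) {
    wt_stop(paste("active", vendor, "link exists for", study_id,
                  "- unlink first"), "weartrial_link_exists")
  }
  link <- list(study_id = study_id, vendor = vendor, token = token,
               linked_date = as_date(date), active = TRUE)
  study$links[[key]] <- link
  append_event(study, study_id, "device_linked", as_date(date),
               payload = list(vendor = vendor))
  link
}

#' @rdname link_device
#' @export
unlink_device <- function(study, study_id, vendor, date = Sys.Date()) {
  key <- paste0(study_id, "::", vendor)
  link <- study$links[[key]]
  assert_that(!is.null(link) && isTRUE(link$active),
              paste("no active", vendor, "link for", study_id))
  link$active <- FALSE
  study$links[[key]] <- link
  append_event(study, study_id, "device_unlinked", as_date(date),
               payload = list(vendor = vendor))
  invisible(link)
}

#' Active device links
#'
#' @param study a [wt_study()].
#' @return data.frame of active links (`study_id`, `vendor`, `linked_date`);
#'   tokens are deliberately omitted.
#' @export
active_links <- function(study) {
  act <- Filter(function(l) isTRUE(l$active), study$links)
  data.frame(
    study_id = vapply(act, `[[`, character(1), "study_id"),
    vendor = vapply(act, `[[`, character(1), "vendor"),
    linked_date = as.Date(vapply(act, function(l) format(l$linked_date),
                                 character(1))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' The participant registry as a data.frame
#'
#' @param study a [wt_study()].
#' @return one row per participant with phase, arm, and withdrawal state.
#' @export
participants <- function(study) {
  r <- study$registry
  data.frame(
    study_id = vapply(r, `[[`, character(1), "study_id"),
    enrollment_date = as.Date(vapply(r, function(p) format(p$enrollment_date),
                                     character(1))),
    phase = vapply(r, `[[`, character(1), "phase"),
    arm = vapply(r, function(p) p$arm %||% NA_character_, character(1)),
    withdrawn_date = as.Date(vapply(r, function(p)
      if (is.null(p$withdrawal)) NA_character_ else format(p$withdrawal$date),
      character(1))),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' The event log as a data.frame
#'
#' @param study a [wt_study()].
#' @return one row per event; payloads are JSON-encoded text.
#' @export
study_events <- function(study) {
  ev <- event_log(study)
  data.frame(
    study_id = vapply(ev, `[[`, character(1), "study_id"),
    event_kind = vapply(ev, `[[`, character(1), "event_kind"),
    timestamp = as.POSIXct(vapply(ev, function(e) as.numeric(e$timestamp),
                                  numeric(1)), origin = "1970-01-01",
                           tz = study$config$timezone),
    payload = vapply(ev, function(e)
      as.character(jsonlite::toJSON(e$payload, auto_unbox = TRUE)),
      character(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Rebuild the participant registry from an event log
#'
#' Pure event-sourcing replay: the returned registry is byte-identical to
#' the live registry of the study that produced the events, which makes all
#' registry-derived reporting replayable.
#'
#' @param events list of event records (from [event_log()]).
#' @param config the study's [wt_config()].
#' @return named list: `study_id` -> participant record.
#' @export
replay_events <- function(events, config = wt_config()) {
  reg <- list()
  for (e in events) {
    id <- e$study_id
    pay <- e$payload
    switch(e$event_kind,
      registered = {
        reg[[id]] <- list(
          study_id = id,
          enrollment_date = as_date(pay$enrollment_date),
          phase = "phase1_screen",
          arm = NULL,
          factor_levels = list(),
          withdrawal = NULL,
          email_hash = pay$email_hash
        )
      },
      advanced = {
        reg[[id]]$phase <- pay$to
      },
      ineligible = {
        reg[[id]]$phase <- "ineligible"
      },
      randomized = {
        reg[[id]]$phase <- "randomized"
        reg[[id]]$arm <- pay$arm
        reg[[id]]$factor_levels <- as.list(pay$factor_levels)
      },
      withdrawn = {
        reg[[id]]$phase <- "withdrawn"
        reg[[id]]$withdrawal <- list(date = as_date(pay$date),
                                     reason = pay$reason)
      },
      NULL
    )
  }
  reg
}

#' Persist / load the event log as JSON-lines
#'
#' One JSON object per line, timestamps in ISO-8601 with the study
#' timezone's UTC offset baked in. `read_events()` restores an event list
#' suitable for [replay_events()].
#'
#' @param study a [wt_study()] (or an event list for `write_events`).
#' @param path file path.
#' @param config study configuration (for the timezone on read).
#' @return `read_events()` returns the event list, invisibly for the writer.
#' @export
write_events <- function(study, path) {
  events <- if (inherits(study, "wt_study")) event_log(study) else study
  lines <- vapply(events, function(e) {
    as.character(jsonlite::toJSON(list(
      study_id = e$study_id, event_kind = e$event_kind,
      timestamp = format(e$timestamp, "%Y-%m-%dT%H:%M:%S%z"),
      payload = e$payload
    ), auto_unbox = TRUE, null = "null"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path, config = wt_config()) {
  lines <- readLines(path)
  lapply(lines, function(ln) {
    e <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    e$timestamp <- as.POSIXct(e$timestamp, format = "%Y-%m-%dT%H:%M:%S%z",
                              tz = config$timezone)
    e$payload <- lapply(e$payload, function(x) x)
    e
  })
}
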