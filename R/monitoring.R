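# Adherence alert scanning over the observation store, tailored-feedback
# message scheduling, and app-usage aggregation.
#
# Alert rules (evaluated daily, per randomized active participant):
#   food_gap_7d           no food entries on the 7 calendar dates ending
#                         at the scan date
#   weight_gap_7d         likewise for weight records
#   tracker_gap_7d        likewise for steps / heart rate / sleep jointly
#                         (a worn tracker produces all three)
#   weight_change_5lb_7d  two weight records at most 7 consecutive days
#                         apart differing by strictly more than 5 lb

.alert_rules <- c("food_gap_7d", "weight_gap_7d", "weight_change_5lb_7d",
                  "tracker_gap_7d")

#' Alert rule configuration
#'
#' @param gap_days span of the no-data rules (consecutive calendar days
#'   ending at the scan date).
#' @param weight_change_lb strict threshold for the rapid-weight-change
#'   rule, in pounds; a change of exactly this size does not fire.
#' @param weight_change_days maximal window (consecutive calendar days,
#'   endpoints included) for the weight-change rule.
#' @param cooldown_days suppression span for re-raising the same rule when
#'   scanning a sequence of days.
#' @return a `wt_alert_config` list.
#' @export
alert_config <- function(gap_days = 7, weight_change_lb = 5,
                         weight_change_days = 7, cooldown_days = 7) {
  structure(list(gap_days = gap_days, weight_change_lb = weight_change_lb,
                 weight_change_days = weight_change_days,
                 cooldown_days = cooldown_days),
            class = "wt_alert_config")
}

empty_alerts <- function() {
  data.frame(study_id = character(0), rule = character(0),
             window_start = as.Date(character(0)),
             window_end = as.Date(character(0)),
             raised_at = as.Date(character(0)),
             change_lb = numeric(0), direction = character(0),
             stringsAsFactors = FALSE)
}

obs_dates <- function(store) as.Date(substr(store$timestamp, 1, 10))

#' Scan adherence alerts for one participant
#'
#' Point-in-time scan as of a date. The three gap rules fire iff the
#' `gap_days` calendar dates ending at `as_of` (inclusive) hold zero
#' records of the respective metrics — so an empty store fires all three.
#' The weight-change rule fires iff two weight records, at most
#' `weight_change_days` consecutive days apart and with the later one
#' inside the gap window, differ by strictly more than `weight_change_lb`
#' pounds (either direction; the direction is reported in the details).
#' Only records dated on or before `as_of` are considered, so scanning a
#' prefix of a stream never looks ahead. Withdrawn or not-yet-randomized
#' participants yield no alerts.
#'
#' @param store observation store (long format, weight in kg).
#' @param participant a participant record (from [get_participant()]).
#' @param as_of scan date.
#' @param config an [alert_config()].
#' @return data.frame of alerts (possibly zero rows): `study_id`, `rule`,
#'   `window_start`, `window_end`, `raised_at`, `change_lb`, `direction`.
#' @export
scan_alerts <- function(store, participant, as_of,
                        config = alert_config()) {
  as_of <- as_date(as_of)
  if (!identical(participant$phase, "randomized") &&
      !identical(participant$phase, "completed")) {
    return(empty_alerts())
  }
  id <- participant$study_id
  obs <- store[store$study_id == id, , drop = FALSE]
  d <- obs_dates(obs)
  keep <- !is.na(d) & d <= as_of
  obs <- obs[keep, , drop = FALSE]
  d <- d[keep]
  win_start <- as_of - (config$gap_days - 1)
  in_win <- d >= win_start
  out <- empty_alerts()
  gap_rule <- function(rule, metrics) {
    if (!any(in_win & obs$metric %in% metrics)) {
      data.frame(study_id = id, rule = rule, window_start = win_start,
                 window_end = as_of, raised_at = as_of,
                 change_lb = NA_real_, direction = NA_character_,
                 stringsAsFactors = FALSE)
    } else empty_alerts()
  }
  out <- rbind(out,
               gap_rule("food_gap_7d", "food_entry"),
               gap_rule("weight_gap_7d", "weight"),
               gap_rule("tracker_gap_7d",
                        c("steps", "heart_rate", "sleep_minutes")))
  # rapid weight change: pairs of records <= (weight_change_days - 1)
  # calendar days apart, the later record inside the current gap window
  w <- obs$metric == "weight"
  if (sum(w) >= 2) {
    wd <- d[w]
    wv_lb <- kg_to_lb(obs$value[w])
    ord <- order(wd)
    wd <- wd[ord]; wv_lb <- wv_lb[ord]
    best <- NULL
    for (i in seq_along(wd)) {
      for (j in seq_along(wd)) {
        if (j <= i) next
        span <- as.numeric(wd[j] - wd[i])
        if (span > config$weight_change_days - 1) next
        if (wd[j] < win_start) next
        ch <- wv_lb[j] - wv_lb[i]
        # strict threshold with float tolerance: an exact 5.0 lb change
        # recorded in kg must not fire after unit round-tripping
        if (abs(ch) > config$weight_change_lb + 1e-9 &&
            (is.null(best) || abs(ch) > abs(best$ch))) {
          best <- list(i = i, j = j, ch = ch)
        }
      }
    }
    if (!is.null(best)) {
      out <- rbind(out, data.frame(
        study_id = id, rule = "weight_change_5lb_7d",
        window_start = wd[best$i], window_end = wd[best$j],
        raised_at = as_of, change_lb = abs(best$ch),
        direction = if (best$ch < 0) "loss" else "gain",
        stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  out
}

#' Scan alerts across a study
#'
#' Runs [scan_alerts()] for every randomized, non-withdrawn participant.
#'
#' @param study a [wt_study()].
#' @param store observation store.
#' @param as_of scan date.
#' @param config an [alert_config()].
#' @return combined alerts data.frame.
#' @export
scan_study_alerts <- function(study, store, as_of,
                              config = alert_config()) {
  out <- lapply(study$registry, function(p)
    scan_alerts(store, p, as_of, config))
  res <- do.call(rbind, c(list(empty_alerts()), out))
  rownames(res) <- NULL
  res
}

#' Scan a range of days with a re-raise cool-down
#'
#' Evaluates the rules daily over `dates`; once a rule has been raised for
#' a participant, the same rule is suppressed for `cooldown_days` days, so
#' a long gap re-raises periodically instead of every day.
#'
#' @param store observation store.
#' @param participant participant record.
#' @param dates ordered scan dates.
#' @param config an [alert_config()].
#' @return alerts data.frame after cool-down de-duplication.
#' @export
scan_alerts_daily <- function(store, participant, dates,
                              config = alert_config()) {
  dates <- sort(as_date(dates))
  last_raised <- list()
  acc <- list()
  for (day in as.list(dates)) {
    al <- scan_alerts(store, participant, day, config)
    for (i in seq_len(nrow(al))) {
      r <- al$rule[i]
      prev <- last_raised[[r]]
      if (!is.null(prev) && as.numeric(day - prev) < config$cooldown_days)
        next
      last_raised[[r]] <- day
      acc[[length(acc) + 1L]] <- al[i, , drop = FALSE]
    }
  }
  res <- do.call(rbind, c(list(empty_alerts()), acc))
  rownames(res) <- NULL
  res
}

# ---- tailored feedback --------------------------------------------------

#' Schedule tailored feedback messages for a day
#'
#' Participants in the feedback arm receive `messages_per_day` messages
#' per day (default 3), each tagged with the self-monitoring category that
#' drove its template selection; categories with data present that day are
#' preferred, cycling when fewer categories than slots are present, and a
#' generic template is used when no data arrived. Message content itself
#' is a pluggable hook (`template_ref` is an opaque label). Participants
#' outside the feedback arm receive nothing.
#'
#' @param participant participant record (arm set at randomization).
#' @param sm_present named logical: which self-monitoring categories
#'   (e.g. `diet`, `activity`, `weight`) have data for the day.
#' @param date message date.
#' @param config a [wt_config()] (supplies `feedback_arm` and
#'   `messages_per_day`).
#' @return data.frame of message events: `study_id`, `date`, `slot`,
#'   `category`, `template_ref`, `status` (initially `delivered`).
#' @export
schedule_feedback <- function(participant, sm_present, date,
                              config = wt_config()) {
  empty <- data.frame(study_id = character(0), date = as.Date(character(0)),
                      slot = integer(0), category = character(0),
                      template_ref = character(0), status = character(0),
                      stringsAsFactors = FALSE)
  if (!identical(participant$arm, config$feedback_arm)) return(empty)
  m <- config$messages_per_day
  if (m < 1) return(empty)
  cats <- names(sm_present)[vapply(sm_present, isTRUE, logical(1))]
  if (length(cats) == 0L) cats <- "generic"
  slot_cat <- rep_len(cats, m)
  data.frame(study_id = participant$study_id, date = as_date(date),
             slot = seq_len(m), category = slot_cat,
             template_ref = paste0(slot_cat, "_", seq_len(m)),
             status = "delivered", stringsAsFactors = FALSE)
}

#' Update a message's delivery status
#'
#' Permitted transitions: `delivered -> opened`; `missed` is terminal and
#' can only be set on a still-`delivered` message (a push that never
#' reached the device).
#'
#' @param log message-event data.frame.
#' @param study_id,date,slot key of the message to update.
#' @param status new status, `"opened"` or `"missed"`.
#' @return updated log.
#' @export
mark_message <- function(log, study_id, date, slot, status) {
  status <- match.arg(status, c("opened", "missed"))
  i <- which(log$study_id == study_id & log$date == as_date(date) &
               log$slot == slot)
  assert_that(length(i) == 1L, "message not found (or key ambiguous)")
  assert_that(log$status[i] == "delivered",
              paste("cannot transition", log$status[i], "->", status))
  log$status[i] <- status
  log
}

#' Aggregate app usage over a period
#'
#' Per-day counts of scheduled messages by final status, plus daily active
#' users from the app-open log. For every day,
#' `delivered + opened + missed = scheduled`.
#'
#' @param message_log message events (as from [schedule_feedback()], with
#'   statuses resolved).
#' @param app_open_log data.frame with `study_id` and `timestamp` (one row
#'   per app open).
#' @param period length-2 date vector `c(start, end)`, inclusive.
#' @return list: `daily` (date, active_users, scheduled, delivered,
#'   opened, missed) and `totals` (the same counts summed).
#' @export
usage_summary <- function(message_log, app_open_log, period) {
  start <- as_date(period[1]); end <- as_date(period[2])
  days <- seq(start, end, by = "day")
  ml <- message_log[message_log$date >= start & message_log$date <= end, ,
                    drop = FALSE]
  ao_dates <- if (nrow(app_open_log))
    as.Date(substr(as.character(app_open_log$timestamp), 1, 10))
  else as.Date(character(0))
  daily <- do.call(rbind, lapply(as.list(days), function(day) {
    md <- ml[ml$date == day, , drop = FALSE]
    opens <- app_open_log$study_id[ao_dates == day]
    data.frame(date = day,
               active_users = length(unique(opens)),
               scheduled = nrow(md),
               delivered = sum(md$status == "delivered"),
               opened = sum(md$status == "opened"),
               missed = sum(md$status == "missed"),
               stringsAsFactors = FALSE)
  }))
  totals <- colSums(daily[, c("active_users", "scheduled", "delivered",
                              "opened", "missed")])
  list(daily = daily, totals = as.list(totals))
}
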