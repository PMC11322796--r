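# Daily synchronization against device-vendor connectors under a
# per-account rolling-hour API quota and a bounded look-back window.
# Cost model: one API call per (endpoint, day).

.endpoints <- c("activity", "food", "sleep", "weight")

#' Metrics served by each vendor endpoint
#'
#' A worn tracker reports activity (steps and heart rate) and sleep; the
#' food endpoint serves diary entries; the scale endpoint serves weight.
#'
#' @param endpoint one of `activity`, `food`, `sleep`, `weight`.
#' @return character vector of metric names.
#' @export
endpoint_metrics <- function(endpoint) {
  switch(match.arg(endpoint, .endpoints),
    activity = c("steps", "heart_rate"),
    food = "food_entry",
    sleep = "sleep_minutes",
    weight = "weight"
  )
}

#' Look-back pull window
#'
#' The half-open calendar-date range `[today - window_days, today)` in the
#' study timezone: the last `window_days` complete days, today excluded.
#' Because the arithmetic is on calendar dates, the window always contains
#' exactly `window_days` dates, across DST transitions included.
#'
#' @param now current time.
#' @param window_days look-back length (default 7).
#' @param tz study timezone.
#' @return list with `start` (inclusive), `end` (exclusive) and `dates`
#'   (the enumerated calendar dates).
#' @export
pull_window <- function(now, window_days = 7, tz = "UTC") {
  assert_that(window_days >= 1, "window_days must be >= 1")
  today <- as.Date(as_time(now, tz), tz = tz)
  start <- today - window_days
  list(start = start, end = today,
       dates = seq(start, by = "day", length.out = window_days))
}

#' Per-account hourly rate budget
#'
#' Tracks granted call timestamps and enforces the vendor quota over every
#' rolling 3600-second interval (a sliding window, not calendar-hour
#' buckets).
#'
#' @param limit_per_hour maximum granted calls in any rolling hour
#'   (default 100, the consumer-wearable API quota).
#' @return a `wt_rate_budget` list.
#' @export
new_rate_budget <- function(limit_per_hour = 100) {
  assert_that(limit_per_hour >= 1, "limit_per_hour must be >= 1")
  structure(list(limit_per_hour = as.integer(limit_per_hour),
                 call_log = numeric(0)),
            class = "wt_rate_budget")
}

#' Request calls against a rate budget
#'
#' Grants `min(n_calls, remaining quota in the rolling hour ending now)`
#' and logs the granted timestamps; the rest are deferred. When calls are
#' deferred, `next_eligible` is the earliest time at which at least one
#' slot frees up.
#'
#' @param budget a [new_rate_budget()].
#' @param n_calls number of calls requested (>= 0).
#' @param now current time.
#' @return list: `granted`, `deferred`, updated `budget`, `next_eligible`
#'   (POSIXct or `NULL` when nothing was deferred).
#' @export
acquire <- function(budget, n_calls, now) {
  assert_that(n_calls >= 0, "n_calls must be >= 0")
  t <- as.numeric(as_time(now))
  recent <- budget$call_log[budget$call_log > t - 3600 & budget$call_log <= t]
  remaining <- budget$limit_per_hour - length(recent)
  granted <- min(n_calls, max(0L, remaining))
  deferred <- n_calls - granted
  if (granted > 0) budget$call_log <- c(budget$call_log, rep(t, granted))
  next_eligible <- NULL
  if (deferred > 0) {
    # a slot frees when the oldest in-window call ages out
    next_eligible <- as.POSIXct(min(sort(recent), t) + 3600,
                                origin = "1970-01-01", tz = "UTC")
  }
  list(granted = as.integer(granted), deferred = as.integer(deferred),
       budget = budget, next_eligible = next_eligible)
}

#' Plan a daily synchronization run
#'
#' Builds one [SyncJob] per (account, endpoint, day in the pull window),
#' admitting jobs against each account's rolling-hour budget: jobs beyond
#' the remaining quota are marked `deferred` with a next-eligible time.
#' Re-planning with the previous plan supplied is idempotent — already
#' planned (account, endpoint, date) triples are not duplicated.
#'
#' @param accounts character vector of account ids (one per participant
#'   vendor link, e.g. `"SMT0001::wearable_vendor"`).
#' @param endpoints endpoints to pull (subset of
#'   `c("activity","food","sleep","weight")`).
#' @param now current time.
#' @param budgets named list of [new_rate_budget()]s keyed by account;
#'   missing accounts get a fresh default budget.
#' @param window_days look-back window length.
#' @param tz study timezone.
#' @param existing previously planned jobs (the `plan` of an earlier call)
#'   for idempotent re-planning.
#' @return list: `plan` (data.frame: account, endpoint, date, status,
#'   next_eligible) and the updated `budgets`.
#' @export
plan_sync <- function(accounts, endpoints, now, budgets = list(),
                      window_days = 7, tz = "UTC", existing = NULL) {
  endpoints <- as.character(endpoints)
  assert_that(all(endpoints %in% .endpoints),
              "unknown endpoint in endpoints")
  win <- pull_window(now, window_days, tz)
  if (length(accounts) == 0L || length(endpoints) == 0L) {
    return(list(plan = data.frame(account = character(0),
                                  endpoint = character(0),
                                  date = as.Date(character(0)),
                                  status = character(0),
                                  next_eligible = as.POSIXct(character(0)),
                                  stringsAsFactors = FALSE),
                budgets = budgets))
  }
  jobs <- expand.grid(date = win$dates, endpoint = endpoints,
                      account = accounts, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  jobs <- jobs[, c("account", "endpoint", "date")]
  if (!is.null(existing) && nrow(existing)) {
    key <- function(df) paste(df$account, df$endpoint, format(df$date),
                              sep = "\x1f")
    jobs <- jobs[!key(jobs) %in% key(existing), , drop = FALSE]
  }
  if (nrow(jobs) == 0L) {
    jobs <- data.frame(account = character(0), endpoint = character(0),
                       date = as.Date(character(0)), stringsAsFactors = FALSE)
  }
  jobs$status <- rep("pending", nrow(jobs))
  jobs$next_eligible <- rep(as.POSIXct(NA), nrow(jobs))
  for (acct in unique(jobs$account)) {
    idx <- which(jobs$account == acct)
    b <- budgets[[acct]] %||% new_rate_budget()
    res <- acquire(b, length(idx), now)
    budgets[[acct]] <- res$budget
    if (res$granted > 0) jobs$status[idx[seq_len(res$granted)]] <- "granted"
    if (res$deferred > 0) {
      di <- idx[(res$granted + 1L):length(idx)]
      jobs$status[di] <- "deferred"
      jobs$next_eligible[di] <- res$next_eligible
    }
  }
  rownames(jobs) <- NULL
  list(plan = jobs, budgets = budgets)
}

# ---- observation store --------------------------------------------------

.obs_cols <- c("study_id", "metric", "timestamp", "value", "unit",
               "source", "retrieved_at")
.metrics <- c("steps", "heart_rate", "sleep_minutes", "food_entry", "weight")

#' Empty observation store
#'
#' Long format: one row per (participant, metric, timestamp, source).
#' Timestamps are text — a calendar date (`YYYY-MM-DD`) for daily metrics,
#' a full datetime for intra-day food entries. Weight values are stored in
#' kilograms.
#'
#' @return zero-row data.frame with the store schema.
#' @export
new_observation_store <- function() {
  data.frame(study_id = character(0), metric = character(0),
             timestamp = character(0), value = numeric(0),
             unit = character(0), source = character(0),
             retrieved_at = character(0), stringsAsFactors = FALSE)
}

obs_key <- function(df) {
  paste(df$study_id, df$metric, df$timestamp, df$source, sep = "\x1f")
}

validate_obs <- function(records) {
  ok <- rep(TRUE, nrow(records))
  ok <- ok & records$metric %in% .metrics
  ok <- ok & !is.na(records$value) & is.finite(records$value)
  ok <- ok & !(records$metric %in% c("steps", "sleep_minutes") &
                 records$value < 0)
  ok <- ok & !(records$metric == "weight" & records$value <= 0)
  ok <- ok & !is.na(records$study_id) & nzchar(records$study_id)
  ok <- ok & !is.na(records$timestamp) & nzchar(records$timestamp)
  ok
}

#' Ingest observation records into a store
#'
#' Idempotent on exact duplicates (same key and value). Records sharing a
#' key with a stored row but carrying a different value are conflicts and
#' are resolved last-writer-wins on `retrieved_at` (ties keep the earlier
#' arrival). Malformed records are rejected individually; the batch
#' continues.
#'
#' @param store a store from [new_observation_store()].
#' @param records data.frame with the store schema (`retrieved_at` filled).
#' @return list: updated `store`, and counts `inserted`,
#'   `duplicates_skipped`, `conflicts`, `rejected`.
#' @export
ingest <- function(store, records) {
  if (is.null(records) || nrow(records) == 0L) {
    return(list(store = store, inserted = 0L, duplicates_skipped = 0L,
                conflicts = 0L, rejected = 0L))
  }
  records <- records[, .obs_cols]
  good <- validate_obs(records)
  rejected <- sum(!good)
  records <- records[good, , drop = FALSE]
  inserted <- 0L; dups <- 0L; conflicts <- 0L
  rk <- obs_key(records)
  sk <- obs_key(store)
  m <- match(rk, sk)
  dup_in_batch <- duplicated(rk) | duplicated(rk, fromLast = TRUE)
  # fast paths: fresh keys, and exact re-sync duplicates (same key+value)
  fresh <- is.na(m) & !dup_in_batch
  exact <- !is.na(m) & !dup_in_batch & records$value == store$value[m]
  inserted <- inserted + sum(fresh)
  dups <- dups + sum(exact)
  if (any(fresh)) store <- rbind(store, records[fresh, , drop = FALSE])
  rest <- records[!(fresh | exact), , drop = FALSE]
  if (nrow(rest)) {
    # collisions needing sequential resolution (conflicts, within-batch
    # repeats): resolved last-writer-wins on retrieved_at
    sk <- obs_key(store)
    idx <- new.env(parent = emptyenv())
    for (i in seq_along(sk)) assign(sk[i], i, envir = idx)
    for (i in seq_len(nrow(rest))) {
      r <- rest[i, ]
      k <- obs_key(r)
      j <- get0(k, envir = idx, ifnotfound = NA_integer_)
      if (is.na(j)) {
        store <- rbind(store, r)
        assign(k, nrow(store), envir = idx)
        inserted <- inserted + 1L
      } else if (isTRUE(store$value[j] == r$value)) {
        dups <- dups + 1L
      } else {
        conflicts <- conflicts + 1L
        if (r$retrieved_at > store$retrieved_at[j]) store[j, ] <- r
      }
    }
  }
  rownames(store) <- NULL
  list(store = store, inserted = inserted, duplicates_skipped = dups,
       conflicts = conflicts, rejected = rejected)
}

#' Read / write the observation store as CSV
#'
#' @param store observation data.frame.
#' @param path CSV path.
#' @return the store (invisibly for the writer).
#' @export
write_observations <- function(store, path) {
  utils::write.csv(store[, .obs_cols], path, row.names = FALSE)
  invisible(store)
}

#' @rdname write_observations
#' @export
read_observations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(study_id = "character",
                                       metric = "character",
                                       timestamp = "character",
                                       value = "numeric",
                                       unit = "character",
                                       source = "character",
                                       retrieved_at = "character"))
  df[, .obs_cols]
}

#' Execute the granted jobs of a sync plan against a connector
#'
#' Fetches each granted (account, endpoint, date) job from the connector
#' (e.g. the mock vendor server), honouring quota refusals by marking the
#' job deferred, and ingests everything fetched in one batch.
#'
#' @param plan a plan from [plan_sync()].
#' @param server a connector supporting [server_fetch()].
#' @param store observation store.
#' @param now fetch time (stamped into `retrieved_at`).
#' @return list: updated `store`, updated `plan` (statuses done / deferred
#'   / failed), and the [ingest()] counts.
#' @export
run_sync <- function(plan, server, store, now) {
  fetched <- list(); nf <- 0L
  status <- plan$status
  next_el <- plan$next_eligible
  acct <- plan$account; ep <- plan$endpoint; dt <- plan$date
  retrieved <- format(as_time(now), "%Y-%m-%d %H:%M:%S")
  for (i in seq_along(status)) {
    if (status[i] != "granted") next
    res <- tryCatch(
      server_fetch(server, acct[i], ep[i], dt[i], now),
      weartrial_error = function(e) e
    )
    if (inherits(res, "condition")) {
      status[i] <- "failed"
    } else if (identical(res$status, "quota_exceeded")) {
      status[i] <- "deferred"
      next_el[i] <- res$retry_at
    } else {
      recs <- res$records
      if (!is.null(recs) && nrow(recs)) {
        recs$retrieved_at <- retrieved
        nf <- nf + 1L
        fetched[[nf]] <- recs[, .obs_cols]
      }
      status[i] <- "done"
    }
  }
  plan$status <- status
  plan$next_eligible <- next_el
  batch <- if (nf > 0) rbind_fast(fetched) else NULL
  ing <- ingest(store, batch)
  list(store = ing$store, plan = plan,
       inserted = ing$inserted, duplicates_skipped = ing$duplicates_skipped,
       conflicts = ing$conflicts, rejected = ing$rejected)
}
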