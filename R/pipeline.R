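# End-to-end synthetic study: cohort -> screening funnel -> minimization
# randomization -> stream generation -> scheduled sync against the mock
# vendor server -> adherence alerts -> reports. Deterministic per seed.

#' Run a complete synthetic study
#'
#' Exercises every stage of the engine offline: generates a cohort,
#' registers everyone and screens them through the three-phase funnel
#' (phase 1 auto-screened from questionnaire answers, phase 2 from the
#' medical item, phase 3 by coordinator-signed food-diary review), links
#' devices, randomizes baseline attendees by minimization on sex and BMI
#' category, generates observation streams, synchronizes them through the
#' rate-limited scheduler against the mock vendor server over several
#' daily cycles, scans adherence alerts, schedules feedback messages for
#' the feedback arm, simulates assessment completion and withdrawals, and
#' assembles the CONSORT flow and retention report. All randomness comes
#' from R's RNG seeded once, so a fixed seed reproduces every output
#' byte-for-byte.
#'
#' @param seed integer seed.
#' @param cohort a [cohort_params()].
#' @param streams a [stream_params()] (per-participant horizon).
#' @param config a [wt_config()].
#' @param alloc a [wt_alloc_config()]; default minimizes over sex and BMI
#'   category (below / at-or-above 35 kg/m^2) with a 0.8 biased coin.
#' @param sync_cycles number of daily synchronization cycles to simulate
#'   at the end of the stream horizon.
#' @param withdrawals integer vector `c(before_6mo, before_12mo)` of
#'   official withdrawals to simulate.
#' @param completion named completion probabilities for the `6mo` and
#'   `12mo` assessments among non-withdrawn randomized participants.
#' @param open_prob daily probability a randomized participant opens the
#'   app; `message_open_prob` / `message_missed_prob` resolve message
#'   statuses.
#' @param message_open_prob,message_missed_prob message status model.
#' @return a list: `study`, `store`, `flow`, `retention`, `alerts`,
#'   `usage`, `message_log`, `snapshot`, `assessments`, `plans`.
#' @export
simulate_study <- function(seed = 1,
                           cohort = cohort_params(),
                           streams = stream_params(),
                           config = wt_config(),
                           alloc = NULL,
                           sync_cycles = 3,
                           withdrawals = c(before_6mo = 4, before_12mo = 5),
                           completion = c("6mo" = 0.8493, "12mo" = 0.7992),
                           open_prob = 0.6,
                           message_open_prob = 0.7,
                           message_missed_prob = 0.1) {
  set.seed(seed)
  if (is.null(alloc)) {
    alloc <- wt_alloc_config(
      factors = list(sex = c("female", "male"),
                     bmi_category = c("bmi_lt_35", "bmi_ge_35")),
      assignment_prob = 0.8
    )
  }
  coh <- generate_cohort(cohort)
  study <- wt_study(config)
  publish_questionnaire(study, phase1_questionnaire())
  publish_questionnaire(study, phase2_questionnaire())
  criteria <- default_criteria()
  start <- streams$start_date
  n <- nrow(coh$profiles)
  reg_days <- pmin(58, pmax(1, ceiling(n / 30)))
  ids <- character(n)

  # --- registration + phase-1 auto-screen
  for (i in seq_len(n)) {
    reg_date <- start - 90 + ((i - 1) %% reg_days)
    p <- register_participant(study, list(email = coh$profiles$email[i]),
                              date = reg_date)
    ids[i] <- p$study_id
    tok <- issue_link(study, "phase1", study_id = p$study_id)
    submit_response(study, tok, coh$answers$phase1[[i]],
                    time = as_time(reg_date, config$timezone) + 3600)
    dec <- evaluate_eligibility(criteria, coh$answers$phase1[[i]],
                                "phase1_screen")
    # pregnancy is exclusionary when reported
    if (identical(coh$answers$phase1[[i]]$pregnant, "yes") &&
        dec$outcome == "eligible") {
      dec <- evaluate_eligibility(
        c(criteria, list(wt_criterion("not_pregnant", "phase1_screen",
                                      item = "pregnant", set = "no"))),
        coh$answers$phase1[[i]], "phase1_screen")
    }
    advance_phase(study, p$study_id, dec,
                  time = as_time(reg_date, config$timezone) + 7200)
  }

  # --- phase-2 auto-screen
  for (i in seq_len(n)) {
    if (!identical(study$registry[[ids[i]]]$phase, "phase2_screen")) next
    t2 <- as_time(start - 80 + ((i - 1) %% reg_days), config$timezone)
    tok <- issue_link(study, "phase2", study_id = ids[i])
    submit_response(study, tok, coh$answers$phase2[[i]], time = t2)
    dec <- evaluate_eligibility(criteria, coh$answers$phase2[[i]],
                                "phase2_screen")
    advance_phase(study, ids[i], dec, time = t2 + 3600)
  }

  # --- phase-3: device links + coordinator-reviewed food diary
  diary_start <- start - 60
  for (i in seq_len(n)) {
    if (!identical(study$registry[[ids[i]]]$phase, "phase3_screen")) next
    t3 <- as_time(start - 70 + ((i - 1) %% reg_days), config$timezone)
    link_device(study, ids[i], "wearable_vendor",
                token = random_token(), date = as.Date(t3))
    link_device(study, ids[i], "scale_vendor",
                token = random_token(), date = as.Date(t3))
    n_days <- if (coh$profiles$diary_complete[i]) 5L else sample(0:4, 1L)
    diary <- if (n_days > 0) {
      dts <- sort(sample(0:4, n_days))
      data.frame(study_id = ids[i], metric = "food_entry",
                 timestamp = sprintf("%s 12:00:00",
                                     format(diary_start + dts)),
                 value = 1, unit = "entry", source = "wearable_vendor",
                 retrieved_at = "", stringsAsFactors = FALSE)
    } else new_observation_store()
    rev <- review_food_diary(diary, diary_start, 5, min_days = 5,
                             study_id = ids[i])
    dec <- if (rev$pass) {
      coordinator_decision("eligible", "phase3_screen", "coord1")
    } else {
      coordinator_decision("ineligible", "phase3_screen", "coord1",
                           failed_criteria = "food_diary_5day")
    }
    advance_phase(study, ids[i], dec, time = t3 + 86400 * 7)
  }

  # --- baseline attendance + minimization randomization
  for (i in seq_len(n)) {
    if (!identical(study$registry[[ids[i]]]$phase, "baseline")) next
    if (!coh$profiles$attends_baseline[i]) next   # no-show: stays pending
    tb <- as_time(start - 30 + ((i - 1) %% reg_days), config$timezone)
    advance_phase(study, ids[i],
                  evaluate_eligibility(list(), list(), "baseline"),
                  time = tb)
    levels <- list(
      sex = coh$profiles$sex[i],
      bmi_category = if (coh$profiles$bmi[i] < 35) "bmi_lt_35"
                     else "bmi_ge_35")
    randomize_participant(study, ids[i], levels, alloc, time = tb + 3600)
  }
  randomized <- names(Filter(function(p) identical(p$phase, "randomized"),
                             study$registry))

  # --- observation streams + mock vendor server
  all_streams <- rbind_fast(lapply(randomized, function(sid)
    generate_streams(sid, streams)))
  if (is.null(all_streams)) {
    all_streams <- data.frame(study_id = character(0), metric = character(0),
                              timestamp = character(0), value = numeric(0),
                              unit = character(0), source = character(0),
                              available_at = character(0),
                              stringsAsFactors = FALSE)
  }
  accounts <- c(paste0(randomized, "::wearable_vendor"),
                paste0(randomized, "::scale_vendor"))
  server <- mock_device_server(all_streams, accounts = accounts)

  # --- daily synchronization cycles at the end of the stream horizon
  store <- new_observation_store()
  budgets <- list()
  plans <- list()
  last_day <- streams$start_date + streams$days - 1
  sync_days <- seq(last_day - sync_cycles + 1, last_day, by = "day")
  for (d in as.list(sync_days)) {
    now_d <- as_time(d, config$timezone) + 9 * 3600
    pl <- plan_sync(accounts, .endpoints, now_d, budgets,
                    window_days = 7, tz = config$timezone)
    budgets <- pl$budgets
    run <- run_sync(pl$plan, server, store, now_d)
    store <- run$store
    plans[[length(plans) + 1L]] <- run$plan
  }

  # --- adherence alerts at the final sync day
  alerts <- scan_study_alerts(study, store, last_day)

  # --- tailored feedback over the last week + usage aggregation
  msg_days <- seq(last_day - 6, last_day, by = "day")
  obs_d <- as.Date(substr(store$timestamp, 1, 10))
  msg_pieces <- list()
  open_pieces <- list()
  for (sid in randomized) {
    p <- study$registry[[sid]]
    sub <- which(store$study_id == sid)
    od <- obs_d[sub]
    om <- store$metric[sub]
    for (d in as.list(msg_days)) {
      has <- function(metrics) any(od == d & om %in% metrics)
      ev <- schedule_feedback(p, list(diet = has("food_entry"),
                                      activity = has(c("steps", "heart_rate",
                                                       "sleep_minutes")),
                                      weight = has("weight")),
                              d, config)
      if (nrow(ev)) {
        u <- stats::runif(nrow(ev))
        ev$status[u < message_missed_prob] <- "missed"
        ev$status[u > 1 - message_open_prob] <- "opened"
        msg_pieces[[length(msg_pieces) + 1L]] <- ev
      }
      if (stats::runif(1) < open_prob) {
        open_pieces[[length(open_pieces) + 1L]] <- data.frame(
          study_id = sid, timestamp = sprintf("%s 10:00:00", format(d)),
          stringsAsFactors = FALSE)
      }
    }
  }
  message_log <- rbind_fast(msg_pieces)
  if (is.null(message_log)) {
    message_log <- schedule_feedback(list(arm = "none"), list(), last_day,
                                     config)
  } else {
    message_log$date <- as.Date(message_log$date, origin = "1970-01-01")
  }
  app_open_log <- rbind_fast(open_pieces) %||%
    data.frame(study_id = character(0), timestamp = character(0),
               stringsAsFactors = FALSE)
  usage <- usage_summary(message_log, app_open_log,
                         c(msg_days[1], last_day))

  # --- withdrawals and assessments
  assessments <- data.frame(label = c("6mo", "12mo"),
                            due_date = c(start + 180, start + 365),
                            stringsAsFactors = FALSE)
  wd1 <- sample(randomized, min(withdrawals[1], length(randomized)))
  for (k in seq_along(wd1)) {
    record_withdrawal(study, wd1[k], start + 90 + k, "health issues")
  }
  active <- setdiff(randomized, wd1)
  done6 <- active[stats::runif(length(active)) < completion[["6mo"]]]
  for (sid in done6) record_assessment(study, sid, "6mo", start + 180)
  wd2 <- sample(active, min(withdrawals[2], length(active)))
  for (k in seq_along(wd2)) {
    record_withdrawal(study, wd2[k], start + 250 + k, "health issues")
  }
  active2 <- setdiff(active, wd2)
  done12 <- active2[stats::runif(length(active2)) < completion[["12mo"]]]
  for (sid in done12) record_assessment(study, sid, "12mo", start + 365)
  for (sid in done12) record_payment(study, sid, 50, start + 366)

  flow <- consort_flow(event_log(study), assessments)
  ret <- retention_report(study, assessments)
  snapshot <- study_snapshot(study, store, last_day, assessments)

  list(study = study, store = store, flow = flow, retention = ret,
       alerts = alerts, usage = usage, message_log = message_log,
       snapshot = snapshot, assessments = assessments, plans = plans,
       randomized = randomized, server = server)
}

#' Write the reports of a simulated study to files
#'
#' Deterministic text outputs (no run timestamps), so two runs with the
#' same seed produce byte-identical files: `consort.json`,
#' `retention.csv`, `alerts.csv`, `usage.csv`, `observations.csv`,
#' `events.jsonl`, `consort.dot`.
#'
#' @param sim result of [simulate_study()].
#' @param dir output directory (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
write_reports <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  f <- function(name) file.path(dir, name)
  flow <- sim$flow
  jsonlite::write_json(
    list(phases = flow$phases, randomized = flow$randomized,
         arms = flow$arms, assessments = flow$assessments),
    f("consort.json"), auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(sim$retention, f("retention.csv"), row.names = FALSE)
  utils::write.csv(sim$alerts, f("alerts.csv"), row.names = FALSE)
  utils::write.csv(sim$usage$daily, f("usage.csv"), row.names = FALSE)
  write_observations(sim$store, f("observations.csv"))
  write_events(sim$study, f("events.jsonl"))
  writeLines(consort_dot(flow), f("consort.dot"))
  paths <- c(f("consort.json"), f("retention.csv"), f("alerts.csv"),
             f("usage.csv"), f("observations.csv"), f("events.jsonl"),
             f("consort.dot"))
  invisible(paths)
}
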