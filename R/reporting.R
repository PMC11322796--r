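# CONSORT-style funnel aggregation, withdrawal-adjusted retention, and
# study snapshots. Everything here is a pure function of the event log
# (plus the observation store for snapshots), so reports are replayable.

#' Record an assessment completion
#'
#' @param study a [wt_study()].
#' @param study_id participant identifier.
#' @param label assessment label (e.g. `"6mo"`, `"12mo"`).
#' @param date completion date.
#' @return invisibly, the study.
#' @export
record_assessment <- function(study, study_id, label, date) {
  get_participant(study, study_id)
  append_event(study, study_id, "assessed", as_date(date),
               payload = list(label = label))
  invisible(study)
}

#' Record a remuneration payment
#'
#' @param study a [wt_study()].
#' @param study_id participant identifier.
#' @param amount payment amount.
#' @param date payment date.
#' @return invisibly, the study.
#' @export
record_payment <- function(study, study_id, amount, date) {
  get_participant(study, study_id)
  append_event(study, study_id, "paid", as_date(date),
               payload = list(amount = amount))
  invisible(study)
}

#' CONSORT flow from an event log
#'
#' Derives the screening funnel purely from events. For each screening
#' phase: `entered` (registrations for phase 1, prior-phase eligibility
#' otherwise), `eligible`, `ineligible`, and `pending = entered − eligible
#' − ineligible` (still in phase, includes mid-phase withdrawals).
#' Randomized counts per arm come from `randomized` events; assessment
#' nodes count completions against a due date, with withdrawals before the
#' due date removed from the due count.
#'
#' @param events event list (from [event_log()]).
#' @param assessments optional data.frame (`label`, `due_date`) declaring
#'   scheduled assessments.
#' @return a `wt_consort` list: `phases` (data.frame), `arms`
#'   (data.frame), `randomized` (count), `assessments` (data.frame or
#'   NULL).
#' @export
consort_flow <- function(events, assessments = NULL) {
  # integrity: per-participant timestamps must be non-decreasing
  last <- new.env(parent = emptyenv())
  for (e in events) {
    t <- as.numeric(e$timestamp)
    prev <- get0(e$study_id, envir = last, ifnotfound = -Inf)
    if (t < prev)
      wt_stop(paste("event log corrupted: out-of-order events for",
                    e$study_id), "weartrial_log_corrupt")
    assign(e$study_id, t, envir = last)
  }
  kinds <- vapply(events, `[[`, character(1), "event_kind")
  n_reg <- sum(kinds == "registered")
  screen_phases <- setdiff(study_phases(), c("randomized", "completed"))
  elig <- ine <- stats::setNames(integer(length(screen_phases)),
                                 screen_phases)
  for (e in events) {
    if (e$event_kind == "eligible") {
      ph <- e$payload$phase
      if (ph %in% screen_phases) elig[ph] <- elig[ph] + 1L
    } else if (e$event_kind == "ineligible") {
      ph <- e$payload$phase
      if (ph %in% screen_phases) ine[ph] <- ine[ph] + 1L
    }
  }
  entered <- integer(length(screen_phases))
  entered[1] <- n_reg
  for (k in seq_along(screen_phases)[-1]) {
    entered[k] <- elig[k - 1L]
  }
  phases <- data.frame(phase = screen_phases, entered = entered,
                       eligible = as.integer(elig),
                       ineligible = as.integer(ine),
                       pending = entered - as.integer(elig) -
                         as.integer(ine),
                       stringsAsFactors = FALSE)
  rand_events <- events[kinds == "randomized"]
  arms_vec <- vapply(rand_events, function(e) e$payload$arm, character(1))
  if (length(arms_vec)) {
    arms <- as.data.frame(table(arm = arms_vec), stringsAsFactors = FALSE)
    names(arms) <- c("arm", "randomized")
  } else {
    arms <- data.frame(arm = character(0), randomized = integer(0),
                       stringsAsFactors = FALSE)
  }
  out_assess <- NULL
  if (!is.null(assessments) && nrow(assessments)) {
    wd_dates <- lapply(events[kinds == "withdrawn"],
                       function(e) as_date(e$payload$date))
    wd_dates <- do.call(c, c(list(as.Date(character(0))), wd_dates))
    asmt_labels <- vapply(events[kinds == "assessed"],
                          function(e) e$payload$label, character(1))
    out_assess <- do.call(rbind, lapply(seq_len(nrow(assessments)),
                                        function(i) {
      lab <- assessments$label[i]
      due_date <- as_date(assessments$due_date[i])
      wb <- sum(wd_dates < due_date)
      data.frame(label = lab,
                 randomized_n = length(rand_events),
                 withdrawn_before = wb,
                 due = length(rand_events) - wb,
                 completed = sum(asmt_labels == lab),
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(phases = phases, arms = arms,
                 randomized = length(rand_events),
                 assessments = out_assess),
            class = "wt_consort")
}

#' @export
print.wt_consort <- function(x, ...) {
  cat("CONSORT flow\n")
  print(x$phases, row.names = FALSE)
  cat("randomized:", x$randomized, "\n")
  if (nrow(x$arms)) print(x$arms, row.names = FALSE)
  if (!is.null(x$assessments)) print(x$assessments, row.names = FALSE)
  invisible(x)
}

#' Export a CONSORT flow as Graphviz DOT text
#'
#' @param flow a `wt_consort` from [consort_flow()].
#' @return character scalar of DOT source.
#' @export
consort_dot <- function(flow) {
  lines <- c("digraph consort {", "  node [shape=box];")
  ph <- flow$phases
  for (i in seq_len(nrow(ph))) {
    lines <- c(lines, sprintf(
      '  %s [label="%s\\nentered %d\\neligible %d / ineligible %d / pending %d"];',
      ph$phase[i], ph$phase[i], ph$entered[i], ph$eligible[i],
      ph$ineligible[i], ph$pending[i]))
    if (i > 1) lines <- c(lines, sprintf("  %s -> %s;", ph$phase[i - 1],
                                         ph$phase[i]))
  }
  lines <- c(lines, sprintf('  randomized [label="randomized\\n%d"];',
                            flow$randomized),
             sprintf("  %s -> randomized;", ph$phase[nrow(ph)]))
  for (i in seq_len(nrow(flow$arms))) {
    nm <- sprintf("arm_%d", i)
    lines <- c(lines, sprintf('  %s [label="%s\\nn=%d"];', nm,
                              flow$arms$arm[i], flow$arms$randomized[i]),
               sprintf("  randomized -> %s;", nm))
  }
  paste(c(lines, "}"), collapse = "\n")
}

#' Withdrawal-adjusted retention
#'
#' The denominator for a scheduled assessment excludes participants who
#' withdrew before it: `denominator = randomized_n − withdrawn_before`.
#' The rate is `100 · completers / denominator`, rounded half-up to two
#' decimals; it is scale-free (multiplying all three counts by a constant
#' leaves it unchanged).
#'
#' @param randomized_n number randomized.
#' @param withdrawn_before withdrawals before the assessment.
#' @param completers participants completing the assessment.
#' @param label optional assessment label.
#' @return a `wt_retention` list: `label`, `randomized_n`,
#'   `withdrawn_before`, `completers`, `denominator`, `rate_percent`.
#' @examples
#' retention(502, 9, 394)$rate_percent  # 79.92
#' @export
retention <- function(randomized_n, withdrawn_before, completers,
                      label = "") {
  assert_that(withdrawn_before >= 0 && withdrawn_before <= randomized_n,
              "withdrawn_before must be in [0, randomized_n]")
  denominator <- randomized_n - withdrawn_before
  assert_that(completers >= 0, "completers must be nonnegative")
  assert_that(completers <= denominator,
              "completers cannot exceed the denominator")
  structure(list(label = label, randomized_n = randomized_n,
                 withdrawn_before = withdrawn_before,
                 completers = completers, denominator = denominator,
                 rate_percent = round_half_up(100 * completers / denominator,
                                              2)),
            class = "wt_retention")
}

#' @export
print.wt_retention <- function(x, ...) {
  cat(sprintf("retention%s: %.2f%% (%d/%d; randomized %d, withdrawn before %d)\n",
              if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
              x$rate_percent, x$completers, x$denominator, x$randomized_n,
              x$withdrawn_before))
  invisible(x)
}

#' Retention report for the study's assessments
#'
#' @param study a [wt_study()].
#' @param assessments data.frame (`label`, `due_date`).
#' @return data.frame, one row per assessment, with the [retention()]
#'   fields.
#' @export
retention_report <- function(study, assessments) {
  flow <- consort_flow(event_log(study), assessments)
  do.call(rbind, lapply(seq_len(nrow(flow$assessments)), function(i) {
    a <- flow$assessments[i, ]
    r <- retention(a$randomized_n, a$withdrawn_before, a$completed,
                   label = a$label)
    data.frame(label = r$label, randomized_n = r$randomized_n,
               withdrawn_before = r$withdrawn_before,
               completers = r$completers, denominator = r$denominator,
               rate_percent = r$rate_percent, stringsAsFactors = FALSE)
  }))
}

#' Study snapshot
#'
#' A dashboard-style summary composed purely from the event log and the
#' observation store: the CONSORT flow, per-phase registry counts, open
#' adherence alerts as of the snapshot date, upcoming assessments, and
#' total remuneration paid.
#'
#' @param study a [wt_study()].
#' @param store observation store.
#' @param as_of snapshot date.
#' @param assessments optional assessments data.frame (`label`,
#'   `due_date`).
#' @param alert_cfg an [alert_config()].
#' @return a list: `as_of`, `flow`, `phase_counts`, `open_alerts`,
#'   `upcoming_assessments`, `remuneration_total`.
#' @export
study_snapshot <- function(study, store, as_of, assessments = NULL,
                           alert_cfg = alert_config()) {
  as_of <- as_date(as_of)
  flow <- consort_flow(event_log(study), assessments)
  reg <- participants(study)
  phase_counts <- if (nrow(reg)) table(reg$phase) else table(character(0))
  alerts <- scan_study_alerts(study, store, as_of, alert_cfg)
  paid <- 0
  for (e in event_log(study)) {
    if (e$event_kind == "paid") paid <- paid + as.numeric(e$payload$amount)
  }
  upcoming <- NULL
  if (!is.null(assessments) && nrow(assessments)) {
    due <- as_date(assessments$due_date)
    upcoming <- assessments[due >= as_of, , drop = FALSE]
  }
  list(as_of = as_of, flow = flow,
       phase_counts = as.list(phase_counts),
       open_alerts = alerts,
       upcoming_assessments = upcoming,
       remuneration_total = paid)
}
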