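# Three-phase screening funnel: automatic eligibility evaluation on
# questionnaire answers, coordinator-supported food-diary review for
# phase 3, and phase advancement along the funnel.

#' Eligibility criterion
#'
#' A predicate over one questionnaire answer, or over a derived quantity.
#' The only built-in derived quantity is `"bmi"`, computed from height and
#' weight items in either US customary (`lb`/`in`) or metric (`kg`/`m`)
#' units. Numeric bounds are inclusive on both ends.
#'
#' @param name criterion name (reported in failure lists).
#' @param phase funnel phase the criterion applies to.
#' @param item item id supplying the value (omit when `derived` is used).
#' @param derived `"bmi"` to derive body-mass index from two items.
#' @param height_item,weight_item item ids for the derived BMI.
#' @param units `"us"` (pounds and inches) or `"metric"` (kg and metres).
#' @param min,max inclusive bounds.
#' @param set allowed values (for choice answers, e.g. smartphone "yes").
#' @return a `wt_criterion` list.
#' @export
wt_criterion <- function(name, phase, item = NULL, derived = NULL,
                         height_item = NULL, weight_item = NULL,
                         units = c("us", "metric"),
                         min = NULL, max = NULL, set = NULL) {
  units <- match.arg(units)
  assert_that(xor(is.null(item), is.null(derived)),
              "give exactly one of item or derived")
  if (!is.null(derived)) {
    derived <- match.arg(derived, "bmi")
    assert_that(!is.null(height_item) && !is.null(weight_item),
                "derived bmi needs height_item and weight_item")
  }
  structure(list(name = name, phase = phase, item = item, derived = derived,
                 height_item = height_item, weight_item = weight_item,
                 units = units, min = min, max = max, set = set),
            class = "wt_criterion")
}

#' Body-mass index from self-reported height and weight
#'
#' @param height height (inches for `units="us"`, metres for metric).
#' @param weight weight (pounds for `units="us"`, kilograms for metric).
#' @param units unit system.
#' @return BMI in kg/m^2.
#' @export
compute_bmi <- function(height, weight, units = c("us", "metric")) {
  units <- match.arg(units)
  if (units == "us") {
    kg <- weight * LB_TO_KG
    m <- height * 0.0254
  } else {
    kg <- weight
    m <- height
  }
  kg / m^2
}

criterion_value <- function(crit, answers) {
  if (!is.null(crit$derived)) {
    h <- answers[[crit$height_item]]
    w <- answers[[crit$weight_item]]
    if (is.null(h) || is.null(w)) return(NULL)
    return(compute_bmi(h, w, crit$units))
  }
  answers[[crit$item]]
}

criterion_passes <- function(crit, value) {
  if (!is.null(crit$set)) return(isTRUE(any(value %in% crit$set)))
  # inclusive bounds with a hair of tolerance so derived quantities (BMI
  # from unit-converted height/weight) are not excluded by float rounding
  eps <- 1e-9
  ok <- TRUE
  if (!is.null(crit$min)) ok <- ok && isTRUE(value >= crit$min - eps)
  if (!is.null(crit$max)) ok <- ok && isTRUE(value <= crit$max + eps)
  ok
}

#' Evaluate eligibility for a screening phase
#'
#' Applies every criterion declared for the phase to the answers. The
#' outcome is `eligible` iff all criteria pass; every failing criterion is
#' listed. A criterion whose source answer is absent cannot be decided
#' automatically and yields `needs_manual_review` instead of a silent
#' failure. Deterministic.
#'
#' @param criteria list of [wt_criterion()]s (other phases are ignored).
#' @param answers named list of answers for the phase's questionnaire.
#' @param phase the phase being screened.
#' @param decided_by `"auto"` for system screening, or a coordinator id.
#' @param time decision timestamp.
#' @return a `wt_decision` list with `outcome`, `failed_criteria`,
#'   `missing_criteria`, `phase`, `decided_at`, `decided_by`.
#' @export
evaluate_eligibility <- function(criteria, answers, phase,
                                 decided_by = "auto", time = Sys.time()) {
  criteria <- Filter(function(cr) identical(cr$phase, phase), criteria)
  failed <- character(0)
  missing <- character(0)
  for (cr in criteria) {
    v <- criterion_value(cr, answers)
    if (is.null(v) || (length(v) == 1L && is.na(v))) {
      missing <- c(missing, cr$name)
    } else if (!criterion_passes(cr, v)) {
      failed <- c(failed, cr$name)
    }
  }
  outcome <- if (length(failed)) "ineligible"
             else if (length(missing)) "needs_manual_review"
             else "eligible"
  structure(list(outcome = outcome, failed_criteria = failed,
                 missing_criteria = missing, phase = phase,
                 decided_at = time, decided_by = decided_by),
            class = "wt_decision")
}

#' Record a coordinator's screening decision
#'
#' Used where automatic screening is insufficient: phase-3 review and any
#' `needs_manual_review` outcome.
#'
#' @param outcome `"eligible"` or `"ineligible"`.
#' @param phase the phase decided.
#' @param decided_by coordinator identifier (not `"auto"`).
#' @param failed_criteria names of failed criteria (required when
#'   ineligible).
#' @param time decision timestamp.
#' @return a `wt_decision`.
#' @export
coordinator_decision <- function(outcome, phase, decided_by,
                                 failed_criteria = character(0),
                                 time = Sys.time()) {
  outcome <- match.arg(outcome, c("eligible", "ineligible"))
  assert_that(!identical(decided_by, "auto"),
              "coordinator decisions need a coordinator id")
  assert_that(outcome != "ineligible" || length(failed_criteria) > 0,
              "ineligible decisions must list failed criteria")
  structure(list(outcome = outcome, failed_criteria = failed_criteria,
                 missing_criteria = character(0), phase = phase,
                 decided_at = time, decided_by = decided_by),
            class = "wt_decision")
}

#' Advance a participant through the funnel
#'
#' An `eligible` decision moves the participant to the next funnel phase
#' and appends `eligible` + `advanced` events; `ineligible` moves to the
#' terminal ineligible state; `needs_manual_review` changes nothing.
#' Phase-3 decisions require coordinator sign-off (the decision's
#' `decided_by` must not be `"auto"`).
#'
#' @param study a [wt_study()].
#' @param study_id participant identifier.
#' @param decision a `wt_decision` for the participant's current phase.
#' @param time event timestamp.
#' @return the updated participant record.
#' @export
advance_phase <- function(study, study_id, decision, time = Sys.time()) {
  p <- get_participant(study, study_id)
  assert_that(identical(decision$phase, p$phase),
              sprintf("decision is for %s but %s is in %s",
                      decision$phase, study_id, p$phase))
  if (identical(p$phase, "phase3_screen")) {
    assert_that(!identical(decision$decided_by, "auto"),
                "phase-3 outcomes require coordinator sign-off")
  }
  if (decision$outcome == "needs_manual_review") return(p)
  if (decision$outcome == "ineligible") {
    append_event(study, study_id, "ineligible", time,
                 payload = list(phase = p$phase,
                                failed = as.list(decision$failed_criteria)))
    p$phase <- "ineligible"
    study$registry[[study_id]] <- p
    return(p)
  }
  # eligible: move to the next funnel phase
  ord <- match(p$phase, study_phases())
  assert_that(ord < length(study_phases()), "cannot advance past completed")
  nxt <- study_phases()[ord + 1L]
  append_event(study, study_id, "eligible", time,
               payload = list(phase = p$phase))
  if (!identical(nxt, "randomized")) {
    # entering 'randomized' happens only through the allocator
    append_event(study, study_id, "advanced", time, payload = list(to = nxt))
    p$phase <- nxt
    study$registry[[study_id]] <- p
  }
  p
}

#' Food-diary review summary for phase-3 screening
#'
#' Counts distinct calendar dates carrying at least one food-log entry in
#' the review window. The screening task asks for a short diary (default:
#' all 5 days of a 5-day window); the entries-per-day minimum is optional
#' and off by default.
#'
#' @param observations observation data.frame (long format); rows with
#'   `metric != "food_entry"` are ignored.
#' @param window_start first date of the review window.
#' @param window_length_days window length in days.
#' @param min_days days with entries needed to pass.
#' @param min_entries_per_day optional minimum mean entries per logged day.
#' @param study_id optional filter when `observations` spans participants.
#' @return list with `days_logged`, `entries_per_day`, `pass`.
#' @export
review_food_diary <- function(observations, window_start,
                              window_length_days = 5, min_days = 5,
                              min_entries_per_day = NULL, study_id = NULL) {
  assert_that(window_length_days >= 1, "empty window")
  window_start <- as_date(window_start)
  days <- seq(window_start, by = "day", length.out = window_length_days)
  obs <- observations[observations$metric == "food_entry", , drop = FALSE]
  if (!is.null(study_id))
    obs <- obs[obs$study_id == study_id, , drop = FALSE]
  dates <- as_date(obs$timestamp)
  in_win <- dates %in% days
  dates <- dates[in_win]
  days_logged <- length(unique(dates))
  epd <- if (days_logged == 0) 0 else length(dates) / days_logged
  pass <- days_logged >= min_days &&
    (is.null(min_entries_per_day) || epd >= min_entries_per_day)
  list(days_logged = days_logged, entries_per_day = epd, pass = pass)
}
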