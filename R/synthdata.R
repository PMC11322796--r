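# Seeded synthetic data: screening cohorts with boundary-straddling
# demographics, wearable/scale observation streams with realistic
# missingness runs, and a mock device-vendor server implementing the
# connector interface with an hourly quota and upload delays — so the
# entire pipeline runs offline.

#' Cohort generator parameters
#'
#' Distributions deliberately straddle the eligibility boundaries (age 18,
#' BMI 27 and 43) so the screening logic is exercised on both sides.
#'
#' @param n cohort size.
#' @param age_mean,age_sd,age_min age model: normal, truncated below at
#'   `age_min` (below the adult cut-off, so ineligible minors occur).
#' @param bmi_dist `"normal"` or `"uniform"`.
#' @param bmi_mean,bmi_sd normal-BMI parameters (span the 27-43 window and
#'   beyond).
#' @param bmi_range support of the uniform BMI option.
#' @param smartphone_rate probability of owning a smartphone.
#' @param pregnancy_rate probability a female respondent reports pregnancy.
#' @param pass_p2 probability of passing the phase-2 medical screen.
#' @param pass_p3 probability of completing the phase-3 food diary.
#' @param attend_baseline probability of attending the baseline
#'   assessment.
#' @param seed optional integer seed; `NULL` uses the current RNG state.
#' @return a `wt_cohort_params` list.
#' @export
cohort_params <- function(n = 1741,
                          age_mean = 45, age_sd = 12, age_min = 16,
                          bmi_dist = c("normal", "uniform"),
                          bmi_mean = 33, bmi_sd = 6,
                          bmi_range = c(20, 50),
                          smartphone_rate = 0.95,
                          pregnancy_rate = 0.03,
                          pass_p2 = 0.725, pass_p3 = 0.653,
                          attend_baseline = 0.849,
                          seed = NULL) {
  bmi_dist <- match.arg(bmi_dist)
  probs <- c(smartphone_rate, pregnancy_rate, pass_p2, pass_p3,
             attend_baseline)
  assert_that(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  assert_that(n >= 0, "n must be nonnegative")
  structure(list(n = n, age_mean = age_mean, age_sd = age_sd,
                 age_min = age_min, bmi_dist = bmi_dist,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 bmi_range = bmi_range, smartphone_rate = smartphone_rate,
                 pregnancy_rate = pregnancy_rate,
                 pass_p2 = pass_p2, pass_p3 = pass_p3,
                 attend_baseline = attend_baseline, seed = seed),
            class = "wt_cohort_params")
}

#' Fixture phase-1 screening questionnaire
#'
#' Demographics and device access, with a branch skipping the pregnancy
#' item for male respondents, and a pregnancy exclusion flag. The item
#' set is a generic weight-trial fixture, not a reconstruction of any
#' specific instrument.
#'
#' @return a [wt_questionnaire()].
#' @export
phase1_questionnaire <- function() {
  wt_questionnaire(
    qid = "phase1", phase = "phase1_screen",
    items = list(
      wt_item("email", "Contact email", "text", pattern = ".+@.+"),
      wt_item("age", "Age in years", "integer", min = 0, max = 120),
      wt_item("sex", "Sex", "choice", choices = c("female", "male")),
      wt_item("pregnant", "Are you currently pregnant?", "choice",
              choices = c("yes", "no")),
      wt_item("height_in", "Height (inches)", "decimal", min = 36, max = 90),
      wt_item("weight_lb", "Weight (pounds)", "decimal", min = 60, max = 700),
      wt_item("smartphone", "Do you use a smartphone?", "choice",
              choices = c("yes", "no"))
    ),
    branch_rules = list(
      wt_branch("sex", "=", "male", "height_in")
    ),
    flags = list(
      wt_flag("pregnancy_excluded", 'pregnant == "yes"')
    )
  )
}

#' Fixture phase-2 screening questionnaire
#'
#' Medical exclusion item plus a short motivation scale with a summed
#' score and a low-motivation flag.
#'
#' @return a [wt_questionnaire()].
#' @export
phase2_questionnaire <- function() {
  wt_questionnaire(
    qid = "phase2", phase = "phase2_screen",
    items = list(
      wt_item("exclusionary_condition",
              "Any medical condition from the exclusion list?", "choice",
              choices = c("yes", "no")),
      wt_item("m1", "Motivation: importance (0-10)", "integer",
              min = 0, max = 10),
      wt_item("m2", "Motivation: confidence (0-10)", "integer",
              min = 0, max = 10),
      wt_item("m3", "Motivation: readiness (0-10)", "integer",
              min = 0, max = 10)
    ),
    scoring = list(
      wt_score("motivation_total", "sum(m1, m2, m3)")
    ),
    flags = list(
      wt_flag("low_motivation", "motivation_total < 3")
    )
  )
}

#' Default eligibility criteria for the fixture questionnaires
#'
#' Adults (age >= 18), BMI within 27-43 kg/m^2 inclusive (derived from
#' self-reported height and weight in US units), smartphone users, and no
#' phase-2 exclusionary condition.
#'
#' @return list of [wt_criterion()]s.
#' @export
default_criteria <- function() {
  list(
    wt_criterion("age_18_plus", "phase1_screen", item = "age", min = 18),
    wt_criterion("bmi_27_43", "phase1_screen", derived = "bmi",
                 height_item = "height_in", weight_item = "weight_lb",
                 units = "us", min = 27, max = 43),
    wt_criterion("smartphone_user", "phase1_screen", item = "smartphone",
                 set = "yes"),
    wt_criterion("no_exclusionary_condition", "phase2_screen",
                 item = "exclusionary_condition", set = "no")
  )
}

#' Generate a synthetic screening cohort
#'
#' Reproducible given the seed. Returns one profile per registrant plus
#' ready-made answer sets for the fixture phase-1 and phase-2
#' questionnaires; downstream pass/fail draws (phase 2 medical, phase 3
#' diary completion, baseline attendance) are materialized as columns so
#' the funnel's configured pass rates are explicit.
#'
#' @param params a [cohort_params()].
#' @return list: `profiles` (data.frame) and `answers` (list with
#'   `phase1`, `phase2`: one named answer list per registrant).
#' @export
generate_cohort <- function(params = cohort_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n
  if (n == 0) {
    return(list(profiles = data.frame(), answers = list(phase1 = list(),
                                                        phase2 = list())))
  }
  age <- pmax(params$age_min,
              round(stats::rnorm(n, params$age_mean, params$age_sd)))
  sex <- sample(c("female", "male"), n, replace = TRUE)
  bmi <- switch(params$bmi_dist,
    normal = stats::rnorm(n, params$bmi_mean, params$bmi_sd),
    uniform = stats::runif(n, params$bmi_range[1], params$bmi_range[2])
  )
  bmi <- pmax(15, bmi)
  height_in <- round(stats::rnorm(n, ifelse(sex == "male", 69, 64), 2.8), 1)
  # invert BMI = kg/m^2 to a self-reported weight in pounds
  weight_lb <- round(bmi * (height_in * 0.0254)^2 / LB_TO_KG, 1)
  smartphone <- ifelse(stats::runif(n) < params$smartphone_rate, "yes", "no")
  pregnant <- ifelse(sex == "female" &
                       stats::runif(n) < params$pregnancy_rate, "yes", "no")
  profiles <- data.frame(
    email = sprintf("p%06d@example.org", seq_len(n)),
    age = age, sex = sex, height_in = height_in, weight_lb = weight_lb,
    bmi = bmi, smartphone = smartphone, pregnant = pregnant,
    medical_ok = stats::runif(n) < params$pass_p2,
    diary_complete = stats::runif(n) < params$pass_p3,
    attends_baseline = stats::runif(n) < params$attend_baseline,
    motivation = matrix(sample(0:10, 3 * n, replace = TRUE), ncol = 3),
    stringsAsFactors = FALSE
  )
  phase1 <- lapply(seq_len(n), function(i) {
    a <- list(email = profiles$email[i], age = profiles$age[i],
              sex = profiles$sex[i])
    if (profiles$sex[i] == "female") a$pregnant <- profiles$pregnant[i]
    a$height_in <- profiles$height_in[i]
    a$weight_lb <- profiles$weight_lb[i]
    a$smartphone <- profiles$smartphone[i]
    a
  })
  phase2 <- lapply(seq_len(n), function(i) {
    list(exclusionary_condition = if (profiles$medical_ok[i]) "no" else "yes",
         m1 = profiles$motivation.1[i], m2 = profiles$motivation.2[i],
         m3 = profiles$motivation.3[i])
  })
  list(profiles = profiles, answers = list(phase1 = phase1, phase2 = phase2))
}

# ---- observation streams ------------------------------------------------

#' Stream generator parameters
#'
#' Daily self-monitoring streams per participant: overdispersed step
#' counts (negative binomial), normal heart rate and sleep, Poisson food
#' entries at meal times, and weight following baseline + linear trend +
#' noise. Adherence is an alternating renewal process: adherent runs and
#' missing runs with geometric lengths, one process per data source
#' (tracker wear, food logging, scale use), which reproduces the
#' multi-day gaps the alert rules target. Records become visible to the
#' vendor server one day after measurement, plus an optional geometric
#' upload delay (connectivity problems).
#'
#' @param days horizon in days.
#' @param start_date first stream date.
#' @param steps_mean,steps_dispersion negative-binomial mean and size.
#' @param hr_mean,hr_sd resting heart rate model (bpm).
#' @param sleep_mean,sleep_sd nightly sleep model (minutes).
#' @param food_mean mean food entries per adherent day (>= 1 entry).
#' @param weight_baseline_lb,weight_trend_lb_wk,weight_noise_lb weight
#'   model in pounds (trend per week); stored values are converted to kg.
#' @param tracker_on_mean,tracker_off_mean mean adherent / missing run
#'   lengths (days) for tracker wear; `off_mean = 0` means full adherence,
#'   `on_mean = 0` none.
#' @param food_on_mean,food_off_mean likewise for food logging.
#' @param weight_on_mean,weight_off_mean likewise for scale use.
#' @param delay_prob probability a record suffers an extra upload delay.
#' @param delay_mean_days mean extra delay in days (geometric, >= 1).
#' @param seed optional integer seed.
#' @return a `wt_stream_params` list.
#' @export
stream_params <- function(days = 28,
                          start_date = as.Date("2020-03-01"),
                          steps_mean = 7500, steps_dispersion = 8,
                          hr_mean = 72, hr_sd = 5,
                          sleep_mean = 420, sleep_sd = 45,
                          food_mean = 3,
                          weight_baseline_lb = 210,
                          weight_trend_lb_wk = -0.5,
                          weight_noise_lb = 0.6,
                          tracker_on_mean = 12, tracker_off_mean = 2,
                          food_on_mean = 10, food_off_mean = 3,
                          weight_on_mean = 6, weight_off_mean = 2,
                          delay_prob = 0.1, delay_mean_days = 1,
                          seed = NULL) {
  assert_that(days >= 1, "days must be >= 1")
  assert_that(all(c(steps_mean, steps_dispersion, hr_mean, sleep_mean,
                    food_mean) >= 0), "rates must be nonnegative")
  assert_that(delay_mean_days >= 1, "mean delay must be >= 1 day")
  structure(list(days = days, start_date = as_date(start_date),
                 steps_mean = steps_mean,
                 steps_dispersion = steps_dispersion,
                 hr_mean = hr_mean, hr_sd = hr_sd,
                 sleep_mean = sleep_mean, sleep_sd = sleep_sd,
                 food_mean = food_mean,
                 weight_baseline_lb = weight_baseline_lb,
                 weight_trend_lb_wk = weight_trend_lb_wk,
                 weight_noise_lb = weight_noise_lb,
                 tracker_on_mean = tracker_on_mean,
                 tracker_off_mean = tracker_off_mean,
                 food_on_mean = food_on_mean,
                 food_off_mean = food_off_mean,
                 weight_on_mean = weight_on_mean,
                 weight_off_mean = weight_off_mean,
                 delay_prob = delay_prob,
                 delay_mean_days = delay_mean_days, seed = seed),
            class = "wt_stream_params")
}

# alternating renewal adherence indicator: TRUE = data present that day
adherence_seq <- function(days, on_mean, off_mean) {
  if (on_mean <= 0) return(rep(FALSE, days))
  if (off_mean <= 0) return(rep(TRUE, days))
  state_on <- stats::runif(1) < on_mean / (on_mean + off_mean)
  out <- logical(0)
  while (length(out) < days) {
    mean_len <- if (state_on) on_mean else off_mean
    len <- stats::rgeom(1, 1 / mean_len) + 1L
    out <- c(out, rep(state_on, len))
    state_on <- !state_on
  }
  out[seq_len(days)]
}

upload_delay_days <- function(n, params) {
  extra <- ifelse(stats::runif(n) < params$delay_prob,
                  stats::rgeom(n, 1 / params$delay_mean_days) + 1L, 0L)
  1L + extra   # records surface the day after measurement at the earliest
}

#' Generate observation streams for one participant
#'
#' Reproducible given the seed; missing runs fall exactly where the
#' adherence draws put them. The returned records carry an
#' `available_at` datetime used by the mock server to emulate upload
#' delays; weight values are in kilograms.
#'
#' @param study_id participant identifier.
#' @param params a [stream_params()].
#' @return data.frame: `study_id`, `metric`, `timestamp`, `value`,
#'   `unit`, `source`, `available_at`.
#' @export
generate_streams <- function(study_id, params = stream_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  days <- params$days
  dates <- seq(params$start_date, by = "day", length.out = days)
  tracker_on <- adherence_seq(days, params$tracker_on_mean,
                              params$tracker_off_mean)
  food_on <- adherence_seq(days, params$food_on_mean, params$food_off_mean)
  weight_on <- adherence_seq(days, params$weight_on_mean,
                             params$weight_off_mean)
  pieces <- list()
  add <- function(metric, ts, value, unit, source) {
    n <- length(ts)
    if (n == 0L) return()
    avail <- format(as.POSIXct(paste(substr(ts, 1, 10), "00:00:00"),
                               tz = "UTC") +
                      upload_delay_days(n, params) * 86400,
                    "%Y-%m-%d %H:%M:%S")
    pieces[[length(pieces) + 1L]] <<- data.frame(
      study_id = study_id, metric = metric, timestamp = ts,
      value = value, unit = unit, source = source,
      available_at = avail, stringsAsFactors = FALSE)
  }
  td <- dates[tracker_on]
  nt <- length(td)
  if (nt) {
    add("steps", format(td),
        as.numeric(stats::rnbinom(nt, size = params$steps_dispersion,
                                  mu = params$steps_mean)),
        "count", "wearable_vendor")
    add("heart_rate", format(td),
        round(stats::rnorm(nt, params$hr_mean, params$hr_sd), 1),
        "bpm", "wearable_vendor")
    add("sleep_minutes", format(td),
        pmax(0, round(stats::rnorm(nt, params$sleep_mean, params$sleep_sd))),
        "min", "wearable_vendor")
  }
  fd <- dates[food_on]
  if (length(fd)) {
    n_entries <- 1L + stats::rpois(length(fd), max(0, params$food_mean - 1))
    ts <- unlist(lapply(seq_along(fd), function(i) {
      hours <- sort(sample(7:21, n_entries[i], replace = TRUE))
      sprintf("%s %02d:%02d:00", format(fd[i]), hours,
              sample(0:59, n_entries[i], replace = TRUE))
    }), use.names = FALSE)
    add("food_entry", ts, rep(1, length(ts)), "entry", "wearable_vendor")
  }
  wd_idx <- which(weight_on)
  if (length(wd_idx)) {
    w_lb <- params$weight_baseline_lb +
      params$weight_trend_lb_wk * (wd_idx - 1) / 7 +
      stats::rnorm(length(wd_idx), 0, params$weight_noise_lb)
    add("weight", format(dates[wd_idx]), round(lb_to_kg(w_lb), 3),
        "kg", "scale_vendor")
  }
  out <- rbind_fast(pieces)
  if (is.null(out)) {
    out <- data.frame(study_id = character(0), metric = character(0),
                      timestamp = character(0), value = numeric(0),
                      unit = character(0), source = character(0),
                      available_at = character(0), stringsAsFactors = FALSE)
  }
  out
}

# ---- mock vendor server -------------------------------------------------

endpoint_vendor <- function(endpoint) {
  if (endpoint == "weight") "scale_vendor" else "wearable_vendor"
}

#' Mock device-vendor server
#'
#' Serves pre-loaded observation streams through the connector interface,
#' enforcing a per-account rolling-hour quota (excess calls are refused
#' with a quota-exceeded signal the scheduler must honour) and emulating
#' upload delays: a record is invisible until its `available_at` time.
#'
#' @param streams records from [generate_streams()] (rows for any number
#'   of participants).
#' @param limit_per_hour server-side quota per account per rolling hour.
#' @param accounts optionally, extra known account ids
#'   (`"study_id::vendor"`); accounts present in `streams` are known
#'   automatically.
#' @return a `wt_mock_server`.
#' @export
mock_device_server <- function(streams, limit_per_hour = 100,
                               accounts = character(0)) {
  s <- new.env(parent = emptyenv())
  s$streams <- streams
  s$limit_per_hour <- limit_per_hour
  s$avail <- as.numeric(as.POSIXct(streams$available_at, tz = "UTC"))
  key <- paste(streams$study_id, streams$metric,
               substr(streams$timestamp, 1, 10), sep = "\x1f")
  s$index <- new.env(parent = emptyenv())
  sp <- split(seq_len(nrow(streams)), key)
  nm <- names(sp)
  for (i in seq_along(sp)) assign(nm[i], sp[[i]], envir = s$index)
  s$accounts <- union(accounts, unique(c(
    paste0(streams$study_id, "::", streams$source))))
  s$budgets <- new.env(parent = emptyenv())
  class(s) <- "wt_mock_server"
  s
}

#' Fetch one (account, endpoint, date) from a connector
#'
#' @param server a connector object.
#' @param account account id (`"study_id::vendor"`).
#' @param endpoint one of `activity`, `food`, `sleep`, `weight`.
#' @param date calendar date requested.
#' @param now current time (for quota accounting and upload-delay
#'   visibility).
#' @return list with `status` (`"ok"` or `"quota_exceeded"`), `records`
#'   (data.frame, for ok) or `retry_at` (for refusals).
#' @export
server_fetch <- function(server, account, endpoint, date, now) {
  UseMethod("server_fetch")
}

#' @export
server_fetch.wt_mock_server <- function(server, account, endpoint, date,
                                        now) {
  if (!account %in% server$accounts) {
    wt_stop(paste("unknown account:", account), "weartrial_unknown_account")
  }
  assert_that(endpoint %in% .endpoints, paste("unknown endpoint:", endpoint))
  b <- get0(account, envir = server$budgets,
            ifnotfound = new_rate_budget(server$limit_per_hour))
  res <- acquire(b, 1L, now)
  assign(account, res$budget, envir = server$budgets)
  if (res$granted < 1L) {
    return(list(status = "quota_exceeded", retry_at = res$next_eligible))
  }
  parts <- strsplit(account, "::", fixed = TRUE)[[1]]
  sid <- parts[1]
  vendor <- parts[2]
  t_now <- as.numeric(as_time(now))
  day <- format(as_date(date))
  idx <- unlist(lapply(endpoint_metrics(endpoint), function(m)
    get0(paste(sid, m, day, sep = "\x1f"),
         envir = server$index, ifnotfound = integer(0))),
    use.names = FALSE)
  if (length(idx)) {
    idx <- idx[server$avail[idx] <= t_now &
                 server$streams$source[idx] == vendor]
  }
  recs <- server$streams[idx, c("study_id", "metric", "timestamp", "value",
                                "unit", "source"), drop = FALSE]
  list(status = "ok", records = recs)
}
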