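# Independent oracles and fixture builders. Each oracle re-derives the
# expected result by a different route than the implementation (explicit
# enumeration, brute-force window scans, direct arithmetic), so agreement
# is informative.

# --- questionnaire fixtures ---------------------------------------------

qn_linear <- function(k = 4) {
  wt_questionnaire(
    "lin", items = lapply(seq_len(k), function(i)
      wt_item(paste0("q", i), paste("Q", i), "integer", min = 0, max = 100))
  )
}

qn_branching <- function() {
  wt_questionnaire(
    "br",
    items = list(
      wt_item("q1", "screener", "integer", min = 0, max = 10),
      wt_item("q2", "detail A", "integer", min = 0, max = 10),
      wt_item("q3", "detail B", "integer", min = 0, max = 10),
      wt_item("q4", "closing", "integer", min = 0, max = 10)
    ),
    branch_rules = list(
      wt_branch("q1", ">=", 5, "q3"),
      wt_branch("q3", "=", 0, "END")
    ),
    scoring = list(wt_score("total", "sum(q1, q2, q3, q4)")),
    flags = list(wt_flag("high", "total > 10"))
  )
}

# random valid definition: forward-only branches guarantee a DAG
random_definition <- function(n_items = 6) {
  items <- lapply(seq_len(n_items), function(i)
    wt_item(paste0("it", i), paste("item", i), "integer",
            min = 0, max = 9))
  branches <- list()
  for (i in seq_len(n_items - 1)) {
    if (stats::runif(1) < 0.4) {
      tgt_pool <- c(paste0("it", seq(i + 1, n_items)), "END")
      branches[[length(branches) + 1L]] <- wt_branch(
        paste0("it", i), sample(c(">", "<=", "="), 1), sample(0:9, 1),
        sample(tgt_pool, 1))
    }
  }
  wt_questionnaire("rnd", items = items, branch_rules = branches)
}

# oracle traversal: explicit edge-following on an adjacency list built
# separately from the implementation's step logic
oracle_walk <- function(def, answers) {
  ids <- vapply(def$items, `[[`, character(1), "item_id")
  nxt_of <- function(iid, ans) {
    for (br in def$branch_rules) {
      if (br$source != iid) next
      hit <- switch(br$op,
        "=" = ans == br$value, "!=" = ans != br$value,
        "<" = ans < br$value, "<=" = ans <= br$value,
        ">" = ans > br$value, ">=" = ans >= br$value,
        "in" = ans %in% br$value)
      if (isTRUE(any(hit))) return(br$target)
    }
    pos <- which(ids == iid)
    if (pos == length(ids)) "END" else ids[pos + 1]
  }
  path <- character(0)
  cur <- ids[1]
  repeat {
    if (cur == "END") return(list(path = path, done = TRUE))
    path <- c(path, cur)
    a <- answers[[cur]]
    if (is.null(a)) return(list(path = path, done = FALSE))
    cur <- nxt_of(cur, a)
  }
}

# --- alert oracle: exhaustive window scans ------------------------------

lb_per_kg <- 1 / 0.45359237

oracle_alert_rules <- function(obs, as_of, gap_days = 7,
                               change_lb = 5, change_days = 7) {
  as_of <- as.Date(as_of)
  d <- as.Date(substr(obs$timestamp, 1, 10))
  keep <- d <= as_of
  obs <- obs[keep, , drop = FALSE]; d <- d[keep]
  win <- seq(as_of - (gap_days - 1), as_of, by = "day")
  fired <- character(0)
  gap <- function(metrics) {
    hits <- vapply(win, function(day)
      any(d == day & obs$metric %in% metrics), logical(1))
    !any(hits)
  }
  if (gap("food_entry")) fired <- c(fired, "food_gap_7d")
  if (gap("weight")) fired <- c(fired, "weight_gap_7d")
  if (gap(c("steps", "heart_rate", "sleep_minutes")))
    fired <- c(fired, "tracker_gap_7d")
  w <- which(obs$metric == "weight")
  found <- FALSE
  if (length(w) >= 2) {
    for (a in w) for (b in w) {
      if (d[b] <= d[a]) next
      if (as.numeric(d[b] - d[a]) > change_days - 1) next
      if (d[b] < as_of - (gap_days - 1)) next   # later record in scan window
      if (abs(obs$value[b] - obs$value[a]) * lb_per_kg > change_lb)
        found <- TRUE
    }
  }
  if (found) fired <- c(fired, "weight_change_5lb_7d")
  sort(fired)
}

# random sparse observation stream for one participant (weight in kg)
random_stream <- function(study_id, days = 30,
                          start = as.Date("2021-05-01")) {
  pieces <- list()
  for (m in c("steps", "food_entry", "weight")) {
    present <- stats::runif(days) < stats::runif(1, 0.1, 0.9)
    dts <- start + which(present) - 1
    if (!length(dts)) next
    val <- switch(m,
      steps = stats::rpois(length(dts), 8000),
      food_entry = rep(1, length(dts)),
      weight = round(stats::runif(length(dts), 70, 100), 3))
    pieces[[length(pieces) + 1L]] <- data.frame(
      study_id = study_id, metric = m, timestamp = format(dts),
      value = val, unit = "x", source = "mock",
      retrieved_at = "2021-06-01 00:00:00", stringsAsFactors = FALSE)
  }
  if (!length(pieces)) return(new_observation_store())
  do.call(rbind, pieces)
}

# --- quota oracle: O(n^2) rolling-window scan ---------------------------

max_calls_any_hour <- function(call_log) {
  if (length(call_log) == 0) return(0L)
  max(vapply(call_log, function(t0)
    sum(call_log >= t0 & call_log < t0 + 3600), integer(1)))
}

# --- misc ---------------------------------------------------------------

rand_participant <- function(study, email, date = "2021-01-01") {
  p <- register_participant(study, list(email = email), date)
  for (ph in c("phase1_screen", "phase2_screen")) {
    advance_phase(study, p$study_id,
                  evaluate_eligibility(list(), list(), ph), date)
  }
  advance_phase(study, p$study_id,
                coordinator_decision("eligible", "phase3_screen", "c1"),
                date)
  advance_phase(study, p$study_id,
                evaluate_eligibility(list(), list(), "baseline"), date)
  cfg <- wt_alloc_config(factors = list(sex = c("f", "m")),
                         assignment_prob = 1)
  randomize_participant(study, p$study_id, list(sex = "f"), cfg, date)
  get_participant(study, p$study_id)
}

max_marginal_imbalance <- function(levels_df, arms_assigned, factors) {
  worst <- 0
  for (f in names(factors)) {
    for (lv in factors[[f]]) {
      sel <- levels_df[[f]] == lv
      tab <- table(factor(arms_assigned[sel], levels = c("A", "B")))
      worst <- max(worst, abs(tab[["A"]] - tab[["B"]]))
    }
  }
  worst
}
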