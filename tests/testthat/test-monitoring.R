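rand_p <- function(id = "P1") list(study_id = id, phase = "randomized",
                                   arm = "SM")

adherent_store <- function(id = "P1", days = 14,
                           start = as.Date("2021-05-01"),
                           weight_kg = 81) {
  dts <- format(seq(start, by = "day", length.out = days))
  rbind(
    data.frame(study_id = id, metric = "food_entry",
               timestamp = paste(dts, "12:00:00"), value = 1,
               unit = "entry", source = "m", retrieved_at = "",
               stringsAsFactors = FALSE),
    data.frame(study_id = id, metric = "steps", timestamp = dts,
               value = 8000, unit = "count", source = "m",
               retrieved_at = "", stringsAsFactors = FALSE),
    data.frame(study_id = id, metric = "weight", timestamp = dts,
               value = weight_kg, unit = "kg", source = "m",
               retrieved_at = "", stringsAsFactors = FALSE)
  )
}

test_that("fully adherent fortnight raises no alerts", {
  st <- adherent_store()
  al <- scan_alerts(st, rand_p(), as.Date("2021-05-14"))
  expect_identical(nrow(al), 0L)
})

test_that("an empty store fires all three gap alerts", {
  al <- scan_alerts(new_observation_store(), rand_p(), "2021-05-14")
  expect_setequal(al$rule, c("food_gap_7d", "weight_gap_7d",
                             "tracker_gap_7d"))
  expect_true(all(al$window_start == as.Date("2021-05-08")))
  expect_true(all(al$window_end == as.Date("2021-05-14")))
})

test_that("weight change of 5.5 lb within 6 days fires; exactly 5.0 does not", {
  base <- adherent_store(days = 14)
  base <- base[base$metric != "weight", ]
  w <- function(lbs, day_offsets, start = as.Date("2021-05-01")) {
    data.frame(study_id = "P1", metric = "weight",
               timestamp = format(start + day_offsets),
               value = lb_to_kg(lbs), unit = "kg", source = "m",
               retrieved_at = "", stringsAsFactors = FALSE)
  }
  # 180.0 lb on day 1 and 174.5 lb on day 6: change 5.5 lb in 6 days
  al <- scan_alerts(rbind(base, w(c(180, 174.5), c(0, 5))), rand_p(),
                    "2021-05-07")
  hit <- al[al$rule == "weight_change_5lb_7d", ]
  expect_identical(nrow(hit), 1L)
  expect_equal(hit$change_lb, 5.5)
  expect_identical(hit$direction, "loss")
  expect_identical(hit$window_start, as.Date("2021-05-01"))
  expect_identical(hit$window_end, as.Date("2021-05-06"))
  # exactly 5.0 lb: strict threshold, nothing fires
  al0 <- scan_alerts(rbind(base, w(c(180, 175), c(0, 5))), rand_p(),
                     "2021-05-07")
  expect_false("weight_change_5lb_7d" %in% al0$rule)
  # 5 lb + epsilon fires, gains count too
  al1 <- scan_alerts(rbind(base, w(c(180, 185.01), c(0, 5))), rand_p(),
                     "2021-05-07")
  hit1 <- al1[al1$rule == "weight_change_5lb_7d", ]
  expect_identical(hit1$direction, "gain")
  # 8 calendar days apart: outside any 7-day window
  al2 <- scan_alerts(rbind(base, w(c(180, 170), c(0, 7))), rand_p(),
                     "2021-05-08")
  expect_false("weight_change_5lb_7d" %in% al2$rule)
})

test_that("alert scanning matches the brute-force oracle on random streams", {
  set.seed(61)
  for (i in 1:200) {
    st <- random_stream("P1", days = 30)
    as_of <- as.Date("2021-05-01") + sample(6:29, 1)
    got <- sort(scan_alerts(st, rand_p(), as_of)$rule)
    expect_identical(got, oracle_alert_rules(st, as_of))
  }
})

test_that("scans never look ahead of the scan date", {
  set.seed(62)
  st <- random_stream("P1", days = 30)
  as_of <- as.Date("2021-05-12")
  prefix <- st[as.Date(substr(st$timestamp, 1, 10)) <= as_of, ]
  expect_identical(scan_alerts(st, rand_p(), as_of),
                   scan_alerts(prefix, rand_p(), as_of))
})

test_that("withdrawn and unrandomized participants are never scanned", {
  wd <- list(study_id = "P1", phase = "withdrawn", arm = "SM")
  sc <- list(study_id = "P1", phase = "phase2_screen", arm = NULL)
  expect_identical(nrow(scan_alerts(new_observation_store(), wd,
                                    "2021-05-14")), 0L)
  expect_identical(nrow(scan_alerts(new_observation_store(), sc,
                                    "2021-05-14")), 0L)
})

test_that("daily scanning re-raises after the cool-down, not before", {
  # no data at all: the food gap rule is eligible every day, but with the
  # default 7-day cool-down it fires on days 1, 8, 15 of the scan range
  dates <- seq(as.Date("2021-05-07"), by = "day", length.out = 15)
  al <- scan_alerts_daily(new_observation_store(), rand_p(), dates)
  food <- al[al$rule == "food_gap_7d", ]
  expect_identical(food$raised_at,
                   as.Date(c("2021-05-07", "2021-05-14", "2021-05-21")))
})

test_that("feedback dose: three tagged messages for the feedback arm only", {
  cfg <- wt_config()
  fb <- list(study_id = "P1", phase = "randomized", arm = "SM+feedback")
  sm <- list(study_id = "P2", phase = "randomized", arm = "SM")
  ev <- schedule_feedback(fb, list(diet = TRUE, activity = TRUE,
                                   weight = FALSE), "2021-05-10", cfg)
  expect_identical(nrow(ev), 3L)
  expect_identical(ev$slot, 1:3)
  expect_true(all(ev$category %in% c("diet", "activity")))
  expect_identical(nrow(schedule_feedback(sm, list(diet = TRUE),
                                          "2021-05-10", cfg)), 0L)
  cfg0 <- wt_config(messages_per_day = 0)
  expect_identical(nrow(schedule_feedback(fb, list(diet = TRUE),
                                          "2021-05-10", cfg0)), 0L)
  # no data present: generic templates
  gen <- schedule_feedback(fb, list(diet = FALSE), "2021-05-10", cfg)
  expect_true(all(gen$category == "generic"))
})

test_that("message statuses transition delivered -> opened only", {
  fb <- list(study_id = "P1", phase = "randomized", arm = "SM+feedback")
  log <- schedule_feedback(fb, list(diet = TRUE), "2021-05-10", wt_config())
  log <- mark_message(log, "P1", "2021-05-10", 1, "opened")
  expect_identical(log$status[1], "opened")
  expect_error(mark_message(log, "P1", "2021-05-10", 1, "missed"),
               "transition")
  log <- mark_message(log, "P1", "2021-05-10", 2, "missed")
  expect_error(mark_message(log, "P1", "2021-05-10", 2, "opened"),
               "transition")
})

test_that("usage summary partitions scheduled messages and matches tallies", {
  cfg <- wt_config()
  set.seed(63)
  days <- seq(as.Date("2021-05-10"), by = "day", length.out = 7)
  logs <- list(); opens <- list()
  for (u in 1:10) {
    p <- list(study_id = sprintf("P%02d", u), phase = "randomized",
              arm = "SM+feedback")
    for (d in as.list(days)) {
      ev <- schedule_feedback(p, list(diet = TRUE), d, cfg)
      miss <- runif(3) < 0.2
      ev$status[miss] <- "missed"
      ev$status[!miss & runif(3) < 0.5] <- "opened"
      logs[[length(logs) + 1]] <- ev
      opens[[length(opens) + 1]] <- data.frame(
        study_id = p$study_id, timestamp = paste(format(d), "09:00:00"),
        stringsAsFactors = FALSE)
    }
  }
  ml <- do.call(rbind, logs)
  ao <- do.call(rbind, opens)
  us <- usage_summary(ml, ao, c(days[1], days[7]))
  expect_equal(us$totals$scheduled, 10 * 3 * 7)
  expect_equal(us$totals$delivered + us$totals$opened +
                 us$totals$missed, us$totals$scheduled)
  # direct tally oracle
  expect_equal(us$totals$missed, sum(ml$status == "missed"))
  expect_equal(us$totals$opened, sum(ml$status == "opened"))
  expect_true(all(us$daily$active_users == 10))
  # empty logs -> zeros
  z <- usage_summary(ml[0, ], ao[0, ], c(days[1], days[7]))
  expect_equal(z$totals$scheduled, 0)
  # one user opening everything
  ml1 <- ml[ml$study_id == "P01", ]
  ml1$status <- "opened"
  u1 <- usage_summary(ml1, ao[ao$study_id == "P01", ],
                      c(days[1], days[7]))
  expect_equal(u1$totals$opened, u1$totals$scheduled)
})
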