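test_that("cohort generation is empty at n=0 and reproducible by seed", {
  expect_identical(nrow(generate_cohort(cohort_params(n = 0))$profiles), 0L)
  c1 <- generate_cohort(cohort_params(n = 50, seed = 5))
  c2 <- generate_cohort(cohort_params(n = 50, seed = 5))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_params(n = 50, seed = 6))
  expect_false(identical(c1$profiles, c3$profiles))
  expect_error(cohort_params(smartphone_rate = 1.2), "probabilities")
})

test_that("uniform-BMI cohorts hit the eligibility window at its measure", {
  coh <- generate_cohort(cohort_params(n = 10000, bmi_dist = "uniform",
                                       bmi_range = c(20, 50), seed = 9))
  frac <- mean(coh$profiles$bmi >= 27 & coh$profiles$bmi <= 43)
  # uniform measure of [27,43] in [20,50] is 16/30; allow 3 SE
  p <- 16 / 30
  se <- sqrt(p * (1 - p) / 10000)
  expect_lt(abs(frac - p), 3 * se)
})

test_that("generated answers pass their questionnaire definitions", {
  coh <- generate_cohort(cohort_params(n = 40, seed = 10))
  q1 <- phase1_questionnaire(); q2 <- phase2_questionnaire()
  for (i in 1:40) {
    expect_identical(validate_response(q1, coh$answers$phase1[[i]]),
                     character(0))
    expect_identical(validate_response(q2, coh$answers$phase2[[i]]),
                     character(0))
  }
})

test_that("full adherence produces every metric on every day", {
  sp <- stream_params(days = 14, tracker_off_mean = 0, food_off_mean = 0,
                      weight_off_mean = 0, seed = 11)
  st <- generate_streams("P1", sp)
  d <- as.Date(substr(st$timestamp, 1, 10))
  days <- seq(sp$start_date, by = "day", length.out = 14)
  for (m in c("steps", "heart_rate", "sleep_minutes", "weight")) {
    expect_identical(sort(unique(d[st$metric == m])), days)
  }
  expect_identical(sort(unique(d[st$metric == "food_entry"])), days)
  expect_true(all(st$value[st$metric == "weight"] > 0))
})

test_that("zero food adherence triggers the food-gap alert by day 7", {
  sp <- stream_params(days = 14, tracker_off_mean = 0, food_on_mean = 0,
                      weight_off_mean = 0, seed = 12)
  st <- generate_streams("P1", sp)
  expect_false("food_entry" %in% st$metric)
  st$retrieved_at <- "2020-04-01 00:00:00"
  p <- list(study_id = "P1", phase = "randomized", arm = "SM")
  al <- scan_alerts(st[, c("study_id", "metric", "timestamp", "value",
                           "unit", "source", "retrieved_at")],
                    p, sp$start_date + 6)
  expect_true("food_gap_7d" %in% al$rule)
  expect_false("tracker_gap_7d" %in% al$rule)
})

test_that("a steep noiseless weight trend fires the rapid-change rule", {
  # -6 lb/week over adjacent-week records: 6 days apart differ by 5.14 lb
  sp <- stream_params(days = 21, weight_trend_lb_wk = -6,
                      weight_noise_lb = 0, weight_off_mean = 0,
                      tracker_off_mean = 0, food_off_mean = 0, seed = 13)
  st <- generate_streams("P1", sp)
  st$retrieved_at <- "2020-04-01 00:00:00"
  p <- list(study_id = "P1", phase = "randomized", arm = "SM")
  al <- scan_alerts(st[, c("study_id", "metric", "timestamp", "value",
                           "unit", "source", "retrieved_at")],
                    p, sp$start_date + 20)
  hit <- al[al$rule == "weight_change_5lb_7d", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$direction, "loss")
  expect_gt(hit$change_lb, 5)
})

test_that("missing runs have geometric lengths near their configured mean", {
  set.seed(14)
  sp <- stream_params(days = 6000, tracker_on_mean = 12,
                      tracker_off_mean = 3)
  st <- generate_streams("P1", sp)
  d <- sort(unique(as.Date(st$timestamp[st$metric == "steps"])))
  present <- seq(sp$start_date, by = "day", length.out = 6000) %in% d
  runs <- rle(present)
  off_mean <- mean(runs$lengths[!runs$values])
  on_mean <- mean(runs$lengths[runs$values])
  expect_gt(off_mean, 2); expect_lt(off_mean, 4.2)
  expect_gt(on_mean, 9); expect_lt(on_mean, 15.5)
})

test_that("the mock server refuses the 101st call within an hour", {
  sp <- stream_params(days = 7, seed = 15)
  st <- generate_streams("P1", sp)
  srv <- mock_device_server(st, limit_per_hour = 100)
  now <- as.POSIXct("2020-03-10 08:00:00", tz = "UTC")
  res <- NULL
  for (k in 1:100) {
    res <- server_fetch(srv, "P1::wearable_vendor", "activity",
                        "2020-03-05", now + k)
    expect_identical(res$status, "ok")
  }
  refused <- server_fetch(srv, "P1::wearable_vendor", "activity",
                          "2020-03-05", now + 101)
  expect_identical(refused$status, "quota_exceeded")
  expect_s3_class(refused$retry_at, "POSIXct")
  # a different account is unaffected
  ok <- server_fetch(srv, "P1::scale_vendor", "weight", "2020-03-05",
                     now + 102)
  expect_identical(ok$status, "ok")
  expect_error(server_fetch(srv, "ghost::mock", "activity", "2020-03-05",
                            now),
               class = "weartrial_unknown_account")
})

test_that("records surface only after their upload delay has elapsed", {
  st <- data.frame(study_id = "P1", metric = "weight",
                   timestamp = "2020-03-05", value = 80, unit = "kg",
                   source = "scale_vendor",
                   available_at = "2020-03-08 00:00:00",
                   stringsAsFactors = FALSE)
  srv <- mock_device_server(st)
  early <- server_fetch(srv, "P1::scale_vendor", "weight", "2020-03-05",
                        "2020-03-06 12:00:00")
  expect_identical(nrow(early$records), 0L)
  late <- server_fetch(srv, "P1::scale_vendor", "weight", "2020-03-05",
                       "2020-03-08 12:00:00")
  expect_identical(nrow(late$records), 1L)
  expect_identical(late$records$value, 80)
})

test_that("the scheduler recovers every available record under budget", {
  sp <- stream_params(days = 7, delay_prob = 0, seed = 16)
  st <- generate_streams("P9", sp)
  srv <- mock_device_server(st)
  accounts <- c("P9::wearable_vendor", "P9::scale_vendor")
  # sync well after the horizon: every record's availability has elapsed
  now <- as_time_utc <- as.POSIXct(paste(sp$start_date + 7, "09:00:00"),
                                   tz = "UTC")
  pl <- plan_sync(accounts, c("activity", "food", "sleep", "weight"), now)
  expect_true(all(pl$plan$status == "granted"))
  run <- run_sync(pl$plan, srv, new_observation_store(), now)
  expect_identical(run$rejected, 0L)
  # no silent loss: everything the generator produced inside the pull
  # window is in the store
  win <- pull_window(now, 7)$dates
  exp_rows <- st[as.Date(substr(st$timestamp, 1, 10)) %in% win, ]
  expect_identical(nrow(run$store), nrow(exp_rows))
  expect_setequal(paste(run$store$metric, run$store$timestamp),
                  paste(exp_rows$metric, exp_rows$timestamp))
})
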