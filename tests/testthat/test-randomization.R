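two_factor_config <- function(p = 0.8) {
  wt_alloc_config(factors = list(f1 = c("a", "b"), f2 = c("x", "y")),
                  assignment_prob = p)
}

test_that("empty state: every candidate arm scores one per factor (range)", {
  cfg <- two_factor_config()
  st <- new_allocation_state(c("A", "B"), cfg)
  lv <- list(f1 = "a", f2 = "x")
  # adding the first participant puts one arm at 1, the other at 0, for
  # each factor: spread 1 per factor, 2 factors
  expect_identical(imbalance(st, cfg, lv, "A"), 2)
  expect_identical(imbalance(st, cfg, lv, "B"), 2)
})

test_that("imbalance matches hand-enumerated hypothetical tables", {
  cfg <- wt_alloc_config(factors = list(f1 = c("L", "M")))
  st <- new_allocation_state(c("A", "B"), cfg)
  st$counts$f1["L", "A"] <- 3L
  st$counts$f1["L", "B"] <- 1L
  lv <- list(f1 = "L")
  # add to A: (4,1) spread 3; add to B: (3,2) spread 1
  expect_identical(imbalance(st, cfg, lv, "A"), 3)
  expect_identical(imbalance(st, cfg, lv, "B"), 1)
  vcfg <- wt_alloc_config(factors = list(f1 = c("L", "M")),
                          imbalance_method = "variance")
  # population variance of (4,1) = 2.25; of (3,2) = 0.25
  expect_identical(imbalance(st, vcfg, lv, "A"), 2.25)
  expect_identical(imbalance(st, vcfg, lv, "B"), 0.25)
  expect_error(imbalance(st, cfg, list(f1 = "Z"), "A"), "unknown level")
})

test_that("imbalance agrees with brute-force recomputation from history", {
  set.seed(41)
  cfg <- two_factor_config()
  arms <- c("A", "B")
  for (rep in 1:20) {
    hist_n <- sample(5:40, 1)
    lv_hist <- data.frame(
      f1 = sample(c("a", "b"), hist_n, replace = TRUE),
      f2 = sample(c("x", "y"), hist_n, replace = TRUE),
      arm = sample(arms, hist_n, replace = TRUE),
      stringsAsFactors = FALSE)
    st <- new_allocation_state(arms, cfg)
    for (i in seq_len(hist_n)) {
      for (f in c("f1", "f2")) {
        st$counts[[f]][lv_hist[[f]][i], lv_hist$arm[i]] <-
          st$counts[[f]][lv_hist[[f]][i], lv_hist$arm[i]] + 1L
      }
    }
    lv <- list(f1 = sample(c("a", "b"), 1), f2 = sample(c("x", "y"), 1))
    cand <- sample(arms, 1)
    # oracle: rebuild hypothetical tables from scratch and sum spreads
    expected <- 0
    for (f in c("f1", "f2")) {
      tab <- vapply(arms, function(ar)
        sum(lv_hist[[f]] == lv[[f]] & lv_hist$arm == ar) +
          as.integer(ar == cand), integer(1))
      expected <- expected + (max(tab) - min(tab))
    }
    expect_identical(imbalance(st, cfg, lv, cand), expected)
  }
})

test_that("first participant is a fair draw; totals always sum to n", {
  cfg <- two_factor_config()
  set.seed(42)
  firsts <- replicate(400, {
    st <- new_allocation_state(c("A", "B"), cfg)
    allocate(st, cfg, list(f1 = "a", f2 = "x"))$arm
  })
  # all scores tie, so the overall draw is uniform
  expect_gt(mean(firsts == "A"), 0.4)
  expect_lt(mean(firsts == "A"), 0.6)
  lv_df <- data.frame(f1 = sample(c("a", "b"), 100, replace = TRUE),
                      f2 = sample(c("x", "y"), 100, replace = TRUE))
  res <- allocate_sequence(c("A", "B"), cfg, lv_df, seed = 99)
  expect_identical(sum(res$state$total_per_arm), 100L)
})

test_that("deterministic minimization always takes a strict minimizer", {
  cfg <- wt_alloc_config(factors = list(f1 = c("L", "M")),
                         assignment_prob = 1)
  st <- new_allocation_state(c("A", "B"), cfg)
  st$counts$f1["L", "A"] <- 3L
  st$counts$f1["L", "B"] <- 1L
  st$total_per_arm <- c(A = 3L, B = 1L)
  set.seed(43)
  for (i in 1:10) {
    expect_identical(allocate(st, cfg, list(f1 = "L"))$arm, "B")
  }
})

test_that("single-factor deterministic minimization balances every level", {
  cfg <- wt_alloc_config(factors = list(site = c("s1", "s2", "s3")),
                         assignment_prob = 1)
  set.seed(44)
  for (rep in 1:10) {
    lv_df <- data.frame(site = sample(c("s1", "s2", "s3"), 200,
                                      replace = TRUE))
    res <- allocate_sequence(c("A", "B"), cfg, lv_df, seed = rep)
    for (s in c("s1", "s2", "s3")) {
      nA <- sum(lv_df$site == s & res$arms == "A")
      nB <- sum(lv_df$site == s & res$arms == "B")
      expect_lte(abs(nA - nB), 1)
    }
  }
})

test_that("the same seed and participant order reproduce the arm sequence", {
  cfg <- two_factor_config()
  set.seed(45)
  lv_df <- data.frame(f1 = sample(c("a", "b"), 150, replace = TRUE),
                      f2 = sample(c("x", "y"), 150, replace = TRUE))
  r1 <- allocate_sequence(c("A", "B"), cfg, lv_df, seed = 7)
  r2 <- allocate_sequence(c("A", "B"), cfg, lv_df, seed = 7)
  expect_identical(r1$arms, r2$arms)
  expect_identical(r1$log, r2$log)
  r3 <- allocate_sequence(c("A", "B"), cfg, lv_df, seed = 8)
  expect_false(identical(r1$arms, r3$arms))
})

test_that("minimization beats simple randomization on marginal balance", {
  cfg <- two_factor_config(p = 0.8)
  factors <- list(f1 = c("a", "b"), f2 = c("x", "y"))
  set.seed(46)
  n_rep <- 60
  d_min <- d_simple <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    lv_df <- data.frame(f1 = sample(c("a", "b"), 300, replace = TRUE),
                        f2 = sample(c("x", "y"), 300, replace = TRUE))
    res <- allocate_sequence(c("A", "B"), cfg, lv_df)
    d_min[r] <- max_marginal_imbalance(lv_df, res$arms, factors)
    simple <- sample(c("A", "B"), 300, replace = TRUE)
    d_simple[r] <- max_marginal_imbalance(lv_df, simple, factors)
  }
  expect_lt(mean(d_min), mean(d_simple))
  p <- stats::wilcox.test(d_min, d_simple, paired = TRUE,
                          alternative = "less", exact = FALSE)$p.value
  expect_lt(p, 0.001)
})

test_that("study-level randomization records arm, levels and audit log", {
  s <- wt_study()
  set.seed(47)
  cfg <- wt_alloc_config(factors = list(sex = c("f", "m")))
  p <- register_participant(s, list(email = "rz@x.org"), "2021-01-01")
  for (ph in c("phase1_screen", "phase2_screen")) {
    advance_phase(s, p$study_id, evaluate_eligibility(list(), list(), ph),
                  "2021-01-02")
  }
  # not yet at baseline: allocation is refused
  expect_error(randomize_participant(s, p$study_id, list(sex = "f"), cfg),
               "baseline")
  advance_phase(s, p$study_id,
                coordinator_decision("eligible", "phase3_screen", "c1"),
                "2021-01-03")
  advance_phase(s, p$study_id,
                evaluate_eligibility(list(), list(), "baseline"),
                "2021-01-04")
  out <- randomize_participant(s, p$study_id, list(sex = "f"), cfg,
                               "2021-01-05")
  expect_true(out$arm %in% s$config$arms)
  expect_identical(out$phase, "randomized")
  expect_error(randomize_participant(s, p$study_id, list(sex = "f"), cfg),
               "baseline")
  log <- allocation_log(s)
  expect_identical(nrow(log), 1L)
  expect_identical(log$chosen, out$arm)
})
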