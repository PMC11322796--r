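# Covariate-adaptive allocation by minimization (Pocock-Simon): each new
# participant goes, with a biased-coin probability, to the arm that
# minimizes the weighted marginal imbalance across prognostic factors.

#' Allocation configuration
#'
#' @param factors named list: factor name -> character vector of levels.
#' @param weights named positive weights per factor (default all 1).
#' @param imbalance_method `"range"` (max - min of the hypothetical arm
#'   counts) or `"variance"` (population variance).
#' @param assignment_prob probability of choosing the minimizing arm; must
#'   exceed 0.5. `1` gives deterministic minimization.
#' @return a `wt_alloc_config` list.
#' @export
wt_alloc_config <- function(factors,
                            weights = NULL,
                            imbalance_method = c("range", "variance"),
                            assignment_prob = 0.8) {
  imbalance_method <- match.arg(imbalance_method)
  assert_that(length(factors) >= 1 && !is.null(names(factors)),
              "factors must be a named list of level sets")
  if (is.null(weights))
    weights <- stats::setNames(rep(1, length(factors)), names(factors))
  assert_that(all(weights > 0), "weights must be positive")
  assert_that(all(names(factors) %in% names(weights)),
              "every factor needs a weight")
  assert_that(assignment_prob > 0.5 && assignment_prob <= 1,
              "assignment_prob must be in (0.5, 1]")
  structure(list(factors = factors, weights = weights,
                 imbalance_method = imbalance_method,
                 assignment_prob = assignment_prob),
            class = "wt_alloc_config")
}

#' Empty allocation state
#'
#' Running per-(factor, level, arm) counts plus per-arm totals; counts are
#' only ever incremented.
#'
#' @param arms arm labels.
#' @param config a [wt_alloc_config()].
#' @return a `wt_alloc_state` list.
#' @export
new_allocation_state <- function(arms, config) {
  counts <- lapply(config$factors, function(levels) {
    matrix(0L, nrow = length(levels), ncol = length(arms),
           dimnames = list(levels, arms))
  })
  structure(list(arms = arms, counts = counts,
                 total_per_arm = stats::setNames(rep(0L, length(arms)), arms)),
            class = "wt_alloc_state")
}

check_levels <- function(config, participant_levels) {
  for (f in names(config$factors)) {
    lv <- participant_levels[[f]]
    assert_that(!is.null(lv), paste("missing level for factor", f))
    assert_that(lv %in% config$factors[[f]],
                paste0("unknown level '", lv, "' for factor ", f))
  }
  invisible(TRUE)
}

#' Marginal imbalance score of a candidate arm
#'
#' Hypothetically adds the participant to `candidate_arm` and returns the
#' weighted sum, over factors, of the spread across arms of the counts at
#' the participant's level of that factor. Smaller is better balanced.
#'
#' @param state a `wt_alloc_state`.
#' @param config a [wt_alloc_config()].
#' @param participant_levels named list: factor -> level.
#' @param candidate_arm arm under consideration.
#' @return nonnegative imbalance score.
#' @export
imbalance <- function(state, config, participant_levels, candidate_arm) {
  check_levels(config, participant_levels)
  assert_that(candidate_arm %in% state$arms,
              paste("unknown arm:", candidate_arm))
  total <- 0
  for (f in names(config$factors)) {
    row <- state$counts[[f]][participant_levels[[f]], ]
    row[candidate_arm] <- row[candidate_arm] + 1L
    spread <- switch(config$imbalance_method,
      range = max(row) - min(row),
      variance = stats::var(row) * (length(row) - 1) / length(row)
    )
    total <- total + config$weights[[f]] * spread
  }
  total
}

#' Allocate one participant by minimization
#'
#' With probability `assignment_prob` the arm with the smallest imbalance
#' score is chosen (fair draw among ties); otherwise a uniform draw among
#' the remaining arms. Consumes draws from R's RNG stream, so a fixed seed
#' and allocation order reproduce the identical arm sequence.
#'
#' @param state a `wt_alloc_state`.
#' @param config a [wt_alloc_config()].
#' @param participant_levels named list: factor -> level.
#' @return list: `arm`, updated `state`, per-arm `scores`, and the
#'   biased-coin `draw` used.
#' @export
allocate <- function(state, config, participant_levels) {
  check_levels(config, participant_levels)
  scores <- vapply(state$arms, function(a)
    imbalance(state, config, participant_levels, a), numeric(1))
  best <- state$arms[scores <= min(scores) + 1e-12]
  pick <- best[sample.int(length(best), 1L)]      # fair tie-break
  draw <- stats::runif(1)
  arm <- pick
  if (draw > config$assignment_prob && length(state$arms) > 1L) {
    rest <- setdiff(state$arms, pick)
    arm <- rest[sample.int(length(rest), 1L)]
  }
  for (f in names(config$factors)) {
    lv <- participant_levels[[f]]
    state$counts[[f]][lv, arm] <- state$counts[[f]][lv, arm] + 1L
  }
  state$total_per_arm[arm] <- state$total_per_arm[arm] + 1L
  list(arm = arm, state = state, scores = scores, draw = draw)
}

#' Allocate an ordered stream of participants
#'
#' Convenience wrapper for simulations: optionally seeds the RNG, then
#' allocates each row of `levels_df` in order.
#'
#' @param arms arm labels.
#' @param config a [wt_alloc_config()].
#' @param levels_df data.frame with one column per factor, one row per
#'   participant, in allocation order.
#' @param seed optional integer seed.
#' @return list: `arms` (character vector of assignments), final `state`,
#'   and the allocation `log` data.frame.
#' @export
allocate_sequence <- function(arms, config, levels_df, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  state <- new_allocation_state(arms, config)
  n <- nrow(levels_df)
  out <- character(n)
  logs <- vector("list", n)
  fac <- names(config$factors)
  cols <- lapply(fac, function(f) as.character(levels_df[[f]]))
  names(cols) <- fac
  for (i in seq_len(n)) {
    lv <- lapply(cols, `[`, i)
    res <- allocate(state, config, lv)
    state <- res$state
    out[i] <- res$arm
    logs[[i]] <- data.frame(
      order = i,
      as.data.frame(lv, stringsAsFactors = FALSE),
      t(res$scores), chosen = res$arm, draw = res$draw,
      stringsAsFactors = FALSE, check.names = FALSE
    )
  }
  list(arms = out, state = state, log = do.call(rbind, logs))
}

#' Randomize a participant within a study
#'
#' Allocates via [allocate()] against the study's running allocation
#' state, sets the arm and factor levels on the participant, moves the
#' phase to `randomized`, and appends a `randomized` event. The
#' participant must be in the `baseline` phase.
#'
#' @param study a [wt_study()].
#' @param study_id participant identifier.
#' @param participant_levels named list: factor -> level.
#' @param config a [wt_alloc_config()]; fixed after the first allocation.
#' @param time event timestamp.
#' @return the updated participant record.
#' @export
randomize_participant <- function(study, study_id, participant_levels,
                                  config, time = Sys.time()) {
  p <- get_participant(study, study_id)
  assert_that(identical(p$phase, "baseline"),
              paste(study_id, "must be at baseline to randomize"))
  assert_that(is.null(p$arm), paste(study_id, "already allocated"))
  if (is.null(study$alloc_state))
    study$alloc_state <- new_allocation_state(study$config$arms, config)
  res <- allocate(study$alloc_state, config, participant_levels)
  study$alloc_state <- res$state
  p$arm <- res$arm
  p$factor_levels <- participant_levels
  p$phase <- "randomized"
  study$registry[[study_id]] <- p
  study$alloc_log[[length(study$alloc_log) + 1L]] <- list(
    study_id = study_id, levels = participant_levels,
    scores = res$scores, arm = res$arm, draw = res$draw
  )
  append_event(study, study_id, "randomized", time,
               payload = list(arm = res$arm,
                              factor_levels = participant_levels))
  p
}

#' Allocation audit log
#'
#' @param study a [wt_study()].
#' @return data.frame: order, study_id, factor levels, per-arm scores,
#'   chosen arm, and the biased-coin draw.
#' @export
allocation_log <- function(study) {
  logs <- study$alloc_log %||% list()
  rows <- lapply(seq_along(logs), function(i) {
    l <- logs[[i]]
    data.frame(order = i, study_id = l$study_id,
               as.data.frame(l$levels, stringsAsFactors = FALSE),
               t(l$scores), chosen = l$arm, draw = l$draw,
               stringsAsFactors = FALSE, check.names = FALSE)
  })
  if (!length(rows)) return(data.frame())
  do.call(rbind, rows)
}
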