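# Questionnaire definitions: items, single-item branch rules, arithmetic
# scoring, and flag predicates. Branching forms a DAG over items; traversal
# is deterministic, so next_item() is a pure function of (definition,
# partial answers).

.answer_types <- c("integer", "decimal", "choice", "multi_choice",
                   "text", "date")
.branch_ops <- c("=", "!=", "<", "<=", ">", ">=", "in")

#' Questionnaire item
#'
#' @param item_id unique identifier within the questionnaire.
#' @param prompt question text shown to the respondent.
#' @param answer_type one of `integer`, `decimal`, `choice`, `multi_choice`,
#'   `text`, `date`.
#' @param required must be answered before advancing past it.
#' @param choices options for (multi_)choice items (at least one).
#' @param min,max inclusive numeric bounds for integer/decimal items.
#' @param pattern regular expression a text answer must match.
#' @return a `wt_item` list.
#' @export
wt_item <- function(item_id, prompt, answer_type = "text", required = TRUE,
                    choices = NULL, min = NULL, max = NULL, pattern = NULL) {
  answer_type <- match.arg(answer_type, .answer_types)
  if (answer_type %in% c("choice", "multi_choice")) {
    assert_that(length(choices) >= 1, paste(item_id, "needs >= 1 choice"))
    choices <- as.character(choices)
  } else {
    choices <- NULL
  }
  structure(list(
    item_id = as.character(item_id), prompt = as.character(prompt),
    answer_type = answer_type, required = isTRUE(required),
    choices = choices,
    min = if (is.null(min)) NULL else as.numeric(min),
    max = if (is.null(max)) NULL else as.numeric(max),
    pattern = if (is.null(pattern)) NULL else as.character(pattern)
  ), class = "wt_item")
}

#' Branch rule
#'
#' When the answer to `source` satisfies `op value`, traversal jumps to
#' `target` (an item id, or `"END"` to finish). Predicates are restricted
#' to a single item; the first matching rule in declaration order wins.
#'
#' @param source item id whose answer is tested.
#' @param op one of `=`, `!=`, `<`, `<=`, `>`, `>=`, `in`.
#' @param value comparison value (vector allowed for `in`).
#' @param target item id to jump to, or `"END"`.
#' @return a `wt_branch` list.
#' @export
wt_branch <- function(source, op, value, target) {
  op <- match.arg(op, .branch_ops)
  structure(list(source = as.character(source), op = op,
                 value = if (is.numeric(value)) as.numeric(value)
                         else as.character(value),
                 target = as.character(target)),
            class = "wt_branch")
}

#' Score rule
#'
#' `formula` is a restricted arithmetic expression over item ids and
#' previously defined score names: the operators `+ - * /`, parentheses,
#' numeric literals, and the aggregate calls `sum(...)` and `count(...)`
#' over listed items. No other function or operator is permitted, so
#' definitions loaded from JSON cannot execute arbitrary code. Items that
#' were not presented (skipped by branching) contribute `NA` to direct
#' arithmetic and are dropped by `sum`/`count`.
#'
#' @param name score name.
#' @param formula expression text, e.g. `"sum(q1, q2, q3) / count(q1, q2, q3)"`.
#' @return a `wt_score` list.
#' @export
wt_score <- function(name, formula) {
  structure(list(name = as.character(name), formula = as.character(formula)),
            class = "wt_score")
}

#' Flag rule
#'
#' A predicate over answers and computed scores; when true, the label is
#' raised. Predicates allow comparisons (`== != < <= > >=`), `%in%`,
#' logical `& | !`, parentheses, `c(...)`, literals, item ids and score
#' names. Flags are evaluated after all scores.
#'
#' @param label flag label to raise.
#' @param predicate predicate text, e.g. `"phq_total > 10"`.
#' @return a `wt_flag` list.
#' @export
wt_flag <- function(label, predicate) {
  structure(list(label = as.character(label),
                 predicate = as.character(predicate)),
            class = "wt_flag")
}

#' Questionnaire definition
#'
#' @param qid questionnaire identifier.
#' @param phase study phase the questionnaire serves.
#' @param items ordered list of [wt_item()]s (document order).
#' @param branch_rules list of [wt_branch()]es.
#' @param scoring list of [wt_score()]s, evaluated in order.
#' @param flags list of [wt_flag()]s, evaluated after scores.
#' @return a `wt_questionnaire` list.
#' @export
wt_questionnaire <- function(qid, phase = "phase1_screen", items = list(),
                             branch_rules = list(), scoring = list(),
                             flags = list()) {
  structure(list(qid = as.character(qid), phase = as.character(phase),
                 items = items, branch_rules = branch_rules,
                 scoring = scoring, flags = flags),
            class = "wt_questionnaire")
}

item_ids <- function(def) vapply(def$items, `[[`, character(1), "item_id")

# ---- restricted expression handling ------------------------------------

.score_calls <- c("+", "-", "*", "/", "(", "sum", "count")
.flag_calls <- c(.score_calls, ">", "<", ">=", "<=", "==", "!=",
                 "%in%", "&", "|", "!", "c")

expr_symbols <- function(e) {
  if (is.symbol(e)) return(as.character(e))
  if (is.call(e)) return(unique(unlist(lapply(as.list(e)[-1], expr_symbols))))
  character(0)
}

check_expr <- function(e, allowed_calls) {
  if (is.symbol(e) || is.numeric(e) || is.character(e) || is.logical(e)) {
    return(character(0))
  }
  if (is.call(e)) {
    fn <- as.character(e[[1]])
    bad <- if (!fn %in% allowed_calls) paste("disallowed call:", fn)
           else character(0)
    return(c(bad, unlist(lapply(as.list(e)[-1], check_expr, allowed_calls))))
  }
  paste("disallowed expression element:", class(e)[1])
}

parse_expr <- function(txt) {
  p <- tryCatch(parse(text = txt, keep.source = FALSE),
                error = function(e) NULL)
  if (is.null(p) || length(p) != 1L) return(NULL)
  p[[1]]
}

# evaluation mask: items/scores as values; sum/count drop NA
expr_env <- function(values) {
  env <- new.env(parent = baseenv())
  for (nm in names(values)) assign(nm, values[[nm]], envir = env)
  env$sum <- function(...) base::sum(..., na.rm = TRUE)
  env$count <- function(...) base::sum(!is.na(c(...)))
  env
}

eval_restricted <- function(txt, values, allowed_calls, what) {
  e <- parse_expr(txt)
  if (is.null(e)) wt_stop(paste("cannot parse", what, ":", txt),
                          "weartrial_expr")
  probs <- check_expr(e, allowed_calls)
  if (length(probs)) wt_stop(paste0(what, " '", txt, "': ",
                                    paste(probs, collapse = "; ")),
                             "weartrial_expr")
  eval(e, envir = expr_env(values))
}

# ---- definition validation ---------------------------------------------

#' Validate a questionnaire definition
#'
#' Structural checks: at least one item, unique item ids, existing branch
#' sources/targets, acyclic traversal graph, and score/flag expressions
#' that parse, use only permitted operators, and reference only existing
#' items (and, for flags, score names).
#'
#' @param def a [wt_questionnaire()].
#' @return character vector of error messages; empty means valid.
#' @export
validate_definition <- function(def) {
  errs <- character(0)
  ids <- item_ids(def)
  if (length(ids) == 0L) return("no items")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) errs <- c(errs, paste("duplicate item ids:",
                                         paste(dup, collapse = ", ")))
  for (it in def$items) {
    if (it$answer_type %in% c("choice", "multi_choice") &&
        length(it$choices) < 1L)
      errs <- c(errs, paste(it$item_id, "has no choices"))
  }
  for (br in def$branch_rules) {
    if (!br$source %in% ids)
      errs <- c(errs, paste("branch source not an item:", br$source))
    if (!identical(br$target, "END") && !br$target %in% ids)
      errs <- c(errs, paste("branch target not an item:", br$target))
  }
  # cycle check over the traversal graph: document-order fallthrough plus
  # branch edges; a cycle means some answer path could revisit an item
  if (!length(errs)) {
    n <- length(ids)
    adj <- vector("list", n)
    for (i in seq_len(n)) {
      tgts <- if (i < n) ids[i + 1L] else character(0)
      for (br in def$branch_rules) {
        if (br$source == ids[i] && !identical(br$target, "END"))
          tgts <- c(tgts, br$target)
      }
      adj[[i]] <- match(unique(tgts), ids)
    }
    state <- integer(n)  # 0 unvisited, 1 in stack, 2 done
    cyclic <- FALSE
    visit <- function(i) {
      if (state[i] == 1L) { cyclic <<- TRUE; return() }
      if (state[i] == 2L) return()
      state[i] <<- 1L
      for (j in adj[[i]]) visit(j)
      state[i] <<- 2L
    }
    visit(1L)
    if (cyclic) errs <- c(errs, "branch rules create a cycle")
  }
  known <- ids
  for (sc in def$scoring) {
    e <- parse_expr(sc$formula)
    if (is.null(e)) {
      errs <- c(errs, paste("score", sc$name, "does not parse"))
      next
    }
    errs <- c(errs, check_expr(e, .score_calls))
    unknown <- setdiff(expr_symbols(e), known)
    if (length(unknown))
      errs <- c(errs, paste("score", sc$name, "references unknown:",
                            paste(unknown, collapse = ", ")))
    known <- c(known, sc$name)
  }
  for (fl in def$flags) {
    e <- parse_expr(fl$predicate)
    if (is.null(e)) {
      errs <- c(errs, paste("flag", fl$label, "does not parse"))
      next
    }
    errs <- c(errs, check_expr(e, .flag_calls))
    unknown <- setdiff(setdiff(expr_symbols(e), known), c("TRUE", "FALSE", "T", "F"))
    if (length(unknown))
      errs <- c(errs, paste("flag", fl$label, "references unknown:",
                            paste(unknown, collapse = ", ")))
  }
  unique(errs)
}

# ---- traversal ----------------------------------------------------------

branch_matches <- function(br, answer) {
  if (is.null(answer)) return(FALSE)
  res <- switch(br$op,
    "=" = answer == br$value,
    "!=" = answer != br$value,
    "<" = answer < br$value,
    "<=" = answer <= br$value,
    ">" = answer > br$value,
    ">=" = answer >= br$value,
    "in" = answer %in% br$value
  )
  isTRUE(any(res))
}

step_from <- function(def, item_id, answer) {
  ids <- item_ids(def)
  for (br in def$branch_rules) {
    if (br$source == item_id && branch_matches(br, answer)) return(br$target)
  }
  i <- match(item_id, ids)
  if (i < length(ids)) ids[i + 1L] else "END"
}

walk_path <- function(def, answers) {
  ids <- item_ids(def)
  path <- character(0)
  cur <- if (length(ids)) ids[1L] else "END"
  while (!identical(cur, "END")) {
    path <- c(path, cur)
    ans <- answers[[cur]]
    if (is.null(ans)) break  # unanswered: path known only up to here
    cur <- step_from(def, cur, ans)
  }
  list(path = path, at_end = identical(cur, "END"))
}

#' Next item to present
#'
#' Walks the questionnaire from the top following document order, except
#' where a matched branch rule redirects; the first unanswered item on the
#' path is returned. Items off the path are "not presented" (distinct from
#' missing). Deterministic and free of side effects.
#'
#' @param def a [wt_questionnaire()].
#' @param answers named list of partial answers (`item_id` -> value).
#' @return the next [wt_item()], or the string `"END"` when traversal is
#'   complete.
#' @export
next_item <- function(def, answers = list()) {
  w <- walk_path(def, answers)
  if (w$at_end) return("END")
  last <- w$path[length(w$path)]
  def$items[[match(last, item_ids(def))]]
}

#' Items presented under a set of answers
#'
#' @param def a [wt_questionnaire()].
#' @param answers named list of answers.
#' @return character vector of presented item ids, in presentation order.
#' @export
presented_items <- function(def, answers) walk_path(def, answers)$path

# ---- response validation ------------------------------------------------

check_answer <- function(it, ans) {
  tname <- it$answer_type
  ok_num <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)
  switch(tname,
    integer = {
      if (!ok_num(ans) || ans != trunc(ans))
        return(paste(it$item_id, ": expected integer"))
    },
    decimal = {
      if (!ok_num(ans)) return(paste(it$item_id, ": expected decimal"))
    },
    choice = {
      if (length(ans) != 1L || !ans %in% it$choices)
        return(paste(it$item_id, ": answer not among choices"))
    },
    multi_choice = {
      if (!all(ans %in% it$choices))
        return(paste(it$item_id, ": answer not among choices"))
    },
    text = {
      if (!is.character(ans) || length(ans) != 1L)
        return(paste(it$item_id, ": expected text"))
      if (!is.null(it$pattern) && !grepl(it$pattern, ans))
        return(paste(it$item_id, ": does not match required pattern"))
    },
    date = {
      d <- tryCatch(as.Date(ans), error = function(e) NA)
      if (is.na(d)) return(paste(it$item_id, ": expected date"))
    }
  )
  if (tname %in% c("integer", "decimal")) {
    if (!is.null(it$min) && ans < it$min)
      return(paste0(it$item_id, ": below minimum ", it$min))
    if (!is.null(it$max) && ans > it$max)
      return(paste0(it$item_id, ": above maximum ", it$max))
  }
  character(0)
}

#' Validate a response set against its definition
#'
#' Checks, along the presented path only: required items answered,
#' answer types match, range/pattern/choice constraints hold, and no
#' answers to items absent from the definition.
#'
#' @param def a [wt_questionnaire()].
#' @param answers named list of answers.
#' @return character vector of error messages (each naming the item);
#'   empty means the response is valid and complete.
#' @export
validate_response <- function(def, answers) {
  errs <- character(0)
  ids <- item_ids(def)
  stray <- setdiff(names(answers), ids)
  if (length(stray))
    errs <- c(errs, paste("answers to unknown items:",
                          paste(stray, collapse = ", ")))
  w <- walk_path(def, answers)
  for (iid in w$path) {
    it <- def$items[[match(iid, ids)]]
    ans <- answers[[iid]]
    if (is.null(ans)) {
      if (it$required)
        errs <- c(errs, paste("required item unanswered:", iid))
      next
    }
    errs <- c(errs, check_answer(it, ans))
  }
  errs
}

# ---- scoring ------------------------------------------------------------

#' Compute scores and flags for a response
#'
#' Scores are evaluated in declaration order over the presented items only
#' (not-presented items are `NA` and dropped by `sum`/`count`); flags are
#' evaluated afterwards over answers and scores. The result is invariant
#' to the storage order of `answers`.
#'
#' @param def a [wt_questionnaire()].
#' @param answers named list of answers passing [validate_response()].
#' @return list with `scores` (named numeric) and `flags` (character).
#' @export
score_and_flag <- function(def, answers) {
  errs <- validate_response(def, answers)
  type_errs <- errs[!grepl("^required item unanswered", errs)]
  if (length(type_errs))
    wt_stop(paste(type_errs, collapse = "; "), "weartrial_response_invalid")
  ids <- item_ids(def)
  shown <- presented_items(def, answers)
  values <- stats::setNames(vector("list", length(ids)), ids)
  for (iid in ids) {
    v <- if (iid %in% shown) answers[[iid]] else NULL
    values[[iid]] <- if (is.null(v)) NA else v
  }
  scores <- numeric(0)
  for (sc in def$scoring) {
    val <- eval_restricted(sc$formula, values, .score_calls,
                           paste("score", sc$name))
    scores[sc$name] <- as.numeric(val)
    values[[sc$name]] <- as.numeric(val)
  }
  flags <- character(0)
  for (fl in def$flags) {
    hit <- eval_restricted(fl$predicate, values, .flag_calls,
                           paste("flag", fl$label))
    if (isTRUE(as.logical(hit))) flags <- c(flags, fl$label)
  }
  list(scores = scores, flags = flags)
}

# ---- publication, links, submission ------------------------------------

#' Publish a questionnaire to a study
#'
#' The definition must validate cleanly; afterwards links can be issued
#' against it and responses collected.
#'
#' @param study a [wt_study()].
#' @param def a [wt_questionnaire()].
#' @return the definition, invisibly.
#' @export
publish_questionnaire <- function(study, def) {
  errs <- validate_definition(def)
  assert_that(length(errs) == 0L,
              paste("definition invalid:", paste(errs, collapse = "; ")))
  study$questionnaires[[def$qid]] <- def
  invisible(def)
}

random_token <- function(n = 20) {
  paste(sample(c(0:9, letters[1:6]), n, replace = TRUE), collapse = "")
}

#' Issue a questionnaire link token
#'
#' A public token (no participant) collects anonymous responses; a private
#' token resolves to exactly one participant and binds every submission
#' through it to that participant.
#'
#' @param study a [wt_study()].
#' @param qid id of a published questionnaire.
#' @param study_id optional participant to bind (private link).
#' @param single_use refuse reuse after a successful submission.
#' @return opaque token string.
#' @export
issue_link <- function(study, qid, study_id = NULL, single_use = TRUE) {
  assert_that(!is.null(study$questionnaires[[qid]]),
              paste("questionnaire not published:", qid))
  if (!is.null(study_id)) get_participant(study, study_id)  # must exist
  tok <- paste0(qid, "-", random_token())
  study$tokens[[tok]] <- list(token = tok, qid = qid, study_id = study_id,
                              single_use = isTRUE(single_use), used = FALSE)
  tok
}

#' Submit a response through a link token
#'
#' Validates the answers, stamps the submission time, stores the response
#' set (bound to the token's participant for private links), and appends a
#' `submitted_questionnaire` event for bound participants.
#'
#' @param study a [wt_study()].
#' @param token a token from [issue_link()].
#' @param answers named list of answers.
#' @param time submission timestamp.
#' @return the stored response set.
#' @export
submit_response <- function(study, token, answers, time = Sys.time()) {
  rec <- study$tokens[[token]]
  assert_that(!is.null(rec), "unknown token")
  if (rec$single_use && rec$used)
    wt_stop("single-use token already used", "weartrial_token_used")
  def <- study$questionnaires[[rec$qid]]
  errs <- validate_response(def, answers)
  assert_that(length(errs) == 0L,
              paste("invalid response:", paste(errs, collapse = "; ")))
  rs <- list(qid = rec$qid, study_id = rec$study_id, token = token,
             answers = answers,
             submitted_at = as_time(time, tz = study$config$timezone))
  study$responses[[length(study$responses) + 1L]] <- rs
  rec$used <- TRUE
  study$tokens[[token]] <- rec
  if (!is.null(rec$study_id)) {
    append_event(study, rec$study_id, "submitted_questionnaire", rs$submitted_at,
                 payload = list(qid = rec$qid))
  }
  rs
}

#' Retrieve stored responses
#'
#' @param study a [wt_study()].
#' @param qid optional questionnaire filter.
#' @param study_id optional participant filter.
#' @return list of response sets.
#' @export
get_responses <- function(study, qid = NULL, study_id = NULL) {
  out <- study$responses
  if (!is.null(qid)) out <- Filter(function(r) identical(r$qid, qid), out)
  if (!is.null(study_id))
    out <- Filter(function(r) identical(r$study_id, study_id), out)
  out
}

#' Export responses to CSV
#'
#' One row per response set, one column per item. Items the branching
#' skipped are exported as the sentinel `"NOT_PRESENTED"`; presented but
#' unanswered optional items are exported empty — the two are distinct.
#'
#' @param study a [wt_study()].
#' @param qid questionnaire id.
#' @param path output CSV path.
#' @return the exported data.frame, invisibly.
#' @export
export_responses_csv <- function(study, qid, path) {
  def <- study$questionnaires[[qid]]
  assert_that(!is.null(def), paste("questionnaire not published:", qid))
  ids <- item_ids(def)
  rs <- get_responses(study, qid = qid)
  rows <- lapply(rs, function(r) {
    shown <- presented_items(def, r$answers)
    vals <- vapply(ids, function(iid) {
      if (!iid %in% shown) return("NOT_PRESENTED")
      v <- r$answers[[iid]]
      if (is.null(v)) "" else paste(as.character(v), collapse = ";")
    }, character(1))
    c(study_id = r$study_id %||% "", submitted_at = format(r$submitted_at),
      vals)
  })
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  if (length(rows) == 0L) {
    df <- as.data.frame(matrix(character(0), ncol = length(ids) + 2,
                               dimnames = list(NULL, c("study_id",
                                                       "submitted_at", ids))),
                        stringsAsFactors = FALSE)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

# ---- JSON round trip ----------------------------------------------------

#' Serialize / restore a questionnaire definition as JSON
#'
#' The JSON schema is the documented external format for questionnaire
#' authoring; `qn_from_json(qn_to_json(def))` is the identity.
#'
#' @param def a [wt_questionnaire()].
#' @param txt JSON text.
#' @return `qn_to_json()` returns JSON text; `qn_from_json()` a definition.
#' @export
qn_to_json <- function(def) {
  strip <- function(x) x[!vapply(x, is.null, logical(1))]
  obj <- list(
    qid = def$qid, phase = def$phase,
    items = lapply(def$items, function(it) strip(unclass(it))),
    branch_rules = lapply(def$branch_rules, function(b) strip(unclass(b))),
    scoring = lapply(def$scoring, function(s) strip(unclass(s))),
    flags = lapply(def$flags, function(f) strip(unclass(f)))
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
}

#' @rdname qn_to_json
#' @export
qn_from_json <- function(txt) {
  o <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  chr1 <- function(x) if (is.null(x)) NULL else as.character(unlist(x))
  items <- lapply(o$items, function(it) {
    wt_item(it$item_id, it$prompt, it$answer_type,
            required = isTRUE(it$required), choices = chr1(it$choices),
            min = it$min, max = it$max, pattern = it$pattern)
  })
  branches <- lapply(o$branch_rules, function(b) {
    val <- unlist(b$value)
    if (!is.numeric(val)) val <- as.character(val)
    wt_branch(b$source, b$op, val, b$target)
  })
  wt_questionnaire(
    o$qid, o$phase, items, branches,
    scoring = lapply(o$scoring, function(s) wt_score(s$name, s$formula)),
    flags = lapply(o$flags, function(f) wt_flag(f$label, f$predicate))
  )
}
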