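`%||%` <- function(x, y) if (is.null(x)) y else x

# kg per pound (exact international definition)
LB_TO_KG <- 0.45359237

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, unlike [round()]'s round-half-to-even.
#' Used wherever a percentage is reported to a fixed number of decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @examples
#' round_half_up(79.9188, 2)  # 79.92
#' round_half_up(0.125, 2)    # 0.13 (round() would give 0.12)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Convert pounds to kilograms and back
#'
#' Observation stores keep weight in kilograms; adherence rules are stated
#' in pounds, so both directions are needed.
#'
#' @param x numeric weight values.
#' @return converted numeric vector.
#' @export
lb_to_kg <- function(x) x * LB_TO_KG

#' @rdname lb_to_kg
#' @export
kg_to_lb <- function(x) x / LB_TO_KG

wt_stop <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "weartrial_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_that <- function(ok, msg, class = "weartrial_invalid") {
  if (!isTRUE(ok)) wt_stop(msg, class)
  invisible(TRUE)
}

is_scalar_chr <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  as.Date(x)
}

.as_time_cache <- new.env(parent = emptyenv())

as_time <- function(x, tz = "UTC") {
  if (inherits(x, "POSIXct")) return(x)
  if (inherits(x, "Date") && length(x) == 1L) {
    # midnight-of-date conversions recur constantly; memoize them
    k <- paste(unclass(x), tz)
    hit <- get0(k, envir = .as_time_cache)
    if (!is.null(hit)) return(hit)
    v <- as.POSIXct(format(x), tz = tz)
    assign(k, v, envir = .as_time_cache)
    return(v)
  }
  if (inherits(x, "Date")) return(as.POSIXct(format(x), tz = tz))
  as.POSIXct(x, tz = tz)
}

# column-wise concatenation of many small homogeneous data.frames;
# much faster than do.call(rbind, ...) for thousands of pieces
rbind_fast <- function(dfs) {
  dfs <- Filter(function(d) !is.null(d) && nrow(d) > 0, dfs)
  if (length(dfs) == 0L) return(NULL)
  cols <- names(dfs[[1]])
  out <- lapply(cols, function(cl)
    unlist(lapply(dfs, function(d) d[[cl]]), use.names = FALSE))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

# stable row-binding of homogeneous lists-of-lists into a data.frame
rbind_records <- function(records, cols) {
  if (length(records) == 0L) {
    out <- lapply(cols, function(x) vector(mode = "character", length = 0L))
    names(out) <- cols
    return(as.data.frame(out, stringsAsFactors = FALSE))
  }
  out <- lapply(cols, function(cl) {
    vapply(records, function(r) {
      v <- r[[cl]]
      if (is.null(v)) NA_character_ else as.character(v)
    }, character(1))
  })
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}
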