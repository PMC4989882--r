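# Sampling times are decimal years. Two direction conventions are supported:
# "forward"  — larger value = later calendar time (the analysis scale);
# "backward" — value is years before present (ancient-DNA convention), so the
#              analysis time is its negation: later sampling is always larger.

#' Construct a set of tip sampling dates
#'
#' @param times Named numeric vector: tip label -> decimal time in years.
#' @param direction \code{"forward"} (calendar years, larger = later) or
#'   \code{"backward"} (years before present, larger = older).
#' @return An object of class \code{"tip_dates"}.
#' @export
tip_dates <- function(times, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (is.null(names(times)) || any(!nzchar(names(times))))
    stop("times must be a named vector (tip labels)", call. = FALSE)
  if (any(!is.finite(times)))
    stop("non-finite date for tip(s): ",
         paste(names(times)[!is.finite(times)], collapse = ", "), call. = FALSE)
  dup <- names(times)[duplicated(names(times))]
  if (length(dup)) {
    # duplicates carrying the same value collapse; conflicting values are an error
    agree <- vapply(unique(dup), function(l) {
      v <- times[names(times) == l]; max(v) - min(v) == 0
    }, logical(1))
    if (!all(agree))
      stop("conflicting dates for tip(s): ",
           paste(unique(dup)[!agree], collapse = ", "), call. = FALSE)
    times <- times[!duplicated(names(times))]
  }
  structure(list(times = times, direction = direction), class = "tip_dates")
}

#' @export
print.tip_dates <- function(x, ...) {
  cat(sprintf("<tip_dates> %d tips, direction = %s (range %.4g .. %.4g)\n",
              length(x$times), x$direction, min(x$times), max(x$times)))
  invisible(x)
}

#' Analysis-scale times
#'
#' Converts a \code{\link{tip_dates}} object to the internal forward scale on
#' which the regression runs: under the backward (years-before-present)
#' convention, \eqn{t_i = -\mathrm{YBP}_i}, so later sampling always has the
#' larger time.
#'
#' @param dates A \code{tip_dates} object.
#' @return Named numeric vector of forward times.
#' @export
analysis_times <- function(dates) {
  stopifnot(inherits(dates, "tip_dates"))
  if (dates$direction == "backward") -dates$times else dates$times
}

#' Parse date strings to decimal years
#'
#' Accepts plain decimals (\code{"2003.45"}, passed through), ISO dates
#' (\code{"2003-06-14"}), year-months (\code{"2003-06"}) and bare years
#' (\code{"2003"}). Partial dates map to the midpoint of the stated period:
#' a bare year to year + 0.5, a year-month to the month's midpoint. ISO dates
#' convert leap-aware as year + (day_of_year - 0.5) / days_in_year, so noon
#' of 1 Jan 2004 is 2004 + 0.5/366.
#'
#' @param text Character vector of date strings.
#' @return Numeric vector of decimal years, same length as \code{text}.
#' @export
#' @examples
#' parse_decimal_date(c("2003", "2004-01-01", "1999.25"))
parse_decimal_date <- function(text) {
  stopifnot(is.character(text))
  out <- rep(NA_real_, length(text))
  s <- trimws(text)
  is_dec  <- grepl("^-?[0-9]+\\.[0-9]+$", s)
  is_year <- grepl("^-?[0-9]+$", s)
  is_iso  <- grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", s)
  is_ym   <- grepl("^[0-9]{4}-[0-9]{2}$", s)
  out[is_dec] <- as.numeric(s[is_dec])
  out[is_year] <- as.numeric(s[is_year]) + 0.5
  if (any(is_iso)) {
    d <- as.Date(s[is_iso], format = "%Y-%m-%d")
    bad <- is.na(d)   # e.g. 2003-02-31
    lt <- as.POSIXlt(d[!bad])
    yr <- lt$year + 1900
    doy <- lt$yday + 1
    idx <- which(is_iso)[!bad]
    out[idx] <- yr + (doy - 0.5) / .days_in_year(yr)
  }
  if (any(is_ym)) {
    yr <- as.numeric(substr(s[is_ym], 1, 4))
    mo <- as.numeric(substr(s[is_ym], 6, 7))
    ok <- mo >= 1 & mo <= 12
    diy <- .days_in_year(yr)
    first <- .cum_days_before_month(yr, mo)        # days elapsed before month
    dim_  <- .days_in_month(yr, mo)
    idx <- which(is_ym)[ok]
    out[idx] <- (yr + (first + dim_ / 2) / diy)[ok]
  }
  bad <- is.na(out)
  if (any(bad))
    stop("unrecognized date format: ",
         paste(sprintf("'%s'", text[bad]), collapse = ", "), call. = FALSE)
  out
}

.is_leap <- function(y) (y %% 4 == 0 & y %% 100 != 0) | y %% 400 == 0
.days_in_year <- function(y) ifelse(.is_leap(y), 366, 365)
.days_in_month <- function(y, m) {
  base <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)[m]
  base + ifelse(m == 2 & .is_leap(y), 1, 0)
}
.cum_days_before_month <- function(y, m) {
  cum <- c(0, cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30)))
  cum[m] + ifelse(m > 2 & .is_leap(y), 1, 0)
}

#' Extract sampling dates embedded in tip labels
#'
#' Either split each label on a delimiter and take a (possibly negative,
#' counted from the end) field index, or apply a regular expression whose
#' first capture group is the date. The extracted text goes through
#' \code{\link{parse_decimal_date}}.
#'
#' @param labels Character vector of tip labels.
#' @param delimiter Single-character field separator (with \code{field}).
#' @param field Integer field index; negative counts from the end.
#' @param regex Regular expression with one capture group (alternative rule).
#' @param direction Passed to \code{\link{tip_dates}}.
#' @return A \code{\link{tip_dates}} object keyed by the full labels.
#' @export
#' @examples
#' extract_dates_from_labels(c("A/HK/2003.45", "B/NY/2004.12"),
#'                           delimiter = "/", field = -1)
extract_dates_from_labels <- function(labels, delimiter = NULL, field = NULL,
                                      regex = NULL,
                                      direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  stopifnot(is.character(labels), length(labels) >= 1)
  if (!is.null(regex)) {
    m <- regmatches(labels, regexec(regex, labels))
    raw <- vapply(m, function(g) if (length(g) >= 2) g[2]
                  else if (length(g) == 1) g[1] else NA_character_,
                  character(1))
  } else {
    if (is.null(delimiter) || is.null(field))
      stop("supply either regex, or delimiter + field", call. = FALSE)
    parts <- strsplit(labels, delimiter, fixed = TRUE)
    raw <- vapply(parts, function(p) {
      i <- if (field < 0) length(p) + field + 1L else field
      if (i >= 1 && i <= length(p) && length(p) > 1L) p[i] else NA_character_
    }, character(1))
  }
  bad <- is.na(raw)
  if (any(bad))
    stop("no date field found in label(s): ",
         paste(labels[bad], collapse = ", "), call. = FALSE)
  vals <- tryCatch(parse_decimal_date(raw), error = function(e) {
    # re-raise naming the offending full labels, not just the fields
    ok <- !vapply(raw, function(r)
      inherits(tryCatch(parse_decimal_date(r), error = identity), "error"),
      logical(1))
    stop("unparseable date field in label(s): ",
         paste(labels[!ok], collapse = ", "), call. = FALSE)
  })
  names(vals) <- labels
  tip_dates(vals, direction)
}

#' Load sampling dates from a tab-delimited table
#'
#' First column is the tip label, second the date (any format accepted by
#' \code{\link{parse_decimal_date}}). Extra columns are ignored with a
#' notice; a header row is auto-detected (a first row whose date field does
#' not parse). Duplicated labels with conflicting dates are an error.
#'
#' @param path Path to a tab-delimited file, or a data frame / matrix of
#'   character columns.
#' @param direction Passed to \code{\link{tip_dates}}.
#' @return A \code{\link{tip_dates}} object.
#' @export
load_dates_table <- function(path, direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  if (is.character(path) && length(path) == 1L) {
    tab <- utils::read.delim(path, header = FALSE, colClasses = "character",
                             sep = "\t", quote = "", comment.char = "",
                             blank.lines.skip = TRUE, stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(path, stringsAsFactors = FALSE)
    tab[] <- lapply(tab, as.character)
  }
  if (ncol(tab) < 2)
    stop("date table needs at least two columns (tip label, date)", call. = FALSE)
  if (ncol(tab) > 2)
    message("date table: ignoring ", ncol(tab) - 2, " extra column(s)")
  # header auto-detect: first row whose date field fails to parse
  first_date <- tryCatch(parse_decimal_date(tab[1, 2]), error = function(e) NULL)
  if (is.null(first_date)) tab <- tab[-1, , drop = FALSE]
  if (nrow(tab) == 0) stop("date table is empty", call. = FALSE)
  vals <- parse_decimal_date(tab[[2]])
  names(vals) <- trimws(tab[[1]])
  tip_dates(vals, direction)
}

#' Check tree tips against available dates
#'
#' Reports the full symmetric difference between the tree's tip set and the
#' date set, for pre-flight validation.
#'
#' @param tree A \code{phylo} object.
#' @param dates A \code{tip_dates} object.
#' @return List with \code{missing_dates} (tips in the tree without a date)
#'   and \code{extra_dates} (dated labels not in the tree).
#' @export
match_dates_to_tree <- function(tree, dates) {
  stopifnot(inherits(tree, "phylo"), inherits(dates, "tip_dates"))
  list(missing_dates = setdiff(tree$tip.label, names(dates$times)),
       extra_dates = setdiff(names(dates$times), tree$tip.label))
}
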