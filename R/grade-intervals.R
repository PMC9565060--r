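#' @keywords internal
"_PACKAGE"

## Grade levels, ordered best to worst.
GRADES <- c("I", "II", "III", "IV", "V")

#' Construct a grade interval
#'
#' A grade interval is one cell of the classification table: a real interval
#' with independently open or closed endpoints.  One side may be unbounded
#' (`-Inf` / `Inf`, always open); a single-point grade is represented as a
#' degenerate interval with both endpoints closed.
#'
#' @param lower,upper Interval endpoints; `-Inf`/`Inf` mark an unbounded side.
#' @param lower_closed,upper_closed Logical endpoint closures.
#' @return An object of class `grade_interval`.
#' @export
grade_interval <- function(lower, upper, lower_closed = TRUE,
                           upper_closed = TRUE) {
  if (!is.finite(lower)) lower_closed <- FALSE
  if (!is.finite(upper)) upper_closed <- FALSE
  if (is.infinite(lower) && is.infinite(upper))
    stop("grade interval cannot be unbounded on both sides", call. = FALSE)
  if (lower > upper)
    stop("grade interval has lower > upper", call. = FALSE)
  if (lower == upper && !(lower_closed && upper_closed))
    stop("single-point grade interval must be closed on both sides",
         call. = FALSE)
  structure(list(lower = lower, upper = upper,
                 lower_closed = lower_closed, upper_closed = upper_closed),
            class = "grade_interval")
}

#' Parse an interval from classification-table notation
#'
#' Accepts bracket notation (`"[0, 0.2]"`, `"(0.2, 0.4]"`), one-sided bounds
#' (`"> 0.8"`, `">= 5"`, `"< 3"`, `"<= 3"`) and bare numbers (single-point
#' grades).  Reversed bracket forms such as `"(15, 12]"` are normalized by
#' sorting the endpoints while keeping the closure printed first on the lower
#' side and last on the upper side.
#'
#' @param s Character scalar.
#' @return A [grade_interval()].
#' @export
parse_interval <- function(s) {
  s <- trimws(s)
  num <- function(z) {
    v <- suppressWarnings(as.numeric(trimws(z)))
    if (is.na(v)) stop("cannot parse interval '", s, "'", call. = FALSE)
    v
  }
  if (grepl("^>=", s)) return(grade_interval(num(sub("^>=", "", s)), Inf, TRUE, FALSE))
  if (grepl("^>", s))  return(grade_interval(num(sub("^>", "", s)), Inf, FALSE, FALSE))
  if (grepl("^<=", s)) return(grade_interval(-Inf, num(sub("^<=", "", s)), FALSE, TRUE))
  if (grepl("^<", s))  return(grade_interval(-Inf, num(sub("^<", "", s)), FALSE, FALSE))
  m <- regmatches(s, regexec("^([[(])\\s*([^,]+),\\s*([^])]+)([])])$", s,
                             perl = TRUE))[[1]]
  if (length(m) == 5) {
    a <- num(m[3]); b <- num(m[4])
    lc <- m[2] == "["; uc <- m[5] == "]"
    if (a > b) { tmp <- a; a <- b; b <- tmp }   # reversed printing
    return(grade_interval(a, b, lc, uc))
  }
  v <- num(s)
  grade_interval(v, v, TRUE, TRUE)
}

interval_contains <- function(iv, x) {
  lo <- if (iv$lower_closed) x >= iv$lower else x > iv$lower
  hi <- if (iv$upper_closed) x <= iv$upper else x < iv$upper
  lo & hi
}

interval_width <- function(iv) iv$upper - iv$lower

interval_midpoint <- function(iv) (iv$lower + iv$upper) / 2

is_unbounded <- function(iv) is.infinite(iv$lower) || is.infinite(iv$upper)

format_interval <- function(iv) {
  if (is.infinite(iv$upper))
    return(paste0(if (iv$lower_closed) ">= " else "> ", iv$lower))
  if (is.infinite(iv$lower))
    return(paste0(if (iv$upper_closed) "<= " else "< ", iv$upper))
  if (iv$lower == iv$upper) return(as.character(iv$lower))
  paste0(if (iv$lower_closed) "[" else "(", iv$lower, ", ", iv$upper,
         if (iv$upper_closed) "]" else ")")
}

#' @export
print.grade_interval <- function(x, ...) {
  cat("<grade_interval>", format_interval(x), "\n")
  invisible(x)
}
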