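#' Closed dose interval
#'
#' All internal dose bookkeeping uses closed intervals `[lo, hi]` in
#' mg/kg/day (or percent for dermal sensitisation concentrations). A point
#' value is an interval with `lo == hi`. Intervals are the natural carrier
#' here because points of departure and exposure estimates are routinely
#' reported as ranges (e.g. a NOEL of 36--360 mg/kg/day) and the engine is
#' required to treat the range ends differently: hazard banding uses the
#' health-protective lower end, exposure categorisation the upper end.
#'
#' @param lo Lower bound (non-negative, finite).
#' @param hi Upper bound, defaults to `lo` (point value).
#' @return An object of class `dose_interval` with fields `lo` and `hi`.
#' @examples
#' dose_interval(36, 360)
#' dose_interval(4) # a point value
#' @export
dose_interval <- function(lo, hi = lo) {
  if (!is.numeric(lo) || !is.numeric(hi) || length(lo) != 1L || length(hi) != 1L) {
    stop("dose_interval bounds must be single numeric values", call. = FALSE)
  }
  if (!is.finite(lo) || !is.finite(hi)) {
    stop("dose_interval bounds must be finite", call. = FALSE)
  }
  if (lo < 0) stop("dose_interval must be non-negative", call. = FALSE)
  if (lo > hi) stop("dose_interval requires lo <= hi", call. = FALSE)
  structure(list(lo = as.numeric(lo), hi = as.numeric(hi)), class = "dose_interval")
}

#' Coerce to a dose interval
#'
#' Accepts an existing `dose_interval`, a single number (point interval) or a
#' numeric vector of length 2 `c(lo, hi)`.
#'
#' @param x Value to coerce.
#' @return A `dose_interval`.
#' @export
as_dose_interval <- function(x) {
  if (inherits(x, "dose_interval")) return(x)
  if (is.numeric(x) && length(x) == 1L) return(dose_interval(x))
  if (is.numeric(x) && length(x) == 2L) return(dose_interval(x[[1L]], x[[2L]]))
  stop("cannot coerce to dose_interval: expected 1 or 2 numeric values", call. = FALSE)
}

#' @export
Ops.dose_interval <- function(e1, e2) {
  if (!.Generic %in% c("*", "/")) {
    stop(sprintf("operation '%s' is not defined for dose intervals", .Generic),
         call. = FALSE)
  }
  if (inherits(e1, "dose_interval") && is.numeric(e2) && length(e2) == 1L) {
    k <- if (.Generic == "*") e2 else 1 / e2
  } else if (inherits(e2, "dose_interval") && is.numeric(e1) && length(e1) == 1L &&
             .Generic == "*") {
    k <- e1
    e1 <- e2
  } else {
    stop("dose intervals can only be scaled by a single positive number",
         call. = FALSE)
  }
  if (!is.finite(k) || k <= 0) {
    stop("dose intervals can only be scaled by a positive factor", call. = FALSE)
  }
  dose_interval(e1$lo * k, e1$hi * k)
}

is_point_interval <- function(x) x$lo == x$hi

#' @export
format.dose_interval <- function(x, ...) {
  if (is_point_interval(x)) format(x$lo, ...) else
    paste0("[", format(x$lo, ...), ", ", format(x$hi, ...), "]")
}

#' @export
print.dose_interval <- function(x, ...) {
  cat("<dose interval> ", format(x), " mg/kg/day\n", sep = "")
  invisible(x)
}

#' @export
as.numeric.dose_interval <- function(x, ...) c(x$lo, x$hi)

interval_equal <- function(a, b, tol = 0) {
  a <- as_dose_interval(a); b <- as_dose_interval(b)
  abs(a$lo - b$lo) <= tol && abs(a$hi - b$hi) <= tol
}

#' Round doses for display
#'
#' The computation core never rounds; reports display doses at a configurable
#' number of significant figures (default 2, matching values such as 0.04 and
#' 0.36--3.6 mg/kg/day).
#'
#' @param x A `dose_interval` or numeric value.
#' @param sigfigs Significant figures to keep.
#' @return A character scalar such as `"0.04"` or `"0.36-3.6"`.
#' @export
format_dose <- function(x, sigfigs = 2) {
  fmt1 <- function(v) format(signif(v, sigfigs), scientific = FALSE, trim = TRUE)
  if (inherits(x, "dose_interval")) {
    if (is_point_interval(x)) fmt1(x$lo) else paste0(fmt1(x$lo), "-", fmt1(x$hi))
  } else {
    fmt1(x)
  }
}
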