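# Internal validation and formatting helpers shared across modules.

#' @keywords internal
#' @noRd
stop_ihc <- function(...) stop(..., call. = FALSE)

# Integer-valued check tolerant of numeric storage (reads from text give
# doubles); fractional values are rejected.
is_wholenumber <- function(x, tol = sqrt(.Machine$double.eps)) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

assert_int_range <- function(x, lo, hi, what) {
  bad <- !is_wholenumber(x) | x < lo | x > hi
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    i <- which(bad | is.na(bad))[1L]
    stop_ihc(sprintf("%s must be an integer in [%s, %s]; got %s",
                     what, lo, hi, deparse(x[i])))
  }
  invisible(x)
}

#' Round half away from zero
#'
#' Decimal rounding with the half-up convention used for all reported
#' percentages (base \code{round()} rounds half to even, which does not
#' reproduce values such as 49.2 from 252/512).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up at \code{digits} places.
#' @examples
#' round_half_up(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Percentage on a denominator, half-up to one decimal; NA when denom is 0.
pct1 <- function(num, denom) {
  ifelse(denom > 0, round_half_up(100 * num / denom, 1), NA_real_)
}

MARKERS <- c("ANLN", "PBK", "PDZK1")
LEVELS <- c("high", "low")

assert_level <- function(x, what = "level") {
  bad <- !is.na(x) & !(x %in% LEVELS)
  if (any(bad)) {
    stop_ihc(sprintf("%s must be 'high', 'low' or NA (missing); got '%s'",
                     what, x[which(bad)[1L]]))
  }
  invisible(x)
}

assert_marker <- function(marker) {
  bad <- !(marker %in% MARKERS)
  if (any(bad)) {
    stop_ihc(sprintf("unknown marker '%s'; expected one of %s",
                     marker[which(bad)[1L]], paste(MARKERS, collapse = ", ")))
  }
  invisible(marker)
}
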