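#' Subcutaneous dosing regimen
#'
#' A sequence of SC dose events. Event times must be non-negative and strictly
#' increasing; doses must be positive. An empty regimen (no events) is allowed
#' and simulates to an identically-zero profile.
#'
#' @param time_h Event times in hours.
#' @param dose_mg Doses in mg (one per event, or a scalar recycled).
#' @return A `dose_regimen`: a tibble with columns `time_h`, `dose_mg`.
#' @export
#' @examples
#' dose_regimen(0, 5)
#' weekly_regimen(5, n_weeks = 8)
dose_regimen <- function(time_h = numeric(), dose_mg = numeric()) {
  if (length(dose_mg) == 1L && length(time_h) > 1L) {
    dose_mg <- rep(dose_mg, length(time_h))
  }
  stopifnot(length(time_h) == length(dose_mg))
  if (length(time_h)) {
    if (any(time_h < 0) || any(diff(time_h) <= 0)) {
      abort("event times must be non-negative and strictly increasing.",
        class = "tirzepk_validation_error"
      )
    }
    if (any(dose_mg <= 0)) {
      abort("doses must be positive.", class = "tirzepk_validation_error")
    }
  }
  structure(
    tibble(time_h = as.numeric(time_h), dose_mg = as.numeric(dose_mg)),
    class = c("dose_regimen", "tbl_df", "tbl", "data.frame")
  )
}

#' @rdname dose_regimen
#' @param doses_mg For `weekly_regimen()`: dose (scalar) or per-week dose
#'   vector in mg.
#' @param n_weeks Number of weekly administrations (168 h apart), used when
#'   `doses_mg` is a scalar.
#' @export
weekly_regimen <- function(doses_mg, n_weeks = length(doses_mg)) {
  if (length(doses_mg) == 1L) doses_mg <- rep(doses_mg, n_weeks)
  dose_regimen(time_h = 168 * (seq_along(doses_mg) - 1L), dose_mg = doses_mg)
}

#' Parse a weekly dosing description
#'
#' Parses strings of the form `"2.5 mg (2), 5 mg (2), 10 mg (4)"`, where the
#' number in parentheses is how many weeks each dose level is given; doses are
#' spaced 168 h apart.
#'
#' @param text Regimen description.
#' @return A [dose_regimen()].
#' @export
#' @examples
#' parse_weekly_regimen("5 mg (8)")
parse_weekly_regimen <- function(text) {
  parts <- strsplit(text, ",")[[1]]
  doses <- unlist(lapply(parts, function(p) {
    m <- regmatches(p, regexec(
      "([0-9]*\\.?[0-9]+)\\s*(?:mg)?\\s*\\(([0-9]+)\\)", p
    ))[[1]]
    if (length(m) != 3L) {
      abort(sprintf("cannot parse regimen fragment '%s'.", trimws(p)),
        class = "tirzepk_validation_error"
      )
    }
    rep(as.numeric(m[[2]]), as.integer(m[[3]]))
  }))
  weekly_regimen(doses)
}
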