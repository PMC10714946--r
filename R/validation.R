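#' Fold error between a prediction and an observation
#'
#' Ratio of predicted to observed PK parameter (default), or the inverse.
#' The published comparison tables tabulate predicted/observed even though the
#' accompanying formula is written the other way round; the default follows
#' the tables, and the convention is switchable.
#'
#' @param predicted,observed Positive values (vectorised).
#' @param convention `"pred_over_obs"` (default) or `"obs_over_pred"`.
#' @return Fold error(s), dimensionless.
#' @export
#' @examples
#' fold_error(113085, 90500) # 1.25
fold_error <- function(predicted, observed,
                       convention = c("pred_over_obs", "obs_over_pred")) {
  convention <- match.arg(convention)
  bad <- !is.na(predicted) & !is.na(observed) &
    (predicted <= 0 | observed <= 0)
  if (any(bad)) {
    abort("fold error requires positive predicted and observed values.",
      class = "tirzepk_domain_error"
    )
  }
  if (convention == "pred_over_obs") predicted / observed else observed / predicted
}

#' Average fold error (geometric mean of fold errors)
#'
#' `AFE = 10^(sum(log10(fe)) / N)`. `NA` entries must be removed by the caller
#' (studies with missing parameters do not count towards N).
#'
#' @param fold_errors Positive fold errors.
#' @return The AFE, dimensionless.
#' @export
#' @examples
#' afe(c(2, 0.5)) # 1
afe <- function(fold_errors) {
  if (!length(fold_errors)) {
    abort("afe() needs at least one fold error.", class = "tirzepk_domain_error")
  }
  if (any(is.na(fold_errors))) {
    abort("remove NA fold errors before calling afe().",
      class = "tirzepk_domain_error"
    )
  }
  if (any(fold_errors <= 0)) {
    abort("fold errors must be positive.", class = "tirzepk_domain_error")
  }
  10^(mean(log10(fold_errors)))
}

#' Two-fold acceptance check
#'
#' Flags values as acceptable when they lie in the closed interval
#' \[0.5, 2\], the conventional PBPK qualification window.
#'
#' @param x Fold errors or AFE values.
#' @return Logical vector.
#' @export
two_fold_check <- function(x) {
  x >= 0.5 & x <= 2
}

#' Qualify model predictions against observed PK parameters
#'
#' Builds the full qualification report: per-study fold errors, per-parameter
#' AFE over the studies where both values exist, and 0.5-2-fold pass flags for
#' every fold error and AFE.
#'
#' @param pk_table A data frame with columns `study_id`, `dose_mg`,
#'   `parameter`, `predicted`, `observed` (one row per study x parameter;
#'   `NA` allowed). See [single_dose_pk_table()] for the bundled adult
#'   single-dose comparison.
#' @param convention Fold-error convention, see [fold_error()].
#' @return An object of class `validation_report`: list with `per_study`
#'   (input plus `fold_error` and `pass_2fold`) and `summary` (per-parameter
#'   `afe`, `n_used`, `pass_2fold`).
#' @export
#' @examples
#' rep <- validation_report(single_dose_pk_table())
#' glance(rep)
validation_report <- function(pk_table,
                              convention = c("pred_over_obs", "obs_over_pred")) {
  convention <- match.arg(convention)
  stopifnot(all(
    c("study_id", "parameter", "predicted", "observed") %in% names(pk_table)
  ))
  per_study <- pk_table |>
    mutate(
      fold_error = fold_error(.data$predicted, .data$observed, convention),
      pass_2fold = two_fold_check(.data$fold_error)
    )
  summary <- per_study |>
    filter(!is.na(.data$fold_error)) |>
    group_by(.data$parameter) |>
    summarise(
      afe = afe(.data$fold_error),
      n_used = dplyr::n(),
      .groups = "drop"
    ) |>
    mutate(pass_2fold = two_fold_check(.data$afe))
  structure(
    list(per_study = per_study, summary = summary, convention = convention),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> (fold error =", x$convention, ")\n")
  print(x$summary)
  invisible(x)
}

#' @rdname validation_report
#' @param x A `validation_report`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.validation_report <- function(x, ...) x$per_study

#' @rdname validation_report
#' @exportS3Method generics::glance
glance.validation_report <- function(x, ...) x$summary

#' Bundled adult PK comparison tables
#'
#' Published predicted and observed adult PK parameters for tirzepatide:
#' `single_dose_pk_table()` covers seven single-dose study arms (2.5-8 mg;
#' AUC, Cmax, T1/2, Tmax, CL/F; the two arms whose AUC was reported over
#' 0-168 h are marked in `auc_window`), `multiple_dose_pk_table()` the eight
#' multiple-dose regimens (steady-state AUC over one 168 h interval, Cmax,
#' T1/2, Tmax). One study reports no CL/F (stored as `NA` and excluded from
#' AFE).
#'
#' @return A tibble in [validation_report()] layout.
#' @export
single_dose_pk_table <- function() {
  .read_fixture("single_dose_observed.csv")
}

#' @rdname single_dose_pk_table
#' @export
multiple_dose_pk_table <- function() {
  .read_fixture("multiple_dose_observed.csv")
}

.read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "tirzepk", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
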