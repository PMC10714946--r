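#' Pediatric renal clearance scaling
#'
#' `CL_renal,ped = (GFR_ped / GFR_adult) * (fu_ped / fu_adult) * CL_renal,adult`.
#' For ages 10 and above albumin is adult-like, so the fu ratio defaults to 1.
#'
#' @param gfr_pediatric,gfr_adult GFR, mL/min.
#' @param cl_renal_adult Calibrated adult renal clearance, L/h.
#' @param fu_pediatric,fu_adult Unbound fractions.
#' @return Pediatric renal clearance, L/h.
#' @export
#' @examples
#' scale_renal_clearance(100, 120, 0.03) # 0.025
scale_renal_clearance <- function(gfr_pediatric, gfr_adult, cl_renal_adult,
                                  fu_pediatric = 1, fu_adult = 1) {
  vals <- c(gfr_pediatric, gfr_adult, cl_renal_adult, fu_pediatric, fu_adult)
  if (any(vals <= 0)) {
    abort("all clearance-scaling inputs must be positive.",
      class = "tirzepk_domain_error"
    )
  }
  (gfr_pediatric / gfr_adult) * (fu_pediatric / fu_adult) * cl_renal_adult
}

#' Extrapolate a calibrated adult model to another individual
#'
#' Drug-specific parameters are kept unaltered; the physiology is replaced by
#' the target individual's, which rescales peptidase clearance implicitly
#' through organ volumes; renal clearance is rescaled by the GFR ratio with a
#' unit fu ratio (no age-related change in plasma binding at 10+ years).
#'
#' @param adult_model A calibrated adult `pbpk_model` (from
#'   [calibrate()]`$model`).
#' @param ind Target `individual_physiology` (pediatric or adult).
#' @return A `pbpk_model` for the target individual.
#' @export
extrapolate <- function(adult_model, ind) {
  stopifnot(inherits(adult_model, "pbpk_model"),
            inherits(ind, "individual_physiology"))
  if (!isTRUE(adult_model$calibrated)) {
    abort("extrapolate() requires a calibrated adult model.",
      class = "tirzepk_state_error"
    )
  }
  drug <- adult_model$drug
  drug$cl_renal <- scale_renal_clearance(
    gfr_pediatric = ind$gfr,
    gfr_adult = adult_model$ind$gfr,
    cl_renal_adult = adult_model$cl_renal
  )
  out <- build_model(ind, drug)
  out$calibrated <- TRUE
  out
}

#' Adult exposure reference range
#'
#' The adult single-dose 5 mg reference ranges used to judge pediatric
#' exposure matching: AUC_0-168h 43459-63467 ng*h/mL, Cmax 305.7-488.3 ng/mL,
#' Tmax 24-72 h. Bundled as JSON; override any bound via arguments.
#'
#' @param auc_0_168,cmax,tmax Optional `c(lo, hi)` overrides.
#' @return A list of class `reference_range`.
#' @export
reference_range <- function(auc_0_168 = NULL, cmax = NULL, tmax = NULL) {
  path <- system.file("extdata", "reference_range.json",
    package = "tirzepk", mustWork = TRUE
  )
  ref <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref$auc_0_168 <- auc_0_168 %||% ref$auc_0_168
  ref$cmax <- cmax %||% ref$cmax
  ref$tmax <- tmax %||% ref$tmax
  for (nm in names(ref)) {
    if (ref[[nm]][[1]] >= ref[[nm]][[2]]) {
      abort("reference range bounds must satisfy lo < hi.",
        class = "tirzepk_validation_error"
      )
    }
  }
  structure(ref, class = "reference_range")
}

#' Simulate a population at one dose
#'
#' Extrapolates the calibrated adult model to each individual, simulates a
#' single SC dose and computes AUC_0-168h, Cmax and Tmax per individual.
#'
#' @param population A `pbpk_population` (or list of individuals).
#' @param adult_model Calibrated adult `pbpk_model`.
#' @param dose_mg Single SC dose, mg.
#' @param t_end,dt_out Simulation window (default 336 h) and grid.
#' @param method Solver.
#' @return A tibble, one row per individual: `id`, `age_years`, `sex`,
#'   `weight_class`, `body_weight`, `dose_mg`, `auc_0_168`, `cmax`, `tmax`.
#' @export
simulate_population <- function(population, adult_model, dose_mg,
                                t_end = 336, dt_out = 0.5,
                                method = c("analytic", "lsoda")) {
  method <- match.arg(method)
  purrr::imap(unclass(population), function(ind, i) {
    model <- extrapolate(adult_model, ind)
    prof <- simulate_profile(
      model, dose_regimen(0, dose_mg),
      t_end = t_end, dt_out = dt_out, method = method
    )
    tibble(
      id = i, age_years = ind$age_years, sex = ind$sex,
      weight_class = ind$weight_class, body_weight = ind$body_weight,
      dose_mg = dose_mg,
      auc_0_168 = .auc_to(prof$time_h, prof$conc_ng_per_ml, 168),
      cmax = max(prof$conc_ng_per_ml),
      tmax = prof$time_h[[which.max(prof$conc_ng_per_ml)]]
    )
  }) |> purrr::list_rbind()
}

#' Find the pediatric dose band matching the adult reference range
#'
#' Simulates the population at every candidate dose and qualifies a dose when
#' the population mean AUC_0-168h AND mean Cmax both lie inside the adult
#' reference range (the default statistic; `"fraction"` instead requires a
#' given fraction of individuals inside the range on both metrics). The
#' recommendation is the contiguous band of qualifying doses; when the full
#' adult dose is the only qualifying dose the result is "no adjustment".
#'
#' @param population A `pbpk_population`.
#' @param adult_model Calibrated adult `pbpk_model`.
#' @param candidate_doses Candidate single doses, mg; default
#'   `c(2.5, 3.125, 3.75, 4.375, 5)` (50-100 % of the 5 mg adult reference
#'   dose).
#' @param ref A [reference_range()].
#' @param statistic `"mean"` (default) or `"fraction"`.
#' @param min_fraction Required fraction of individuals inside the range when
#'   `statistic = "fraction"`.
#' @param method Solver.
#' @param dt_out Output grid, h.
#' @return A list of class `dose_recommendation`: `band` (`c(lo, hi)` in mg or
#'   `NULL`), `no_adjustment` (logical), `per_dose` (tibble of population
#'   means and qualification flags per dose), `per_individual` (all simulated
#'   exposures).
#' @export
find_dose_band <- function(population, adult_model,
                           candidate_doses = c(2.5, 3.125, 3.75, 4.375, 5),
                           ref = reference_range(),
                           statistic = c("mean", "fraction"),
                           min_fraction = 0.5,
                           method = c("analytic", "lsoda"),
                           dt_out = 0.5) {
  statistic <- match.arg(statistic)
  method <- match.arg(method)
  candidate_doses <- sort(candidate_doses)
  adult_dose <- max(candidate_doses)

  per_individual <- purrr::map(
    candidate_doses,
    function(d) {
      simulate_population(population, adult_model, d,
        dt_out = dt_out, method = method
      )
    }
  ) |> purrr::list_rbind()

  inside <- function(x, b) x >= b[[1]] & x <= b[[2]]
  per_dose <- per_individual |>
    group_by(.data$dose_mg) |>
    summarise(
      mean_auc_0_168 = mean(.data$auc_0_168),
      mean_cmax = mean(.data$cmax),
      mean_tmax = mean(.data$tmax),
      frac_auc_in = mean(inside(.data$auc_0_168, ref$auc_0_168)),
      frac_cmax_in = mean(inside(.data$cmax, ref$cmax)),
      .groups = "drop"
    ) |>
    mutate(
      qualifies = if (statistic == "mean") {
        inside(.data$mean_auc_0_168, ref$auc_0_168) &
          inside(.data$mean_cmax, ref$cmax)
      } else {
        .data$frac_auc_in >= min_fraction & .data$frac_cmax_in >= min_fraction
      }
    )

  qual <- per_dose$dose_mg[per_dose$qualifies]
  band <- if (length(qual)) range(qual) else NULL
  no_adjustment <- length(qual) == 1L && qual == adult_dose
  structure(
    list(
      band = band, no_adjustment = no_adjustment,
      per_dose = per_dose, per_individual = per_individual,
      ref = ref, statistic = statistic
    ),
    class = "dose_recommendation"
  )
}

#' @export
print.dose_recommendation <- function(x, ...) {
  if (x$no_adjustment) {
    cat("<dose_recommendation> no dose adjustment needed\n")
  } else if (is.null(x$band)) {
    cat("<dose_recommendation> no candidate dose qualifies\n")
  } else {
    cat(sprintf(
      "<dose_recommendation> %.3g-%.3g mg\n", x$band[[1]], x$band[[2]]
    ))
  }
  print(x$per_dose)
  invisible(x)
}

#' @rdname find_dose_band
#' @param x A `dose_recommendation`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.dose_recommendation <- function(x, ...) x$per_dose

#' Dose-adjustment table across age bands and weight classes
#'
#' Runs [find_dose_band()] for the three pediatric age bands (children 10-12,
#' early adolescents 12-15, adolescents 15-18), each as normal-weight and
#' obese populations, and assembles the recommendation table.
#'
#' @param adult_model Calibrated adult `pbpk_model`.
#' @param n_per_sex Individuals per sex in each virtual population.
#' @param seed Integer seed; each subgroup uses a distinct seed derived from
#'   it.
#' @param candidate_doses,ref,statistic,method,dt_out Passed to
#'   [find_dose_band()].
#' @return A tibble: `age_band`, `weight_class`, `dose_lo_mg`, `dose_hi_mg`,
#'   `no_adjustment`, plus a `detail` list-column of `dose_recommendation`s.
#' @export
dose_adjustment_table <- function(adult_model, n_per_sex = 50L, seed = 1L,
                                  candidate_doses = c(2.5, 3.125, 3.75, 4.375, 5),
                                  ref = reference_range(),
                                  statistic = "mean",
                                  method = "analytic", dt_out = 0.5) {
  bands <- tibble(
    age_band = c("children_10_12", "early_adol_12_15", "adol_15_18"),
    lo = c(10, 12, 15), hi = c(12, 15, 18)
  )
  grid <- tidyr::expand_grid(bands, weight_class = c("normal", "obese"))
  out <- purrr::pmap(grid, function(age_band, lo, hi, weight_class) {
    sub_seed <- (seed * 8191L +
      match(age_band, bands$age_band) * 64L +
      match(weight_class, c("normal", "obese"))) %% .Machine$integer.max
    pop <- sample_population(
      population_spec(n_per_sex, n_per_sex, c(lo, hi), weight_class,
        seed = sub_seed
      )
    )
    rec <- find_dose_band(pop, adult_model,
      candidate_doses = candidate_doses, ref = ref,
      statistic = statistic, method = method, dt_out = dt_out
    )
    tibble(
      age_band = age_band, weight_class = weight_class,
      dose_lo_mg = if (rec$no_adjustment || is.null(rec$band)) {
        NA_real_
      } else {
        rec$band[[1]]
      },
      dose_hi_mg = if (rec$no_adjustment || is.null(rec$band)) {
        NA_real_
      } else {
        rec$band[[2]]
      },
      no_adjustment = rec$no_adjustment,
      detail = list(rec)
    )
  })
  purrr::list_rbind(out)
}
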