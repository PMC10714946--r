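#' Construct a virtual individual
#'
#' Builds an age/sex-consistent virtual individual: anthropometry from the
#' bundled growth reference, lean organ volumes scaled allometrically from the
#' same-sex adult reference, adipose tissue absorbing the remaining body
#' weight, perfusion as fixed fractions of an allometrically scaled cardiac
#' output, and absolute GFR from a body-surface-area-normalised reference
#' (120 mL/min/1.73 m^2; renal maturation is adult-like from age 10).
#'
#' With `cv = 0` (default) the individual sits exactly at the reference
#' medians, so repeated calls are identical; `sample_population()` adds
#' between-subject variability.
#'
#' @param age Age in years; supported range 10-80.
#' @param sex `"female"` or `"male"`.
#' @param weight_class `"normal"` or `"obese"`. Obese individuals are built
#'   normal-weight and then passed through [apply_obesity()] with a target BMI
#'   above the bundled 95th-percentile curve.
#' @param seed Optional integer seed controlling the anthropometry draw when
#'   `cv > 0`.
#' @param cv Coefficient of variation of the body-weight draw around the age/
#'   sex median (height uses `cv / 3`); draws truncated at 2.5 SD.
#' @param target_weight Optional body weight (kg) overriding the sampled /
#'   median weight (all organs rescale with the weight ratio).
#' @param scaling An [obesity_scaling()] object used when
#'   `weight_class = "obese"`.
#' @return An object of class `individual_physiology`: a list with fields
#'   `age_years`, `sex`, `body_weight` (kg), `height` (cm), `bmi` (kg/m^2),
#'   `organ_volumes` (L, includes `plasma`), `organ_blood_flows` (L/h),
#'   `cardiac_output` (L/h), `gfr` (mL/min), `hematocrit`, `weight_class`.
#' @export
#' @examples
#' adult <- build_individual(30, "male")
#' adult$body_weight
#' child <- build_individual(11, "female", weight_class = "obese")
#' child$bmi > bmi_percentile(11, "female")
build_individual <- function(age, sex, weight_class = c("normal", "obese"),
                             seed = NULL, cv = 0, target_weight = NULL,
                             scaling = obesity_scaling()) {
  sex <- match.arg(sex, c("female", "male"))
  weight_class <- match.arg(weight_class)
  if (!is.numeric(age) || length(age) != 1L || is.na(age)) {
    abort("`age` must be a single number.", class = "tirzepk_validation_error")
  }
  if (age < 10 || age > 80) {
    abort(
      sprintf("age %.1f y outside the supported range [10, 80].", age),
      class = "tirzepk_domain_error"
    )
  }

  med <- .interp_growth(age, sex)
  draw <- function() {
    if (cv <= 0) {
      c(1, 1)
    } else {
      zw <- .rtruncnorm(1, 0, 1, lower = -2.5, upper = 2.5)
      zh <- .rtruncnorm(1, 0, 1, lower = -2.5, upper = 2.5)
      c(exp(zw * sqrt(log(1 + cv^2))), exp(zh * sqrt(log(1 + (cv / 3)^2))))
    }
  }
  f <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  weight <- target_weight %||% (med$weight * f[[1]])
  height <- med$height * f[[2]]

  ind <- .assemble_physiology(age, sex, weight, height)
  if (weight_class == "obese") {
    ind <- apply_obesity(ind, scaling = scaling)
  }
  ind
}

# Deterministic core: lean organs allometric in body weight, adipose residual.
.assemble_physiology <- function(age, sex, weight, height) {
  ref <- .adult_reference[[sex]]
  ratio <- weight / ref$body_weight
  lean <- setdiff(PBPK_ORGANS, "adipose")
  vols <- setNames(numeric(length(PBPK_ORGANS) + 1L), c(PBPK_ORGANS, "plasma"))
  for (org in lean) {
    vols[[org]] <- ref$volumes[[org]] * ratio^.organ_weight_exponents[[org]]
  }
  vols[["plasma"]] <- ref$plasma * ratio
  vols[["adipose"]] <- weight - sum(vols[lean]) - vols[["plasma"]]
  if (vols[["adipose"]] <= 0) {
    abort(
      "lean organ mass exceeds body weight; weight too low for this age/sex.",
      class = "tirzepk_domain_error"
    )
  }

  co <- ref$cardiac_output * ratio^0.75
  flows <- .flow_fractions[PBPK_ORGANS] * co

  hct <- if (sex == "male") {
    if (age >= 18) 0.44 else if (age <= 15) 0.40 else 0.40 + 0.04 * (age - 15) / 3
  } else {
    0.40
  }

  structure(
    list(
      age_years = age,
      sex = sex,
      body_weight = weight,
      height = height,
      bmi = weight / (height / 100)^2,
      organ_volumes = vols,
      organ_blood_flows = flows,
      cardiac_output = co,
      gfr = .gfr_from_bsa(weight, height),
      hematocrit = hct,
      weight_class = "normal"
    ),
    class = "individual_physiology"
  )
}

#' Obesity scaling factors
#'
#' Lean-organ volume multipliers applied when converting a normal-weight
#' individual to an obese one. Kidney and liver grow to 115 % of their
#' normal-weight volume, other lean organs to a configurable default (105 %),
#' and adipose tissue absorbs the remaining excess body weight. Absolute GFR
#' scales with kidney volume.
#'
#' @param kidney,liver Volume factors for kidney and liver (default 1.15).
#' @param lean_default Factor for the remaining lean organs and plasma
#'   (default 1.05).
#' @param bmi_percentile_threshold Percentile defining obesity (default 95).
#' @param bmi_excess Default target BMI expressed as a multiple of the
#'   threshold percentile curve (default 1.15, i.e. 15 % above it).
#' @param gfr_scaling How GFR responds to obesity; only
#'   `"per_organ_volume"` (scale with kidney volume) is implemented.
#' @return An object of class `obesity_scaling`.
#' @export
obesity_scaling <- function(kidney = 1.15, liver = 1.15, lean_default = 1.05,
                            bmi_percentile_threshold = 95, bmi_excess = 1.15,
                            gfr_scaling = "per_organ_volume") {
  factors <- setNames(
    rep(lean_default, length(PBPK_ORGANS) + 1L), c(PBPK_ORGANS, "plasma")
  )
  factors[["kidney"]] <- kidney
  factors[["liver"]] <- liver
  factors[["adipose"]] <- NA_real_ # residual, not a factor
  if (any(factors < 1, na.rm = TRUE)) {
    abort("all obesity volume factors must be >= 1.",
      class = "tirzepk_validation_error"
    )
  }
  gfr_scaling <- match.arg(gfr_scaling, "per_organ_volume")
  structure(
    list(
      organ_volume_factors = factors,
      bmi_percentile_threshold = bmi_percentile_threshold,
      bmi_excess = bmi_excess,
      gfr_scaling = gfr_scaling
    ),
    class = "obesity_scaling"
  )
}

#' Convert a normal-weight individual to an obese one
#'
#' Lean organ volumes are multiplied by their scaling factors, the excess body
#' weight beyond the lean-organ increase is assigned to adipose tissue, organ
#' blood flows rescale proportionally to the new volumes (raising cardiac
#' output), and absolute GFR scales with kidney volume.
#'
#' @param ind A normal-weight `individual_physiology`.
#' @param scaling An [obesity_scaling()] object.
#' @param target_bmi Target BMI (kg/m^2). Default: `bmi_excess` times the
#'   bundled threshold-percentile curve for the individual's age and sex.
#' @return The obese `individual_physiology`; total body weight equals the sum
#'   of organ masses by construction.
#' @export
apply_obesity <- function(ind, scaling = obesity_scaling(), target_bmi = NULL) {
  stopifnot(inherits(ind, "individual_physiology"))
  if (!identical(ind$weight_class, "normal")) {
    abort("apply_obesity() expects a normal-weight individual.",
      class = "tirzepk_validation_error"
    )
  }
  if (any(scaling$organ_volume_factors < 1, na.rm = TRUE)) {
    abort("all obesity volume factors must be >= 1.",
      class = "tirzepk_validation_error"
    )
  }
  target_bmi <- target_bmi %||%
    (scaling$bmi_excess *
      bmi_percentile(ind$age_years, ind$sex, scaling$bmi_percentile_threshold))
  target_weight <- target_bmi * (ind$height / 100)^2

  vols <- ind$organ_volumes
  lean <- setdiff(names(vols), "adipose")
  new_vols <- vols
  new_vols[lean] <- vols[lean] * scaling$organ_volume_factors[lean]
  new_vols[["adipose"]] <- target_weight - sum(new_vols[lean])
  if (new_vols[["adipose"]] < vols[["adipose"]] - 1e-9) {
    abort(
      "target BMI leaves no excess weight for adipose tissue; individual may already be heavier than the target.",
      class = "tirzepk_domain_error"
    )
  }

  flows <- ind$organ_blood_flows
  vol_ratio <- new_vols[names(flows)] / vols[names(flows)]
  new_flows <- flows * vol_ratio

  out <- ind
  out$organ_volumes <- new_vols
  out$organ_blood_flows <- new_flows
  out$cardiac_output <- ind$cardiac_output *
    sum(new_flows) / sum(flows)
  out$gfr <- ind$gfr * scaling$organ_volume_factors[["kidney"]]
  out$body_weight <- target_weight
  out$bmi <- target_weight / (out$height / 100)^2
  out$weight_class <- "obese"
  out
}

#' Specify a virtual population
#'
#' @param n_female,n_male Number of individuals per sex (`n_female + n_male >= 1`).
#' @param age_range Length-2 numeric, years; must lie within \[10, 18\] for
#'   pediatric groups or be entirely adult (>= 18).
#' @param weight_class `"normal"` or `"obese"`.
#' @param seed Integer seed; the whole population is reproducible from it.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(n_female, n_male, age_range,
                            weight_class = c("normal", "obese"), seed = 1L) {
  weight_class <- match.arg(weight_class)
  stopifnot(length(age_range) == 2L, age_range[[1]] <= age_range[[2]])
  if (n_female + n_male < 1) {
    abort("population must contain at least one individual.",
      class = "tirzepk_validation_error"
    )
  }
  if (age_range[[1]] < 10) {
    abort("ages below 10 y are unsupported.", class = "tirzepk_domain_error")
  }
  if (age_range[[2]] > 18 && age_range[[1]] < 18) {
    abort("age_range must lie within [10, 18] or be entirely adult.",
      class = "tirzepk_validation_error"
    )
  }
  structure(
    list(
      n_female = as.integer(n_female), n_male = as.integer(n_male),
      age_range = as.numeric(age_range), weight_class = weight_class,
      seed = as.integer(seed)
    ),
    class = "population_spec"
  )
}

#' Sample a virtual population
#'
#' Draws `n_female + n_male` individuals with ages uniform over the spec's age
#' range and anthropometry sampled around the age/sex medians (body-weight CV
#' 10 %, truncated at 2.5 SD). For obese populations the target BMI is drawn
#' a little above the 95th-percentile curve so every individual classifies as
#' obese. Fully reproducible from the spec seed.
#'
#' @param spec A [population_spec()].
#' @param cv Body-weight coefficient of variation (default 0.1).
#' @param scaling An [obesity_scaling()] object for obese populations.
#' @return A list of `individual_physiology` objects with class
#'   `pbpk_population`; see [as_tibble.pbpk_population()] for a tabular view.
#' @export
#' @examples
#' pop <- sample_population(population_spec(3, 3, c(10, 12), "normal", seed = 42))
#' as_tibble(pop)
sample_population <- function(spec, cv = 0.1, scaling = obesity_scaling()) {
  stopifnot(inherits(spec, "population_spec"))
  sexes <- c(rep("female", spec$n_female), rep("male", spec$n_male))
  n <- length(sexes)
  withr::with_seed(spec$seed, {
    ages <- runif(n, spec$age_range[[1]], spec$age_range[[2]])
    zw <- .rtruncnorm(n, 0, 1, lower = -2.5, upper = 2.5)
    zh <- .rtruncnorm(n, 0, 1, lower = -2.5, upper = 2.5)
    zb <- .rtruncnorm(n, 0, 1, lower = -2.17, upper = 3.33) # BMI excess draw
    inds <- vector("list", n)
    for (i in seq_len(n)) {
      med <- .interp_growth(ages[[i]], sexes[[i]])
      w <- med$weight * exp(zw[[i]] * sqrt(log(1 + cv^2)))
      h <- med$height * exp(zh[[i]] * sqrt(log(1 + (cv / 3)^2)))
      ind <- .assemble_physiology(ages[[i]], sexes[[i]], w, h)
      if (spec$weight_class == "obese") {
        excess <- scaling$bmi_excess + 0.06 * zb[[i]] # truncation keeps > 1.02
        tb <- excess * bmi_percentile(
          ages[[i]], sexes[[i]], scaling$bmi_percentile_threshold
        )
        ind <- apply_obesity(ind, scaling = scaling, target_bmi = tb)
      }
      inds[[i]] <- ind
    }
    structure(inds, class = "pbpk_population", spec = spec)
  })
}

# standard-normal draws truncated to [lower, upper] via inverse CDF
# (fixed number of RNG calls, so population draws stay reproducible)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  p <- runif(n, stats::pnorm(lower), stats::pnorm(upper))
  mean + sd * stats::qnorm(p)
}

#' @describeIn sample_population One row per individual with organ volumes and
#'   flows spread into `vol_*` / `flow_*` columns (the CSV export layout).
#' @param x A `pbpk_population`.
#' @param ... Unused.
#' @exportS3Method tibble::as_tibble
as_tibble.pbpk_population <- function(x, ...) {
  purrr::imap(unclass(x), function(ind, i) {
    dplyr::bind_cols(
      tibble(
        id = i, age_years = ind$age_years, sex = ind$sex,
        weight_class = ind$weight_class, body_weight = ind$body_weight,
        height = ind$height, bmi = ind$bmi,
        cardiac_output = ind$cardiac_output, gfr = ind$gfr,
        hematocrit = ind$hematocrit
      ),
      tibble::as_tibble_row(setNames(
        as.list(ind$organ_volumes), paste0("vol_", names(ind$organ_volumes))
      )),
      tibble::as_tibble_row(setNames(
        as.list(ind$organ_blood_flows),
        paste0("flow_", names(ind$organ_blood_flows))
      ))
    )
  }) |> purrr::list_rbind()
}

#' @export
print.individual_physiology <- function(x, ...) {
  cat(sprintf(
    "<individual_physiology> %s, %.1f y, %s weight\n  %.1f kg, %.0f cm (BMI %.1f), CO %.0f L/h, GFR %.0f mL/min\n",
    x$sex, x$age_years, x$weight_class, x$body_weight, x$height, x$bmi,
    x$cardiac_output, x$gfr
  ))
  invisible(x)
}

# Internal invariant check used by tests and the engine.
.validate_individual <- function(ind) {
  stopifnot(
    all(ind$organ_volumes > 0),
    all(ind$organ_blood_flows >= 0),
    sum(ind$organ_blood_flows) <= ind$cardiac_output + 1e-9,
    abs(ind$bmi - ind$body_weight / (ind$height / 100)^2) < 1e-9,
    ind$gfr > 0, ind$hematocrit > 0, ind$hematocrit < 1
  )
  invisible(TRUE)
}
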