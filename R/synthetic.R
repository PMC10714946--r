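#' Specify a synthetic clinical trial
#'
#' Describes a trial-like observed dataset: subjects drawn around the
#' generating model's parameters with log-normal between-subject variability
#' on absorption (`ka`), total clearance (`cl_total`, applied jointly to the
#' renal and peptidase pathways so the urinary split is preserved) and
#' distribution volume (`v`, applied to the tissue partition scale), plus
#' multiplicative log-normal residual error on each observation.
#'
#' @param n_subjects Number of subjects.
#' @param regimen A [dose_regimen()].
#' @param n_female Number of female subjects (rest male).
#' @param age_mean_sd,weight_mean_sd `c(mean, sd)` of age (years) and body
#'   weight (kg); draws truncated at 2.5 SD and clamped to the supported age
#'   range.
#' @param iiv_cv Named CV fractions for `ka`, `cl_total`, `v` (each in
#'   \[0, 1)).
#' @param residual_cv Residual CV fraction.
#' @param sampling_times Observation times, h.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A `trial_spec`.
#' @export
trial_spec <- function(n_subjects = 56L,
                       regimen = dose_regimen(0, 5),
                       n_female = 3L,
                       age_mean_sd = c(39.4, 10.3),
                       weight_mean_sd = c(71.9, 11.1),
                       iiv_cv = c(ka = 0.25, cl_total = 0.25, v = 0.2),
                       residual_cv = 0.15,
                       sampling_times = c(
                         0, 4, 8, 12, 24, 48, 72, 96, 120, 168, 336, 504, 672
                       ),
                       seed = 1L) {
  stopifnot(n_subjects >= 1, n_female <= n_subjects)
  if (any(iiv_cv < 0) || any(iiv_cv >= 1) || residual_cv < 0 || residual_cv >= 1) {
    abort("CV fractions must lie in [0, 1).", class = "tirzepk_validation_error")
  }
  iiv <- c(ka = 0, cl_total = 0, v = 0)
  iiv[names(iiv_cv)] <- iiv_cv
  structure(
    list(
      n_subjects = as.integer(n_subjects), regimen = regimen,
      n_female = as.integer(n_female), age_mean_sd = age_mean_sd,
      weight_mean_sd = weight_mean_sd, iiv_cv = iiv,
      residual_cv = residual_cv, sampling_times = sampling_times,
      seed = as.integer(seed)
    ),
    class = "trial_spec"
  )
}

#' Generate a synthetic observed trial
#'
#' Simulates every subject with individually perturbed parameters, applies
#' residual error at the sampling times, and summarises per-subject NCA into
#' an observed PK-parameter table (arithmetic means, as clinical PK tables
#' report them).
#'
#' @param spec A [trial_spec()].
#' @param ind Baseline individual physiology for the cohort (subject weights
#'   rescale it).
#' @param drug Generating drug parameters (typically a calibrated set).
#' @param t_end Simulation horizon for NCA, h.
#' @param paths Optional named list `list(profiles =, pk_table =)` of CSV
#'   output paths.
#' @return A list of class `synthetic_trial`: `profiles` (long tibble:
#'   `subject_id`, `time_h`, `conc_ng_per_ml`), `pk_table` (per-subject NCA,
#'   long: `subject_id`, `parameter`, `value`), `summary` (parameter means and
#'   SDs), `subjects` (drawn covariates and parameter multipliers), and the
#'   generating `truth` (ka, cl_pept_factor, cl_renal).
#' @export
#' @examples
#' \donttest{
#' tr <- generate_trial(
#'   trial_spec(n_subjects = 4, seed = 11),
#'   build_individual(30, "male"), default_tirzepatide()
#' )
#' tr$summary
#' }
generate_trial <- function(spec, ind, drug, t_end = 1500, paths = NULL) {
  stopifnot(inherits(spec, "trial_spec"),
            inherits(ind, "individual_physiology"),
            inherits(drug, "drug_parameters"))
  base_model <- build_model(ind, drug)
  truth <- c(
    ka = drug$ka, cl_pept_factor = drug$cl_pept_factor,
    cl_renal = base_model$cl_renal
  )
  dose_total <- sum(spec$regimen$dose_mg)
  sd_ln <- function(cv) sqrt(log(1 + cv^2))

  withr::with_seed(spec$seed, {
    n <- spec$n_subjects
    sexes <- c(rep("female", spec$n_female), rep("male", n - spec$n_female))
    ages <- pmin(pmax(
      spec$age_mean_sd[[1]] +
        spec$age_mean_sd[[2]] * .rtruncnorm(n, 0, 1, -2.5, 2.5),
      10
    ), 80)
    weights <- pmax(
      spec$weight_mean_sd[[1]] +
        spec$weight_mean_sd[[2]] * .rtruncnorm(n, 0, 1, -2.5, 2.5),
      40
    )
    m_ka <- exp(rnorm(n, 0, sd_ln(spec$iiv_cv[["ka"]])))
    m_cl <- exp(rnorm(n, 0, sd_ln(spec$iiv_cv[["cl_total"]])))
    m_v <- exp(rnorm(n, 0, sd_ln(spec$iiv_cv[["v"]])))
    eps <- matrix(
      exp(rnorm(n * length(spec$sampling_times), 0, sd_ln(spec$residual_cv))),
      nrow = n
    )

    subjects <- tibble(
      subject_id = seq_len(n), sex = sexes, age_years = ages,
      body_weight = weights, m_ka = m_ka, m_cl = m_cl, m_v = m_v
    )

    profiles <- vector("list", n)
    pk_rows <- vector("list", n)
    for (i in seq_len(n)) {
      ind_i <- build_individual(ages[[i]], sexes[[i]],
        target_weight = weights[[i]]
      )
      drug_i <- drug
      drug_i$ka <- drug$ka * m_ka[[i]]
      drug_i$cl_pept_factor <- drug$cl_pept_factor * m_cl[[i]]
      drug_i$kp_scale <- drug$kp_scale * m_v[[i]]
      # joint clearance multiplier preserves the urinary split; renal scales
      # with the subject's GFR relative to the cohort reference as well
      drug_i$cl_renal <- base_model$cl_renal * m_cl[[i]] *
        ind_i$gfr / ind$gfr
      model_i <- build_model(ind_i, drug_i)
      dense <- simulate_profile(model_i, spec$regimen,
        t_end = t_end, dt_out = 1
      )
      pred <- stats::approx(
        dense$time_h, dense$conc_ng_per_ml,
        xout = spec$sampling_times, rule = 2
      )$y
      obs <- pred * eps[i, ]
      obs[spec$sampling_times == 0] <- 0
      profiles[[i]] <- tibble(
        subject_id = i, time_h = spec$sampling_times, conc_ng_per_ml = obs
      )
      pk <- compute_nca(
        tibble(time_h = spec$sampling_times, conc_ng_per_ml = obs),
        dose_mg = dose_total
      )
      pk_rows[[i]] <- tibble(
        subject_id = i,
        parameter = c("auc_0_inf", "auc_0_168", "cmax", "tmax", "t_half",
                      "cl_over_f"),
        value = c(pk$auc_0_inf, pk$auc_0_168, pk$cmax, pk$tmax, pk$t_half,
                  pk$cl_over_f)
      )
    }
    profiles <- purrr::list_rbind(profiles)
    pk_table <- purrr::list_rbind(pk_rows)
    summary <- pk_table |>
      group_by(.data$parameter) |>
      summarise(
        mean = mean(.data$value), sd = stats::sd(.data$value),
        .groups = "drop"
      )

    if (!is.null(paths)) {
      if (!is.null(paths$profiles)) {
        readr::write_csv(profiles, paths$profiles)
      }
      if (!is.null(paths$pk_table)) readr::write_csv(pk_table, paths$pk_table)
    }

    structure(
      list(
        profiles = profiles, pk_table = pk_table, summary = summary,
        subjects = subjects, truth = truth, spec = spec
      ),
      class = "synthetic_trial"
    )
  })
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %d subjects, %d observations\n",
    x$spec$n_subjects, nrow(x$profiles)
  ))
  print(x$summary)
  invisible(x)
}
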