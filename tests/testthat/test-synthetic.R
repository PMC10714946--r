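test_that("the noise-free limit reproduces the generating model exactly", {
  spec <- trial_spec(
    n_subjects = 3, n_female = 1,
    age_mean_sd = c(40, 0), weight_mean_sd = c(71.9, 0),
    iiv_cv = c(ka = 0, cl_total = 0, v = 0), residual_cv = 0,
    seed = 2
  )
  drug <- default_tirzepatide()
  tr <- generate_trial(spec, reference_adult(), drug)
  # every subject identical and equal to the model prediction at the grid
  ref_model <- build_model(reference_adult(), drug)
  ind <- build_individual(40, "female", target_weight = 71.9)
  drug_i <- drug
  drug_i$cl_renal <- ref_model$cl_renal * ind$gfr / reference_adult()$gfr
  base <- simulate_profile(
    build_model(ind, drug_i), spec$regimen,
    t_end = 1500, dt_out = 1
  )
  pred <- base$conc_ng_per_ml[match(spec$sampling_times, base$time_h)]
  pred[spec$sampling_times == 0] <- 0
  obs1 <- tr$profiles |> dplyr::filter(.data$subject_id == 1)
  expect_equal(obs1$conc_ng_per_ml, pred, tolerance = 1e-12)
})

test_that("generation is byte-identical under a fixed seed", {
  spec <- trial_spec(n_subjects = 4, seed = 11)
  drug <- default_tirzepatide()
  t1 <- generate_trial(spec, reference_adult(), drug)
  t2 <- generate_trial(spec, reference_adult(), drug)
  expect_identical(t1$profiles, t2$profiles)
  expect_identical(t1$pk_table, t2$pk_table)

  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  generate_trial(spec, reference_adult(), drug,
    paths = list(profiles = p1)
  )
  generate_trial(spec, reference_adult(), drug,
    paths = list(profiles = p2)
  )
  expect_identical(readLines(p1), readLines(p2))
})

test_that("trial means sit near the generating model at cohort size", {
  drug <- default_tirzepatide()
  truth_pk <- compute_nca(
    simulate_profile(
      build_model(reference_adult(), drug), dose_regimen(0, 5),
      t_end = 1500, dt_out = 1
    ), 5
  )
  spec <- trial_spec(n_subjects = 56, residual_cv = 0.15, seed = 11)
  tr <- generate_trial(spec, reference_adult(), drug)
  mean_auc <- tr$summary$mean[tr$summary$parameter == "auc_0_inf"]
  sd_auc <- tr$summary$sd[tr$summary$parameter == "auc_0_inf"]
  se <- sd_auc / sqrt(spec$n_subjects)
  expect_lt(abs(mean_auc - truth_pk$auc_0_inf), 3 * se + 0.1 * truth_pk$auc_0_inf)
})

test_that("generated means converge to the generating values as n grows", {
  # the generating value is the NCA of the noise-free model on the same
  # sparse sampling grid (the estimator the trial table uses); small CVs
  # keep the arithmetic-mean/log-normal (Jensen) offset below the tolerance
  drug <- default_tirzepatide()
  spec <- trial_spec(
    n_subjects = 400,
    age_mean_sd = c(40, 5), weight_mean_sd = c(72, 5),
    iiv_cv = c(ka = 0.1, cl_total = 0.1, v = 0.1), residual_cv = 0.01,
    seed = 29
  )
  dense <- simulate_profile(
    build_model(reference_adult(), drug), spec$regimen,
    t_end = 1500, dt_out = 1
  )
  sparse <- tibble::tibble(
    time_h = spec$sampling_times,
    conc_ng_per_ml = dense$conc_ng_per_ml[match(
      spec$sampling_times, dense$time_h
    )]
  )
  truth_pk <- compute_nca(sparse, 5)
  tr <- generate_trial(spec, reference_adult(), drug)
  for (p in c("auc_0_inf", "cmax", "t_half")) {
    gen <- tr$summary$mean[tr$summary$parameter == p]
    expect_equal(gen, truth_pk[[p]], tolerance = 0.03)
  }
})

test_that("trial specs reject impossible variability settings", {
  expect_error(trial_spec(residual_cv = 1.2), class = "tirzepk_validation_error")
  expect_error(trial_spec(iiv_cv = c(ka = -0.1)),
    class = "tirzepk_validation_error"
  )
  expect_error(trial_spec(n_subjects = 0))
})
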