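test_that("renal clearance scales linearly with the GFR and fu ratios", {
  expect_equal(scale_renal_clearance(100, 120, 0.03), 0.025)
  expect_equal(scale_renal_clearance(96, 120, 0.0236), 0.8 * 0.0236)
  expect_equal(scale_renal_clearance(120, 120, 0.0296), 0.0296)
  # linear in each ratio
  base <- scale_renal_clearance(90, 120, 0.03, 0.01, 0.01)
  expect_equal(scale_renal_clearance(180, 120, 0.03, 0.01, 0.01), 2 * base)
  expect_equal(scale_renal_clearance(90, 120, 0.06, 0.01, 0.01), 2 * base)
  expect_equal(scale_renal_clearance(90, 120, 0.03, 0.02, 0.01), 2 * base)
  expect_error(scale_renal_clearance(-1, 120, 0.03),
    class = "tirzepk_domain_error"
  )
})

test_that("extrapolation needs a calibrated model and preserves drug parameters", {
  raw <- build_model(reference_adult(), default_tirzepatide())
  child <- build_individual(11, "male")
  expect_error(extrapolate(raw, child), class = "tirzepk_state_error")

  fit <- calibrated_adult_fit()
  ped <- extrapolate(fit$model, child)
  drug_fields <- setdiff(names(unclass(fit$model$drug)), "cl_renal")
  expect_identical(
    unclass(ped$drug)[drug_fields], unclass(fit$model$drug)[drug_fields]
  )
  expect_equal(
    ped$cl_renal, fit$model$cl_renal * child$gfr / fit$model$ind$gfr
  )
})

test_that("passing the adult physiology through extrapolation is the identity", {
  fit <- calibrated_adult_fit()
  same <- extrapolate(fit$model, fit$model$ind)
  expect_equal(same$cl_renal, fit$model$cl_renal, tolerance = 1e-12)
  expect_equal(same$A, fit$model$A, tolerance = 1e-12)
})

test_that("young children overshoot the adult exposure range at the adult dose", {
  fit <- calibrated_adult_fit()
  child <- build_individual(10, "male")
  mod <- extrapolate(fit$model, child)
  prof <- simulate_profile(mod, dose_regimen(0, 5), t_end = 336)
  auc168 <- compute_nca(prof, 5)$auc_0_168
  expect_gt(auc168, reference_range()$auc_0_168[[2]])
})

test_that("obesity lowers exposure at matched age (larger body, higher clearance)", {
  fit <- calibrated_adult_fit()
  normal <- build_individual(13, "male", seed = 4)
  obese <- build_individual(13, "male", "obese", seed = 4)
  auc <- function(ind) {
    prof <- simulate_profile(
      extrapolate(fit$model, ind), dose_regimen(0, 5),
      t_end = 336
    )
    compute_nca(prof, 5)$auc_0_168
  }
  expect_lt(auc(obese), auc(normal))
})

test_that("the reference range carries the published adult bounds", {
  ref <- reference_range()
  expect_equal(ref$auc_0_168, c(43459, 63467))
  expect_equal(ref$cmax, c(305.7, 488.3))
  expect_equal(ref$tmax, c(24, 72))
  expect_error(reference_range(cmax = c(10, 5)),
    class = "tirzepk_validation_error"
  )
})

test_that("dose-band search agrees with the linear-PK hand computation", {
  fit <- calibrated_adult_fit()
  pop <- sample_population(population_spec(4, 4, c(10, 12), "normal", seed = 2))
  ref <- reference_range()
  rec <- find_dose_band(pop, fit$model, dt_out = 1)

  # linear PK: per-dose means are proportional to dose, so the qualifying set
  # follows by arithmetic from the 5 mg means alone
  m5 <- rec$per_dose |> dplyr::filter(.data$dose_mg == 5)
  doses <- rec$per_dose$dose_mg
  expected_qualifies <- vapply(doses, function(d) {
    auc <- m5$mean_auc_0_168 * d / 5
    cmax <- m5$mean_cmax * d / 5
    auc >= ref$auc_0_168[[1]] && auc <= ref$auc_0_168[[2]] &&
      cmax >= ref$cmax[[1]] && cmax <= ref$cmax[[2]]
  }, logical(1))
  expect_equal(rec$per_dose$qualifies, expected_qualifies)
  expect_equal(
    rec$per_dose$mean_auc_0_168, m5$mean_auc_0_168 * doses / 5,
    tolerance = 1e-9
  )
  if (any(expected_qualifies)) {
    expect_equal(rec$band, range(doses[expected_qualifies]))
  }
})

test_that("the fraction-inside-range statistic is available", {
  fit <- calibrated_adult_fit()
  pop <- sample_population(population_spec(3, 3, c(10, 12), "normal", seed = 2))
  rec <- find_dose_band(pop, fit$model,
    statistic = "fraction", min_fraction = 0.5, dt_out = 1
  )
  expect_true(all(c("frac_auc_in", "frac_cmax_in") %in% names(rec$per_dose)))
})

test_that("the dose-adjustment table covers all bands and stays reproducible", {
  fit <- calibrated_adult_fit()
  tab1 <- dose_adjustment_table(fit$model, n_per_sex = 2, seed = 3, dt_out = 1)
  tab2 <- dose_adjustment_table(fit$model, n_per_sex = 2, seed = 3, dt_out = 1)
  expect_equal(nrow(tab1), 6)
  expect_setequal(
    unique(tab1$age_band),
    c("children_10_12", "early_adol_12_15", "adol_15_18")
  )
  expect_identical(
    tab1 |> dplyr::select(-"detail"), tab2 |> dplyr::select(-"detail")
  )
})
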