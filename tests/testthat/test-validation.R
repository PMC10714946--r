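test_that("fold error follows the tabulated predicted/observed convention", {
  expect_equal(round(fold_error(56546, 53200), 2), 1.06)
  expect_equal(round(fold_error(113085, 90500), 2), 1.25)
  expect_equal(fold_error(123.4, 123.4), 1)
  expect_equal(
    fold_error(113085, 90500, convention = "obs_over_pred"),
    1 / fold_error(113085, 90500)
  )
  expect_error(fold_error(-1, 2), class = "tirzepk_domain_error")
  expect_error(fold_error(1, 0), class = "tirzepk_domain_error")
})

test_that("AFE is the base-10 geometric mean with the expected algebra", {
  expect_equal(afe(c(2, 0.5)), 1)
  expect_equal(
    round(afe(c(1.06, 1.25, 1.32, 1.09, 1.40, 1.34, 0.87)), 2), 1.18
  )
  expect_equal(round(afe(c(0.94, 0.80, 0.76, 0.71, 0.75, 1.15)), 2), 0.84)
  # properties: reciprocal inversion, permutation invariance, scale covariance
  withr::with_seed(5, {
    for (i in 1:20) {
      fe <- exp(rnorm(7, 0, 0.5))
      expect_equal(afe(fe) * afe(1 / fe), 1, tolerance = 1e-12)
      expect_equal(afe(sample(fe)), afe(fe), tolerance = 1e-12)
      cc <- runif(1, 0.1, 10)
      expect_equal(afe(cc * fe), cc * afe(fe), tolerance = 1e-12)
    }
  })
  expect_error(afe(numeric()), class = "tirzepk_domain_error")
  expect_error(afe(c(1, NA)), class = "tirzepk_domain_error")
  expect_error(afe(c(1, -2)), class = "tirzepk_domain_error")
})

test_that("the two-fold window is closed at both ends", {
  expect_true(two_fold_check(0.5))
  expect_true(two_fold_check(2))
  expect_false(two_fold_check(2.28))
  expect_false(two_fold_check(0.49))
  expect_equal(two_fold_check(c(1.18, 1.09, 1.04, 1.42, 0.84)), rep(TRUE, 5))
})

test_that("the bundled single-dose table reproduces every printed fold error", {
  tab <- single_dose_pk_table()
  rep <- validation_report(tab)
  per <- tidy(rep)
  printed <- c(
    # karino 2.5 / 5 / 8 mg: auc, cmax, t_half, tmax, cl_over_f
    1.06, 0.99, 1.07, 2.28, 0.94,
    1.25, 1.24, 1.04, 1.66, 0.80,
    1.32, 1.03, 1.16, 1.14, 0.76,
    # furihata 5 mg (CL/F not reported)
    1.09, 1.36, 1.01, 0.83, NA,
    # urva 5 mg
    1.40, 1.46, 1.06, 0.83, 0.71,
    # study_4 5 mg
    1.34, 0.97, 1.03, 1.67, 0.75,
    # study_5 2.5 mg
    0.87, 0.75, 0.92, 2.28, 1.15
  )
  expect_equal(round(per$fold_error, 2), printed)
  # the only out-of-window fold errors are the known Tmax excursions
  fails <- per |> dplyr::filter(!.data$pass_2fold & !is.na(.data$fold_error))
  expect_true(all(fails$parameter == "tmax"))
})

test_that("single-dose AFE per parameter matches the reported values", {
  rep <- validation_report(single_dose_pk_table())
  s <- glance(rep)
  got <- setNames(round(s$afe, 2), s$parameter)
  expect_equal(got[["auc"]], 1.18)
  expect_equal(got[["cmax"]], 1.09)
  expect_equal(got[["t_half"]], 1.04)
  expect_equal(got[["tmax"]], 1.42)
  expect_equal(got[["cl_over_f"]], 0.84)
  # the study with missing CL/F is dropped from that parameter's N
  expect_equal(s$n_used[s$parameter == "cl_over_f"], 6)
  expect_equal(s$n_used[s$parameter == "auc"], 7)
  expect_true(all(s$pass_2fold))
})

test_that("the multiple-dose table passes the two-fold qualification", {
  rep <- validation_report(multiple_dose_pk_table())
  per <- tidy(rep)
  # all non-Tmax fold errors within the window, as reported
  non_tmax <- per |> dplyr::filter(.data$parameter != "tmax")
  expect_true(all(non_tmax$pass_2fold))
  expect_equal(round(per$fold_error[[1]], 2), 0.96) # corrected first-row AUC
})
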