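test_that("default adult model lands near the reported apparent clearance", {
  mod <- build_model(reference_adult(), default_tirzepatide())
  cl_over_f <- mod$cl_total / mod$f
  ratio <- cl_over_f / 0.0442
  expect_gt(ratio, 0.5)
  expect_lt(ratio, 2)
})

test_that("urinary split is honoured by construction and in simulation", {
  mod <- build_model(reference_adult(), default_tirzepatide())
  expect_equal(mod$cl_renal / mod$cl_total, 0.66, tolerance = 1e-9)
  prof <- simulate_profile(mod, dose_regimen(0, 5), t_end = 1500)
  expect_equal(urine_fraction(prof), 0.66, tolerance = 0.005)
})

test_that("a renal-only drug excretes everything in urine", {
  drug <- default_tirzepatide()
  drug$cl_spec_peptidase <- 0
  drug$cl_renal <- 0.03
  mod <- build_model(reference_adult(), drug)
  prof <- simulate_profile(mod, dose_regimen(0, 5), t_end = 1500)
  expect_equal(urine_fraction(prof), 1.0, tolerance = 1e-9)
})

test_that("doubling peptidase concentration doubles non-renal clearance", {
  drug <- default_tirzepatide()
  drug$cl_renal <- 0.03
  m1 <- build_model(reference_adult(), drug)
  drug$peptidase_conc <- 2 * drug$peptidase_conc
  m2 <- build_model(reference_adult(), drug)
  expect_equal(sum(m2$cl_pept), 2 * sum(m1$cl_pept), tolerance = 1e-12)
  expect_equal(m2$cl_renal, m1$cl_renal)
})

test_that("one-compartment reduction reproduces the Bateman function", {
  v <- 8; cl <- 0.04; ka <- 0.0996; f <- 0.81
  mod <- one_compartment_model(v, cl, ka, f)
  for (method in c("analytic", "lsoda")) {
    prof <- simulate_profile(mod, dose_regimen(0, 5),
      t_end = 1500, dt_out = 0.5, method = method
    )
    expected <- bateman_conc(prof$time_h, 5, f, ka, cl / v, v)
    expect_lt(
      max(abs(prof$conc_ng_per_ml - expected)) / max(expected), 1e-4
    )
  }
})

test_that("analytic and stiff-solver routes agree on the whole-body model", {
  mod <- build_model(reference_adult(), default_tirzepatide())
  reg <- weekly_regimen(5, 3)
  pa <- simulate_profile(mod, reg, t_end = 600, dt_out = 1)
  pl <- simulate_profile(mod, reg, t_end = 600, dt_out = 1, method = "lsoda")
  expect_lt(
    max(abs(pa$conc_ng_per_ml - pl$conc_ng_per_ml)) /
      max(pa$conc_ng_per_ml),
    1e-6
  )
  expect_lt(check_mass_balance(pl), 1e-6)
})

test_that("mass is conserved and concentrations stay non-negative", {
  mod <- build_model(reference_adult(), default_tirzepatide())
  reg <- weekly_regimen(c(2.5, 2.5, 5, 5, 10), 5)
  prof <- simulate_profile(mod, reg, t_end = 1200)
  expect_lt(check_mass_balance(prof), 1e-9)
  expect_true(all(prof$conc_ng_per_ml >= 0))
})

test_that("a zero-dose regimen yields an identically zero profile", {
  mod <- build_model(reference_adult(), default_tirzepatide())
  prof <- simulate_profile(mod, dose_regimen(), t_end = 300)
  expect_true(all(prof$conc_ng_per_ml == 0))
  expect_equal(check_mass_balance(prof), 0)
})

test_that("exposure is dose-proportional and increases with dose", {
  mod <- build_model(reference_adult(), default_tirzepatide())
  doses <- c(1.25, 2.5, 5, 10)
  pk <- lapply(doses, function(d) {
    compute_nca(simulate_profile(mod, dose_regimen(0, d), t_end = 1500), d)
  })
  auc <- vapply(pk, `[[`, numeric(1), "auc_0_inf")
  cmax <- vapply(pk, `[[`, numeric(1), "cmax")
  expect_true(all(diff(auc) > 0))
  expect_true(all(diff(cmax) > 0))
  expect_equal(auc[[3]] / auc[[2]], 2, tolerance = 1e-6)
  expect_equal(cmax[[3]] / cmax[[2]], 2, tolerance = 1e-6)
})

test_that("weekly steady state obeys superposition of the single dose", {
  mod <- build_model(reference_adult(), default_tirzepatide())
  single <- compute_nca(
    simulate_profile(mod, dose_regimen(0, 5), t_end = 1500), 5
  )
  multi <- simulate_regimen_table(mod, "5 mg (8)")[[1]]
  ss <- compute_nca(multi, 5, window = "last_interval_168h")
  expect_equal(ss$auc_0_168, single$auc_0_inf, tolerance = 0.01)
})

test_that("regimen strings expand to the stated weekly events", {
  r8 <- parse_weekly_regimen("5 mg (8)")
  expect_equal(nrow(r8), 8)
  expect_equal(r8$time_h, 168 * 0:7)
  r4 <- parse_weekly_regimen("4.5 mg (4)")
  expect_equal(nrow(r4), 4)
  expect_equal(unique(r4$dose_mg), 4.5)
  esc <- parse_weekly_regimen("2.5 mg (2), 5 mg (2), 10 (4)")
  expect_equal(esc$dose_mg, c(2.5, 2.5, 5, 5, 10, 10, 10, 10))
  expect_error(parse_weekly_regimen("five mg"),
    class = "tirzepk_validation_error"
  )
  mod <- build_model(reference_adult(), default_tirzepatide())
  expect_identical(simulate_regimen_table(mod, list()), list())
})

test_that("regimen and simulation inputs are validated", {
  expect_error(dose_regimen(c(0, 0), c(5, 5)),
    class = "tirzepk_validation_error"
  )
  expect_error(dose_regimen(0, -5), class = "tirzepk_validation_error")
  mod <- build_model(reference_adult(), default_tirzepatide())
  expect_error(
    simulate_profile(mod, weekly_regimen(5, 4), t_end = 100),
    class = "tirzepk_validation_error"
  )
})
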