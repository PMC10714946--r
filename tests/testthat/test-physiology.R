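test_that("reference adult matches the training-cohort anthropometry", {
  adult <- build_individual(30, "male")
  expect_gt(adult$body_weight, 70)
  expect_lt(adult$body_weight, 73)
  expect_equal(adult$bmi, adult$body_weight / (adult$height / 100)^2,
    tolerance = 1e-12
  )
  # repeated deterministic construction is identical
  expect_identical(adult, build_individual(30, "male"))
})

test_that("individual invariants hold across ages, sexes and weight classes", {
  grid <- expand.grid(
    age = c(10, 12.5, 15, 18, 30, 60),
    sex = c("female", "male"),
    wc = c("normal", "obese"),
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(grid))) {
    ind <- build_individual(grid$age[[i]], grid$sex[[i]], grid$wc[[i]],
      seed = i, cv = 0.1
    )
    expect_true(all(ind$organ_volumes > 0))
    expect_true(all(ind$organ_blood_flows >= 0))
    expect_lte(sum(ind$organ_blood_flows), ind$cardiac_output + 1e-9)
    expect_equal(ind$bmi, ind$body_weight / (ind$height / 100)^2,
      tolerance = 1e-9
    )
    expect_gt(ind$gfr, 0)
    # organ masses account for total body weight (density ~1)
    expect_equal(sum(ind$organ_volumes), ind$body_weight, tolerance = 0.01)
  }
})

test_that("growth is monotone: weight and every organ volume rise with age", {
  for (sex in c("female", "male")) {
    inds <- lapply(seq(10, 18, by = 1), build_individual, sex = sex)
    w <- vapply(inds, `[[`, numeric(1), "body_weight")
    expect_true(all(diff(w) > 0))
    vols <- t(vapply(inds, function(i) i$organ_volumes, inds[[1]]$organ_volumes))
    expect_true(all(diff(vols) >= -1e-12))
  }
  # also with sampling variability at a fixed seed
  a15 <- build_individual(15, "male", seed = 3, cv = 0.1)
  a10 <- build_individual(10, "male", seed = 3, cv = 0.1)
  expect_true(all(a15$organ_volumes > a10$organ_volumes))
})

test_that("age and sex inputs are validated", {
  expect_error(build_individual(5, "male"), class = "tirzepk_domain_error")
  expect_error(build_individual(90, "male"), class = "tirzepk_domain_error")
  expect_error(build_individual(30, "other"))
})

test_that("obese individuals exceed the 95th-percentile BMI curve", {
  child <- build_individual(12, "female", "obese", seed = 7)
  expect_gt(child$bmi, bmi_percentile(12, "female", 95))
  expect_identical(child$weight_class, "obese")
})

test_that("obesity scaling grows kidney/liver by their factors and conserves mass", {
  ind <- build_individual(13, "male")
  obese <- apply_obesity(ind)
  expect_equal(
    obese$organ_volumes[["kidney"]] / ind$organ_volumes[["kidney"]], 1.15
  )
  expect_equal(
    obese$organ_volumes[["liver"]] / ind$organ_volumes[["liver"]], 1.15
  )
  expect_gt(obese$organ_volumes[["adipose"]], ind$organ_volumes[["adipose"]])
  expect_equal(obese$gfr / ind$gfr, 1.15)
  expect_equal(sum(obese$organ_volumes), obese$body_weight, tolerance = 0.01)
  # flows rescale with volumes, raising cardiac output
  expect_gt(obese$cardiac_output, ind$cardiac_output)
  expect_lte(sum(obese$organ_blood_flows), obese$cardiac_output + 1e-9)
})

test_that("identity obesity scaling with unchanged BMI leaves physiology alone", {
  ind <- build_individual(13, "male")
  s <- obesity_scaling(kidney = 1, liver = 1, lean_default = 1)
  same <- apply_obesity(ind, scaling = s, target_bmi = ind$bmi)
  expect_equal(same$organ_volumes, ind$organ_volumes, tolerance = 1e-12)
  expect_equal(same$body_weight, ind$body_weight, tolerance = 1e-12)
  expect_equal(same$gfr, ind$gfr)
})

test_that("obesity scaling rejects shrinking factors and obese inputs", {
  expect_error(obesity_scaling(kidney = 0.9), class = "tirzepk_validation_error")
  obese <- build_individual(13, "male", "obese")
  expect_error(apply_obesity(obese), class = "tirzepk_validation_error")
})

test_that("sampled populations have the requested size, sexes and age range", {
  spec <- population_spec(50, 50, c(10, 12), "normal", seed = 42)
  pop <- sample_population(spec)
  expect_length(pop, 100)
  tab <- tibble::as_tibble(pop)
  expect_equal(sum(tab$sex == "female"), 50)
  expect_equal(sum(tab$sex == "male"), 50)
  expect_true(all(tab$age_years >= 10 & tab$age_years <= 12))
})

test_that("population sampling is reproducible and obesity is guaranteed", {
  spec <- population_spec(1, 0, c(10, 10), "normal", seed = 1)
  expect_identical(sample_population(spec), sample_population(spec))

  pop <- sample_population(population_spec(8, 8, c(15, 18), "obese", seed = 9))
  for (ind in pop) {
    expect_gt(ind$bmi, bmi_percentile(ind$age_years, ind$sex, 95))
  }
})

test_that("population specs are validated", {
  expect_error(population_spec(0, 0, c(10, 12)),
    class = "tirzepk_validation_error"
  )
  expect_error(population_spec(1, 1, c(8, 12)),
    class = "tirzepk_domain_error"
  )
  expect_error(population_spec(1, 1, c(15, 25)),
    class = "tirzepk_validation_error"
  )
})
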