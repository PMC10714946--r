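# Observed adult 5 mg single-dose training targets (training-study means).
karino_targets <- function() {
  list(auc_0_inf = 90500, cmax = 397, t_half = 123)
}

reference_adult <- function() build_individual(30, "male")

# One shared calibrated adult fit: several tests exercise the calibrated
# model, and Nelder-Mead polish makes the optimum seed-insensitive.
calibrated_adult_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- calibrate(
        karino_targets(), reference_adult(),
        n_samples = 150, seed = 101
      )
    }
    cache
  }
})

# Closed-form Bateman concentration (ng/mL) for a single SC dose into a
# one-compartment model: the analytic oracle for solver and NCA.
bateman_conc <- function(t, dose_mg, f, ka, ke, v_l) {
  (f * dose_mg * 1e6 * ka) / (v_l * 1000 * (ka - ke)) *
    (exp(-ke * t) - exp(-ka * t))
}
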