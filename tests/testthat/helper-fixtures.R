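## Shared fixtures, built in code at test time.

## one subject, known parameters, rich or sparse sampling
tiny_dataset <- function(times = c(0.5, 1, 2, 6), conc = NULL,
                         wt = 12, egfr = 120, dose = 60, n_doses = 1) {
  subjects <- data.frame(id = "S1", wt = wt, height = 90, age = 2.5,
                         sex = "M", scr = 26, egfr = egfr,
                         stringsAsFactors = FALSE)
  doses <- data.frame(id = "S1", regimen(dose, 12, 1, n_doses))
  if (is.null(conc)) {
    conc <- concentration(times, cl = 5.23, vd = 11.35, doses)
  }
  obs <- data.frame(id = "S1", time = times, conc = conc,
                    stringsAsFactors = FALSE)
  pk_dataset(subjects, doses, obs)
}

## small synthetic study for estimation tests: denser sampling and a modest
## cohort keep the fits quick while leaving all parameters identifiable
small_study <- function(n_subjects = 40, obs_per_subject = 3, seed = 101,
                        truth = final_model_params()) {
  cfg <- generator_config(n_subjects = n_subjects,
                          target_n_obs = n_subjects * obs_per_subject,
                          truth = truth)
  set.seed(seed)
  cohort <- generate_cohort(cfg)
  generate_dataset(cohort, cfg)
}

expect_rel_error <- function(actual, expected, tol) {
  testthat::expect_lt(abs(actual - expected) / abs(expected), tol)
}
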