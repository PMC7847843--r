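test_that("stepwise thresholds equal the chi-square critical values", {
  expect_equal(OFV_FORWARD, 3.84, tolerance = 1e-3)
  expect_equal(OFV_BACKWARD, 6.63, tolerance = 1e-3)
  expect_equal(OFV_FORWARD, stats::qchisq(0.95, 1), tolerance = 1e-12)
  expect_equal(OFV_BACKWARD, stats::qchisq(0.99, 1), tolerance = 1e-12)
})

test_that("correlation screen flags collinear pairs and handles degeneracies", {
  set.seed(8)
  cohort <- generate_cohort(generator_config())
  scr <- correlation_screen(cohort[, c("wt", "height", "age", "kf")])
  ## the generator builds in the weight-height correlation
  expect_true(any(scr$exclusive_pairs$cov1 == "wt" &
                    scr$exclusive_pairs$cov2 == "height"))
  expect_gt(abs(scr$correlation["wt", "height"]), 0.5)
  expect_equal(diag(scr$correlation), rep(1, 4), ignore_attr = TRUE)
  ## independently sampled covariates are admissible
  set.seed(9)
  indep <- data.frame(a = rnorm(500), b = rnorm(500))
  scr2 <- correlation_screen(indep)
  expect_equal(nrow(scr2$exclusive_pairs), 0L)
  ## constant column dropped with a warning
  expect_warning(correlation_screen(data.frame(a = rnorm(20), b = 1,
                                               c = rnorm(20))),
                 "constant")
})

test_that("forward step includes a planted effect and respects exclusions", {
  res <- small_study(n_subjects = 30, obs_per_subject = 3, seed = 21)
  ds <- res$dataset
  base <- fit_foce(ds, base_model_spec(), seed = 1, compute_se = FALSE,
                   compute_residuals = FALSE)
  cands <- data.frame(param = c("cl", "cl"), cov = c("wt", "scr"),
                      form = "power",
                      ref = c(stats::median(ds$subjects$wt),
                              stats::median(ds$subjects$scr)),
                      stringsAsFactors = FALSE)
  fs <- forward_step(ds, base, cands, seed = 1)
  ## the generating model has a strong weight effect on clearance
  expect_equal(fs$selected$cov, "wt")
  expect_lte(min(fs$trace$delta_ofv), -OFV_FORWARD)
  ## empty candidate list: nothing to add
  none <- forward_step(ds, base, cands[0, ], seed = 1)
  expect_null(none$selected)
  ## exclusivity: a candidate correlated with an in-model covariate is
  ## never fitted
  fit_wt <- fs$fit
  excl <- data.frame(cov1 = "wt", cov2 = "height", r = 0.9)
  cands2 <- data.frame(param = "cl", cov = "height", form = "power",
                       ref = stats::median(ds$subjects$height),
                       stringsAsFactors = FALSE)
  fs2 <- forward_step(ds, fit_wt, cands2, exclusive_pairs = excl, seed = 1)
  expect_null(fs2$selected)
  expect_null(fs2$trace)
})

test_that("stepwise search recovers planted covariates and drops noise", {
  res <- small_study(n_subjects = 60, obs_per_subject = 3, seed = 31)
  ds <- res$dataset
  cands <- data.frame(
    param = c("cl", "vd", "cl"), cov = c("wt", "wt", "scr"), form = "power",
    ref = c(12, 12, stats::median(ds$subjects$scr)),
    stringsAsFactors = FALSE)
  sw <- stepwise_search(ds, base_model_spec(), cands, seed = 1)
  final_covs <- gcvppk:::spec_covariates(sw$final_spec)
  expect_true(any(final_covs$param == "cl" & final_covs$cov == "wt"))
  expect_true(any(final_covs$param == "vd" & final_covs$cov == "wt"))
  expect_false(any(final_covs$cov == "scr"))
  ## trace is Table-style: base row plus one row per decision, OFV drops
  ## at forward steps
  expect_equal(sw$trace$decision[1], "base model")
  fwd <- sw$trace[grepl("forward", sw$trace$decision), ]
  expect_true(all(fwd$delta_ofv <= -OFV_FORWARD))
  ## no candidates: base model unchanged
  sw0 <- stepwise_search(ds, base_model_spec(), cands[0, ], seed = 1)
  expect_equal(nrow(sw0$trace), 1L)
  expect_equal(gcvppk:::model_label(sw0$final_spec), "base")
})
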