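test_that("penalized individual -2LL matches hand-computed density terms", {
  ## choose the dose so the model prediction at t = 1 is exactly 4.0, then
  ## the data term for y = 4.4 under proportional error sigma = 0.0823 is
  ## ln(2 pi) + 2 ln(0.0823 * 4) + (0.4 / 0.3292)^2
  cl <- 5.23; vd <- 11.35; ke <- cl / vd
  amt <- 4.0 / ((1 / cl) * (1 - exp(-ke)))
  ds <- tiny_dataset(times = 1, conc = 4.4, dose = amt)
  spec <- pk_model_spec(error = "proportional", iiv = c(cl = FALSE, vd = FALSE))
  params <- list(theta = c(tv_cl = cl, tv_vd = vd), omega = c(cl = 0, vd = 0),
                 sigma = c(prop = 0.0823))
  val <- individual_neg2ll(c(0, 0), ds, "S1", spec, params)
  expect_equal(val, log(2 * pi) + 2 * log(0.0823 * 4) + (0.4 / (0.0823 * 4))^2,
               tolerance = 1e-10)
  expect_equal(val, 1.0920, tolerance = 1e-3)
  ## y = f exactly: residual term vanishes
  ds2 <- tiny_dataset(times = 1, conc = 4.0, dose = amt)
  expect_equal(individual_neg2ll(c(0, 0), ds2, "S1", spec, params),
               log(2 * pi) + 2 * log(0.0823 * 4), tolerance = 1e-10)
  ## active etas add the prior terms: at eta = 0 just the normalizing constant
  params3 <- params; params3$omega <- c(cl = 0.2, vd = 0.5)
  spec3 <- pk_model_spec(error = "proportional")
  expect_equal(individual_neg2ll(c(0, 0), ds2, "S1", spec3, params3) -
                 individual_neg2ll(c(0, 0), ds2, "S1", spec, params),
               2 * log(2 * pi) + 2 * log(0.2) + 2 * log(0.5),
               tolerance = 1e-10)
})

test_that("FOCE OFV is exact when the hierarchy is degenerate (omega = 0)", {
  res <- small_study(n_subjects = 12, seed = 42)
  ds <- res$dataset
  params <- final_model_params(omega_cl = 0, omega_vd = 0)
  spec <- final_model_spec()
  ofv <- foce_ofv(ds, spec, params)
  ## independent arithmetic: -2 log L of the fixed-effect model
  th <- theta_final()
  s <- ds$subjects
  direct <- 0
  for (i in seq_len(nrow(s))) {
    cl <- final_cl(th, s$wt[i], s$kf[i])
    vd <- final_vd(th, s$wt[i])
    obs <- ds$observations[ds$observations$id == s$id[i] &
                             !ds$observations$below_loq, ]
    dos <- ds$doses[ds$doses$id == s$id[i], ]
    f <- concentration(obs$time, cl, vd, dos)
    g2 <- (0.0823 * f)^2
    direct <- direct + sum(log(2 * pi) + log(g2) + (obs$conc - f)^2 / g2)
  }
  expect_equal(ofv, direct, tolerance = 1e-8)
})

test_that("Laplace marginal matches the closed form for a linear model", {
  ## y_ij = a + b eta_i + eps, additive error: the marginal is Gaussian with
  ## covariance sigma^2 I + b^2 omega^2 J, computable exactly
  a <- 2.0; b <- 1.5; omega <- 0.7; sigma <- 0.3
  n_subj <- 4; n_obs_i <- 3
  set.seed(99)
  eta_true <- rnorm(n_subj, 0, omega)
  y <- as.vector(vapply(seq_len(n_subj), function(i)
    a + b * eta_true[i] + rnorm(n_obs_i, 0, sigma), numeric(n_obs_i)))
  obs_subj <- rep(seq_len(n_subj), each = n_obs_i)
  pred_fun <- function(eta_mat) a + b * eta_mat[obs_subj, 1]
  modes <- gcvppk:::inner_modes(
    pred_fun, y, obs_subj, n_subj, omega_sd = c(omega, 0),
    sigma = c(add = sigma), error = "additive",
    active = c(TRUE, FALSE))
  ofv <- gcvppk:::laplace_ofv(modes, c(TRUE, FALSE))
  V <- diag(sigma^2, n_obs_i) + b^2 * omega^2
  direct <- 0
  for (i in seq_len(n_subj)) {
    r <- y[obs_subj == i] - a
    direct <- direct + n_obs_i * log(2 * pi) + determinant(V)$modulus +
      drop(r %*% solve(V, r))
  }
  expect_equal(ofv, as.numeric(direct), tolerance = 1e-6)
})

test_that("OFV of a full model never exceeds that of a nested reduction", {
  res <- small_study(n_subjects = 15, seed = 5)
  base <- fit_foce(res$dataset, base_model_spec(), seed = 1,
                   compute_se = FALSE, compute_residuals = FALSE)
  full_spec <- pk_model_spec(
    cl_terms = data.frame(cov = "wt", form = "power", ref = 12),
    error = "proportional")
  full <- fit_foce(res$dataset, full_spec, seed = 1, compute_se = FALSE,
                   compute_residuals = FALSE)
  expect_lte(full$ofv, base$ofv + 1e-4)
})

test_that("empirical Bayes estimates shrink to zero and recover rich data", {
  ## no quantifiable observations: posterior mode is the prior mode
  subjects <- data.frame(id = c("A", "B"), wt = c(10, 14), height = c(80, 95),
                         age = c(1, 3), sex = c("M", "F"), scr = c(20, 30),
                         egfr = c(100, 110), stringsAsFactors = FALSE)
  doses <- data.frame(id = c("A", "B"), time = 0, amount = c(50, 70),
                      duration = 1)
  obs <- data.frame(id = "B", time = 2, conc = 3.0)
  ds <- pk_dataset(subjects, doses, obs)
  eb <- empirical_bayes(ds, final_model_spec(), final_model_params())
  expect_equal(eb$eta_cl[eb$id == "A"], 0)
  expect_equal(eb$eta_vd[eb$id == "A"], 0)
  ## omega -> 0 shrinks every EBE to 0 regardless of data
  eb0 <- empirical_bayes(ds, final_model_spec(),
                         final_model_params(omega_cl = 1e-6, omega_vd = 1e-6))
  expect_lt(max(abs(c(eb0$eta_cl, eb0$eta_vd))), 1e-3)
  ## dense low-noise data pins the known random effects
  truth <- final_model_params(sigma_prop = 0.02)
  cfg <- generator_config(n_subjects = 1, target_n_obs = 1, truth = truth)
  set.seed(11)
  cohort <- generate_cohort(cfg)
  th <- theta_final()
  eta_known <- c(0.2, -0.1)
  cl_i <- final_cl(th, cohort$wt, cohort$kf) * exp(eta_known[1])
  vd_i <- final_vd(th, cohort$wt) * exp(eta_known[2])
  reg <- regimen(5 * cohort$wt, 12, 1, n_doses = 6)
  times <- sort(runif(50, 0.25, 70))
  f <- concentration(times, cl_i, vd_i, reg)
  conc <- f * (1 + rnorm(50, 0, 0.02))
  ds_rich <- pk_dataset(cohort[, c("id", "wt", "height", "age", "sex",
                                   "scr", "egfr")],
                        data.frame(id = cohort$id, reg),
                        data.frame(id = cohort$id, time = times, conc = conc))
  eb_rich <- empirical_bayes(ds_rich, final_model_spec(), truth)
  expect_equal(eb_rich$eta_cl, eta_known[1], tolerance = 0.02)
  expect_equal(eb_rich$eta_vd, eta_known[2], tolerance = 0.1)
})

test_that("information criteria identities reproduce printed triples", {
  ## AIC = OFV + 2 k and BIC = OFV + ln(138) k recover the candidate-model
  ## table exactly, with k inferred from the AIC-OFV gap
  triples <- data.frame(
    ofv = c(311.74, 298.25, 312.02, 306.98, 332.86, 298.85, 309.25),
    aic = c(323.74, 308.25, 324.02, 320.98, 350.86, 316.85, 327.25),
    bic = c(341.31, 322.89, 341.58, 341.47, 377.2, 343.19, 353.59))
  k <- (triples$aic - triples$ofv) / 2
  expect_equal(k, c(6, 5, 6, 7, 9, 9, 9))
  expect_equal(triples$ofv + 2 * k, triples$aic, tolerance = 1e-9)
  expect_equal(triples$ofv + log(138) * k, triples$bic, tolerance = 0.011)
  ## the fitted object uses the same identities
  res <- small_study(n_subjects = 10, seed = 2)
  fit <- fit_foce(res$dataset, base_model_spec(), seed = 1,
                  compute_se = FALSE, compute_residuals = FALSE)
  expect_equal(fit$aic, fit$ofv + 2 * fit$n_par)
  expect_equal(fit$bic, fit$ofv + log(fit$n_obs) * fit$n_par)
  expect_equal(fit$n_par, 5)  # tv_cl, tv_vd, omega_cl, omega_vd, sigma
})

test_that("sparse-design fit recovers the generating typical values", {
  res <- small_study(n_subjects = 40, obs_per_subject = 3, seed = 101)
  fit <- fit_foce(res$dataset, final_model_spec(), seed = 1,
                  compute_residuals = FALSE)
  expect_true(fit$converged)
  expect_rel_error(fit$estimates[["tv_cl"]], 5.23, 0.15)
  expect_rel_error(fit$estimates[["tv_vd"]], 11.35, 0.25)
  expect_rel_error(fit$estimates[["beta_cl_wt"]], 1.02, 0.35)
  ## standard errors exist and are positive
  expect_true(all(is.finite(fit$se_pct)))
  expect_true(all(fit$se_pct > 0))
})

test_that("CWRES behave like standardized residuals under the true model", {
  res <- small_study(n_subjects = 40, obs_per_subject = 3, seed = 77)
  ## conditioning on the generating parameters isolates the residual check
  ## from estimation error
  design_fit <- fit_foce(res$dataset, final_model_spec(),
                         inits = final_model_params(), seed = 1,
                         compute_se = FALSE)
  cw <- cwres(design_fit)$cwres
  expect_true(all(is.finite(cw)))
  expect_gte(mean(abs(cw) <= 3), 0.99)
  expect_lt(abs(mean(cw)), 0.25)
  ## single-observation subject, additive error, no IIV: CWRES = (y - f)/sigma
  cl <- 5.23; vd <- 11.35; ke <- cl / vd
  amt <- 4.0 / ((1 / cl) * (1 - exp(-ke)))
  ds1 <- tiny_dataset(times = 1, conc = 4.4, dose = amt)
  spec_add <- pk_model_spec(error = "additive",
                            iiv = c(cl = FALSE, vd = FALSE))
  params_add <- list(theta = c(tv_cl = cl, tv_vd = vd),
                     omega = c(cl = 0, vd = 0), sigma = c(add = 0.25))
  design <- gcvppk:::build_design(ds1)
  cw1 <- gcvppk:::compute_cwres(design, spec_add, params_add,
                                matrix(0, 1, 2), 4.0)
  expect_equal(cw1, 0.4 / 0.25, tolerance = 1e-6)
})
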