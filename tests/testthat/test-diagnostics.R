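test_that("bootstrap bias formula reproduces the published table arithmetic", {
  ## every row of the final-parameter table: bias recomputed from its own
  ## median and estimate columns matches the printed bias column
  est <- c(11.35, 5.23, 0.80, 0.92, 1.02, 65.78, 12.90, 8.23)
  med <- c(11.26, 5.17, 0.79, 0.97, 0.98, 63.79, 13.11, 8.37)
  printed <- c(-0.79, -1.15, -1.25, 5.43, -3.92, -3.03, 1.63, 1.70)
  expect_equal(bootstrap_bias(med, est), printed, tolerance = 0.011)
  expect_equal(bootstrap_bias(5.17, 5.23), -1.15, tolerance = 0.01)
})

test_that("subject bootstrap brackets the reference estimates", {
  res <- small_study(n_subjects = 25, obs_per_subject = 3, seed = 55)
  fit <- fit_foce(res$dataset, final_model_spec(),
                  inits = final_model_params(), seed = 1,
                  compute_se = FALSE, compute_residuals = FALSE)
  bs <- bootstrap_model(res$dataset, fit, n_replicates = 8, seed = 2)
  expect_gte(bs$n_converged, 6)
  s <- bs$summary
  expect_true(all(s$p2.5 <= s$boot_median & s$boot_median <= s$p97.5))
  expect_true(all(is.finite(s$bias_pct)))
  ## typical clearance: reference estimate inside the percentile interval
  row_cl <- s[s$parameter == "tv_cl", ]
  expect_gte(row_cl$estimate, row_cl$p2.5 - 1e-9)
  expect_lte(row_cl$estimate, row_cl$p97.5 + 1e-9)
  ## bias consistent with its own columns
  expect_equal(s$bias_pct, 100 * (s$boot_median - s$estimate) / s$estimate)
})

test_that("VPC calibrates under the true model and collapses at n_sim = 1", {
  res <- small_study(n_subjects = 60, obs_per_subject = 3, seed = 66)
  fit <- list(spec = final_model_spec(), params = final_model_params())
  ## calibration check on data simulated at the fixed design times: rows
  ## below the quantification limit drop out of the observed side exactly
  ## as the VPC conditions its simulated percentiles, so ~95% of observed
  ## percentile points should fall inside their 95% bands (pooled over
  ## replicate datasets)
  set.seed(660)
  sim <- simulate_replicates(res$dataset, fit$spec, fit$params, 4)
  remake <- function(conc) {
    obs <- res$dataset$observations
    obs$conc <- pmax(conc, 0)
    pk_dataset(res$dataset$subjects[, c("id", "wt", "height", "age",
                                        "sex", "scr", "egfr")],
               res$dataset$doses, obs[, c("id", "time", "conc")])
  }
  cov_by_rep <- vapply(1:4, function(k) {
    vpc(remake(sim[, k]), fit, n_sim = 200, seed = 3)$coverage
  }, numeric(1))
  expect_gte(mean(cov_by_rep), 0.9)
  ## on the generator's own data (with its informative quantifiable-time
  ## redraw, which a fixed-design VPC cannot reproduce) most points still
  ## sit inside their bands
  v <- vpc(res$dataset, fit, n_sim = 200, seed = 3)
  expect_gte(v$coverage, 0.75)
  tab <- v$table
  expect_true(all(tab$band_lo <= tab$band_hi))
  ## percentile curves ordered within each bin
  for (b in unique(tab$bin)) {
    o <- tab$observed[tab$bin == b][order(tab$percentile[tab$bin == b])]
    expect_true(all(diff(o) >= 0))
  }
  ## single simulation: the band collapses onto the simulated percentiles
  ds <- res$dataset
  v1 <- vpc(ds, fit, n_sim = 1, seed = 3)
  expect_equal(v1$table$band_lo, v1$table$band_hi)
  ## bands widen with sigma (on average: between-subject variability
  ## dominates the profile spread, so the residual contribution is modest)
  infl <- final_model_params(sigma_prop = 3 * 0.0823)
  v3 <- vpc(ds, list(spec = final_model_spec(), params = infl),
            n_sim = 200, seed = 3)
  expect_gt(mean(v3$table$band_hi - v3$table$band_lo),
            mean(v$table$band_hi - v$table$band_lo))
})

test_that("NPDE is calibrated under the true model and detects bias", {
  res <- small_study(n_subjects = 200, obs_per_subject = 3, seed = 88)
  fit <- list(spec = final_model_spec(), params = final_model_params())
  nd <- npde(res$dataset, fit, n_sim = 600, seed = 4)
  v <- nd$npde[!is.na(nd$npde)]
  expect_lt(abs(mean(v)), 0.1)
  expect_lt(abs(stats::var(v) - 1), 0.15)
  expect_gt(nd$p_global, 0.05)
  expect_equal(nd$p_global,
               min(1, 3 * min(nd$p_wilcoxon, nd$p_variance, nd$p_shapiro)))
  ## +50% clearance bias shifts every prediction: the location test fires
  biased <- final_model_params(theta_final(theta_cl = 5.23 * 1.5))
  nd_b <- npde(res$dataset, list(spec = final_model_spec(), params = biased),
               n_sim = 300, seed = 4)
  expect_lt(nd_b$p_wilcoxon, 0.01)
})
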