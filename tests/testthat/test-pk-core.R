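## independent oracle: numerical integration of the one-compartment ODE
## dA/dt = in(t) - ke A, concentration = A/Vd
ode_conc <- function(times, cl, vd, doses) {
  testthat::skip_if_not_installed("deSolve")
  rate_at <- function(t) {
    sum(doses$amount / doses$duration *
          (t >= doses$time & t < doses$time + doses$duration))
  }
  f <- function(t, y, parms) list(rate_at(t) - (cl / vd) * y)
  grid <- sort(unique(c(0, times, doses$time, doses$time + doses$duration)))
  out <- deSolve::lsoda(c(A = 0), grid, f, NULL, rtol = 1e-10, atol = 1e-12)
  out[match(times, out[, "time"]), "A"] / vd
}

test_that("closed-form infusion profile matches the ODE oracle", {
  doses <- regimen(60, 12, 1, n_doses = 1)
  cl <- 5.23; vd <- 11.35
  tt <- c(0.25, 0.5, 1, 1.5, 3, 6, 12)
  expect_equal(concentration(tt, cl, vd, doses), ode_conc(tt, cl, vd, doses),
               tolerance = 1e-7)
  ## frozen worked values: end of a 1-h 60-mg infusion, and 11 h later
  expect_equal(concentration(1, cl, vd, doses), 4.236, tolerance = 1e-3)
  expect_equal(concentration(12, cl, vd, doses), 0.0266, tolerance = 1e-2)
  expect_equal(concentration(0, cl, vd, doses), 0)
  ## multiple doses, multiple observation times
  reg5 <- regimen(60, 12, 1, n_doses = 5)
  tt5 <- c(1, 13, 25, 49.5, 55)
  expect_equal(concentration(tt5, cl, vd, reg5), ode_conc(tt5, cl, vd, reg5),
               tolerance = 1e-7)
})

test_that("superposition, continuity and dose proportionality hold", {
  cl <- 3; vd <- 20
  reg3 <- regimen(100, 8, 0.5, n_doses = 3)
  tt <- seq(0.1, 30, by = 0.37)
  single <- lapply(seq_len(3), function(k) {
    d1 <- reg3[k, , drop = FALSE]
    concentration(tt, cl, vd, d1)
  })
  expect_equal(concentration(tt, cl, vd, reg3), Reduce(`+`, single),
               tolerance = 1e-12)
  ## continuity at infusion end
  eps <- 1e-9
  expect_equal(concentration(0.5 - eps, cl, vd, reg3),
               concentration(0.5 + eps, cl, vd, reg3), tolerance = 1e-6)
  ## linear scaling with dose
  reg2x <- regimen(200, 8, 0.5, n_doses = 3)
  expect_equal(concentration(tt, cl, vd, reg2x),
               2 * concentration(tt, cl, vd, reg3), tolerance = 1e-12)
  ## monotone decay after the final infusion
  post <- concentration(seq(16.5, 40, by = 0.5), cl, vd, reg3)
  expect_true(all(diff(post) < 0))
})

test_that("steady-state AUC24 identity agrees with trapezoidal integration", {
  cl <- 5.23
  expect_equal(steady_state_auc24(120, cl), 120 / 5.23)
  expect_equal(steady_state_auc24(0, cl), 0)
  expect_equal(steady_state_auc24(240, cl), 2 * steady_state_auc24(120, cl))
  ## trapezoid over a steady-state day converges to daily dose / CL
  vd <- 11.35
  t_ss <- steady_state_start(cl, vd, 12)
  reg <- regimen(60, 12, 1, n_doses = (t_ss + 24) / 12 + 2)
  tt <- seq(t_ss, t_ss + 24, length.out = 2001)
  cc <- concentration(tt, cl, vd, reg)
  trap <- sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
  expect_equal(trap, steady_state_auc24(120, cl), tolerance = 1e-3)
  expect_error(steady_state_auc24(120, 0), "positive")
})

test_that("exposure metrics: cmax at infusion end, threshold times consistent", {
  cl <- 5.23; vd <- 11.35
  t_ss <- steady_state_start(cl, vd, 12)
  reg <- regimen(60, 12, 1, n_doses = (t_ss + 24) / 12 + 2)
  m <- exposure_metrics(cl, vd, reg, c(t_ss, t_ss + 24),
                        thresholds = c(0, 0.5, 100))
  expect_equal(m$cmax, 4.24, tolerance = 2e-2)
  expect_gte(m$cmax, m$cmin)
  expect_equal(m$auc24, 120 / cl, tolerance = 2e-3)
  ## threshold 0: above whenever drug present; above cmax: never
  expect_equal(unname(m$time_above[["0"]]), 24)
  expect_equal(unname(m$time_above[["100"]]), 0)
  ## time above is non-increasing in the threshold
  thr <- c(0.025, 0.1, 0.5, 1.5, 3)
  ta <- exposure_metrics(cl, vd, reg, c(t_ss, t_ss + 24), thr)$time_above
  expect_true(all(diff(ta) <= 1e-9))
  expect_true(all(ta <= 24 + 1e-9))
  ## cross-check one threshold against a dense-grid count
  tt <- seq(t_ss, t_ss + 24, length.out = 200001)
  frac <- mean(concentration(tt, cl, vd, reg) > 0.5) * 24
  expect_equal(unname(ta[["0.5"]]), frac, tolerance = 1e-3)
  expect_error(exposure_metrics(cl, vd, reg, c(10, 10)), "window")
})
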