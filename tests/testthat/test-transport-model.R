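test_that("shape factor: small-bead limit, interior maximum, and direct values", {
  expect_lt(shape_factor(1e-8), 1e-12)
  expect_equal(shape_factor(1 / pi), 4 * exp(-2))
  ## unique interior maximum at beta = 1/pi
  beta <- seq(0.01, 0.49, by = 0.005)
  g <- shape_factor(beta)
  expect_equal(beta[which.max(g)], 1 / pi, tolerance = 0.01)
  expect_lt(max(g[abs(beta - 1 / pi) > 0.02]), 4 * exp(-2))
  ## the reference bead/pitch combination, by direct arithmetic
  b <- 1.4 / 8
  expect_equal(shape_factor(b), (2 * pi * b)^2 * exp(-2 * pi * b))
  expect_error(shape_factor(0), "beta")
})

test_that("coupling calibration round-trips through the critical frequency", {
  beta <- 1.4 / 8
  k <- calibrate_coupling(27, beta)
  p <- transport_params(kappa_s = k)
  expect_equal(critical_frequency(p), 27)
  ## linearity
  expect_equal(calibrate_coupling(54, beta), 2 * k)
  ## zero coupling transports nothing
  expect_equal(critical_frequency(transport_params(kappa_s = 0)), 0)
  expect_error(critical_frequency(transport_params()), "uncalibrated")
  ## fc is maximal over beta at beta = 1/pi for fixed kappa
  fcs <- sapply(seq(0.05, 0.45, by = 0.01), function(b)
    critical_frequency(transport_params(r_um = b * 8, kappa_s = k)))
  expect_equal(seq(0.05, 0.45, by = 0.01)[which.max(fcs)], 1 / pi,
               tolerance = 0.01)
})

test_that("species measured separately calibrate to different couplings", {
  beta <- 1.4 / 8
  k_mono <- calibrate_coupling(27, beta)    # single beads on C
  k_dimer <- calibrate_coupling(22.5, beta) # dimers on C
  expect_false(isTRUE(all.equal(k_mono, k_dimer)))
  expect_equal(k_dimer / k_mono, 22.5 / 27)
})

test_that("closed-form velocity: locked branch, continuity, and slipping values", {
  expect_equal(closed_form_velocity(10, 27, 8), 80)
  ## continuity at the knee from both branches
  expect_equal(closed_form_velocity(27, 27, 8), 27 * 8)
  expect_equal(closed_form_velocity(27 + 1e-12, 27, 8), 27 * 8,
               tolerance = 1e-6)
  ## v(2 fc) = (2 - sqrt(3)) fc d
  expect_equal(closed_form_velocity(54, 27, 8), (2 - sqrt(3)) * 27 * 8)
  ## nonincreasing above the knee, vanishing at high frequency
  f <- seq(27, 2000, by = 1)
  v <- closed_form_velocity(f, 27, 8)
  expect_true(all(diff(v) <= 1e-9))
  ## asymptotically v ~ fc^2 d / (2 f) -> 0
  expect_lt(closed_form_velocity(1e5, 27, 8), 0.03)
  expect_error(closed_form_velocity(-1, 27, 8), ">= 0")
})

test_that("immobilization frequency: closed-form 10 percent rule gives 5.05 fc", {
  prof <- closed_form_profile(seq(1, 200, by = 0.25), 27, 8)
  fi <- immobilization_frequency(prof)
  ## algebraic inversion: f - sqrt(f^2 - fc^2) = 0.1 fc  =>  f = 5.05 fc
  expect_equal(as.numeric(fi), 5.05 * 27, tolerance = 1e-3)
  ## degenerate threshold: fraction = 1 returns the argmax frequency
  fi1 <- immobilization_frequency(prof, fraction = 1)
  expect_equal(as.numeric(fi1), 27, tolerance = 0.3)
  ## sweep that never decays is censored
  expect_warning(fi2 <- immobilization_frequency(
    closed_form_profile(seq(1, 20, 1), 27, 8)), "never")
  expect_true(attr(fi2, "censored"))
})

test_that("immobilization crossing is linearly interpolated between samples", {
  ## synthetic monotone profile crossing 10 percent of max between samples
  prof <- data.frame(freq_hz = c(1, 2, 3, 4), v_um_s = c(100, 60, 14, 6))
  fi <- immobilization_frequency(prof)
  ## threshold 10: crosses between f = 3 (v = 14) and f = 4 (v = 6)
  expect_equal(as.numeric(fi), 3 + (10 - 14) / (6 - 14), tolerance = 1e-12)
})

test_that("Omega reproduces the printed worked examples and rejects inconsistency", {
  expect_equal(omega_ratio(22.5, 30), 0.75)
  expect_equal(omega_ratio(16.5, 25), 0.66)
  expect_equal(omega_ratio(10, 10), 1)
  expect_error(omega_ratio(31, 30), "inconsistent")
  expect_error(omega_ratio(0, 10), "> 0")
})

test_that("critical frequency is recovered from noisy closed-form profiles", {
  freqs <- seq(1, 60, by = 1.5)
  pr <- closed_form_profile(freqs, 27, 8, noise_sd = 0.05, seed = 11)
  fit <- estimate_critical_frequency(pr, 8, method = "fit")
  expect_equal(as.numeric(fit), 27, tolerance = 0.05 * 27)
  ## exact profile: threshold estimator finds the knee
  thr <- estimate_critical_frequency(closed_form_profile(freqs, 27, 8), 8)
  expect_equal(as.numeric(thr), 27, tolerance = 1.5)
  ## all-locked profile is censored
  expect_warning(cns <- estimate_critical_frequency(
    closed_form_profile(seq(1, 20, 1), 27, 8), 8), "divergence")
  expect_true(attr(cns, "censored"))
})

test_that("profile characteristics bundle fc, fi and Omega coherently", {
  prof <- closed_form_profile(seq(1, 200, by = 0.5), 27, 8)
  ch <- profile_characteristics(prof, 8)
  expect_s3_class(ch, "nlm_freqchar")
  expect_equal(ch$fc_hz, 27, tolerance = 1)
  expect_equal(ch$fi_hz / ch$fc_hz, 5.05, tolerance = 0.05)
  expect_equal(ch$omega, ch$fc_hz / ch$fi_hz)
})

test_that("transport params enforce physical invariants", {
  expect_error(transport_params(r_um = 5, d_um = 8), "beta")
  expect_error(transport_params(eta_Pa_s = 0), "viscosity")
  p <- transport_params(r_um = 1.4, d_um = 8)
  expect_equal(p$beta, 0.175)
})
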