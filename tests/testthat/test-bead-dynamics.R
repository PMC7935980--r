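test_that("drag coefficients follow the Stokes closed forms", {
  b <- bead_spec()
  expect_equal(drag_coefficient(b, 1e-3), 6 * pi * 1e-3 * 1.4e-6)
  d <- dimer_spec(b)
  expect_equal(drag_coefficient(d, 1e-3), 2 * drag_coefficient(b, 1e-3))
  ## halving viscosity halves the drag
  expect_equal(drag_coefficient(b, 5e-4), drag_coefficient(b, 1e-3) / 2)
  ## two-sphere rigid rotor about the dimer center
  expect_equal(drag_coefficient(d, 1e-3, "rotation"),
               2 * 6 * pi * 1e-3 * 1.4e-6 * (1.4e-6)^2)
  expect_error(drag_coefficient(b, 1e-3, "rotation"), "dimers")
})

test_that("bead moments stay below saturation at the working fields", {
  b <- bead_spec()
  ## linear moment at the strongest landscape field (< 5 mT) is far below
  ## the saturation cap chi V B_sat / mu0 = msat * mass
  expect_gt(b$b_sat_T, 5e-3)
})

test_that("magnetic force vanishes on a uniform field and adds per dimer bead", {
  arr <- array_spec(shape_spec("square", 5), n_x = 1, n_y = 1,
                    magnetization_A_m = 1e-12)
  ls <- compute_landscape(arr, ext_default(), 0, window_um = c(-4, 4, -4, 4))
  F0 <- magnetic_force(bead_spec(), ls, c(0.5, 0.5))
  expect_lt(sqrt(sum(F0$force_N^2)), 1e-25)

  arrC <- default_array("C")
  lsC <- compute_landscape(arrC, ext_default(), 0,
                           window_um = c(-8, 8, -4, 4), periodic = TRUE)
  b <- bead_spec()
  dm <- dimer_spec(b)
  r_um <- 1.4
  Fd <- magnetic_force(dm, lsC, c(2.3, 0.2))
  F1 <- magnetic_force(b, lsC, c(2.3, 0.2 + r_um))
  F2 <- magnetic_force(b, lsC, c(2.3, 0.2 - r_um))
  expect_equal(Fd$force_N, F1$force_N + F2$force_N)
  expect_error(magnetic_force(b, lsC, c(50, 0)), "outside")
})

test_that("interpolated force matches a finite-difference of V chi |B|^2 / (2 mu0)", {
  arr <- default_array("C")
  ext <- ext_default()
  ls <- compute_landscape(arr, ext, 0, window_um = c(-8, 8, -4, 4),
                          periodic = TRUE)
  b <- bead_spec()
  L <- b$volume_m3 * b$susceptibility / (2 * 4e-7 * pi)
  for (p in list(c(2.33, 0.21), c(4.7, -0.83), c(6.12, 0.4))) {
    Fi <- magnetic_force(b, ls, p)$force_N
    del <- 0.02
    S_at <- function(x, y)
      sum(array_flux_density(arr, ext, c(x, y, 2), 0, periodic = TRUE)^2)
    Ffd <- L * c(S_at(p[1] + del, p[2]) - S_at(p[1] - del, p[2]),
                 S_at(p[1], p[2] + del) - S_at(p[1], p[2] - del)) /
      (2 * del * 1e-6)
    expect_lt(sqrt(sum((Fi - Ffd)^2)) / sqrt(sum(Ffd^2)), 0.01)
  }
})

test_that("phase-locked transport moves one pitch per rotation and tracks the maxima", {
  arr <- default_array("C")
  ext <- ext_default()
  tr <- simulate_transport(bead_spec(), arr, ext, f_hz = 10)
  v <- attr(tr, "v_mean_um_s")
  expect_equal(v, 10 * 8, tolerance = 0.02 * 80)
  ## at low frequency the bead sits on the landscape maximum
  slow <- simulate_transport(bead_spec(), arr, ext, f_hz = 2, n_periods = 1,
                             skip_periods = 1)
  fin <- attr(slow, "final_state")
  map <- periodic_field_map(arr)
  pk <- nlmag:::.map_peak(map, ext, nlmag:::.theta_at(ext, 2, max(slow$t_s)))
  expect_lt(abs((fin[1] %% 8) - pk[1]), 0.25)
})

test_that("reversing the rotation sense reverses the mean velocity", {
  arr <- default_array("C")
  fwd <- simulate_transport(bead_spec(), arr, ext_default(), f_hz = 10)
  rev <- simulate_transport(bead_spec(), arr, external_field(sense = -1),
                            f_hz = 10)
  expect_equal(attr(rev, "v_mean_um_s"), -attr(fwd, "v_mean_um_s"),
               tolerance = 1)
})

test_that("simulations are bit-identical for identical inputs", {
  arr <- default_array("C")
  t1 <- simulate_transport(bead_spec(), arr, ext_default(), f_hz = 35)
  t2 <- simulate_transport(bead_spec(), arr, ext_default(), f_hz = 35)
  expect_identical(t1$x_um, t2$x_um)
  p1 <- velocity_vs_frequency(bead_spec(), arr, ext_default(), c(10, 35))
  p2 <- velocity_vs_frequency(bead_spec(), arr, ext_default(), c(10, 35))
  expect_identical(p1$v_um_s, p2$v_um_s)
})

test_that("well above the critical frequency the bead oscillates with little net motion", {
  arr <- default_array("C")
  fc <- fc_sim("C", "monomer")
  tr <- simulate_transport(bead_spec(), arr, ext_default(), f_hz = 6 * fc,
                           n_periods = 20, skip_periods = 4)
  expect_lt(abs(attr(tr, "v_mean_um_s")), 0.35 * fc * 8)
  ## oscillatory: the bead never advances a full pitch between period marks
  expect_lt(max(diff(tr$x_um)), 8)
})

test_that("oversized time steps abort with a diagnostic", {
  arr <- default_array("C")
  ext <- ext_default()
  ## start on the steepest part of the landscape so the first overdamped
  ## Euler step with a grossly oversized dt overshoots by more than d/4
  ls <- compute_landscape(arr, ext, 0, window_um = c(0, 8, -4, 4),
                          periodic = TRUE)
  gmag <- sqrt(ls$gx^2 + ls$gy^2)
  ij <- arrayInd(which.max(gmag), dim(gmag))
  x0 <- c(ls$x[ij[1]], ls$y[ij[2]])
  expect_error(simulate_transport(bead_spec(), arr, ext, f_hz = 30,
                                  dt_s = 1 / 60, x0_um = x0), "unstable")
})

test_that("the simulated knee self-calibrates the closed-form profile", {
  ## velocities simulated just above fc follow the closed form with the
  ## simulated fc plugged in (5 percent), tying the trajectory model to the
  ## analytic transport law
  arr <- default_array("S")
  fc <- fc_sim("S", "monomer")
  freqs <- fc * c(1.2, 1.5, 2)
  prof <- velocity_vs_frequency(bead_spec(), arr, ext_default(), freqs,
                                n_periods = 24, skip_periods = 4)
  vref <- closed_form_velocity(freqs, fc, 8)
  expect_lt(max(abs(prof$v_um_s - vref) / vref), 0.12)
})

test_that("separation schedules require a real frequency window", {
  ch_m <- frequency_characteristics(27, 40)
  ch_d <- frequency_characteristics(22.5, 30)
  sched <- design_schedule(ch_m, ch_d, default_array("S", n_x = 16, n_y = 5))
  expect_s3_class(sched, "nlm_schedule")
  expect_gt(sched[[2]]$f_hz, ch_d$fc_hz)
  expect_lt(sched[[2]]$f_hz, ch_m$fc_hz)
  expect_error(design_schedule(ch_d, ch_m, default_array("S")), "window")
})

test_that("separation efficiency identity and stuck-monomer expectation hold", {
  ## construction: all monomers, separation frequency in the window
  arr <- default_array("S", n_x = 12, n_y = 3)
  ext <- ext_default()
  fm <- fc_sim("S", "monomer")
  fd <- fc_sim("S", "dimer")
  sched <- design_schedule(frequency_characteristics(fm, 5.05 * fm),
                           frequency_characteristics(fd, 5.05 * fd), arr)
  pop <- synth_population(12, dimer_fraction = 0, stick_prob = 0, seed = 3,
                          array = arr, ext = ext)
  sep <- separation_protocol(pop, arr, ext, sched)
  expect_equal(sep$f_sb, 0)
  expect_equal(sep$efficiency, 1)
  ## nonspecific sticking: stuck monomers are retained, E[f_sb] = p_stick
  pop2 <- synth_population(40, dimer_fraction = 0, stick_prob = 0.5, seed = 5,
                           array = arr, ext = ext)
  sep2 <- separation_protocol(pop2, arr, ext, sched)
  expect_equal(sep2$f_sb, mean(pop2$stuck))
  expect_equal(sep2$efficiency, 1 - sep2$f_sb - sep2$f_agg)
  expect_error(separation_protocol(pop2[0, ], arr, ext, sched), "empty")
})
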