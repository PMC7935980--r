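test_that("an external-only (flat) landscape yields no maxima and is flagged", {
  arr <- array_spec(shape_spec("square", 5), n_x = 1, n_y = 1,
                    magnetization_A_m = 1e-12)
  ls <- compute_landscape(arr, ext_default(), 0, window_um = c(-4, 4, -4, 4))
  pk <- find_maxima(ls)
  expect_identical(nrow(pk), 0L)
  expect_true(attr(pk, "flat"))
})

test_that("the default circular array has one dominant maximum per lattice cell", {
  arr <- default_array("C")
  ls <- compute_landscape(arr, ext_default(), 0,
                          window_um = c(-8, 8, -4, 4), periodic = TRUE)
  pk <- find_maxima(ls, min_prominence = 0.25)
  ## two full cells in x, one row: two dominant peaks, one pitch apart
  expect_identical(nrow(pk), 2L)
  expect_equal(diff(pk$x_um), 8, tolerance = 0.1)
})

test_that("maxima positions shift with the evaluation window by one pitch", {
  arr <- default_array("C")
  ext <- ext_default()
  l1 <- compute_landscape(arr, ext, 0, window_um = c(-4, 4, -4, 4),
                          periodic = TRUE)
  l2 <- compute_landscape(arr, ext, 0, window_um = c(4, 12, -4, 4),
                          periodic = TRUE)
  p1 <- find_maxima(l1, min_prominence = 0.25)
  p2 <- find_maxima(l2, min_prominence = 0.25)
  expect_equal(p2$x_um, p1$x_um + 8, tolerance = 1e-6)
})

test_that("maxima tracking reverses with the rotation sense", {
  arr <- default_array("C")
  fwd <- track_maxima(arr, ext_default())
  ext_rev <- external_field(sense = -1)
  rev <- track_maxima(arr, ext_rev)
  expect_equal(fwd$displacement_per_rotation_um, 8, tolerance = 0.15)
  expect_equal(rev$displacement_per_rotation_um, -8, tolerance = 0.15)
})

test_that("phase schedules that are too short or too coarse are rejected", {
  arr <- default_array("C")
  expect_error(track_maxima(arr, ext_default(), seq(0, -180, by = -30)),
               "360")
  expect_error(track_maxima(arr, ext_default(), seq(0, -360, by = -60)),
               "30")
})

test_that("line profiles normalize to a maximum of exactly 1", {
  arr <- default_array("C")
  ls <- compute_landscape(arr, ext_default(), 0,
                          window_um = row_window(arr), periodic = TRUE)
  for (line in c("a", "b", "c")) {
    p <- line_profile(ls, line)
    expect_equal(max(p$value), 1)
  }
  expect_error(line_profile(ls, "c", y_center_um = 3.2), "outside")
})

test_that("dimer-edge modulation is below the center-line modulation on C but not on R", {
  ext <- ext_default()
  cs <- lapply(c("C", "R"), function(g) {
    arr <- default_array(g)
    ls <- compute_landscape(arr, ext, 0, window_um = row_window(arr),
                            periodic = TRUE)
    c(a = profile_contrast(line_profile(ls, "a")),
      b_vs_a = max(abs(line_profile(ls, "a")$value -
                       line_profile(ls, "b")$value)),
      c = profile_contrast(line_profile(ls, "c")))
  })
  names(cs) <- c("C", "R")
  ## C: the outer edge of a dimer sees strictly less modulation
  expect_lt(cs$C["c"], cs$C["a"])
  ## R: center and edge lines agree within 10 percent relative contrast
  expect_lt(abs(cs$R["c"] - cs$R["a"]) / cs$R["a"], 0.10)
  ## lines a and b agree pointwise on R (same field for monomer and dimer center)
  expect_lt(cs$R["b_vs_a"], 0.10)
})

test_that("profile asymmetry vanishes for even profiles and is scale-invariant", {
  x <- seq(-8, 8, by = 0.1)
  even <- structure(data.frame(x_um = x, value = exp(-x^2 / 8),
                               raw_T = exp(-x^2 / 8)),
                    class = c("nlm_profile", "data.frame"))
  expect_equal(profile_asymmetry(even), 0, tolerance = 1e-12)
  skewed <- even
  skewed$value <- skewed$value * (1 + 0.3 * sin(pi * x / 8))
  a1 <- profile_asymmetry(skewed)
  skewed2 <- skewed
  skewed2$value <- skewed$value * 7.3
  expect_gt(a1, 0)
  expect_equal(profile_asymmetry(skewed2), a1, tolerance = 1e-12)
})

test_that("triangular magnets give more asymmetric profiles than circular ones", {
  ext <- ext_default()
  asym <- sapply(c("C", "T"), function(g) {
    arr <- default_array(g)
    ls <- compute_landscape(arr, ext, 0, window_um = row_window(arr),
                            periodic = TRUE)
    profile_asymmetry(line_profile(ls, "a"))
  })
  expect_lt(asym["C"], asym["T"])
})

test_that("dimer overhang geometry: zero inside large footprints, frozen value on the 5 um circle", {
  circle5 <- shape_spec("circle", 5)
  dimer <- dimer_spec()
  ## a centered 2.8 um monomer projects strictly inside the 5 um circle
  expect_equal(dimer_overhang_fraction(circle5, bead_spec()), 0)
  ## a centered y-aligned dimer fits inside the 5 x 12.5 um rectangle
  expect_equal(dimer_overhang_fraction(shape_spec("rectangle", c(5, 12.5)),
                                       dimer), 0)
  ## frozen from a 1e7-sample Monte-Carlo volume integration (0.04388
  ## +/- 0.00007); low single-digit percent, consistent with the reported
  ## "approximately 6 percent" overhang
  q <- dimer_overhang_fraction(circle5, dimer)
  expect_equal(q, 0.04388, tolerance = 0.01)
  expect_gt(q, 0.01)
  expect_lt(q, 0.09)
})

test_that("dimer overhang is monotone nonincreasing in the magnet lateral dimension", {
  dimer <- dimer_spec()
  fr <- sapply(c(4.5, 5, 5.3, 5.6, 6), function(s) {
    dimer_overhang_fraction(shape_spec("circle", s), dimer)
  })
  expect_true(all(diff(fr) <= 0))
  expect_error(dimer_overhang_fraction(shape_spec("circle", 5), dimer,
                                       center_um = c(NA, 0)), "degenerate")
})
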