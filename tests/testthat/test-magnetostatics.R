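test_that("dipole field matches the axial and equatorial closed forms", {
  m <- c(1e-14, 0, 0)
  expect_equal(as.numeric(dipole_flux_density(m, c(1e-6, 0, 0))),
               c(2e-3, 0, 0))
  expect_equal(as.numeric(dipole_flux_density(m, c(0, 1e-6, 0))),
               c(-1e-3, 0, 0))
  expect_error(dipole_flux_density(m, c(0, 0, 0)), "nonzero")
})

test_that("dipole field agrees with a vanishingly small prism of equal moment", {
  ## 10 nm prism at ~1 um: multipole corrections are O((L/r)^2) ~ 1e-4
  dims <- c(0.01, 0.01, 0.01)
  M <- 8e4
  m <- M * prod(dims) * 1e-18
  for (p in list(c(1.1, 0.3, 0.7), c(-0.5, 0.9, 1.2), c(0.2, -1.3, 0.8))) {
    Bp <- as.numeric(prism_flux_density(dims, M, p))
    Bd <- as.numeric(dipole_flux_density(c(m, 0, 0), p * 1e-6))
    expect_lt(sqrt(sum((Bp - Bd)^2)) / sqrt(sum(Bd^2)), 1e-3)
  }
})

test_that("prism field has the mirror symmetry of an x-magnetized cuboid", {
  dims <- c(5, 5, 0.1)
  p1 <- prism_flux_density(dims, 8e4, c(1.7, 2.2, 1.5))
  p2 <- prism_flux_density(dims, 8e4, c(1.7, -2.2, 1.5))
  expect_equal(p1[1, "Bx"], p2[1, "Bx"])
  expect_equal(p1[1, "By"], -p2[1, "By"])
  expect_equal(p1[1, "Bz"], p2[1, "Bz"])
})

test_that("prism closed form matches Monte-Carlo surface-charge integration", {
  dims <- c(5, 5, 0.1)
  M <- 8e4
  pts <- list(c(3, 1, 1.2), c(0.5, -2, 2), c(-4, 3, 1.5))
  for (i in seq_along(pts)) {
    Bc <- as.numeric(prism_flux_density(dims, M, pts[[i]]))
    Bmc <- prism_mc_oracle(dims, M, pts[[i]], n = 4e5, seed = 100 + i)
    expect_lt(sqrt(sum((Bc - Bmc)^2)) / sqrt(sum(Bmc^2)), 0.005)
  }
})

test_that("prism far field converges to the equal-moment dipole", {
  dims <- c(5, 5, 0.1)
  M <- 8e4
  m <- M * prod(dims) * 1e-18
  p <- c(60, 25, 40)   # ~10x the prism diagonal away
  Bp <- as.numeric(prism_flux_density(dims, M, p))
  Bd <- as.numeric(dipole_flux_density(c(m, 0, 0), p * 1e-6))
  expect_lt(sqrt(sum((Bp - Bd)^2)) / sqrt(sum(Bd^2)), 0.01)
})

test_that("interior prism points are flagged", {
  expect_warning(B <- prism_flux_density(c(5, 5, 0.1), 8e4, c(0, 0, 0)),
                 "inside")
  expect_true(all(is.na(B)))
})

test_that("raster solver reproduces the analytic prism within 1 percent at z >= 1 um", {
  arr <- array_spec(shape_spec("square", 5), n_x = 1, n_y = 1)
  ext0 <- external_field(0, 0)
  g <- expand.grid(x = seq(-6, 6, by = 1), y = seq(-6, 6, by = 1),
                   z = c(1, 1.5, 2))
  pts <- as.matrix(g)
  Br <- array_flux_density(arr, ext0, pts, 0, cell_um = 0.25)
  Bp <- prism_flux_density(c(5, 5, 0.1), 8e4, pts, center_um = c(0, 0, -0.05))
  relerr <- sqrt(rowSums((Br - Bp)^2)) / sqrt(rowSums(Bp^2))
  expect_lt(max(relerr), 0.01)
})

test_that("zero-magnetization limit returns exactly the external field", {
  ## a vanishing magnetization makes the raster contribution negligible
  arr <- array_spec(shape_spec("square", 5), n_x = 2, n_y = 2,
                    magnetization_A_m = 1e-9)
  ext <- external_field(30, 35)
  B <- array_flux_density(arr, ext, c(4, 4, 2), theta_deg = -35)
  expect_equal(as.numeric(B), as.numeric(ext_field_vector(ext, -35)),
               tolerance = 1e-9)
})

test_that("fields superpose: a two-magnet array equals the sum of its magnets", {
  ext0 <- external_field(0, 0)
  p <- c(3.1, 0.7, 1.6)
  one_a <- array_spec(shape_spec("square", 5), n_x = 1, n_y = 1)
  one_b <- array_spec(shape_spec("square", 5), n_x = 1, n_y = 1,
                      origin_um = c(8, 0))
  two <- array_spec(shape_spec("square", 5), n_x = 2, n_y = 1)
  B2 <- array_flux_density(two, ext0, p)
  B1 <- array_flux_density(one_a, ext0, p) + array_flux_density(one_b, ext0, p)
  expect_equal(as.numeric(B2), as.numeric(B1))
})

test_that("array field is lattice-periodic deep inside a large array", {
  arr <- default_array("C", n_x = 15, n_y = 15)
  ext0 <- external_field(0, 0)
  ctr <- (7 - 1) * 8    # an interior magnet
  B1 <- array_flux_density(arr, ext0, c(ctr + 2, ctr + 1, 2))
  B2 <- array_flux_density(arr, ext0, c(ctr + 10, ctr + 1, 2))
  expect_lt(sqrt(sum((B1 - B2)^2)) / sqrt(sum(B1^2)), 0.005)
})

test_that("sampled field is numerically divergence-free", {
  arr <- default_array("C", n_x = 3, n_y = 3)
  ext0 <- external_field(0, 0)
  h <- 0.05
  p0 <- c(10.3, 8.6, 1.8)
  stencil <- rbind(p0 + c(h, 0, 0), p0 - c(h, 0, 0),
                   p0 + c(0, h, 0), p0 - c(0, h, 0),
                   p0 + c(0, 0, h), p0 - c(0, 0, h))
  B <- array_flux_density(arr, ext0, stencil, 0)
  div <- (B[1, 1] - B[2, 1] + B[3, 2] - B[4, 2] + B[5, 3] - B[6, 3]) /
    (2 * h * 1e-6)
  Bmag <- sqrt(sum(array_flux_density(arr, ext0, p0, 0)^2))
  expect_lt(abs(div), 1e-3 * Bmag / (h * 1e-6))
})

test_that("evaluation below the glass surface is rejected", {
  arr <- default_array("C", n_x = 2, n_y = 2)
  expect_error(array_flux_density(arr, external_field(), c(0, 0, 0.1)),
               "glass")
})

test_that("landscapes are 360-degree periodic in the drive phase", {
  arr <- default_array("C", n_x = 5, n_y = 5)
  ext <- ext_default()
  win <- c(8, 24, -4, 4)
  l0 <- compute_landscape(arr, ext, 0, window_um = win)
  l1 <- compute_landscape(arr, ext, -360, window_um = win)
  expect_equal(l0$Bmag, l1$Bmag)
})

test_that("landscape maxima advance monotonically in +x over the four standard phases", {
  arr <- default_array("C")
  ext <- ext_default()
  ## window chosen so the single dominant maximum stays interior while it
  ## travels one pitch over the four phases
  xs <- sapply(c(0, -90, -180, -270), function(th) {
    ls <- compute_landscape(arr, ext, th, window_um = c(2, 10.5, -4, 4),
                            periodic = TRUE)
    pk <- find_maxima(ls, min_prominence = 0.25)
    pk$x_um[which.max(pk$B_T)]
  })
  expect_true(all(diff(xs) > 0))
  expect_lt(max(xs) - min(xs), 8)
})

test_that("doubling the landscape grid resolution changes max |B| by < 1 percent", {
  arr <- default_array("C", n_x = 5, n_y = 5)
  ext <- ext_default()
  win <- c(8, 16, -4, 4)
  c1 <- max(compute_landscape(arr, ext, 0, grid_step_um = 0.2,
                              window_um = win)$Bmag)
  c2 <- max(compute_landscape(arr, ext, 0, grid_step_um = 0.1,
                              window_um = win)$Bmag)
  expect_lt(abs(c1 - c2) / c2, 0.01)
})

test_that("coarse landscape grids trigger a warning", {
  arr <- default_array("C", n_x = 3, n_y = 3)
  expect_warning(compute_landscape(arr, ext_default(), 0, grid_step_um = 0.6,
                                   window_um = c(0, 8, -4, 4)),
                 "unreliable")
})
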