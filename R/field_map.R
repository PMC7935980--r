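#' Periodic field map of an array (dynamics backend)
#'
#' Precomputes the static (array-only) flux-density components and their
#' in-plane derivatives on one lattice period at the bead-center height,
#' treating the lattice as infinite. Because only the spatially uniform
#' external field rotates in time, the total field anywhere and at any
#' phase is `B_array(x, y) + B_ext(theta)`; the trajectory integrator
#' therefore only needs fast bilinear interpolation into this map. The map
#' is cached per session.
#'
#' @param array An [array_spec()] object.
#' @param z_um Evaluation height (um above magnet top); default bead plane
#'   `glass_nm/1000 + 1.4`.
#' @param grid_step_um Grid step; must divide both pitches.
#' @param cell_um Raster cell size for the source magnets.
#' @param cutoff_periods Neighbor cutoff in lattice periods.
#' @return An object of class `nlm_fieldmap`.
#' @export
periodic_field_map <- function(array, z_um = NULL, grid_step_um = 0.1,
                               cell_um = 0.25, cutoff_periods = 5) {
  stopifnot(inherits(array, "nlm_array"))
  if (is.null(z_um)) z_um <- array$glass_nm / 1000 + 1.4
  px <- array$pitch_x_um; py <- array$pitch_y_um
  nx <- round(px / grid_step_um); ny <- round(py / grid_step_um)
  if (abs(nx * grid_step_um - px) > 1e-9 || abs(ny * grid_step_um - py) > 1e-9)
    stop("grid_step_um must divide both lattice pitches")
  ## the infinite-lattice map is independent of the finite magnet counts
  key_spec <- array[setdiff(names(array), c("n_x", "n_y"))]
  key <- paste("map", paste(deparse(key_spec), collapse = ""), z_um,
               grid_step_um, cell_um, cutoff_periods, sep = "|")
  key <- gsub("\\s+", "", key)
  .cache_get(key, function() {
    ## sample one period [0, px) x [0, py); periodic closure by wrapping
    x <- (seq_len(nx) - 1) * grid_step_um
    y <- (seq_len(ny) - 1) * grid_step_um
    g <- expand.grid(x_um = x, y_um = y, KEEP.OUT.ATTRS = FALSE)
    placements <- .nearby_placements(array, c(0, px, 0, py), cutoff_periods,
                                     periodic = TRUE)
    dip <- .array_dipoles(array, placements, cell_um)
    B <- dipole_sum_x(cbind(g$x_um, g$y_um, z_um) * 1e-6, dip$points, dip$moment)
    comp <- list(Bx = matrix(B[, 1], nx, ny),
                 By = matrix(B[, 2], nx, ny),
                 Bz = matrix(B[, 3], nx, ny))
    h_m <- grid_step_um * 1e-6
    ddx <- function(M) (M[c(2:nx, 1), ] - M[c(nx, 1:(nx - 1)), ]) / (2 * h_m)
    ddy <- function(M) (M[, c(2:ny, 1)] - M[, c(ny, 1:(ny - 1))]) / (2 * h_m)
    structure(
      list(x = x, y = y, z_um = z_um, pitch_x_um = px, pitch_y_um = py,
           grid_step_um = grid_step_um, nx = nx, ny = ny,
           Bx = comp$Bx, By = comp$By, Bz = comp$Bz,
           dBx_dx = ddx(comp$Bx), dBy_dx = ddx(comp$By), dBz_dx = ddx(comp$Bz),
           dBx_dy = ddy(comp$Bx), dBy_dy = ddy(comp$By), dBz_dy = ddy(comp$Bz),
           array = array),
      class = "nlm_fieldmap")
  })
}

#' @export
print.nlm_fieldmap <- function(x, ...) {
  cat(sprintf("<nlm_fieldmap> one %g x %g um period at z = %g um, step %g um\n",
              x$pitch_x_um, x$pitch_y_um, x$z_um, x$grid_step_um))
  invisible(x)
}

# Bilinear periodic interpolation of all 9 stored fields at (x_um, y_um).
# Returns a list of numeric vectors. Positions may be any real numbers;
# they are wrapped into the lattice period.
.map_interp <- function(map, x_um, y_um) {
  h <- map$grid_step_um
  fx <- (x_um %% map$pitch_x_um) / h
  fy <- (y_um %% map$pitch_y_um) / h
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  i0 <- (as.integer(i0) %% map$nx) + 1L
  j0 <- (as.integer(j0) %% map$ny) + 1L
  i1 <- i0 %% map$nx + 1L
  j1 <- j0 %% map$ny + 1L
  w00 <- (1 - tx) * (1 - ty); w10 <- tx * (1 - ty)
  w01 <- (1 - tx) * ty;       w11 <- tx * ty
  k00 <- cbind(i0, j0); k10 <- cbind(i1, j0)
  k01 <- cbind(i0, j1); k11 <- cbind(i1, j1)
  take <- function(M) w00 * M[k00] + w10 * M[k10] + w01 * M[k01] + w11 * M[k11]
  list(Bx = take(map$Bx), By = take(map$By), Bz = take(map$Bz),
       dBx_dx = take(map$dBx_dx), dBy_dx = take(map$dBy_dx),
       dBz_dx = take(map$dBz_dx),
       dBx_dy = take(map$dBx_dy), dBy_dy = take(map$dBy_dy),
       dBz_dy = take(map$dBz_dy))
}

# gradient of |B_total|^2 at positions, given the external field vector be
# (length 3, tesla). d(|B|^2)/dx = 2 B . dB_array/dx since B_ext is uniform.
# Returns list(gx, gy) in T^2/m, plus Bmag (T).
.grad_B2 <- function(map, x_um, y_um, be) {
  f <- .map_interp(map, x_um, y_um)
  bx <- f$Bx + be[1]; by <- f$By + be[2]; bz <- f$Bz + be[3]
  list(gx = 2 * (bx * f$dBx_dx + by * f$dBy_dx + bz * f$dBz_dx),
       gy = 2 * (bx * f$dBx_dy + by * f$dBy_dy + bz * f$dBz_dy),
       Bmag = sqrt(bx^2 + by^2 + bz^2))
}

# |B_total|^2 over the map grid at a set of phases; used to bound the
# landscape stiffness for the integrator time step and to locate maxima.
.map_B2_grid <- function(map, ext, theta_deg) {
  Be <- ext_field_vector(ext, theta_deg)
  lapply(seq_along(theta_deg), function(k) {
    (map$Bx + Be[k, 1])^2 + (map$By + Be[k, 2])^2 + (map$Bz + Be[k, 3])^2
  })
}

# position (um) of the global maximum of |B|^2 at phase theta
.map_peak <- function(map, ext, theta_deg = 0) {
  S <- .map_B2_grid(map, ext, theta_deg)[[1]]
  ij <- arrayInd(which.max(S), dim(S))
  c(x_um = map$x[ij[1]], y_um = map$y[ij[2]])
}
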