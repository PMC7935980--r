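#' Rotating external drive field
#'
#' An ellipsoidal field rotating in the xz-plane:
#' `B_ext(theta) = (Bx * cos(theta), 0, Bz * sin(theta))` with the phase
#' `theta` advancing by -360 degrees per drive period (for `sense = +1`),
#' which translates the flux-density maxima of an x-magnetized array toward
#' +x. Defaults are the experimental drive of 30 G along x and 35 G along z.
#'
#' @param bx,bz Field amplitudes (default gauss; see `unit`).
#' @param unit `"gauss"` or `"tesla"`.
#' @param frequency_hz Drive rotation frequency (cyclic, Hz).
#' @param sense +1 for +x transport, -1 to reverse.
#' @return An object of class `nlm_ext_field` with amplitudes stored in tesla.
#' @examples
#' external_field()                 # 30 G / 35 G default
#' external_field(0, 0)             # array-only landscapes
#' @export
external_field <- function(bx = 30, bz = 35, unit = c("gauss", "tesla"),
                           frequency_hz = 10, sense = 1) {
  unit <- match.arg(unit)
  if (bx < 0 || bz < 0) stop("field amplitudes must be >= 0")
  if (!sense %in% c(-1, 1)) stop("sense must be +1 or -1")
  f <- if (unit == "gauss") gauss_to_tesla else identity
  structure(list(bx_T = f(bx), bz_T = f(bz),
                 frequency_hz = frequency_hz, sense = sense),
            class = "nlm_ext_field")
}

#' @export
print.nlm_ext_field <- function(x, ...) {
  cat(sprintf("<nlm_ext_field> Bx = %g G, Bz = %g G, f = %g Hz, sense %+d\n",
              tesla_to_gauss(x$bx_T), tesla_to_gauss(x$bz_T),
              x$frequency_hz, x$sense))
  invisible(x)
}

#' External field vector at a phase
#'
#' @param ext An [external_field()] object.
#' @param theta_deg Phase(s) in degrees.
#' @return Matrix with columns `Bx`, `By`, `Bz` in tesla (one row per phase).
#' @export
ext_field_vector <- function(ext, theta_deg) {
  stopifnot(inherits(ext, "nlm_ext_field"))
  th <- theta_deg * pi / 180
  cbind(Bx = ext$bx_T * cos(th), By = 0 * th, Bz = ext$bz_T * sin(th))
}

# drive phase (degrees) at time t for frequency f
.theta_at <- function(ext, f_hz, t_s) -360 * f_hz * t_s * ext$sense

#' Point-dipole flux density
#'
#' `B = (mu0 / 4 pi) * (3 (m . rhat) rhat - m) / r^3`, the elementary source
#' summed by the raster solver.
#'
#' @param moment Dipole moment vector, A m^2 (length 3).
#' @param displacement Field point relative to the dipole, meters (length 3
#'   or an n x 3 matrix).
#' @return Flux density in tesla (n x 3 matrix).
#' @examples
#' dipole_flux_density(c(1e-14, 0, 0), c(1e-6, 0, 0))  # 2 mT axial
#' @export
dipole_flux_density <- function(moment, displacement) {
  stopifnot(length(moment) == 3)
  r <- if (is.matrix(displacement)) displacement else matrix(displacement, ncol = 3)
  rn <- sqrt(rowSums(r^2))
  if (any(rn == 0)) stop("displacement must be nonzero")
  mdotr <- as.vector(r %*% moment)
  k <- 1e-7
  B <- k * (3 * r * mdotr / rn^5 - matrix(moment, nrow(r), 3, byrow = TRUE) / rn^3)
  colnames(B) <- c("Bx", "By", "Bz")
  B
}

#' Analytic field of a uniformly x-magnetized rectangular prism
#'
#' Closed-form flux density of a cuboid magnetized uniformly along +x,
#' obtained from the equivalent magnetic surface charges +M and -M on the
#' two x-faces (log/arctan corner sums). Serves as the independent analytic
#' oracle against which the dipole-raster solver is validated.
#'
#' @param dims_um Prism edge lengths `c(Lx, Ly, Lz)` in um.
#' @param M_A_m Magnetization along +x in A/m.
#' @param points_um Evaluation points (n x 3 matrix or length-3 vector), um,
#'   relative to the prism center.
#' @param center_um Prism center, um.
#' @return n x 3 matrix of flux density in tesla. Points inside the prism
#'   are flagged: their rows are `NA` and a warning is raised (interior
#'   demagnetizing fields are not needed for bead-plane work).
#' @export
prism_flux_density <- function(dims_um, M_A_m, points_um, center_um = c(0, 0, 0)) {
  p <- if (is.matrix(points_um)) points_um else matrix(points_um, ncol = 3)
  p <- sweep(p, 2, center_um) * 1e-6
  half <- dims_um / 2 * 1e-6
  inside <- abs(p[, 1]) < half[1] & abs(p[, 2]) < half[2] & abs(p[, 3]) < half[3]
  x <- p[, 1]; y <- p[, 2]; z <- p[, 3]
  Hx <- Hy <- Hz <- numeric(nrow(p))
  for (sface in c(1, -1)) {          # charged faces at x = +/- Lx/2
    x0 <- sface * half[1]
    for (jj in 1:2) for (kk in 1:2) {
      yj <- c(-1, 1)[jj] * half[2]
      zk <- c(-1, 1)[kk] * half[3]
      sgn <- sface * c(-1, 1)[jj] * c(-1, 1)[kk]
      R <- sqrt((x - x0)^2 + (y - yj)^2 + (z - zk)^2)
      Hx <- Hx + sgn * atan2((y - yj) * (z - zk), (x - x0) * R)
      Hy <- Hy + sgn * log((zk - z) + R)
      Hz <- Hz + sgn * log((yj - y) + R)
    }
  }
  B <- .mu0 * M_A_m / (4 * pi) * cbind(Bx = Hx, By = Hy, Bz = Hz)
  if (any(inside)) {
    warning("point(s) inside the prism flagged as NA")
    B[inside, ] <- NA_real_
  }
  B
}

# magnet placements within a cutoff of a bounding box, on the infinite
# extension of the lattice (periodic = TRUE) or the actual finite array
.nearby_placements <- function(array, bbox_um, cutoff_periods = 5,
                               periodic = FALSE) {
  cx <- cutoff_periods * array$pitch_x_um
  cy <- cutoff_periods * array$pitch_y_um
  if (periodic) {
    i_lo <- floor((bbox_um[1] - cx - array$origin_um[1]) / array$pitch_x_um)
    i_hi <- ceiling((bbox_um[2] + cx - array$origin_um[1]) / array$pitch_x_um)
    j_lo <- floor((bbox_um[3] - cy - array$origin_um[2]) / array$pitch_y_um)
    j_hi <- ceiling((bbox_um[4] + cy - array$origin_um[2]) / array$pitch_y_um)
    g <- expand.grid(i = i_lo:i_hi, j = j_lo:j_hi, KEEP.OUT.ATTRS = FALSE)
    g$x_um <- array$origin_um[1] + g$i * array$pitch_x_um
    g$y_um <- array$origin_um[2] + g$j * array$pitch_y_um
    g
  } else {
    g <- build_lattice(array)
    keep <- g$x_um >= bbox_um[1] - cx & g$x_um <= bbox_um[2] + cx &
            g$y_um >= bbox_um[3] - cy & g$y_um <= bbox_um[4] + cy
    g[keep, , drop = FALSE]
  }
}

#' Total flux density above a micromagnet array
#'
#' Sums the dipole fields of all raster cells of magnets within a neighbor
#' cutoff of the evaluation points, plus the rotating external field at
#' phase `theta_deg`. Fields decay at least as r^-3, so a cutoff of 5
#' lattice periods truncates the array sum with < 0.5 percent error.
#'
#' @param array An [array_spec()] object.
#' @param ext An [external_field()] object (amplitudes may be zero).
#' @param points_um Evaluation points (n x 3 or length 3), um. Must lie above
#'   the glass surface.
#' @param theta_deg External-field phase in degrees.
#' @param cell_um Raster cell size, um.
#' @param cutoff_periods Neighbor cutoff in lattice periods.
#' @param periodic If `TRUE`, treat the lattice as infinite (deep-array
#'   approximation); if `FALSE`, use the actual finite magnet count.
#' @return n x 3 matrix of flux density in tesla.
#' @export
array_flux_density <- function(array, ext, points_um, theta_deg = 0,
                               cell_um = 0.25, cutoff_periods = 5,
                               periodic = FALSE) {
  stopifnot(inherits(array, "nlm_array"), inherits(ext, "nlm_ext_field"))
  p <- if (is.matrix(points_um)) points_um else matrix(points_um, ncol = 3)
  glass_top <- array$glass_nm / 1000
  if (any(p[, 3] < glass_top))
    stop("evaluation points must lie above the glass surface (z >= ",
         glass_top, " um)")
  bbox <- c(range(p[, 1]), range(p[, 2]))
  placements <- .nearby_placements(array, bbox, cutoff_periods, periodic)
  dip <- .array_dipoles(array, placements, cell_um)
  Barr <- dipole_sum_x(p * 1e-6, dip$points, dip$moment)
  Bext <- ext_field_vector(ext, theta_deg)
  B <- sweep(Barr, 2, as.vector(Bext), "+")
  colnames(B) <- c("Bx", "By", "Bz")
  B
}

# Static (array-only) field components sampled on a rectangular grid.
# Cached per session: this is the expensive dipole sum.
.static_field_grid <- function(array, window_um, z_um, grid_step_um,
                               cell_um = 0.25, cutoff_periods = 5,
                               periodic = FALSE) {
  key <- paste("grid", paste(deparse(array[setdiff(names(array), "")]), collapse = ""),
               paste(window_um, collapse = ","), z_um, grid_step_um, cell_um,
               cutoff_periods, periodic, sep = "|")
  key <- gsub("\\s+", "", key)
  .cache_get(key, function() {
    x <- seq(window_um[1], window_um[2], by = grid_step_um)
    y <- seq(window_um[3], window_um[4], by = grid_step_um)
    g <- expand.grid(x_um = x, y_um = y, KEEP.OUT.ATTRS = FALSE)
    pts <- cbind(g$x_um, g$y_um, z_um)
    placements <- .nearby_placements(array, c(range(x), range(y)),
                                     cutoff_periods, periodic)
    dip <- .array_dipoles(array, placements, cell_um)
    B <- dipole_sum_x(pts * 1e-6, dip$points, dip$moment)
    list(x = x, y = y, z_um = z_um,
         Bx = matrix(B[, 1], length(x), length(y)),
         By = matrix(B[, 2], length(x), length(y)),
         Bz = matrix(B[, 3], length(x), length(y)))
  })
}

#' Flux-density landscape on the bead-center plane
#'
#' Samples the magnitude of the total flux density, and the gradient of its
#' square, on a rectangular (x, y) grid at fixed height. The default height
#' is the bead-center plane: glass top + bead radius, i.e. 1.4 um above the
#' spin-on glass for 2.8 um beads (2.0 um above the magnet top). The static
#' array field is cached, so landscapes at many phases are cheap.
#'
#' @param array An [array_spec()] object.
#' @param ext An [external_field()] object.
#' @param theta_deg External-field phase, degrees.
#' @param z_um Evaluation height (um above magnet top); default
#'   `glass_nm/1000 + 1.4`.
#' @param grid_step_um Grid step (um); a warning is raised above 0.5 um
#'   because maxima localization becomes unreliable.
#' @param window_um Window `c(x0, x1, y0, y1)` in um; default spans the two
#'   central lattice cells of the array.
#' @param cell_um Raster cell size for the source magnets.
#' @param periodic Treat the lattice as infinite (see [array_flux_density()]).
#' @return An object of class `nlm_landscape`: grid vectors `x`, `y` (um),
#'   matrices `Bmag` (T), `Bx`, `By`, `Bz`, and `gx`, `gy` = gradient of
#'   |B|^2 (T^2/m), plus phase and provenance.
#' @export
compute_landscape <- function(array, ext, theta_deg = 0, z_um = NULL,
                              grid_step_um = 0.1, window_um = NULL,
                              cell_um = 0.25, periodic = FALSE) {
  stopifnot(inherits(array, "nlm_array"), inherits(ext, "nlm_ext_field"))
  if (grid_step_um > 0.5)
    warning("grid_step_um > 0.5 um: maxima localization unreliable")
  if (is.null(z_um)) z_um <- array$glass_nm / 1000 + 1.4
  if (is.null(window_um)) {
    icx <- floor(array$n_x / 2); icy <- floor(array$n_y / 2)
    x0 <- array$origin_um[1] + (icx - 1) * array$pitch_x_um
    y0 <- array$origin_um[2] + (icy - 1) * array$pitch_y_um
    window_um <- c(x0, x0 + 2 * array$pitch_x_um, y0, y0 + array$pitch_y_um)
  }
  st <- .static_field_grid(array, window_um, z_um, grid_step_um, cell_um,
                           cutoff_periods = 5, periodic = periodic)
  Be <- ext_field_vector(ext, theta_deg)
  Bx <- st$Bx + Be[1]; By <- st$By + Be[2]; Bz <- st$Bz + Be[3]
  S <- Bx^2 + By^2 + Bz^2
  h_m <- grid_step_um * 1e-6
  gx <- S * 0; gy <- S * 0
  nx <- nrow(S); ny <- ncol(S)
  gx[2:(nx - 1), ] <- (S[3:nx, ] - S[1:(nx - 2), ]) / (2 * h_m)
  gx[c(1, nx), ] <- gx[c(2, nx - 1), ]
  gy[, 2:(ny - 1)] <- (S[, 3:ny] - S[, 1:(ny - 2)]) / (2 * h_m)
  gy[, c(1, ny)] <- gy[, c(2, ny - 1)]
  structure(
    list(x = st$x, y = st$y, z_um = z_um, theta_deg = theta_deg,
         Bmag = sqrt(S), Bx = Bx, By = By, Bz = Bz, gx = gx, gy = gy,
         grid_step_um = grid_step_um,
         provenance = list(array = array, ext = ext, cell_um = cell_um,
                           periodic = periodic)),
    class = "nlm_landscape")
}

#' @export
print.nlm_landscape <- function(x, ...) {
  cat(sprintf(
    "<nlm_landscape> %d x %d grid, z = %g um, theta = %g deg, |B| in [%.3g, %.3g] mT\n",
    length(x$x), length(x$y), x$z_um, x$theta_deg,
    1e3 * min(x$Bmag), 1e3 * max(x$Bmag)))
  invisible(x)
}

#' Export a landscape as CSV
#'
#' Long-format table `x_um, y_um, Bmag_T, gx_T2_m, gy_T2_m`.
#'
#' @param landscape An `nlm_landscape`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape_csv <- function(landscape, path) {
  g <- expand.grid(x_um = landscape$x, y_um = landscape$y,
                   KEEP.OUT.ATTRS = FALSE)
  g$Bmag_T <- as.vector(landscape$Bmag)
  g$gx_T2_m <- as.vector(landscape$gx)
  g$gy_T2_m <- as.vector(landscape$gy)
  write.csv(g, path, row.names = FALSE)
  invisible(path)
}
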