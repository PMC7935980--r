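#' Local flux-density maxima of a landscape
#'
#' Finds strict interior local maxima of |B| by 8-neighborhood comparison,
#' with quadratic (parabolic) sub-grid refinement in x and y. The maxima are
#' the positions to which magnetically focused beads are attracted. Ties are
#' ordered by smallest x then smallest y.
#'
#' @param landscape An `nlm_landscape` from [compute_landscape()].
#' @param flat_tol Relative flatness tolerance: if the peak-to-trough range
#'   of |B| is below `flat_tol * max(|B|)` (a uniform, external-only field),
#'   no peaks are reported and the result is flagged.
#' @param min_prominence Keep only maxima whose |B| exceeds
#'   `min(|B|) + min_prominence * range(|B|)`; filters grid-noise ripples.
#' @return A data.frame with columns `x_um`, `y_um`, `B_T` and attribute
#'   `flat` (TRUE when the landscape was flagged flat).
#' @export
find_maxima <- function(landscape, flat_tol = 1e-6, min_prominence = 0.05) {
  stopifnot(inherits(landscape, "nlm_landscape"))
  B <- landscape$Bmag
  nx <- nrow(B); ny <- ncol(B)
  rng <- max(B) - min(B)
  out <- data.frame(x_um = numeric(0), y_um = numeric(0), B_T = numeric(0))
  if (!is.finite(rng) || rng <= flat_tol * max(B)) {
    attr(out, "flat") <- TRUE
    return(out)
  }
  if (nx < 3 || ny < 3) stop("landscape grid too small for maxima detection")
  C <- B[2:(nx - 1), 2:(ny - 1)]
  is_max <- C > B[1:(nx - 2), 2:(ny - 1)] & C > B[3:nx, 2:(ny - 1)] &
            C > B[2:(nx - 1), 1:(ny - 2)] & C > B[2:(nx - 1), 3:ny] &
            C > B[1:(nx - 2), 1:(ny - 2)] & C > B[3:nx, 3:ny] &
            C > B[1:(nx - 2), 3:ny] & C > B[3:nx, 1:(ny - 2)]
  thr <- min(B) + min_prominence * rng
  idx <- which(is_max & C > thr, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    attr(out, "flat") <- FALSE
    return(out)
  }
  i <- idx[, 1] + 1L; j <- idx[, 2] + 1L
  h <- landscape$grid_step_um
  ## parabolic refinement, separable in x and y
  dxo <- (B[cbind(i - 1, j)] - B[cbind(i + 1, j)]) /
         (2 * (B[cbind(i - 1, j)] - 2 * B[cbind(i, j)] + B[cbind(i + 1, j)]))
  dyo <- (B[cbind(i, j - 1)] - B[cbind(i, j + 1)]) /
         (2 * (B[cbind(i, j - 1)] - 2 * B[cbind(i, j)] + B[cbind(i, j + 1)]))
  dxo[!is.finite(dxo)] <- 0; dyo[!is.finite(dyo)] <- 0
  dxo <- pmin(pmax(dxo, -0.5), 0.5); dyo <- pmin(pmax(dyo, -0.5), 0.5)
  out <- data.frame(x_um = landscape$x[i] + dxo * h,
                    y_um = landscape$y[j] + dyo * h,
                    B_T = B[cbind(i, j)])
  out <- out[order(out$x_um, out$y_um), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "flat") <- FALSE
  out
}

#' Track a flux-density maximum through a field rotation
#'
#' Computes landscapes over a schedule of external-field phases and follows
#' one maximum by nearest-neighbor association (ties broken toward +x, the
#' physically expected direction of motion). The net x-displacement per full
#' 360-degree rotation equals the lattice pitch when the landscape
#' translates with the drive, the geometric fact underlying phase-locked
#' transport at v = f d.
#'
#' @param array An [array_spec()] object.
#' @param ext An [external_field()] object.
#' @param theta_deg Phase schedule in degrees; must span at least 360
#'   degrees with steps of at most 30 degrees. Defaults to one full
#'   rotation in the direction implied by the field's rotation sense.
#' @param grid_step_um Landscape grid step.
#' @param z_um Evaluation height (default bead plane).
#' @param max_jump_um Association gate per step (default pitch/2 + 2 grid
#'   steps).
#' @return An object of class `nlm_track`: data.frame `track` with
#'   `theta_deg`, `x_um`, `y_um`, `B_T`, plus `displacement_um` (net x
#'   displacement) and `displacement_per_rotation_um`.
#' @export
track_maxima <- function(array, ext, theta_deg = NULL,
                         grid_step_um = 0.1, z_um = NULL, max_jump_um = NULL) {
  if (is.null(theta_deg))
    theta_deg <- seq(0, -360 * ext$sense, by = -30 * ext$sense)
  span <- abs(theta_deg[length(theta_deg)] - theta_deg[1])
  if (span < 360) stop("phase schedule must span at least 360 degrees")
  if (max(abs(diff(theta_deg))) > 30 + 1e-9)
    stop("phase steps must be <= 30 degrees")
  if (is.null(max_jump_um))
    max_jump_um <- array$pitch_x_um / 2 + 2 * grid_step_um
  ## window: 3 periods wide so the tracked peak never leaves it, centered on
  ## a magnet row in y so row maxima are interior points
  win <- c(-array$pitch_x_um, 2 * array$pitch_x_um,
           -array$pitch_y_um / 2, array$pitch_y_um / 2)
  ls0 <- compute_landscape(array, ext, theta_deg[1], z_um = z_um,
                           grid_step_um = grid_step_um, window_um = win,
                           periodic = TRUE)
  pk <- find_maxima(ls0)
  if (nrow(pk) == 0) stop("no maxima found at the initial phase")
  ## start from the peak closest to the window center
  ctr <- c(mean(win[1:2]), mean(win[3:4]))
  d0 <- sqrt((pk$x_um - ctr[1])^2 + (pk$y_um - ctr[2])^2)
  cur <- pk[which.min(d0), ]
  rows <- cbind(theta_deg = theta_deg[1], cur)
  for (k in seq_along(theta_deg)[-1]) {
    lsk <- compute_landscape(array, ext, theta_deg[k], z_um = z_um,
                             grid_step_um = grid_step_um, window_um = win,
                             periodic = TRUE)
    pk <- find_maxima(lsk)
    if (nrow(pk) == 0) stop("maxima lost at theta = ", theta_deg[k])
    dd <- sqrt((pk$x_um - cur$x_um)^2 + (pk$y_um - cur$y_um)^2)
    ## nearest neighbor with +x preference on near-ties (within one grid step)
    best <- which(dd <= min(dd) + grid_step_um)
    nxt <- pk[best[which.max(pk$x_um[best])], ]
    if (min(dd) > max_jump_um)
      stop(sprintf("association jump %.2f um exceeds gate %.2f um at theta = %g",
                   min(dd), max_jump_um, theta_deg[k]))
    cur <- nxt
    rows <- rbind(rows, cbind(theta_deg = theta_deg[k], cur))
  }
  rownames(rows) <- NULL
  disp <- rows$x_um[nrow(rows)] - rows$x_um[1]
  structure(list(track = rows,
                 displacement_um = disp,
                 displacement_per_rotation_um = disp * 360 / span),
            class = "nlm_track")
}

#' @export
print.nlm_track <- function(x, ...) {
  cat(sprintf("<nlm_track> %d phases, net displacement %.2f um (%.2f um per rotation)\n",
              nrow(x$track), x$displacement_um, x$displacement_per_rotation_um))
  invisible(x)
}

#' Normalized flux-density line profile
#'
#' Samples |B| along x at a fixed y and normalizes to the profile maximum.
#' The three conventional lines probe the field sampled by different parts
#' of the particles: `"a"` the monomer trajectory center, `"b"` the dimer
#' center trajectory (identical y for a centered, y-aligned dimer; both are
#' retained for fidelity to the standard figure construction), and `"c"`
#' offset by 1.1 um in y from b, through the outer edge of a dimer.
#'
#' @param landscape An `nlm_landscape`.
#' @param line `"a"`, `"b"` or `"c"`.
#' @param y_center_um y of the particle trajectory (row center), um.
#' @param offset_c_um y offset of line c from line b (default 1.1 um).
#' @return An object of class `nlm_profile`: data.frame with `x_um`,
#'   `value` (normalized, max = 1) and `raw_T`.
#' @export
line_profile <- function(landscape, line = c("a", "b", "c"),
                         y_center_um = 0, offset_c_um = 1.1) {
  stopifnot(inherits(landscape, "nlm_landscape"))
  line <- match.arg(line)
  y0 <- y_center_um + if (line == "c") offset_c_um else 0
  if (y0 < min(landscape$y) || y0 > max(landscape$y))
    stop(sprintf("line %s at y = %g um lies outside the sampled window", line, y0))
  ## linear interpolation between the two bracketing grid rows
  j <- findInterval(y0, landscape$y, all.inside = TRUE)
  t <- (y0 - landscape$y[j]) / (landscape$y[j + 1] - landscape$y[j])
  raw <- (1 - t) * landscape$Bmag[, j] + t * landscape$Bmag[, j + 1]
  structure(
    data.frame(x_um = landscape$x, value = raw / max(raw), raw_T = raw),
    line = line, y_um = y0, class = c("nlm_profile", "data.frame"))
}

#' Peak-to-trough contrast of a line profile
#'
#' `(max - min) / max` over the sampled span (one spatial period for the
#' standard windows). This is the explicit landscape-modulation metric used
#' to compare what monomer centers and dimer edges experience.
#'
#' @param profile An `nlm_profile`.
#' @return Contrast in `[0, 1]`.
#' @export
profile_contrast <- function(profile) {
  v <- profile$raw_T
  (max(v) - min(v)) / max(v)
}

#' Mirror-asymmetry index of a line profile
#'
#' Reflects the profile about its peak and reports the normalized L1
#' distance between profile and mirror over their overlap:
#' `sum |v - v_mirror| / sum (v + v_mirror)`. Zero for an even profile;
#' invariant under uniform rescaling. Triangular magnets give asymmetric
#' profiles (their transport is direction-dependent), circles do not.
#'
#' @param profile An `nlm_profile` spanning at least one full period.
#' @return Asymmetry index in `[0, 1]`.
#' @export
profile_asymmetry <- function(profile) {
  x <- profile$x_um; v <- profile$value
  ip <- which.max(v)
  ## parabolic refinement of the mirror center
  xp <- x[ip]
  if (ip > 1 && ip < length(x)) {
    den <- v[ip - 1] - 2 * v[ip] + v[ip + 1]
    if (is.finite(den) && den != 0) {
      off <- (v[ip - 1] - v[ip + 1]) / (2 * den)
      xp <- x[ip] + max(min(off, 0.5), -0.5) * (x[2] - x[1])
    }
  }
  xm <- 2 * xp - x
  keep <- xm >= min(x) & xm <= max(x)
  if (sum(keep) < 3) return(0)
  vm <- approx(x, v, xout = xm[keep])$y
  vv <- v[keep]
  sum(abs(vv - vm)) / sum(vv + vm)
}

#' Dimer (or monomer) volume fraction outside a magnet footprint
#'
#' Fraction of total particle volume whose (x, y) projection falls outside
#' the micromagnet footprint, computed by deterministic column quadrature
#' over each sphere's projected disk (column height `2 sqrt(r^2 - rho^2)`).
#' This is the geometric mechanism of dimer/monomer separability: the part
#' of a dimer hanging over the magnet edge samples a weaker field.
#'
#' @param shape An [shape_spec()] object (footprint centered at origin).
#' @param particle A [bead_spec()] (monomer) or [dimer_spec()].
#' @param center_um Particle center `c(x, y)` relative to the footprint
#'   center, um.
#' @param axis_deg In-plane dimer axis angle from +x, degrees (default 90:
#'   dimer transverse to transport, the low-frequency orientation).
#' @param grid_n Quadrature resolution per sphere diameter.
#' @return Volume fraction in `[0, 1]`.
#' @examples
#' b <- bead_spec()
#' dimer_overhang_fraction(shape_spec("circle", 5), b)            # 0
#' @export
dimer_overhang_fraction <- function(shape, particle, center_um = c(0, 0),
                                    axis_deg = 90, grid_n = 400) {
  stopifnot(inherits(shape, "nlm_shape"))
  if (length(center_um) != 2 || any(!is.finite(center_um)))
    stop("degenerate placement: center_um must be two finite numbers")
  r_um <- particle$radius_m * 1e6
  centers <- if (inherits(particle, "nlm_dimer")) {
    u <- c(cos(axis_deg * pi / 180), sin(axis_deg * pi / 180))
    rbind(center_um + r_um * u, center_um - r_um * u)
  } else {
    rbind(center_um)
  }
  h <- 2 * r_um / grid_n
  s <- (seq_len(grid_n) - (grid_n + 1) / 2) * h
  gx <- rep(s, times = grid_n); gy <- rep(s, each = grid_n)
  rho2 <- gx^2 + gy^2
  disk <- rho2 <= r_um^2
  col_h <- 2 * sqrt(pmax(r_um^2 - rho2[disk], 0))
  vol_out <- 0
  for (k in seq_len(nrow(centers))) {
    inside <- point_in_footprint(shape, centers[k, 1] + gx[disk],
                                 centers[k, 2] + gy[disk])
    vol_out <- vol_out + sum(col_h[!inside]) * h^2
  }
  vol_tot <- nrow(centers) * 4 / 3 * pi * r_um^3
  vol_out / vol_tot
}
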