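#' Superparamagnetic bead specification
#'
#' Defaults describe 2.8 um streptavidin-coated SPM beads: density
#' 1.6e3 kg/m^3, saturation magnetization 11.2 A m^2/kg (an informational
#' cap on the induced moment; the simulator works in the linear,
#' unsaturated regime), volume susceptibility 0.7.
#'
#' @param diameter_um Bead diameter, um.
#' @param susceptibility Volume susceptibility (dimensionless, > 0).
#' @param density_kg_m3 Bead density.
#' @param msat_A_m2_kg Mass saturation magnetization.
#' @return An object of class `nlm_bead` with derived `radius_m`,
#'   `volume_m3` and `b_sat_T`, the flux density at which the induced
#'   moment would reach saturation.
#' @export
bead_spec <- function(diameter_um = 2.8, susceptibility = 0.7,
                      density_kg_m3 = 1.6e3, msat_A_m2_kg = 11.2) {
  if (diameter_um <= 0 || susceptibility <= 0) stop("radius and chi must be > 0")
  r <- diameter_um / 2 * 1e-6
  structure(list(diameter_um = diameter_um, radius_m = r,
                 volume_m3 = 4 / 3 * pi * r^3,
                 susceptibility = susceptibility,
                 density_kg_m3 = density_kg_m3,
                 msat_A_m2_kg = msat_A_m2_kg,
                 b_sat_T = msat_A_m2_kg * density_kg_m3 * .mu0 / susceptibility),
            class = "nlm_bead")
}

#' @export
print.nlm_bead <- function(x, ...) {
  cat(sprintf("<nlm_bead> %g um, chi = %g, saturates at %.3g mT\n",
              x$diameter_um, x$susceptibility, 1e3 * x$b_sat_T))
  invisible(x)
}

#' Rigid bead dimer specification
#'
#' Two identical touching beads (center separation = one diameter) moving
#' as a rigid body in the bead-center plane, with in-plane orientation
#' `phi` (angle of the longitudinal axis from +x). The default
#' `phi = pi/2` is the transverse orientation dimers adopt during
#' low-frequency transport.
#'
#' @param bead An [bead_spec()] object (both beads identical).
#' @param phi_rad Initial in-plane orientation, radians in `[0, 2 pi)`.
#' @param c_drag Translational drag correction factor relative to two
#'   independent spheres (default 1: independent-sphere drag; substrate
#'   hydrodynamic corrections are out of scope but can be absorbed here).
#' @return An object of class `nlm_dimer` (inherits bead fields).
#' @export
dimer_spec <- function(bead = bead_spec(), phi_rad = pi / 2, c_drag = 1) {
  stopifnot(inherits(bead, "nlm_bead"))
  phi_rad <- phi_rad %% (2 * pi)
  structure(c(bead, list(phi_rad = phi_rad, c_drag = c_drag)),
            class = c("nlm_dimer", "nlm_bead"))
}

#' @export
print.nlm_dimer <- function(x, ...) {
  cat(sprintf("<nlm_dimer> 2 x %g um beads, phi = %.3g rad, c_drag = %g\n",
              x$diameter_um, x$phi_rad, x$c_drag))
  invisible(x)
}

#' Stokes drag coefficients
#'
#' Translation: `6 pi eta r` for a monomer; twice that (times an optional
#' correction `c_drag`) for a dimer of independent spheres. Rotation of a
#' dimer about its center: two spheres at lever arm r, each with Stokes
#' translational drag, giving `2 * 6 pi eta r * r^2` (N m s).
#'
#' @param particle A [bead_spec()] or [dimer_spec()].
#' @param eta_Pa_s Medium viscosity.
#' @param mode `"translation"` or `"rotation"` (rotation only for dimers).
#' @return Drag coefficient (N s/m, or N m s for rotation).
#' @examples
#' drag_coefficient(bead_spec())    # 6 pi * 1e-3 * 1.4e-6
#' @export
drag_coefficient <- function(particle, eta_Pa_s = 1e-3,
                             mode = c("translation", "rotation")) {
  mode <- match.arg(mode)
  g1 <- 6 * pi * eta_Pa_s * particle$radius_m
  if (inherits(particle, "nlm_dimer")) {
    if (mode == "translation") 2 * g1 * particle$c_drag
    else 2 * g1 * particle$radius_m^2 * particle$c_drag
  } else {
    if (mode == "rotation") stop("rotational drag is defined for dimers only")
    g1
  }
}

# force prefactor L such that F = L * grad(|B|^2), per bead
.force_prefactor <- function(particle) {
  particle$volume_m3 * particle$susceptibility / (2 * .mu0)
}

#' Magnetic force on a particle from a sampled landscape
#'
#' `F = V chi grad(|B|^2) / (2 mu0)` per bead (linear, unsaturated
#' magnetization). For dimers the force is the sum of the two per-bead
#' forces evaluated at each bead center, and the in-plane torque about the
#' center is returned alongside.
#'
#' @param particle A [bead_spec()] or [dimer_spec()].
#' @param landscape An `nlm_landscape` (carries `gx`, `gy` in T^2/m).
#' @param position_um Particle center `c(x, y)` in um.
#' @param phi_rad Dimer orientation override (default: the spec's).
#' @return List with `force_N` (`c(Fx, Fy)`) and, for dimers,
#'   `torque_Nm` (z component).
#' @export
magnetic_force <- function(particle, landscape, position_um, phi_rad = NULL) {
  stopifnot(inherits(landscape, "nlm_landscape"))
  L <- .force_prefactor(particle)
  interp2 <- function(M, x0, y0) {
    if (x0 < min(landscape$x) || x0 > max(landscape$x) ||
        y0 < min(landscape$y) || y0 > max(landscape$y))
      stop("position outside the sampled landscape grid")
    i <- findInterval(x0, landscape$x, all.inside = TRUE)
    j <- findInterval(y0, landscape$y, all.inside = TRUE)
    tx <- (x0 - landscape$x[i]) / (landscape$x[i + 1] - landscape$x[i])
    ty <- (y0 - landscape$y[j]) / (landscape$y[j + 1] - landscape$y[j])
    (1 - tx) * (1 - ty) * M[i, j] + tx * (1 - ty) * M[i + 1, j] +
      (1 - tx) * ty * M[i, j + 1] + tx * ty * M[i + 1, j + 1]
  }
  if (inherits(particle, "nlm_dimer")) {
    if (is.null(phi_rad)) phi_rad <- particle$phi_rad
    r_um <- particle$radius_m * 1e6
    u <- c(cos(phi_rad), sin(phi_rad))
    p1 <- position_um + r_um * u
    p2 <- position_um - r_um * u
    F1 <- L * c(interp2(landscape$gx, p1[1], p1[2]),
                interp2(landscape$gy, p1[1], p1[2]))
    F2 <- L * c(interp2(landscape$gx, p2[1], p2[2]),
                interp2(landscape$gy, p2[1], p2[2]))
    arm <- particle$radius_m * u
    tau <- (arm[1] * F1[2] - arm[2] * F1[1]) - (arm[1] * F2[2] - arm[2] * F2[1])
    list(force_N = F1 + F2, torque_Nm = tau)
  } else {
    F1 <- L * c(interp2(landscape$gx, position_um[1], position_um[2]),
                interp2(landscape$gy, position_um[1], position_um[2]))
    list(force_N = F1)
  }
}

# Stable explicit time step: bound the landscape stiffness L * max|Hess(S)|
# by second differences of S = |B|^2 over the map grid at 8 drive phases,
# then take a fraction of the overdamped relaxation time gamma / k.
.stable_dt <- function(map, ext, particle, eta_Pa_s, safety = 0.25) {
  key <- paste("dt", map$z_um, map$grid_step_um, map$pitch_x_um,
               paste(deparse(map$array), collapse = ""),
               ext$bx_T, ext$bz_T, particle$diameter_um,
               particle$susceptibility, eta_Pa_s,
               inherits(particle, "nlm_dimer"), sep = "|")
  key <- gsub("\\s+", "", key)
  .cache_get(key, function() {
    h_m <- map$grid_step_um * 1e-6
    hmax <- 0
    for (S in .map_B2_grid(map, ext, seq(0, -315, by = -45))) {
      nx <- nrow(S); ny <- ncol(S)
      d2x <- (S[c(2:nx, 1), ] - 2 * S + S[c(nx, 1:(nx - 1)), ]) / h_m^2
      d2y <- (S[, c(2:ny, 1)] - 2 * S + S[, c(ny, 1:(ny - 1))]) / h_m^2
      hmax <- max(hmax, abs(d2x), abs(d2y))
    }
    L <- .force_prefactor(particle)
    gamma <- 6 * pi * eta_Pa_s * particle$radius_m   # per-bead drag
    safety * gamma / (L * hmax)
  })
}

# Vectorized overdamped Euler stepping of a set of identical particles.
# state: monomers -> matrix [x_um, y_um]; dimers -> [x_um, y_um, phi].
# Returns list(state, record) where record holds positions at the
# requested sample times (period boundaries).
.sim_population <- function(kind, state, map, ext, f_hz, t_end_s, dt_s,
                            particle, eta_Pa_s, sample_times = numeric(0),
                            active = NULL, absorb = NULL) {
  n_steps <- ceiling(t_end_s / dt_s)
  dt_s <- t_end_s / n_steps
  L <- .force_prefactor(particle)
  gamma_t <- drag_coefficient(particle, eta_Pa_s, "translation")
  gamma_r <- if (kind == "dimer") drag_coefficient(particle, eta_Pa_s, "rotation") else NA
  r_um <- particle$radius_m * 1e6
  d4 <- map$pitch_x_um / 4
  if (is.null(active)) active <- rep(TRUE, nrow(state))
  rec <- matrix(NA_real_, length(sample_times), nrow(state))
  rec_i <- 1L
  next_sample <- if (length(sample_times)) sample_times[1] else Inf
  t <- 0
  ## record any samples at (or before) the start time
  while (next_sample <= dt_s / 2 && rec_i <= length(sample_times)) {
    rec[rec_i, ] <- state[, 1]
    rec_i <- rec_i + 1L
    next_sample <- if (rec_i <= length(sample_times)) sample_times[rec_i] else Inf
  }
  for (s in seq_len(n_steps)) {
    th <- .theta_at(ext, f_hz, t)
    be <- ext_field_vector(ext, th)
    idx <- which(active)
    if (length(idx)) {
      if (kind == "monomer") {
        g <- .grad_B2(map, state[idx, 1], state[idx, 2], be)
        ddx <- (L / gamma_t) * g$gx * dt_s * 1e6     # um
        ddy <- (L / gamma_t) * g$gy * dt_s * 1e6
        if (max(abs(ddx), abs(ddy)) > d4)
          stop(sprintf("integration unstable: step displacement %.3g um > pitch/4 at t = %.3g s, f = %g Hz; reduce dt",
                       max(abs(ddx), abs(ddy)), t, f_hz))
        state[idx, 1] <- state[idx, 1] + ddx
        state[idx, 2] <- state[idx, 2] + ddy
      } else {
        ux <- cos(state[idx, 3]); uy <- sin(state[idx, 3])
        x1 <- state[idx, 1] + r_um * ux; y1 <- state[idx, 2] + r_um * uy
        x2 <- state[idx, 1] - r_um * ux; y2 <- state[idx, 2] - r_um * uy
        g1 <- .grad_B2(map, x1, y1, be)
        g2 <- .grad_B2(map, x2, y2, be)
        Fx1 <- L * g1$gx; Fy1 <- L * g1$gy
        Fx2 <- L * g2$gx; Fy2 <- L * g2$gy
        arm <- particle$radius_m
        tau <- arm * (ux * (Fy1 - Fy2) - uy * (Fx1 - Fx2))
        ddx <- (Fx1 + Fx2) / gamma_t * dt_s * 1e6
        ddy <- (Fy1 + Fy2) / gamma_t * dt_s * 1e6
        if (max(abs(ddx), abs(ddy)) > d4)
          stop(sprintf("integration unstable: step displacement %.3g um > pitch/4 at t = %.3g s, f = %g Hz; reduce dt",
                       max(abs(ddx), abs(ddy)), t, f_hz))
        state[idx, 1] <- state[idx, 1] + ddx
        state[idx, 2] <- state[idx, 2] + ddy
        state[idx, 3] <- state[idx, 3] + tau / gamma_r * dt_s
      }
    }
    t <- t + dt_s
    if (!is.null(absorb)) {
      out <- active & (state[, 1] < absorb[1] | state[, 1] > absorb[2])
      active[out] <- FALSE
    }
    while (t >= next_sample - dt_s / 2 && rec_i <= length(sample_times)) {
      rec[rec_i, ] <- state[, 1]
      rec_i <- rec_i + 1L
      next_sample <- if (rec_i <= length(sample_times)) sample_times[rec_i] else Inf
    }
  }
  list(state = state, record = rec, active = active, dt_s = dt_s)
}

#' Simulate NLM transport of one particle
#'
#' Integrates the overdamped (inertialess) equation of motion
#' `gamma dx/dt = F(x, theta(t))` in the bead-center plane, with the
#' magnetic force from the periodic field map and the rotating external
#' field. Dimers carry force plus torque and rotate rigidly in plane. The
#' dynamics are deterministic (thermal noise is negligible at these force
#' scales and is not modeled).
#'
#' The time step is the smaller of `period/200` and a stability bound
#' derived from the landscape stiffness; it is then rounded so an integer
#' number of steps spans each drive period, making period-averaged
#' velocities exact differences of period-boundary positions.
#'
#' @param particle A [bead_spec()] or [dimer_spec()].
#' @param array An [array_spec()] object.
#' @param ext An [external_field()] object.
#' @param f_hz Drive frequency, Hz.
#' @param n_periods Periods averaged for the velocity (after the skipped
#'   transient).
#' @param skip_periods Transient periods discarded.
#' @param dt_s Time step override (default: automatic).
#' @param eta_Pa_s Viscosity.
#' @param x0_um Start position `c(x, y)`; default: the flux-density maximum
#'   at phase 0.
#' @param grid_step_um,cell_um Field-map resolution.
#' @return An `nlm_traj`: data.frame of period-boundary states (`t_s`,
#'   `x_um`, `y_um`, and `phi` for dimers) with attributes `v_mean_um_s`
#'   (mean x velocity over the averaging window), `v_per_period_um_s`,
#'   `f_hz`, `dt_s`.
#' @export
simulate_transport <- function(particle, array, ext, f_hz, n_periods = 4,
                               skip_periods = 2, dt_s = NULL, eta_Pa_s = 1e-3,
                               x0_um = NULL, grid_step_um = 0.1, cell_um = 0.25) {
  stopifnot(inherits(particle, "nlm_bead"))
  if (f_hz <= 0) stop("f_hz must be > 0")
  map <- periodic_field_map(array, grid_step_um = grid_step_um, cell_um = cell_um)
  maxB <- sqrt(max(map$Bx^2 + map$By^2 + map$Bz^2)) + ext$bx_T + ext$bz_T
  if (maxB > particle$b_sat_T)
    warning(sprintf("peak field %.3g mT exceeds the bead saturation field %.3g mT; the linear-moment force overestimates",
                    1e3 * maxB, 1e3 * particle$b_sat_T))
  period <- 1 / f_hz
  if (is.null(dt_s))
    dt_s <- min(period / 200, .stable_dt(map, ext, particle, eta_Pa_s))
  steps_per_period <- max(ceiling(period / dt_s), 2L)
  dt_s <- period / steps_per_period
  if (is.null(x0_um)) x0_um <- .map_peak(map, ext, 0)
  kind <- if (inherits(particle, "nlm_dimer")) "dimer" else "monomer"
  state <- if (kind == "dimer") {
    matrix(c(x0_um[1], x0_um[2], particle$phi_rad), 1)
  } else matrix(x0_um[1:2], 1)
  total <- skip_periods + n_periods
  sample_times <- period * seq(0, total)
  res <- .sim_population(kind, state, map, ext, f_hz, total * period, dt_s,
                         particle, eta_Pa_s, sample_times = sample_times)
  ## record holds x at period boundaries (row 1 = t = 0 start)
  xs <- res$record[, 1]
  v_pp <- diff(xs) / period                               # um/s per period
  vwin <- v_pp[(skip_periods + 1):total]
  traj <- data.frame(t_s = sample_times, x_um = xs)
  structure(traj,
            v_mean_um_s = mean(vwin), v_per_period_um_s = vwin,
            f_hz = f_hz, dt_s = dt_s, final_state = res$state,
            class = c("nlm_traj", "data.frame"))
}

#' Simulated velocity-frequency profile
#'
#' Runs [simulate_transport()] over a frequency grid and collects the
#' period-averaged mean velocity and its dispersion across periods.
#'
#' @inheritParams simulate_transport
#' @param freqs_hz Frequency grid, Hz.
#' @return An `nlm_vprofile` data.frame (`freq_hz`, `v_um_s`, `v_sd`, `n`)
#'   with attribute `d_um` = pitch.
#' @export
velocity_vs_frequency <- function(particle, array, ext, freqs_hz,
                                  n_periods = 4, skip_periods = 2,
                                  eta_Pa_s = 1e-3, grid_step_um = 0.1,
                                  cell_um = 0.25) {
  rows <- lapply(freqs_hz, function(f) {
    tr <- simulate_transport(particle, array, ext, f, n_periods, skip_periods,
                             eta_Pa_s = eta_Pa_s, grid_step_um = grid_step_um,
                             cell_um = cell_um)
    vp <- attr(tr, "v_per_period_um_s")
    data.frame(freq_hz = f, v_um_s = attr(tr, "v_mean_um_s"),
               v_sd = stats::sd(vp), n = length(vp))
  })
  structure(do.call(rbind, rows), d_um = array$pitch_x_um,
            class = c("nlm_vprofile", "data.frame"))
}

# locked predicate: period-averaged velocity within locked_fraction of f*d
.is_locked <- function(particle, array, ext, f_hz, locked_fraction = 0.95, ...) {
  tr <- simulate_transport(particle, array, ext, f_hz, ...)
  attr(tr, "v_mean_um_s") >= locked_fraction * f_hz * array$pitch_x_um
}

#' Simulated critical frequency by bisection
#'
#' Finds the locked/slipping boundary of the simulated dynamics: doubles
#' the frequency from `f_start` until the particle unlocks (period-averaged
#' velocity below `locked_fraction * f d`), then bisects to relative
#' tolerance `rel_tol`.
#'
#' @inheritParams simulate_transport
#' @param f_start Initial (locked) guess, Hz.
#' @param f_max Abort bound, Hz.
#' @param locked_fraction Locking criterion.
#' @param rel_tol Relative bracket width at termination.
#' @return Critical frequency estimate (Hz) with attribute
#'   `bracket = c(locked, unlocked)`.
#' @export
simulated_critical_frequency <- function(particle, array, ext, f_start = 10,
                                         f_max = 5000, locked_fraction = 0.95,
                                         rel_tol = 0.02, eta_Pa_s = 1e-3,
                                         grid_step_um = 0.1, cell_um = 0.25) {
  args <- list(eta_Pa_s = eta_Pa_s, grid_step_um = grid_step_um,
               cell_um = cell_um)
  locked <- function(f) do.call(.is_locked,
    c(list(particle, array, ext, f, locked_fraction), args))
  f_lo <- f_start
  while (!locked(f_lo)) {
    f_lo <- f_lo / 2
    if (f_lo < 1e-2) stop("particle not even locked at 0.01 Hz; check parameters")
  }
  f_hi <- f_lo * 2
  while (locked(f_hi)) {
    f_lo <- f_hi; f_hi <- f_hi * 2
    if (f_hi > f_max) stop("still phase-locked at f_max = ", f_max, " Hz")
  }
  while ((f_hi - f_lo) / f_lo > rel_tol) {
    f_mid <- sqrt(f_lo * f_hi)
    if (locked(f_mid)) f_lo <- f_mid else f_hi <- f_mid
  }
  structure(sqrt(f_lo * f_hi), bracket = c(f_lo, f_hi))
}

#' Simulated immobilization frequency (first threshold crossing)
#'
#' Smallest frequency at which the simulated period-averaged velocity
#' falls below `fraction` of the maximum velocity `fc * d`. The
#' deterministic dynamics can re-lock at subharmonic steps well above the
#' knee, so the search is an upward geometric scan for the first crossing
#' (matching the operational first-crossing definition), with the crossing
#' linearly interpolated between the last two samples. Velocities in the
#' slipping regime are averaged over many periods because the slip cycle
#' is incommensurate with the drive.
#'
#' @inheritParams simulated_critical_frequency
#' @param fc_hz Simulated critical frequency (from
#'   [simulated_critical_frequency()]).
#' @param fraction Threshold fraction of the maximum velocity.
#' @param step_ratio Geometric scan step (frequency multiplier per sample).
#' @param n_periods Averaging window per sample, drive periods.
#' @return Immobilization frequency estimate (Hz); attribute
#'   `censored = TRUE` (value `f_max`) if the velocity never crosses.
#' @export
simulated_immobilization_frequency <- function(particle, array, ext, fc_hz,
                                               fraction = 0.1, f_max = 50 * fc_hz,
                                               step_ratio = 1.12,
                                               n_periods = 20, eta_Pa_s = 1e-3,
                                               grid_step_um = 0.1,
                                               cell_um = 0.25) {
  v_at <- function(f) {
    tr <- simulate_transport(particle, array, ext, f, n_periods = n_periods,
                             skip_periods = 4, eta_Pa_s = eta_Pa_s,
                             grid_step_um = grid_step_um, cell_um = cell_um)
    attr(tr, "v_mean_um_s")
  }
  v_thr <- fraction * fc_hz * array$pitch_x_um
  f_prev <- fc_hz
  v_prev <- v_at(f_prev)
  f <- fc_hz * step_ratio
  repeat {
    v <- v_at(f)
    if (v < v_thr) {
      ## interpolate the crossing on (f, v)
      fi <- f_prev + (v_thr - v_prev) * (f - f_prev) / (v - v_prev)
      return(structure(fi, censored = FALSE))
    }
    f_prev <- f; v_prev <- v
    f <- f * step_ratio
    if (f > f_max) {
      warning("velocity above threshold up to f_max; returning f_max (censored)")
      return(structure(f_max, censored = TRUE))
    }
  }
}

#' Separation schedule
#'
#' Three-phase drive program of the monomer/dimer separation protocol:
#' forward loading at a low (locked) frequency, a hold at the separation
#' frequency where dimers are immobile but monomers still advance off the
#' +x edge, and a reversed-rotation recovery phase that walks the retained
#' dimers back toward -x.
#'
#' @param f_load_hz,t_load_s Loading phase (locked transport).
#' @param f_sep_hz,t_sep_s Separation hold.
#' @param f_return_hz,t_return_s Reversed-rotation recovery.
#' @return A list of phases, class `nlm_schedule`.
#' @export
separation_schedule <- function(f_load_hz, t_load_s, f_sep_hz, t_sep_s,
                                f_return_hz, t_return_s) {
  structure(list(
    list(f_hz = f_load_hz, t_s = t_load_s, sense = 1),
    list(f_hz = f_sep_hz, t_s = t_sep_s, sense = 1),
    list(f_hz = f_return_hz, t_s = t_return_s, sense = -1)),
    class = "nlm_schedule")
}

#' Design a separation schedule from species characteristics
#'
#' Places the separation frequency just below the monomer critical
#' frequency, inside the window where monomers are still phase-locked
#' (advancing at the full `f d`) while dimers, whose critical frequency is
#' lower, slip at a substantially reduced velocity. The hold is sized so
#' the monomers clear the array (with a safety margin) while the slipping
#' dimers, by the closed-form velocity ratio, do not.
#'
#' @param mono_char,dimer_char `nlm_freqchar` objects for the two species
#'   (simulated or measured).
#' @param array The target [array_spec()].
#' @param travel_um Distance the monomers must cover (default: full array
#'   length plus one pitch).
#' @param margin Safety factor on the hold duration.
#' @param window_fraction Position of the separation frequency within the
#'   locked window, as a fraction of the monomer critical frequency.
#' @return An `nlm_schedule`.
#' @export
design_schedule <- function(mono_char, dimer_char, array, travel_um = NULL,
                            margin = 1.15, window_fraction = 0.95) {
  if (dimer_char$fc_hz >= mono_char$fc_hz)
    stop("no separation window: dimer critical frequency is not below the monomer's")
  f_sep <- window_fraction * mono_char$fc_hz
  if (f_sep <= dimer_char$fc_hz)
    stop("separation window too narrow: f_sep would not exceed the dimer critical frequency")
  if (is.null(travel_um)) travel_um <- array$n_x * array$pitch_x_um + array$pitch_x_um
  v_mono <- f_sep * array$pitch_x_um          # locked
  f_load <- 0.5 * dimer_char$fc_hz
  separation_schedule(
    f_load_hz = f_load, t_load_s = 2 / f_load,
    f_sep_hz = f_sep, t_sep_s = margin * travel_um / v_mono,
    f_return_hz = f_load, t_return_s = 4 / f_load)
}

#' Simulate the monomer/dimer separation protocol
#'
#' Runs a mixed particle population through a [separation_schedule()] on a
#' finite array. Particles leaving the array edges are absorbed: monomers
#' cleared off the +x edge are successfully removed, dimers cleared off +x
#' are lost aggregates. Particles flagged `stuck` (nonspecific adhesion,
#' drawn upstream by [synth_population()]) never move.
#'
#' Efficiency is `epsilon = 1 - f_sb - f_agg` with `f_sb` the fraction of
#' single beads retained (immobilized) on the array and `f_agg` the
#' fraction of dimers lost.
#'
#' @param population Data frame from [synth_population()] (columns
#'   `species`, `x_um`, `y_um`, `phi`, `stuck`).
#' @param array An [array_spec()] object.
#' @param ext An [external_field()] object.
#' @param schedule An `nlm_schedule`.
#' @param bead Monomer [bead_spec()] (dimers are built from the same bead).
#' @param eta_Pa_s Viscosity.
#' @param grid_step_um,cell_um Field-map resolution.
#' @return An `nlm_sep`: per-particle `fates` data.frame plus `f_sb`,
#'   `f_agg`, `efficiency`, and counts.
#' @export
separation_protocol <- function(population, array, ext, schedule,
                                bead = bead_spec(), eta_Pa_s = 1e-3,
                                grid_step_um = 0.1, cell_um = 0.25) {
  if (nrow(population) == 0) stop("empty population")
  stopifnot(all(c("species", "x_um", "y_um", "stuck") %in% names(population)))
  map <- periodic_field_map(array, grid_step_um = grid_step_um, cell_um = cell_um)
  edges <- c(array$origin_um[1] - array$pitch_x_um / 2,
             array$origin_um[1] + (array$n_x - 1) * array$pitch_x_um +
               array$pitch_x_um / 2)
  dimer <- dimer_spec(bead)
  run_species <- function(kind, particle, rows) {
    if (nrow(rows) == 0)
      return(data.frame(id = integer(0), cleared_plus = logical(0)))
    state <- if (kind == "dimer") {
      cbind(rows$x_um, rows$y_um, rows$phi)
    } else cbind(rows$x_um, rows$y_um)
    active <- !rows$stuck
    for (ph in schedule) {
      e <- ext
      e$sense <- ext$sense * ph$sense
      dt <- min(1 / ph$f_hz / 200, .stable_dt(map, e, particle, eta_Pa_s))
      res <- .sim_population(kind, state, map, e, ph$f_hz, ph$t_s, dt,
                             particle, eta_Pa_s, active = active,
                             absorb = edges)
      state <- res$state
      active <- res$active & !rows$stuck
    }
    data.frame(id = rows$id,
               x_final_um = state[, 1],
               cleared_plus = state[, 1] > edges[2],
               cleared_minus = state[, 1] < edges[1])
  }
  population$id <- seq_len(nrow(population))
  mono_rows <- population[population$species == "monomer", ]
  dim_rows <- population[population$species == "dimer", ]
  out <- rbind(run_species("monomer", bead, mono_rows),
               run_species("dimer", dimer, dim_rows))
  out <- out[order(out$id), ]
  fates <- merge(population, out, by = "id")
  fates$fate <- ifelse(fates$cleared_plus, "cleared_plus",
                       ifelse(fates$cleared_minus, "cleared_minus", "retained"))
  n_mono <- nrow(mono_rows); n_dim <- nrow(dim_rows)
  f_sb <- if (n_mono) sum(fates$species == "monomer" &
                          fates$fate != "cleared_plus") / n_mono else 0
  f_agg <- if (n_dim) sum(fates$species == "dimer" &
                          fates$fate == "cleared_plus") / n_dim else 0
  structure(list(fates = fates, f_sb = f_sb, f_agg = f_agg,
                 efficiency = 1 - f_sb - f_agg,
                 n_monomer = n_mono, n_dimer = n_dim,
                 schedule = schedule),
            class = "nlm_sep")
}

#' @export
print.nlm_sep <- function(x, ...) {
  cat(sprintf("<nlm_sep> %d monomers, %d dimers: f_sb = %.3f, f_agg = %.3f, efficiency = %.3f\n",
              x$n_monomer, x$n_dimer, x$f_sb, x$f_agg, x$efficiency))
  invisible(x)
}
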