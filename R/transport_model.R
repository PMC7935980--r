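#' Geometric shape factor of the critical frequency
#'
#' `g(beta) = (2 pi beta)^2 exp(-2 pi beta)` with `beta = r / d` the ratio
#' of bead radius to lattice pitch. The factor has a unique interior
#' maximum at `beta = 1/pi` where `g = 4 exp(-2)`: beads much smaller than
#' the pitch couple weakly to the landscape, beads comparable to it average
#' the landscape out.
#'
#' @param beta Bead radius over lattice pitch (must be > 0; vectorized).
#' @return The shape factor (positive scalar/vector).
#' @examples
#' shape_factor(1 / pi)        # 4 * exp(-2) ~ 0.5413, the maximum
#' shape_factor(1.4 / 8)       # 2.8 um beads on an 8 um pitch
#' @export
shape_factor <- function(beta) {
  if (any(beta <= 0)) stop("beta must be > 0")
  (2 * pi * beta)^2 * exp(-2 * pi * beta)
}

#' Transport-model parameters
#'
#' Aggregates the bead and array properties entering the critical-frequency
#' law. The coupling `kappa` collapses `chi * mu0 * sigma0(H_ext) / (18 eta)`
#' into a single rate constant (1/s): the field-distribution parameter
#' sigma0 is experimental, so kappa is calibrated from one measured critical
#' frequency via [calibrate_coupling()] rather than derived.
#'
#' All user-facing frequencies are cyclic (Hz).
#'
#' @param r_um Bead radius, um (default 1.4: a 2.8 um bead).
#' @param d_um Lattice pitch along the transport direction, um.
#' @param chi Bead volume susceptibility (dimensionless; default 0.7,
#'   typical of 2.8 um streptavidin beads). Used by the dynamics module's
#'   force scale, not by the closed-form law once kappa is calibrated.
#' @param eta_Pa_s Medium viscosity (default 1e-3, aqueous buffer at room
#'   temperature).
#' @param kappa_s Coupling constant, 1/s (NA until calibrated).
#' @return An object of class `nlm_transport_params` with derived
#'   `beta = r/d`.
#' @export
transport_params <- function(r_um = 1.4, d_um = 8, chi = 0.7,
                             eta_Pa_s = 1e-3, kappa_s = NA_real_) {
  if (r_um <= 0 || d_um <= 0) stop("r_um and d_um must be > 0")
  beta <- r_um / d_um
  if (beta >= 0.5) stop("beta = r/d must be < 0.5 (bead smaller than one pitch)")
  if (eta_Pa_s <= 0) stop("viscosity must be > 0")
  if (!is.na(kappa_s) && kappa_s < 0) stop("kappa must be >= 0")
  structure(list(r_um = r_um, d_um = d_um, beta = beta, chi = chi,
                 eta_Pa_s = eta_Pa_s, kappa_s = kappa_s),
            class = "nlm_transport_params")
}

#' @export
print.nlm_transport_params <- function(x, ...) {
  cat(sprintf("<nlm_transport_params> r = %g um, d = %g um (beta = %.4g), chi = %g, eta = %g Pa s, kappa = %s\n",
              x$r_um, x$d_um, x$beta, x$chi, x$eta_Pa_s,
              if (is.na(x$kappa_s)) "uncalibrated" else sprintf("%.4g /s", x$kappa_s)))
  invisible(x)
}

#' Calibrate the coupling constant from a measured critical frequency
#'
#' Inverts the critical-frequency law: `kappa = 2 pi f_c / g(beta)`, so that
#' [critical_frequency()] returns the measured value exactly. Calibration
#' from one measurement is the intended use of the law; monomers and dimers
#' generally calibrate to different kappa (species-specific coupling).
#'
#' @param measured_fc_hz Measured critical frequency, Hz (> 0).
#' @param beta Bead radius over pitch.
#' @return kappa in 1/s.
#' @examples
#' k <- calibrate_coupling(27, 1.4 / 8)
#' critical_frequency(transport_params(kappa_s = k))   # 27 Hz
#' @export
calibrate_coupling <- function(measured_fc_hz, beta) {
  if (measured_fc_hz <= 0) stop("measured critical frequency must be > 0")
  2 * pi * measured_fc_hz / shape_factor(beta)
}

#' Critical frequency of NLM transport
#'
#' `f_c = kappa * g(beta) / (2 pi)` in Hz: the drive frequency above which
#' hydrodynamic drag exceeds the available magnetic restoring force and the
#' bead starts slipping against the translating landscape.
#'
#' @param params An [transport_params()] object with calibrated `kappa_s`.
#' @return Critical frequency in Hz.
#' @export
critical_frequency <- function(params) {
  stopifnot(inherits(params, "nlm_transport_params"))
  if (is.na(params$kappa_s))
    stop("kappa is uncalibrated: supply kappa_s or use calibrate_coupling() ",
         "with a measured critical frequency")
  params$kappa_s * shape_factor(params$beta) / (2 * pi)
}

#' Closed-form bead velocity versus drive frequency
#'
#' Phase-locked below the critical frequency (`v = f d`), phase-slipping
#' above it (`v = (f - sqrt(f^2 - f_c^2)) d`); the two branches meet
#' continuously at `f = f_c` where the velocity peaks at `f_c d`.
#'
#' @param f_hz Drive frequency, Hz (vectorized).
#' @param fc_hz Critical frequency, Hz.
#' @param d_um Lattice pitch, um.
#' @return Mean velocity in um/s.
#' @examples
#' closed_form_velocity(10, 27, 8)    # 80 um/s, phase-locked
#' closed_form_velocity(54, 27, 8)    # (2 - sqrt(3)) * 27 * 8
#' @export
closed_form_velocity <- function(f_hz, fc_hz, d_um) {
  if (any(f_hz < 0) || fc_hz < 0 || d_um <= 0)
    stop("frequencies must be >= 0 and pitch > 0")
  v <- ifelse(f_hz <= fc_hz,
              f_hz * d_um,
              (f_hz - sqrt(pmax(f_hz^2 - fc_hz^2, 0))) * d_um)
  as.numeric(v)
}

#' Closed-form velocity-frequency profile
#'
#' Convenience wrapper producing an `nlm_vprofile` table from the
#' closed-form law, optionally with seeded multiplicative noise emulating
#' measurement scatter.
#'
#' @param freqs_hz Frequency grid, Hz.
#' @param fc_hz Critical frequency, Hz.
#' @param d_um Pitch, um.
#' @param noise_sd Multiplicative noise sd (0 = exact).
#' @param seed RNG seed used when `noise_sd > 0`.
#' @return An `nlm_vprofile` data.frame (`freq_hz`, `v_um_s`, `v_sd`, `n`).
#' @export
closed_form_profile <- function(freqs_hz, fc_hz, d_um, noise_sd = 0, seed = NULL) {
  v <- closed_form_velocity(freqs_hz, fc_hz, d_um)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    v <- v * (1 + stats::rnorm(length(v), 0, noise_sd))
  }
  structure(data.frame(freq_hz = freqs_hz, v_um_s = v,
                       v_sd = abs(v) * noise_sd, n = 1L),
            d_um = d_um, class = c("nlm_vprofile", "data.frame"))
}

#' Immobilization frequency from a velocity profile
#'
#' Smallest frequency at which the mean velocity falls below a fraction
#' (default 10 percent) of the profile maximum, linearly interpolated
#' between samples. Operationally, beads above this frequency only rock in
#' place ("immobile"). For the exact closed-form profile the 10 percent
#' rule gives `f_i = 5.05 f_c`.
#'
#' @param profile An `nlm_vprofile` (or data.frame with `freq_hz`, `v_um_s`).
#' @param fraction Threshold fraction of the maximum velocity.
#' @return Frequency in Hz. If the velocity never falls below threshold the
#'   sweep maximum is returned with attribute `censored = TRUE` and a
#'   warning.
#' @export
immobilization_frequency <- function(profile, fraction = 0.1) {
  f <- profile$freq_hz; v <- profile$v_um_s
  o <- order(f); f <- f[o]; v <- v[o]
  vmax <- max(v)
  imax <- which.max(v)
  thr <- fraction * vmax
  below <- which(v < thr & seq_along(v) >= imax)
  if (length(below) == 0) {
    warning("velocity never falls below the threshold within the sweep; ",
            "returning the sweep maximum (censored)")
    return(structure(max(f), censored = TRUE))
  }
  k <- below[1]
  if (k == 1) return(structure(f[1], censored = FALSE))
  ## linear interpolation of the crossing
  fi <- f[k - 1] + (thr - v[k - 1]) * (f[k] - f[k - 1]) / (v[k] - v[k - 1])
  structure(fi, censored = FALSE)
}

#' Sharpness parameter Omega = f_c / f_i
#'
#' Ratio of critical to immobilization frequency: a sharpness measure of
#' the mobile-to-immobile transition. Values close to 1 mean an abrupt
#' transition (precise frequency-selective separation); small values mean a
#' long slipping tail.
#'
#' @param fc_hz Critical frequency, Hz (> 0).
#' @param fi_hz Immobilization frequency, Hz (>= fc_hz).
#' @return Omega in (0, 1].
#' @examples
#' omega_ratio(22.5, 30)   # 0.75
#' @export
omega_ratio <- function(fc_hz, fi_hz) {
  if (any(fc_hz <= 0)) stop("fc must be > 0")
  if (any(fc_hz > fi_hz))
    stop("inconsistent characteristics: fc must not exceed fi")
  fc_hz / fi_hz
}

#' Frequency characteristics of one particle species
#'
#' @param fc_hz Critical frequency, Hz.
#' @param fi_hz Immobilization frequency, Hz.
#' @return An object of class `nlm_freqchar` with `fc_hz`, `fi_hz` and
#'   `omega`.
#' @export
frequency_characteristics <- function(fc_hz, fi_hz) {
  structure(list(fc_hz = fc_hz, fi_hz = fi_hz,
                 omega = omega_ratio(fc_hz, fi_hz)),
            class = "nlm_freqchar")
}

#' @export
print.nlm_freqchar <- function(x, ...) {
  cat(sprintf("<nlm_freqchar> fc = %.3g Hz, fi = %.3g Hz, Omega = %.3g\n",
              x$fc_hz, x$fi_hz, x$omega))
  invisible(x)
}

#' Critical frequency estimated from a sampled velocity profile
#'
#' Two estimators. `"threshold"`: the first frequency at which the mean
#' velocity diverges below 95 percent of the phase-locked line `f d`
#' (crossing linearly interpolated on the ratio `v / (f d)`); this
#' operationalizes "velocity starts to diverge from the landscape
#' velocity". `"fit"`: least-squares fit of the full closed-form profile,
#' robust for noisy data.
#'
#' @param profile An `nlm_vprofile`.
#' @param d_um Lattice pitch, um (taken from the profile attribute when
#'   absent).
#' @param method `"threshold"` or `"fit"`.
#' @param locked_fraction Divergence threshold for `"threshold"`.
#' @return Estimated critical frequency in Hz. Flagged with attribute
#'   `censored = TRUE` (and the sweep maximum returned) when the knee lies
#'   beyond the sweep.
#' @export
estimate_critical_frequency <- function(profile, d_um = NULL,
                                        method = c("threshold", "fit"),
                                        locked_fraction = 0.95) {
  method <- match.arg(method)
  if (is.null(d_um)) d_um <- attr(profile, "d_um")
  if (is.null(d_um)) stop("d_um not given and not stored on the profile")
  f <- profile$freq_hz; v <- profile$v_um_s
  o <- order(f); f <- f[o]; v <- v[o]
  if (method == "fit") {
    sse <- function(fc) sum((v - closed_form_velocity(f, fc, d_um))^2)
    opt <- optimize(sse, interval = c(min(f) / 2, 2 * max(f)))
    return(structure(opt$minimum, censored = FALSE))
  }
  ratio <- v / (f * d_um)
  below <- which(ratio < locked_fraction)
  if (length(below) == 0) {
    warning("no divergence from the phase-locked line within the sweep")
    return(structure(max(f), censored = TRUE))
  }
  k <- below[1]
  if (k == 1) return(structure(f[1], censored = TRUE))
  fc <- f[k - 1] + (locked_fraction - ratio[k - 1]) * (f[k] - f[k - 1]) /
        (ratio[k] - ratio[k - 1])
  structure(fc, censored = FALSE)
}

#' Frequency characteristics from a sampled velocity profile
#'
#' Applies the 95-percent-of-`f d` rule for the critical frequency and the
#' 10-percent-of-maximum rule for the immobilization frequency, then forms
#' Omega.
#'
#' @param profile An `nlm_vprofile` spanning the knee and the decay.
#' @param d_um Lattice pitch, um.
#' @param locked_fraction Divergence threshold for f_c.
#' @param immobile_fraction Velocity fraction defining f_i.
#' @return An `nlm_freqchar`.
#' @export
profile_characteristics <- function(profile, d_um = NULL,
                                    locked_fraction = 0.95,
                                    immobile_fraction = 0.1) {
  fc <- estimate_critical_frequency(profile, d_um, "threshold", locked_fraction)
  fi <- immobilization_frequency(profile, immobile_fraction)
  ch <- frequency_characteristics(as.numeric(fc), as.numeric(fi))
  ch$fc_censored <- isTRUE(attr(fc, "censored"))
  ch$fi_censored <- isTRUE(attr(fi, "censored"))
  ch
}

#' Write a velocity profile as CSV
#'
#' @param profile An `nlm_vprofile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  write.csv(as.data.frame(profile), path, row.names = FALSE)
  invisible(path)
}
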