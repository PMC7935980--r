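#' Heat map of a flux-density landscape
#'
#' @param landscape An `nlm_landscape`.
#' @param unit `"mT"` or `"T"`.
#' @return A ggplot object (filled raster of |B| with equal axes).
#' @export
plot_landscape <- function(landscape, unit = c("mT", "T")) {
  unit <- match.arg(unit)
  g <- expand.grid(x_um = landscape$x, y_um = landscape$y,
                   KEEP.OUT.ATTRS = FALSE)
  g$B <- as.vector(landscape$Bmag) * if (unit == "mT") 1e3 else 1
  ggplot2::ggplot(g, ggplot2::aes(x = x_um, y = y_um,
                                  fill = B)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = paste0("|B| (", unit, ")"),
                                  option = "inferno") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("theta = %g deg, z = %g um",
                                  landscape$theta_deg, landscape$z_um))
}

#' Velocity-frequency profile plot
#'
#' Mean velocity with error bars against the drive frequency, with the
#' phase-locked line `v = f d` for reference.
#'
#' @param profile An `nlm_vprofile`.
#' @param d_um Lattice pitch for the reference line (from the profile
#'   attribute when absent).
#' @return A ggplot object.
#' @export
plot_velocity_profile <- function(profile, d_um = NULL) {
  if (is.null(d_um)) d_um <- attr(profile, "d_um")
  p <- ggplot2::ggplot(as.data.frame(profile),
                       ggplot2::aes(x = freq_hz, y = v_um_s)) +
    ggplot2::geom_point() + ggplot2::geom_line() +
    ggplot2::labs(x = "drive frequency (Hz)", y = "mean velocity (um/s)")
  if (!is.null(profile$v_sd) && any(profile$v_sd > 0, na.rm = TRUE))
    p <- p + ggplot2::geom_errorbar(ggplot2::aes(
      ymin = v_um_s - v_sd, ymax = v_um_s + v_sd),
      width = 0)
  if (!is.null(d_um))
    p <- p + ggplot2::geom_abline(slope = d_um, intercept = 0,
                                  linetype = "dashed")
  p
}

#' Overlayed normalized line profiles
#'
#' @param profiles Named list of `nlm_profile` objects (names become the
#'   legend labels, e.g. `a`, `b`, `c`).
#' @return A ggplot object.
#' @export
plot_line_profiles <- function(profiles) {
  d <- do.call(rbind, lapply(names(profiles), function(nm) {
    data.frame(line = nm, x_um = profiles[[nm]]$x_um,
               value = profiles[[nm]]$value)
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = x_um, y = value,
                                  color = line)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "x (um)", y = "normalized |B|", color = "line")
}

# non-standard-evaluation columns used in ggplot calls
utils::globalVariables(c("x_um", "y_um", "B", "freq_hz", "v_um_s", "v_sd",
                         "value", "line"))
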