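# Shared fixtures. Everything is generated in code; the expensive pieces
# (field maps, simulated critical frequencies) are memoized for the whole
# test run.

ext_default <- function() external_field()   # 30 G / 35 G, sense +1

# window covering one magnet row, centered so row maxima are interior
row_window <- function(array) {
  c(-array$pitch_x_um, array$pitch_x_um,
    -array$pitch_y_um / 2, array$pitch_y_um / 2)
}

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, fn) {
  if (is.null(.fixture_env[[key]])) assign(key, fn(), envir = .fixture_env)
  .fixture_env[[key]]
}

# simulated critical frequency per geometry and species, memoized
fc_sim <- function(geometry, kind = c("monomer", "dimer")) {
  kind <- match.arg(kind)
  memo(paste0("fc_", geometry, "_", kind), function() {
    particle <- if (kind == "dimer") dimer_spec() else bead_spec()
    as.numeric(simulated_critical_frequency(particle, default_array(geometry),
                                            ext_default()))
  })
}

# brute-force surface-charge oracle for the x-magnetized prism: magnetic
# charge +/- M on the two x-faces, integrated by seeded Monte Carlo
prism_mc_oracle <- function(dims_um, M_A_m, point_um, n = 4e5, seed = 99) {
  set.seed(seed)
  half <- dims_um / 2 * 1e-6
  p <- point_um * 1e-6
  H <- c(0, 0, 0)
  area <- dims_um[2] * dims_um[3] * 1e-12
  for (s in c(1, -1)) {
    ys <- runif(n, -half[2], half[2])
    zs <- runif(n, -half[3], half[3])
    rx <- p[1] - s * half[1]; ry <- p[2] - ys; rz <- p[3] - zs
    r3 <- (rx^2 + ry^2 + rz^2)^1.5
    H <- H + s * M_A_m / (4 * pi) * area *
      c(mean(rx / r3), mean(ry / r3), mean(rz / r3))
  }
  4e-7 * pi * H   # B = mu0 H outside the magnet
}
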