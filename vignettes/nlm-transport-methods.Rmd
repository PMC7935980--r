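---
title: "Modeling nonlinear magnetophoresis on micromagnet arrays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling nonlinear magnetophoresis on micromagnet arrays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nlmag)
```

## The physical system

Nonlinear magnetophoresis (NLM) transports superparamagnetic (SPM) beads
across a chip patterned with a rectilinear lattice of micron-scale magnets
(a micromagnet array, MMA). The magnets are magnetized in-plane along +x;
an external field of a few millitesla rotates in the xz-plane. The
superposition of the static array field and the rotating uniform field
produces a landscape of flux-density maxima that translates by exactly one
lattice pitch per field rotation. A bead magnetizes linearly in the local
field and is pulled toward the maxima with force

    F = V chi grad(|B|^2) / (2 mu0),

so at low drive frequency it rides a maximum at velocity `v = f d` (the
*phase-locked* regime; `d` is the pitch along x). Above a *critical
frequency* `f_c` the Stokes drag `6 pi eta r v` required to keep up exceeds
the available magnetic restoring force and the bead periodically slips,
with mean velocity

    v = [f - sqrt(f^2 - f_c^2)] d,

decaying toward zero. Because `f_c` depends on bead size and on how much of
the particle samples the strong-field region of a magnet, bead *dimers*
(two beads rigidly linked by a captured analyte) unlock at lower frequency
than monomers on magnets smaller than the dimer — the physical basis of
on-chip separation of assay product from unreacted beads.

The closed-form critical frequency is parameterized here as

    f_c = kappa * g(beta) / (2 pi),      g(beta) = (2 pi beta)^2 e^(-2 pi beta),

with `beta = r/d`. The coupling `kappa` collapses the bead susceptibility,
the vacuum permeability, an empirical field-distribution factor and the
viscosity (`chi mu0 sigma0(H_ext) / 18 eta`) into one rate constant. The
field-distribution factor is not derivable from tabulated constants, so
`kappa` is treated as calibratable from a single measured `f_c`
(`calibrate_coupling()`), after which the law predicts the full velocity
profile. `g(beta)` has a unique interior maximum at `beta = 1/pi` — beads
much smaller than the pitch couple weakly, beads comparable to the pitch
average the landscape out.

## Magnetostatics: dipole rasterization with an analytic oracle

Reference studies of these chips compute the field landscape with
commercial finite-element solvers. This package instead rasterizes each
magnet footprint into square cells (default 0.25 um, with per-cell
coverage fractions from a 6 x 6 subgrid) carrying point dipoles at the
magnetic layer's mid-thickness, and sums their fields with a compiled
kernel. The method is shape-agnostic — circle, square, equilateral
triangle and rectangle are implemented — and its accuracy is controlled
against an independent analytic oracle: the closed-form field of a
uniformly x-magnetized rectangular prism (`prism_flux_density()`, the
classical surface-charge corner sums). At bead-plane heights (z >= 1 um
above the magnet top) the raster solver agrees with the oracle to better
than 0.5 percent at the default cell size; the oracle itself is verified
in the test suite against seeded Monte-Carlo surface-charge integration
and against the equal-moment dipole in the far field.

Assumptions inherited from the reference FEM treatment: uniform
magnetization of 80 kA/m along +x (no self-consistent micromagnetics, no
hysteresis), chromium cap layers magnetically ignored, and the 100 nm
magnetic layer collapsed to a single dipole sheet at mid-thickness —
justified because the evaluation height (about 2 um) is twenty times the
layer thickness. The 80 kA/m value is far below cobalt saturation; whether
it encodes an effective remanence is not stated in the source material, so
it is treated as the authoritative boundary condition and is exposed in
the array configuration.

Array sums truncate at magnets within 5 lattice periods of the evaluation
window; dipole fields decay at least as r^-3, making the truncation error
below 0.5 percent. Landscapes are sampled by default at the bead-center
plane: 600 nm of spin-on glass plus a 1.4 um bead radius above the magnet
top.

## Geometry defaults

The four reference arrays (`default_array()`):

| geometry | magnet | lateral size (um) | pitch x/y (um) |
|---|---|---|---|
| C | circle | 5 (diameter) | 8 / 8 |
| S | square | 5 (side) | 8 / 8 |
| T | equilateral triangle | 5 (side) | 8 / 8 |
| R | rectangle | 5 x 12.5 | 8 / 16 |

All are 100 nm thick under 600 nm of glass. The source material never
states the triangle's orientation relative to the transport axis; because
triangular landscapes are explicitly not mirror-symmetric in x, the vertex
direction is a configuration flag, defaulting to +x (one side parallel
to y).

The drive is an ellipsoidal rotating field, 30 G along x and 35 G along z,
with phase advancing by -360 degrees per period for +x transport; gauss
are accepted at all configuration interfaces and converted at 1 G = 1e-4 T.

## Trajectory dynamics

`simulate_transport()` integrates the overdamped equation of motion
`gamma dx/dt = F(x, theta(t))` in the bead-center plane. Inertia is
irrelevant (Reynolds and Stokes numbers are far below one) and thermal
noise is not modeled: at these force scales (tens of piconewtons) the
Peclet number is enormous and the reference transport model is
deterministic. Dimers are rigid touching pairs with an in-plane
orientation angle; they feel the sum of the two per-bead forces and the
corresponding torque, with translational drag twice the single-sphere
Stokes value (an optional correction factor `c_drag` is exposed but
defaults to 1; substrate-wall hydrodynamic corrections are deliberately
out of scope) and rotational drag `2 (6 pi eta r) r^2`. The vertical
degree of freedom is frozen at the bead-center plane, matching the 2-D
landscape analysis of the reference treatment.

Because only the uniform external field varies in time, the total field at
any phase is the static array field plus the external vector. The static
components and their in-plane derivatives are therefore precomputed once
per array on one lattice period (0.1 um grid, cached for the session) and
the integrator works from bilinear periodic interpolation — a deep-array
approximation appropriate away from edges, with absorbing edges applied at
the finite array bounds during separation runs.

Numerical choices:

* Explicit Euler stepping with `dt = min(period/200, 0.25 gamma / k_max)`,
  where `k_max` bounds the landscape stiffness by second differences of
  |B|^2 over the map at eight drive phases. The second term keeps the
  overdamped relaxation stable near maxima at low drive frequency.
* The step count is rounded so an integer number of steps spans each drive
  period; period-averaged velocities are then exact position differences
  at period boundaries, free of windowing bias in the locked regime.
* A runaway guard aborts if any step displaces a particle by more than a
  quarter pitch.
* Velocities in the slipping regime are averaged over many periods
  (20-24) because the slip cycle is incommensurate with the drive; short
  windows alias badly.

The simulated critical frequency is located by bisection on the locking
predicate (period-averaged velocity at least 95 percent of `f d`), which
is crisp because the slipping branch drops discontinuously steeply below
the locked line. The 95 percent threshold operationalizes "velocity starts
to diverge from the landscape velocity"; no numeric divergence criterion
is stated in the source material, and the threshold is configurable. The
immobilization frequency uses the operational 10-percent-of-maximum rule;
for sampled profiles the first crossing is linearly interpolated. For the
exact closed-form profile this rule gives `f_i = 5.05 f_c`.

A caution discovered with this simulator and documented deliberately: the
deterministic dynamics re-lock at subharmonic steps well above the knee
(Shapiro-step-like plateaus familiar from driven lattice transport), so
`simulated_immobilization_frequency()` scans upward for the *first*
threshold crossing rather than bisecting blindly, and the deterministic
decay beyond the knee is slower than measured immobilization. Measured
sharpness parameters (Omega near 0.7) reflect disorder, thermal noise and
surface interactions that the clean deterministic model intentionally
omits; simulated Omega values are therefore smaller, and the package
asserts measured Omega arithmetic and simulated *orderings*, not simulated
Omega magnitudes.

## What the simulation does and does not reproduce

With default physical parameters (chi = 0.7, eta = 1e-3 Pa s, 80 kA/m
magnets, 30/35 G drive) and no tuning, the simulated critical frequencies
land on the measured scale (simulated C monomer about 30 Hz against a
measured 27 Hz) and reproduce the measured structure:

* dimers unlock below monomers on C, S and T, because the dimer's outer
  bead overhangs the magnet edge where the landscape modulation is weaker;
* on R the two species are nearly indistinguishable (smallest gap of the
  four geometries), since the 12.5 um magnet covers the whole dimer;
* the monomer geometry ordering T < C ~ S < R follows the landscape
  modulation ordering of the four shapes.

After one calibration on C monomers (a single multiplicative frequency
scale), the remaining seven species/geometry critical frequencies agree
with the measured values to within about 10 percent. Absolute measured
frequencies are experimental quantities and are not claimed from first
principles. "C approximately equal to S" is asserted as a relative gap
below 20 percent — a round qualitative band, not a fitted one.

## Separation protocol

`separation_protocol()` reproduces the assay workflow: load at a low
locked frequency, hold at a separation frequency, then reverse the
rotation to walk retained aggregates back. The deterministic separation
window is `f_c(dimer) < f < f_c(monomer)`: monomers remain locked at the
full `f d` while dimers slip at a substantially reduced velocity.
`design_schedule()` places the hold at 95 percent of the monomer critical
frequency and sizes it so monomers clear the array with a 15 percent
margin. Nonspecific bead-surface adhesion — the dominant efficiency loss
in the reference assay — is modeled, when requested, as a seeded
per-particle Bernoulli immobilization at protocol start (`stick_prob`),
giving `E[f_sb] = p_stick` and efficiency `1 - f_sb - f_agg` directly
comparable to the reported form.

The synthetic population generator (`synth_population()`) draws species
i.i.d. with a given dimer fraction and places particles on the flux maxima
of the loading columns. It emulates the composition and placement of an
assay product, not its chemistry: binding kinetics, higher-order clumps
(excluded from the reference measurements as unpredictable), bead-size
dispersion (3 percent CV) and out-of-plane motion are not represented.
End-to-end tests that pass on these populations therefore validate the
transport-and-counting pipeline, not the wet-lab aggregation step.

## Counting statistics

Aggregate fractions are reported with Wilson 95 percent score intervals,
which behave correctly at 0/n and n/n — both routinely reached at
dose-response extremes. The reference tables print plus/minus values of
unstated type; they are stored verbatim as fixture metadata
(`printed_pct`, `printed_pm`) and never reinterpreted. Method comparison
(on-chip counting against flow cytometry) uses the two-proportion score
test. Dose-response tables impose no monotonicity: bead-assembly assays
show the hook effect, where excess analyte saturates binding sites and
suppresses aggregation, and the bundled BBSA fixture peaks at 1e-9
mol/dm^3 accordingly.

Counts are stored as integers out of 100 beads per condition (the
reference counting depth); printed percentages with decimals are kept as
metadata alongside the nearest-integer counts.

## Problem sizes and reproducibility

The test suite and the acceptance script run everything at desk scale,
chosen as the smallest sizes that leave the assertions comfortably inside
their tolerances: one-period field maps at 0.1 um grid and 0.25 um raster
cells; velocity averaging over 4 periods when locked and 20-24 when
slipping; separation studies on a 12 x 3 magnet array with populations of
40 particles and 20-50 seeded replicates; 100 seeded replicates for noisy
parameter recovery; and a frozen 1e7-sample Monte-Carlo value for the
dimer-overhang geometry (4.39 percent of the dimer volume outside a 5 um
circle, the same few-percent scale as the reported figure). All
randomness is seeded; trajectory dynamics are fully deterministic, so
repeated runs are bit-identical.

## Known limitations

* No thermal noise, disorder or surface roughness: simulated knees are
  sharper and slipping tails longer than measured ones.
* Deep-array (periodic) field approximation during transport; edge fields
  only enter through absorbing boundaries.
* No bead-bead magnetic interactions during transport, and no out-of-plane
  dimer rotation (both excluded by scope).
* The linear-magnetization force law is used throughout; the bead
  saturation field (about 32 mT for the default beads) is checked and
  warned about but not modeled.
* Dimer hydrodynamics use independent-sphere drag; wall corrections are
  absorbed, if desired, into the configurable `c_drag`.
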