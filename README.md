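# nlmag — nonlinear magnetophoresis on micromagnet arrays

`nlmag` is a simulator and analysis toolkit for **nonlinear magnetophoresis
(NLM)**: the frequency-selective transport of superparamagnetic (SPM) beads
across a chip patterned with a lattice of micromagnets, driven by a rotating
external magnetic field. It is aimed at lab-on-chip designers and assay
developers who want to explore micromagnet array (MMA) geometries, bead
transport regimes and separation protocols on a desk before committing to
lithography.

The package covers the full pipeline:

* **Magnetostatics** — flux-density landscapes of circular, square,
  triangular and rectangular micromagnet arrays under a rotating drive,
  computed by dipole rasterization and validated against the analytic field
  of a uniformly magnetized prism (`compute_landscape()`,
  `prism_flux_density()`).
* **Landscape analysis** — tracking of the translating flux maxima, the
  normalized line profiles that monomer centers and dimer edges sample, and
  dimer-overhang geometry (`track_maxima()`, `line_profile()`,
  `dimer_overhang_fraction()`).
* **Transport** — the closed-form NLM law and an overdamped trajectory
  simulator for bead monomers and rigid dimers (`closed_form_velocity()`,
  `simulate_transport()`, `simulated_critical_frequency()`).
* **Separation and assay statistics** — the load / hold / reverse
  separation protocol and counting statistics for magnetic-bead-assembly
  (MBA) aggregation assays (`separation_protocol()`,
  `aggregate_fraction()`, `dose_response()`).

## The model

A bead of volume `V` and susceptibility `chi` in the landscape `B(x, t)` is
pulled toward flux maxima with force `F = V chi grad(|B|^2) / (2 mu0)`. The
maxima translate one lattice pitch `d` per drive rotation, so below the
**critical frequency** the bead is *phase-locked* at `v = f d`; above it the
bead slips with mean velocity `v = [f - sqrt(f^2 - f_c^2)] d`. The critical
frequency follows

```
f_c = kappa (2 pi beta)^2 exp(-2 pi beta) / (2 pi),   beta = r / d,
```

where `kappa` aggregates `chi mu0 sigma0(H_ext) / (18 eta)` and is
calibrated from one measured knee (`calibrate_coupling()`). Dimers unlock
at lower frequency than monomers on magnets smaller than the dimer — the
basis of on-chip separation of assay aggregates from unreacted beads. The
operational **immobilization frequency** (velocity below 10 percent of
maximum) and sharpness parameter `Omega = f_c / f_i` complete the
characterization.

## Worked example

```r
library(nlmag)
arr <- default_array("C")        # 5 um circles, 8 um pitch, 80 kA/m
ext <- external_field()          # 30 G (x) / 35 G (z) rotating drive

track_maxima(arr, ext)
#> <nlm_track> 13 phases, net displacement 8.00 um (8.00 um per rotation)

fc_mono  <- simulated_critical_frequency(bead_spec(),  arr, ext)
fc_dimer <- simulated_critical_frequency(dimer_spec(), arr, ext)
round(c(monomer = as.numeric(fc_mono), dimer = as.numeric(fc_dimer)), 1)
#> monomer   dimer
#>    30.0    27.2

closed_form_velocity(c(10, 27, 54), fc_hz = 27, d_um = 8)
#> [1]  80.0 216.0  57.9

omega_ratio(22.5, 30)     # sharpness of the dimer mobile/immobile transition
#> [1] 0.75

dr <- dose_response(load_assay_fixture("bbsa"))
dr[, c("concentration_mol_dm3", "n_aggregate", "percent",
       "lower_pct", "upper_pct")]
#>   concentration_mol_dm3 n_aggregate percent lower_pct upper_pct
#> 1                 1e-13          10      10      5.52      17.4
#> 2                 1e-11          27      27     19.27      36.4
#> 3                 1e-09          67      67     57.31      75.4
#> 4                 1e-07          18      18     11.70      26.7
```

The tracked flux maxima advance exactly one pitch (8 um) per field
rotation — the geometric fact behind phase-locked transport. The simulated
critical frequencies (2.8 um beads, default physical parameters, no tuning)
land at 30 Hz for monomers and 27 Hz for dimers on the circular array:
dimers unlock first because their outer bead overhangs the magnet edge
where the landscape modulation is weaker. The closed-form velocities show
the locked value `f d` at 10 Hz, the maximum `f_c d` at the knee, and the
collapsed slipping velocity at `2 f_c`. The dose-response table reports
aggregate percentages with Wilson 95 percent intervals; the curve peaks at
1e-9 mol/dm^3 and falls at higher concentration (hook effect).

A command-line wrapper over the same functions is installed at
`system.file("cli", "nlmag.R", package = "nlmag")` with subcommands
`landscape`, `profile`, `simulate`, `characteristics`, `separate` and
`assay-stats`.

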