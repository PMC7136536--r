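# rootbench

Benchmarks for functional-structural models of root water uptake, as a
self-contained R package.

Functional-structural root architecture models couple three things: a
stochastic simulator of root system geometry, the Richards equation for
water flow in unsaturated soil, and a porous-pipe ("hydraulic
architecture") model of water flow inside the root network, joined through
a sink term that represents uptake by roots treated as line sources.
Different research codes implement each piece differently, and systematic
benchmark problems — simple scenarios with analytical or well-controlled
reference solutions — are how such codes are compared and verified.
`rootbench` implements a full desk-scale benchmark suite of this kind:
every scenario can be generated, solved, and checked against its reference
on a laptop, with no external data.

## What is inside

* **Soil hydraulics** — van Genuchten–Mualem retention and conductivity
  (`water_content()`, `hydraulic_conductivity()`, `water_diffusivity()`,
  `matric_flux_potential()`), with the three benchmark soils (sand, loam,
  clay) shipped as a plain-text catalogue (`soil_catalogue()`).
* **Analytical references** — traveling-wave infiltration profiles
  (`infiltration_profile()`), two-stage evaporation with the desorptivity
  computed from the exact Boltzmann similarity solution
  (`desorptivity()`, `evaporation_rate()`), and steady-rate single-root
  uptake with stress-onset analysis (`radial_mfp_profile()`,
  `stress_onset()`).
* **Richards solvers** — mass-conservative finite volumes with
  modified-Picard iteration (chord-slope and L-scheme stabilized, Newton
  fallback with line search) on vertical 1D, radially symmetric 1D
  (compiled kernel) and structured 3D grids (sparse Cholesky), with the
  benchmarks' switching boundary conditions
  (`richards_run()`, `run_infiltration_benchmark()`,
  `run_evaporation_benchmark()`, `run_radial_uptake_benchmark()`).
* **Root systems** — a minimal stochastic architecture generator
  (`grow_root_system()`), RSML reading and writing (`read_rsml()`,
  `write_rsml()`), segment-resolution control
  (`discretize_root_system()`).
* **Architecture metrics** — traits with Fitter's topological indices
  (`root_traits()`), the rooting-depth distribution index beta from
  Y(d) = 1 − beta^d (`depth_distribution()`, `fit_beta()`), persistence
  barcodes of the geodesic collar distance (`persistence_barcode()`) and
  bottleneck distances (`bottleneck_distance()`).
* **Xylem flow** — the cosh closed form for a single root
  (`single_root_psi()`) and a Doussan-type sparse network solver with
  constant or age/type-dependent conductivities and a flux-limited collar
  (`solve_xylem()`).
* **Coupled scenarios** — operator-split soil–root coupling with an
  implicit sink, sinusoidal transpiration and collar stress switching
  (`run_coupled()`, `run_c12_scenario()`, `run_c21_scenario()`,
  `run_c22_scenario()`).
* **Benchmark runner** — `run_benchmark()` dispatches scenario ids
  (M1.1–C2.2), writes the prescribed comma-separated text, CSV, RSML and
  legacy-ASCII VTK outputs plus a JSON run manifest.  A thin command-line
  wrapper lives in `inst/cli/rootbench.R`.

## A worked example

Verify the single-root xylem benchmark against its closed form, then look
at a drying-soil uptake run:

```r
library(rootbench)

# a 50 cm vertical root, collar pinned at -1000 cm, soil at -200 cm
rs  <- single_root_system(50, dz = 0.1)
sol <- solve_xylem(rs, constant_hydraulics(), psi_s = -200,
                   collar_head(-1000))
round(sol$psi_x[c(1, 251, 501)], 2)   # collar, mid, tip
#> [1] -1000.00  -747.25  -671.19
round(sol$collar_flow, 4)             # cm^3/d taken up
#> [1] 0.6265

# the closed form at the tip: psi_s + (psi_0-psi_s)/cosh(c l)
cc <- sqrt(2 * 0.02 * pi * 1.73e-4 / 4.32e-2)
round(-200 - 800 / cosh(cc * 50), 2)
#> [1] -671.19
```

The tip agrees with the analytical value to the printed digits, and the
solver converges to it at second order in the segment length (see
`tests/testthat/test-xylem.R`).

```r
# three days of sinusoidal transpiration from a drying loam box
res <- run_c12_scenario("a", resolution = 1, t_end = 3)
max(res$series$Q_act, na.rm = TRUE)    # first-day peak, cm^3/d
#> [1] 8.09
min(res$series$psi_x_min, na.rm = TRUE)  # pinned at the collar limit
#> [1] -15290
res$water_balance_err                  # storage change vs cumulative uptake
#> [1] 2.7e-08
```

Actual transpiration tracks the 12.8 cm³/d potential peak only on the
first day and falls on later days as the soil around the roots dries —
the expected stress phenomenology for this scenario.

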