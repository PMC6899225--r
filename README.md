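# orbweb

Multibody dynamic simulation of a spider orb web struck by a flying-prey
projectile, with climate-scenario transforms of the silk properties.

## The science

An orb web is a pretensioned cable network: ~31 radial spokes of stiff
major ampullate (MA) silk, a ~43-turn capture spiral of soft flagelliform
silk, and peripheral frame threads, all carrying initial tension. A flying
insect delivers on the order of a millijoule of kinetic energy in a few
tens of milliseconds; the web must absorb that energy elastically without
its threads exceeding their breaking strain.

MA silk is strongly hygroscopic: between dry and saturated air its maximum
strain changes by roughly ±78% and its mean stiffness by ±94%
(supercontraction), while over a 20–55 °C temperature range the same
properties move by only ±1% and ±18%. `orbweb` turns those measured
response ranges into six climate scenarios (low/medium/high humidity and
temperature), applies them to the web's material model, and simulates
projectile impacts across a grid of target points to ask: *does the web
still function as a prey-capture device when the climate changes the silk
underneath it?*

The model is a tension-only linear-spring network with:

- pretension realised as shortened rest lengths (so every thread carries
  its tabulated initial tension in the as-built geometry),
- lumped silk masses at the nodes, in-plane gravity, and per-link axial
  damping,
- sphere–thread contact solved implicitly as a penalty impulse
  (unconditionally stable at the default time step) with exact energy
  bookkeeping,
- permanent thread breakage when a link's strain exceeds its breaking
  strain, with the released elastic energy booked as dissipated,
- a semi-implicit (symplectic) Euler integrator at `dt = 1e-6 s` and a
  full energy audit (kinetic + elastic + contact + dissipated −
  gravitational work) for every run.

## Worked example

Build the default web and check its census (the published geometry gives
exactly 2731 links):

```r
library(orbweb)

web <- build_web(web_geometry_params())
count_links(web)
#> Link census: 1395 radial + 1332 spiral + 4 frame = 2731 total
```

Fire the 500 mg, 2.0 m s⁻¹ projectile (impact energy exactly 1.0 mJ) at
the web centre under the baseline (medium) scenario — a full 0.5 s run
takes ~25 s:

```r
sim <- simulate_impact(web, silk_materials(), projectile(), c(0, 0),
                       sim_config())
summary(sim)
#> Impact [baseline] at (0, 0): stopped
#>   broken threads: 0; peak strain energy 0.8137 mJ; max strain fraction 0.896
#>   final forward position -0.5532 m at -1.72 m s-1
```

The web catches the projectile: no thread breaks, the peak elastic strain
energy (0.8137 mJ) stays below the 1.0 mJ impact energy, and the
projectile's forward velocity reverses sign as it is thrown back out of
the web plane. Under high humidity the same impact ends differently:

```r
wet <- apply_scenario(silk_materials(), climate_scenario("humidity", "high"))
summary(simulate_impact(web, wet, projectile(), c(0, 0), sim_config()))
#> Impact [humidity_high] at (0, 0): pass_through
#>   broken threads: 1; peak strain energy 0.1034 mJ; max strain fraction 1
#>   final forward position 0.9405 m at 1.884 m s-1
```

The softened web (−94% stiffness) stores barely a tenth of the impact
energy before a radial fails and the projectile punches through almost
unslowed. Check the energy ledger of any run with:

```r
print(energy_audit(sim))
#> Energy closure: initial total 1.007 mJ, max |drift| 84.03 uJ, 0 uJ released by breakage
```

(The 84 µJ drift is at the damped working step; with damping off and the
time step halved the same run closes to 1.2 µJ — see the vignette.)

The full sweep — six scenarios × the 23-point impact grid — runs with
`run_grid()` or from the command line (`inst/scripts/orbweb grid`); a
`qualitative_report()` then scores the expected climate pattern (does
high humidity always pass through? do the humidity extremes break more
threads? …).

## What the model reproduces — and what it does not

On the reduced acceptance grid (web centre plus one point on each ring of
the 23-point pattern) the model reproduces most of the expected climate
pattern: high humidity passes through at every point, low humidity at
every tested point, and both humidity extremes break more threads than
baseline. It does **not** reproduce the expectation that temperature
scenarios stop the projectile everywhere: away from the centre the
contact load concentrates on a single radial whose total elastic capacity
(½·EA·ε²·L ≈ 0.64 mJ) is below the 1.0 mJ impact energy, so that radial
fails and the projectile slips through. The corresponding acceptance test
is left failing deliberately rather than patching the physics with
untabulated parameters; see the methods vignette for the full analysis.

## Tests

```r
testthat::test_dir("tests/testthat", package = "orbweb",
                   load_package = "installed")
```

The suite includes unit tests per module, property tests (census formula
across web sizes, tension-only force law, breakage monotonicity, energy
conservation with dt refinement, bitwise determinism, closed-form
harmonic and ballistic oracles) and an acceptance file with one block per
headline criterion. Full run ≈ 10 minutes; all blocks pass except the
documented temperature sub-pattern above.

## Package layout

- `R/web_geometry.R` — geometry parameters, web graph builder, census,
  impact grid, plotting.
- `R/silk_scenarios.R` — material table, humidity/temperature response
  tables, scenario derivation and application.
- `R/impact_dynamics.R` + `src/sim_core.cpp` — projectile, configuration,
  force law, lumped masses, the C++ integrator, energy audit.
- `R/experiment_pipeline.R` — outcome classification, scenario × point
  grid runner, summaries, strain histograms, qualitative report.
- `R/cli_io.R` + `inst/scripts/orbweb` — YAML run configuration, JSON/CSV
  persistence, `build`/`simulate`/`grid`/`report` commands.
- `vignettes/orbweb-methods.Rmd` — model formulation, numerical choices
  and limitations.
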