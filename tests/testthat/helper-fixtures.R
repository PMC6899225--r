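# Shared fixtures, memoised per test session. The full-scale 0.5 s runs
# dominate the suite's runtime, so anything used by more than one test is
# computed once and cached here.

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache, inherits = FALSE))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache, inherits = FALSE)
}

fx_params <- function() fixture("params", web_geometry_params())

fx_web <- function() fixture("web", build_web(fx_params()))

fx_materials <- function() fixture("materials", silk_materials())

# A small but fully consistent web (internal 0.011 + 6 * 0.004 = 0.035)
# for fast dynamics tests: ~56 links, runs in well under a second.
fx_small_params <- function() fixture(
  "small_params",
  web_geometry_params(external_radius = 0.035, internal_radius = 0.011,
                      support_width = 0.1, support_height = 0.1,
                      spiral_pitch = 0.004, spiral_turns = 6L,
                      radial_strands = 8L))

fx_small_web <- function() fixture("small_web", build_web(fx_small_params()))

# The reference run: baseline scenario, centre impact, full 0.5 s at the
# default settings. Used by the energy-containment, symmetry and target
# checks.
fx_baseline_central <- function() fixture(
  "baseline_central",
  simulate_impact(fx_web(), fx_materials(), projectile(), c(0, 0),
                  sim_config()))

# Reduced acceptance grid: the centre point plus one point of each ring of
# the 23-point pattern (point 2 on the 0.35 R ring, point 10 on the 0.70 R
# ring).
fx_reduced_grid <- function() fixture("reduced_grid", {
  g <- impact_points(fx_params(), 23L)
  g <- g[c(1L, 2L, 10L), ]
  g$point <- seq_len(nrow(g))
  rownames(g) <- NULL
  g
})

# The six climate scenarios on the reduced grid (the two zero-delta
# mediums are deduplicated internally, so this is 15 full-scale runs).
fx_reduced_results <- function() fixture(
  "reduced_results",
  run_grid(fx_web(), fx_materials(), climate_scenarios(), fx_reduced_grid(),
           sim_config(), projectile()))

# Closed-form oracle helpers, shared by the unit and acceptance suites.

# Pretensioned fixed--free--fixed chain: undamped axial harmonic
# oscillator z(t) = A cos(w t). Returns the max |simulated - analytic|
# relative to the amplitude.
harmonic_oracle_error <- function() {
  m <- fx_materials()
  toy <- fx_small_web()
  L <- 0.004
  toy$nodes <- data.frame(id = 1:3, x = 0, y = 0, z = c(0, -L, L),
                          fixed = c(FALSE, TRUE, TRUE),
                          role = c("center", "perimeter_anchor",
                                   "perimeter_anchor"),
                          radial = c(NA, 1L, 2L), turn = NA_integer_)
  toy$links <- data.frame(id = 1:2, node_a = 1L, node_b = 2:3,
                          thread_type = "radial", natural_length = L,
                          broken = FALSE)
  cfg <- sim_config(duration = 6e-5, dt = 1e-9, record_interval = 6e-7,
                    damping_ratio = 0, gravity = 0, start_gap = 1)
  arr <- orbweb:::link_arrays(toy, m, cfg)
  omega <- sqrt(2 * (arr$EA / arr$L0)[1] / arr$mass[1])
  A <- 0.45 * (L - arr$L0[1])
  toy$nodes$z[1] <- A
  sim <- simulate_impact(toy, m, projectile(speed = 0), c(0.05, 0.05), cfg,
                         track_node = 1L)
  nt <- sim$node_track
  max(abs(nt$z - A * cos(omega * nt$time))) / A
}

# Projectile free flight before first contact: constant forward speed and
# a quadratic gravitational drop. Returns the max relative errors.
ballistic_oracle_error <- function() {
  gap <- 0.05
  cfg <- sim_config(duration = 2e-2, dt = 1e-6, record_interval = 1e-4,
                    start_gap = gap)
  sim <- simulate_impact(fx_small_web(), fx_materials(), projectile(),
                         c(0, 0), cfg)
  tr <- sim$trajectory
  x0 <- -(projectile()$radius + gap)
  list(forward = max(abs(tr$forward - (x0 + 2.0 * tr$time))) / abs(x0),
       vertical = max(abs(tr$vertical - (-0.5 * 9.81 * tr$time^2))) /
         max(abs(tr$vertical)))
}
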