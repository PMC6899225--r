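#' Projectile specification
#'
#' The flying-prey stand-in: a rigid sphere fired horizontally at the web
#' along the web-plane normal. Defaults are the 500 mg, 2.0 m s-1 projectile
#' (impact kinetic energy 1.0 mJ) with a 5 mm radius, comparable to the
#' 4 mm mesh pitch so several threads are engaged at once.
#'
#' @param mass Mass in kg.
#' @param radius Sphere radius in m.
#' @param speed Initial speed in m s-1, directed along the web normal.
#' @return An object of class `"projectile"`.
#' @examples
#' projectile_kinetic_energy(projectile()$mass, projectile()$speed)
#' @export
projectile <- function(mass = 5e-4, radius = 5e-3, speed = 2.0) {
  if (mass <= 0 || radius <= 0) stop("mass and radius must be positive", call. = FALSE)
  if (speed < 0) stop("speed must be non-negative", call. = FALSE)
  structure(list(mass = mass, radius = radius, speed = speed),
            class = "projectile")
}

#' Simulation configuration
#'
#' Numerical and physical settings for the impact integration.
#'
#' @param duration Simulated time in s (default 0.5, the full impact window).
#' @param dt Integration time step in s. The default 1e-6 sits under the
#'   stability bound `0.5 * sqrt(m_min / k_max)` for the default web
#'   (k_max = EA/L0 of a radial link, ~8 N m-1, node masses ~1e-10 kg).
#' @param record_interval Sampling interval for trajectory/energy series (s).
#' @param damping_ratio Per-link axial damping as a fraction of critical
#'   (dimensionless, default 0.1).
#' @param contact_stiffness Sphere-thread penalty stiffness (N m-1).
#' @param contact_damping Contact viscous coefficient (N s m-1).
#' @param gravity Gravitational acceleration (m s-2), acting in-plane
#'   downward.
#' @param pretension_scale Multiplier on the tabulated initial tensions
#'   (1 = as published; supercontraction-like tensioning can be emulated by
#'   raising it).
#' @param start_gap Gap between the sphere surface and the web plane at
#'   t = 0 (m); the projectile starts "a few millimetres from contact".
#' @param strain_reference Reference length for the breakage strain:
#'   `"rest"` (pretension-adjusted rest length, the default) or
#'   `"natural"` (as-built geometric length).
#' @param pass_through_distance Forward displacement beyond the web plane
#'   past which (with positive forward velocity) an impact counts as a
#'   pass-through (m).
#' @param vmax_abort Instability detector: any body speed above this
#'   (m s-1) aborts the run with a diagnostic.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(duration = 0.5, dt = 1e-6, record_interval = 1e-4,
                       damping_ratio = 0.1, contact_stiffness = 1e3,
                       contact_damping = 1e-2, gravity = 9.81,
                       pretension_scale = 1, start_gap = 3e-3,
                       strain_reference = c("rest", "natural"),
                       pass_through_distance = 0.10, vmax_abort = 1e3) {
  strain_reference <- match.arg(strain_reference)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (duration < 0) stop("duration must be non-negative", call. = FALSE)
  if (duration > 0 && (record_interval < dt || duration < record_interval))
    stop("need duration >= record_interval >= dt", call. = FALSE)
  if (damping_ratio < 0 || pretension_scale < 0 || start_gap < 0)
    stop("damping_ratio, pretension_scale and start_gap must be non-negative",
         call. = FALSE)
  structure(list(duration = duration, dt = dt, record_interval = record_interval,
                 damping_ratio = damping_ratio,
                 contact_stiffness = contact_stiffness,
                 contact_damping = contact_damping,
                 gravity = gravity, pretension_scale = pretension_scale,
                 start_gap = start_gap, strain_reference = strain_reference,
                 pass_through_distance = pass_through_distance,
                 vmax_abort = vmax_abort),
            class = "sim_config")
}

#' Pretension-adjusted rest length
#'
#' A thread built at geometric length `L` that must carry tension `T0` in
#' place is modelled as a linear spring with rest length
#' `L0 = L / (1 + T0 / EA)`, so that at the as-built geometry its tension is
#' exactly `T0`.
#'
#' @param natural_length As-built geometric length (m).
#' @param initial_tension Pretension force (N, >= 0).
#' @param EA Axial stiffness, modulus times cross-section area (N, > 0).
#' @return Rest length in m (vectorised).
#' @examples
#' rest_length(0.004, 132e-6, 0.031536)
#' @export
rest_length <- function(natural_length, initial_tension, EA) {
  if (any(EA <= 0)) stop("EA must be positive", call. = FALSE)
  if (any(initial_tension < 0)) stop("initial tension must be non-negative", call. = FALSE)
  natural_length / (1 + initial_tension / EA)
}

#' Axial force of a tension-only link
#'
#' The scalar tension of a linear-spring thread: `EA * eps` for positive
#' engineering strain `eps = (L - L0)/L0`, zero when slack (threads cannot
#' push), plus an axial viscous term `c * dL/dt` clamped so the total force
#' never turns compressive.
#'
#' @param length Current length (m, > 0).
#' @param rest_length Rest length L0 (m).
#' @param EA Axial stiffness (N).
#' @param dLdt Rate of elongation (m s-1).
#' @param damping Axial damping coefficient c (N s m-1).
#' @return Tension in N (>= 0).
#' @examples
#' link_tension(0.004, rest_length(0.004, 132e-6, 0.031536), 0.031536)
#' @export
link_tension <- function(length, rest_length, EA, dLdt = 0, damping = 0) {
  if (any(length <= 0)) stop("zero or negative current length: degenerate geometry",
                             call. = FALSE)
  eps <- (length - rest_length) / rest_length
  el <- ifelse(eps > 0, EA * eps, 0)
  tot <- ifelse(eps > 0, pmax(el + damping * dLdt, 0), 0)
  tot
}

#' Lumped node masses from the silk mass distribution
#'
#' Each link contributes half of its silk mass `rho * A * L_natural` to each
#' endpoint. Fixed nodes (anchors, frame corners) keep their tally for
#' bookkeeping but are immobile in the integration.
#'
#' @param web A `"spider_web"`.
#' @param materials A `"material_set"`.
#' @return Numeric vector of node masses (kg), one per node.
#' @examples
#' sum(lumped_masses(build_web(), silk_materials()))   # total web silk mass
#' @export
lumped_masses <- function(web, materials) {
  stopifnot(inherits(web, "spider_web"), inherits(materials, "material_set"))
  rho <- attr(materials, "silk_density")
  idx <- match(web$links$thread_type, materials$thread_type)
  A <- cross_section_area(materials$diameter[idx])
  mlink <- rho * A * web$links$natural_length
  m <- numeric(nrow(web$nodes))
  half <- mlink / 2
  for (s in c("node_a", "node_b")) {
    tab <- tapply(half, web$links[[s]], sum)
    ids <- as.integer(names(tab))
    m[ids] <- m[ids] + as.numeric(tab)
  }
  m
}

# per-link arrays fed to the C++ core
link_arrays <- function(web, materials, config) {
  idx <- match(web$links$thread_type, materials$thread_type)
  if (anyNA(idx)) stop("material set lacks a thread type used by the web", call. = FALSE)
  A <- cross_section_area(materials$diameter[idx])
  EA <- materials$modulus[idx] * A
  T0 <- materials$tension[idx] * config$pretension_scale
  Lnat <- web$links$natural_length
  # pretension strain is fixed per geometry: it is defined by the Table
  # tension over the BASELINE modulus, so under a climate scenario the
  # rest length stays put and the actual tension scales with the modulus
  scale <- attr(materials, "stiffness_scale")
  if (is.null(scale)) scale <- 1
  L0 <- rest_length(Lnat, T0, EA / scale)
  Lref <- if (config$strain_reference == "rest") L0 else Lnat
  mass <- lumped_masses(web, materials)
  ma <- mass[web$links$node_a]; mb <- mass[web$links$node_b]
  fa <- web$nodes$fixed[web$links$node_a]; fb <- web$nodes$fixed[web$links$node_b]
  mred <- ifelse(fa & fb, 0, ifelse(fa, mb, ifelse(fb, ma, ma * mb / (ma + mb))))
  cdamp <- 2 * config$damping_ratio * sqrt((EA / L0) * mred)
  list(EA = EA, L0 = L0, Lref = Lref, cdamp = cdamp,
       eps_break = materials$breaking_strain[idx], mass = mass)
}

#' Simulate a projectile impact on the web
#'
#' Integrates the full multibody system -- tension-only pretensioned spring
#' network with lumped silk masses, in-plane gravity, axial damping,
#' sphere-thread penalty contact and permanent thread breakage -- with a
#' semi-implicit (symplectic) Euler scheme from a start a few millimetres
#' before contact to `config$duration`. The run is fully deterministic.
#'
#' @param web A `"spider_web"`.
#' @param materials A `"material_set"` (possibly scenario-transformed).
#' @param proj A [projectile()].
#' @param impact_point Numeric `c(u, v)`: the in-plane target the projectile
#'   is aimed at (m, relative to the hub), or a single row of an
#'   [impact_points()] grid.
#' @param config A [sim_config()].
#' @param track_node Optional node id whose position/velocity time series is
#'   recorded alongside the projectile trajectory.
#' @return An object of class `"impact_sim"` with elements:
#'   `trajectory` (data frame `time`, `forward`, `vertical`, `lateral`, and
#'   the velocity components), `energy` (data frame `time`,
#'   `kinetic_projectile`, `kinetic_web`, `elastic`, `contact`, `dissipated`,
#'   `gravitational`; J), `break_events` (`time`, `link`, `strain`),
#'   `peak_strain_fraction` (per link, with thread type and broken flag),
#'   `final` (node and projectile end state), plus the inputs echoed.
#' @examples
#' \donttest{
#' web <- build_web()
#' sim <- simulate_impact(web, silk_materials(), projectile(), c(0, 0),
#'                        sim_config(duration = 0.01))
#' summary(sim)
#' }
#' @export
simulate_impact <- function(web, materials, proj = projectile(),
                            impact_point = c(0, 0), config = sim_config(),
                            track_node = NULL) {
  stopifnot(inherits(web, "spider_web"), inherits(materials, "material_set"),
            inherits(proj, "projectile"), inherits(config, "sim_config"))
  if (is.data.frame(impact_point)) impact_point <- c(impact_point$u[1], impact_point$v[1])
  impact_point <- as.numeric(impact_point)
  if (length(impact_point) != 2L || anyNA(impact_point))
    stop("impact_point must be a numeric (u, v) pair", call. = FALSE)

  arr <- link_arrays(web, materials, config)
  free <- !web$nodes$fixed
  kmax_free <- max((arr$EA / arr$L0)[!(web$nodes$fixed[web$links$node_a] &
                                       web$nodes$fixed[web$links$node_b])])
  dt_crit <- 0.5 * sqrt(min(arr$mass[free]) / kmax_free)
  if (config$dt > dt_crit)
    warning(sprintf("dt = %.3g exceeds the stability bound 0.5*sqrt(m_min/k_max) = %.3g",
                    config$dt, dt_crit), call. = FALSE)

  pos0 <- as.matrix(web$nodes[, c("x", "y", "z")])
  ppos <- c(-(proj$radius + config$start_gap), impact_point[2], impact_point[1])
  pvel <- c(proj$speed, 0, 0)
  track <- if (is.null(track_node)) -1L else as.integer(track_node) - 1L

  res <- sim_core(pos0, as.integer(web$nodes$fixed), arr$mass,
                  as.integer(web$links$node_a) - 1L,
                  as.integer(web$links$node_b) - 1L,
                  arr$L0, arr$Lref, arr$EA, arr$cdamp, arr$eps_break,
                  proj$mass, proj$radius, ppos, pvel,
                  config$dt, config$duration, config$record_interval,
                  config$gravity, config$contact_stiffness,
                  config$contact_damping, config$vmax_abort, track)

  if (res$status != 0) {
    cond <- structure(
      class = c("orbweb_instability", "error", "condition"),
      list(message = sprintf(paste0("simulation unstable: a body exceeded %g m s-1 ",
                                    "after %.4g ms (%d links broken); reduce dt or ",
                                    "soften the contact"),
                             config$vmax_abort, 1e3 * res$steps_done * config$dt,
                             sum(res$broken != 0)),
           call = sys.call(),
           time_reached = res$steps_done * config$dt,
           impact_point = impact_point,
           scenario = attr(materials, "scenario")))
    stop(cond)
  }

  traj <- as.data.frame(res$trajectory)
  names(traj) <- c("time", "forward", "vertical", "lateral", "v_forward",
                   "v_vertical", "v_lateral")
  en <- as.data.frame(res$energy)
  names(en) <- c("time", "kinetic_projectile", "kinetic_web", "elastic",
                 "contact", "dissipated", "gravitational")
  ev <- as.data.frame(res$events)
  names(ev) <- c("time", "link", "strain")
  psf <- data.frame(link = web$links$id,
                    thread_type = web$links$thread_type,
                    peak_fraction = res$peak_fraction,
                    broken = res$broken != 0L)
  nt <- NULL
  if (!is.null(res$node_track)) {
    nt <- as.data.frame(cbind(traj$time, res$node_track))
    names(nt) <- c("time", "x", "y", "z", "vx", "vy", "vz")
  }
  structure(list(trajectory = traj, energy = en, break_events = ev,
                 peak_strain_fraction = psf, node_track = nt,
                 final = list(positions = res$positions,
                              velocities = res$velocities,
                              proj_position = res$proj_position,
                              proj_velocity = res$proj_velocity),
                 impact_point = impact_point, scenario = attr(materials, "scenario"),
                 projectile = proj, config = config,
                 link_arrays = arr[c("EA", "L0", "Lref", "eps_break")]),
            class = "impact_sim")
}

#' Elastic strain energy of the web in a given configuration
#'
#' Sums `0.5 * (EA/L0) * (L - L0)^2` over all unbroken links with positive
#' strain. With the default (as-built) node positions this is the stored
#' pretension energy.
#'
#' @param web A `"spider_web"`.
#' @param materials A `"material_set"`.
#' @param positions Node positions, an `n x 3` matrix (defaults to the
#'   as-built geometry).
#' @param config A [sim_config()] (for `pretension_scale`).
#' @param broken Optional logical per-link vector of failed links to skip.
#' @return Energy in J.
#' @export
web_strain_energy <- function(web, materials, positions = NULL,
                              config = sim_config(), broken = NULL) {
  arr <- link_arrays(web, materials, config)
  if (is.null(positions)) positions <- as.matrix(web$nodes[, c("x", "y", "z")])
  if (is.null(broken)) broken <- rep(FALSE, nrow(web$links))
  a <- web$links$node_a; b <- web$links$node_b
  L <- sqrt(rowSums((positions[a, , drop = FALSE] - positions[b, , drop = FALSE])^2))
  s <- L - arr$L0
  sum(ifelse(!broken & s > 0, 0.5 * (arr$EA / arr$L0) * s^2, 0))
}

#' Energy closure audit of an impact run
#'
#' Checks that kinetic + elastic + contact + dissipated energy minus the
#' work done by gravity stays at its initial value over the run, and
#' reports the drift. The elastic energy released when a thread breaks is
#' booked as dissipated, so breakage does not open the ledger.
#'
#' @param sim An `"impact_sim"`.
#' @return An object of class `"energy_audit"`: list with the closure
#'   `series` (time, total, drift), `max_drift` (J), `initial_total` (J)
#'   and `break_energy` (J released by failures).
#' @export
energy_audit <- function(sim) {
  stopifnot(inherits(sim, "impact_sim"))
  en <- sim$energy
  total <- en$kinetic_projectile + en$kinetic_web + en$elastic + en$contact +
    en$dissipated - en$gravitational
  drift <- total - total[1L]
  ev <- sim$break_events
  brk <- 0
  if (nrow(ev) > 0) {
    l <- ev$link
    L0 <- sim$link_arrays$L0[l]; Lref <- sim$link_arrays$Lref[l]
    EA <- sim$link_arrays$EA[l]
    L <- Lref * (1 + ev$strain)
    s <- pmax(L - L0, 0)
    brk <- sum(0.5 * (EA / L0) * s^2)
  }
  structure(list(series = data.frame(time = en$time, total = total, drift = drift),
                 max_drift = max(abs(drift)), initial_total = total[1L],
                 break_energy = brk),
            class = "energy_audit")
}

#' @export
print.energy_audit <- function(x, ...) {
  cat(sprintf("Energy closure: initial total %.4g mJ, max |drift| %.4g uJ, %.4g uJ released by breakage\n",
              1e3 * x$initial_total, 1e6 * x$max_drift, 1e6 * x$break_energy))
  invisible(x)
}

#' @export
print.impact_sim <- function(x, ...) {
  tr <- x$trajectory
  n <- nrow(tr)
  cat(sprintf("Impact simulation [%s] at (u = %.3g, v = %.3g) m, %d samples over %.3g s\n",
              x$scenario, x$impact_point[1], x$impact_point[2], n, tr$time[n]))
  cat(sprintf("  final forward position %.4g m, forward velocity %.4g m s-1\n",
              tr$forward[n], tr$v_forward[n]))
  cat(sprintf("  %d threads broken; peak web strain energy %.4g mJ\n",
              nrow(x$break_events), 1e3 * max(x$energy$elastic)))
  invisible(x)
}

#' @export
summary.impact_sim <- function(object, ...) {
  tr <- object$trajectory; en <- object$energy
  n <- nrow(tr)
  out <- list(scenario = object$scenario,
              impact_point = object$impact_point,
              outcome = classify_outcome(object),
              broken_count = nrow(object$break_events),
              peak_strain_energy = max(en$elastic),
              max_strain_fraction = max(object$peak_strain_fraction$peak_fraction),
              final_forward_position = tr$forward[n],
              final_forward_velocity = tr$v_forward[n],
              duration = tr$time[n])
  class(out) <- "summary.impact_sim"
  out
}

#' @export
print.summary.impact_sim <- function(x, ...) {
  cat(sprintf("Impact [%s] at (%.3g, %.3g): %s\n", x$scenario,
              x$impact_point[1], x$impact_point[2], x$outcome))
  cat(sprintf("  broken threads: %d; peak strain energy %.4g mJ; max strain fraction %.3g\n",
              x$broken_count, 1e3 * x$peak_strain_energy, x$max_strain_fraction))
  cat(sprintf("  final forward position %.4g m at %.4g m s-1\n",
              x$final_forward_position, x$final_forward_velocity))
  invisible(x)
}

#' Plot an impact run
#'
#' `which = "trajectory"` draws the forward and vertical projectile
#' coordinates against time; `which = "energy"` the energy partitioning.
#'
#' @param x An `"impact_sim"`.
#' @param which `"trajectory"` or `"energy"`.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.impact_sim <- function(x, which = c("trajectory", "energy"), ...) {
  which <- match.arg(which)
  if (which == "trajectory") {
    tr <- x$trajectory
    graphics::matplot(tr$time, cbind(tr$forward, tr$vertical), type = "l",
                      lty = 1, col = c("firebrick", "steelblue"),
                      xlab = "time (s)", ylab = "position (m)", ...)
    graphics::legend("topleft", c("forward", "vertical"), lty = 1,
                     col = c("firebrick", "steelblue"), bty = "n")
  } else {
    en <- x$energy
    graphics::matplot(en$time, 1e3 * cbind(en$kinetic_projectile, en$elastic, en$dissipated),
                      type = "l", lty = 1,
                      col = c("firebrick", "forestgreen", "grey40"),
                      xlab = "time (s)", ylab = "energy (mJ)", ...)
    graphics::legend("topright", c("projectile KE", "web elastic", "dissipated"),
                     lty = 1, col = c("firebrick", "forestgreen", "grey40"), bty = "n")
  }
  invisible(x)
}
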