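#' Classify the capture outcome of an impact run
#'
#' An impact counts as `pass_through` when the projectile's final forward
#' position lies beyond the web plane by more than
#' `config$pass_through_distance` (default 0.10 m, about 25 mesh pitches,
#' far beyond any elastic deflection at 1 mJ) *and* its final forward
#' velocity is still positive; otherwise it is `stopped`. Note that
#' `stopped` does not mean at rest -- the projectile keeps oscillating in
#' the web -- only that its forward progress has been arrested.
#'
#' @param sim An `"impact_sim"`.
#' @param config A [sim_config()]; defaults to the one the run used.
#' @return `"stopped"` or `"pass_through"`.
#' @export
classify_outcome <- function(sim, config = sim$config) {
  stopifnot(inherits(sim, "impact_sim"))
  tr <- sim$trajectory
  if (nrow(tr) < 1L) stop("truncated trajectory", call. = FALSE)
  n <- nrow(tr)
  if (tr$forward[n] > config$pass_through_distance && tr$v_forward[n] > 0)
    "pass_through" else "stopped"
}

#' Run the scenario-by-impact-point grid
#'
#' Simulates every (climate scenario, impact point) pair and reduces each
#' run to an outcome record. Scenarios whose transforms are identical (the
#' two zero-delta mediums) are simulated once and reported under each
#' label. Runs are independent and deterministic, so parallel execution
#' yields output identical to serial.
#'
#' @param web A `"spider_web"`.
#' @param base_materials The baseline `"material_set"`.
#' @param scenarios Named list of `"scenario_transform"`s (default the six
#'   published climate scenarios).
#' @param grid An [impact_points()] grid.
#' @param config A [sim_config()].
#' @param proj A [projectile()].
#' @param cores Number of worker processes (forked; 1 = serial).
#' @return An object of class `"web_result_table"`: list with `records`
#'   (one row per scenario x point: outcome, broken thread count, peak
#'   strain energy, max strain fraction, final forward velocity/position,
#'   status), `strain_fractions` (per-scenario matrix of per-link peak
#'   strain fractions, one column per impact point) and the inputs echoed.
#' @examples
#' \donttest{
#' web <- build_web(web_geometry_params(spiral_turns = 4, radial_strands = 6))
#' }
#' @export
run_grid <- function(web, base_materials, scenarios = climate_scenarios(),
                     grid = impact_points(web$params), config = sim_config(),
                     proj = projectile(), cores = 1L) {
  stopifnot(inherits(web, "spider_web"), inherits(base_materials, "material_set"))
  if (length(scenarios) == 0L) {
    return(structure(list(records = empty_records(), strain_fractions = list(),
                          scenarios = scenarios, grid = grid, config = config),
                     class = "web_result_table"))
  }
  key <- vapply(scenarios, function(s)
    paste(s$delta_breaking_strain, s$delta_stiffness), "")
  ukey <- unique(key)
  reps <- lapply(ukey, function(k) names(scenarios)[key == k])
  umats <- lapply(ukey, function(k)
    apply_scenario(base_materials, scenarios[[match(k, key)]]))

  specs <- expand.grid(si = seq_along(ukey), pi = seq_len(nrow(grid)))
  one <- function(r) {
    si <- specs$si[r]; pidx <- specs$pi[r]
    pt <- c(grid$u[pidx], grid$v[pidx])
    tryCatch({
      sim <- simulate_impact(web, umats[[si]], proj, pt, config)
      list(ok = TRUE, point = pidx, si = si,
           outcome = classify_outcome(sim, config),
           broken_count = nrow(sim$break_events),
           peak_strain_energy = max(sim$energy$elastic),
           max_strain_fraction = max(sim$peak_strain_fraction$peak_fraction),
           final_forward_velocity = sim$trajectory$v_forward[nrow(sim$trajectory)],
           final_forward_position = sim$trajectory$forward[nrow(sim$trajectory)],
           fractions = sim$peak_strain_fraction$peak_fraction,
           message = "")
    }, error = function(e) {
      list(ok = FALSE, point = pidx, si = si, outcome = NA_character_,
           broken_count = NA_integer_, peak_strain_energy = NA_real_,
           max_strain_fraction = NA_real_, final_forward_velocity = NA_real_,
           final_forward_position = NA_real_, fractions = NULL,
           message = conditionMessage(e))
    })
  }
  runs <- if (cores > 1L) {
    parallel::mclapply(seq_len(nrow(specs)), one, mc.cores = cores,
                       mc.preschedule = TRUE)
  } else {
    lapply(seq_len(nrow(specs)), one)
  }

  rows <- list(); fracs <- list()
  for (r in seq_along(runs)) {
    x <- runs[[r]]
    for (nm in reps[[x$si]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        scenario = nm, point = x$point,
        u = grid$u[x$point], v = grid$v[x$point],
        outcome = x$outcome, broken_count = x$broken_count,
        peak_strain_energy = x$peak_strain_energy,
        max_strain_fraction = x$max_strain_fraction,
        final_forward_velocity = x$final_forward_velocity,
        final_forward_position = x$final_forward_position,
        status = if (x$ok) "ok" else "failed", message = x$message)
      if (x$ok) {
        if (is.null(fracs[[nm]]))
          fracs[[nm]] <- matrix(NA_real_, nrow(web$links), nrow(grid),
                                dimnames = list(NULL, paste0("p", seq_len(nrow(grid)))))
        fracs[[nm]][, x$point] <- x$fractions
      }
    }
  }
  records <- do.call(rbind, rows)
  records <- records[order(match(records$scenario, names(scenarios)), records$point), ]
  rownames(records) <- NULL
  structure(list(records = records, strain_fractions = fracs,
                 scenarios = scenarios, grid = grid, config = config,
                 thread_type = web$links$thread_type),
            class = "web_result_table")
}

empty_records <- function() {
  data.frame(scenario = character(), point = integer(), u = numeric(),
             v = numeric(), outcome = character(), broken_count = integer(),
             peak_strain_energy = numeric(), max_strain_fraction = numeric(),
             final_forward_velocity = numeric(), final_forward_position = numeric(),
             status = character(), message = character())
}

#' @export
print.web_result_table <- function(x, ...) {
  cat(sprintf("Impact result table: %d records (%d scenarios x %d points)\n",
              nrow(x$records), length(unique(x$records$scenario)),
              length(unique(x$records$point))))
  print(summary(x))
  invisible(x)
}

#' Per-scenario aggregates of a result table
#'
#' @param object A `"web_result_table"`.
#' @param top_bin Strain-fraction threshold for the "near failure" tally
#'   (default 0.9, the top decile of the breaking strain).
#' @param ... Unused.
#' @return A data frame with one row per scenario: run counts by outcome,
#'   broken-thread totals, peak strain-energy statistics and the number of
#'   links whose peak strain fraction reached the top bin.
#' @export
summary.web_result_table <- function(object, top_bin = 0.9, ...) {
  rec <- object$records
  if (nrow(rec) == 0L) return(data.frame())
  sc <- unique(rec$scenario)
  out <- lapply(sc, function(s) {
    r <- rec[rec$scenario == s & rec$status == "ok", ]
    fr <- object$strain_fractions[[s]]
    data.frame(scenario = s, n = sum(rec$scenario == s),
               failed = sum(rec$scenario == s & rec$status != "ok"),
               stopped = sum(r$outcome == "stopped"),
               pass_through = sum(r$outcome == "pass_through"),
               broken_total = sum(r$broken_count),
               broken_max = if (nrow(r)) max(r$broken_count) else NA_integer_,
               peak_energy_mean = mean(r$peak_strain_energy),
               peak_energy_max = if (nrow(r)) max(r$peak_strain_energy) else NA_real_,
               top_bin_links = if (is.null(fr)) NA_real_ else
                 sum(fr >= top_bin, na.rm = TRUE))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Histogram of peak thread strain fractions
#'
#' Bins the per-link maxima of strain as a fraction of the breaking strain
#' over `[0, 1]`, with links at or beyond failure (fraction >= 1, i.e.
#' broken threads) accumulated in the terminal bin. Also reports the
#' moment skewness of each scenario's distribution: more negative skew
#' means more mass piled up towards 1.
#'
#' @param x A `"web_result_table"` or a single `"impact_sim"`.
#' @param bins Bin edges on the fraction axis (default deciles of the
#'   breaking strain); the last bin is extended to `Inf`.
#' @return A list with `counts` (scenario x bin matrix), `breaks` and
#'   `skewness` (named per scenario).
#' @export
strain_fraction_histogram <- function(x, bins = seq(0, 1, by = 0.1)) {
  get_fracs <- function() {
    if (inherits(x, "impact_sim")) {
      f <- list(x$peak_strain_fraction$peak_fraction)
      names(f) <- x$scenario
      f
    } else if (inherits(x, "web_result_table")) {
      lapply(x$strain_fractions, function(m) as.numeric(m[!is.na(m)]))
    } else stop("x must be an impact_sim or web_result_table", call. = FALSE)
  }
  fr <- get_fracs()
  edges <- c(bins, Inf)
  counts <- t(vapply(fr, function(v) {
    v <- pmax(v, 0)                       # slack links carry no positive strain
    as.numeric(table(cut(v, edges, right = FALSE, include.lowest = TRUE)))
  }, numeric(length(edges) - 1L)))
  colnames(counts) <- paste0("[", utils::head(edges, -1L), ",",
                             c(utils::tail(bins, -1L), "Inf"), ")")
  skew <- vapply(fr, function(v) {
    m <- mean(v); s <- stats::sd(v)
    if (s == 0) 0 else mean((v - m)^3) / s^3
  }, 0)
  list(counts = counts, breaks = edges, skewness = skew)
}

#' Qualitative reproduction report
#'
#' Checks the ordering claims the scenario sweep is expected to show:
#' temperature scenarios stop the projectile at (essentially) all points;
#' high humidity passes through everywhere; low humidity passes through at
#' most points; the humidity extremes break more threads and push more
#' links near failure than the baseline; and within a scenario, stopped
#' impacts store more peak strain energy than pass-throughs.
#'
#' @param results A `"web_result_table"` from the six climate scenarios.
#' @param top_bin Strain-fraction threshold for the near-failure tally.
#' @return A named list of logical flags plus the underlying summary table.
#' @export
qualitative_report <- function(results, top_bin = 0.9) {
  s <- summary(results, top_bin = top_bin)
  rownames(s) <- s$scenario
  rec <- results$records[results$records$status == "ok", ]
  frac_stopped <- function(nm) {
    r <- s[nm, ]
    ifelse(r$stopped + r$pass_through > 0, r$stopped / (r$stopped + r$pass_through), NA)
  }
  temp <- c("temperature_low", "temperature_medium", "temperature_high")
  hum_med <- "humidity_medium"
  stopped_vs_pass <- vapply(unique(rec$scenario), function(nm) {
    r <- rec[rec$scenario == nm, ]
    a <- r$peak_strain_energy[r$outcome == "stopped"]
    b <- r$peak_strain_energy[r$outcome == "pass_through"]
    if (length(a) == 0 || length(b) == 0) NA else mean(a) > mean(b)
  }, NA)
  flags <- list(
    temperature_all_stopped = all(vapply(temp, frac_stopped, 0) >= 0.9),
    humidity_high_all_pass = s["humidity_high", "pass_through"] ==
      s["humidity_high", "stopped"] + s["humidity_high", "pass_through"],
    humidity_low_majority_pass = frac_stopped("humidity_low") < 0.5,
    humidity_extremes_more_breakage =
      s["humidity_low", "broken_total"] > s[hum_med, "broken_total"] &&
      s["humidity_high", "broken_total"] > s[hum_med, "broken_total"],
    humidity_extremes_more_near_failure =
      s["humidity_low", "top_bin_links"] > s[hum_med, "top_bin_links"] &&
      s["humidity_high", "top_bin_links"] > s[hum_med, "top_bin_links"],
    stopped_store_more_energy = all(stopped_vs_pass, na.rm = TRUE))
  list(flags = flags, summary = s)
}
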