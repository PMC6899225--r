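# Pipeline tests run on the small consistent web with short horizons so
# the whole file stays in the seconds range.

small_cfg <- function(duration = 2e-2)
  sim_config(duration = duration, dt = 1e-6, record_interval = 1e-4)

test_that("classify_outcome applies the distance-and-velocity rule", {
  web <- fx_small_web()
  m <- fx_materials()
  sim <- simulate_impact(web, m, projectile(), c(0, 0), small_cfg())
  expect_true(classify_outcome(sim) %in% c("stopped", "pass_through"))
  # synthetic tails exercise both sides of the rule
  fake <- sim
  n <- nrow(fake$trajectory)
  fake$trajectory$forward[n] <- 0.2
  fake$trajectory$v_forward[n] <- 0.5
  expect_identical(classify_outcome(fake), "pass_through")
  fake$trajectory$v_forward[n] <- -0.5   # beyond the plane but rebounding
  expect_identical(classify_outcome(fake), "stopped")
  fake$trajectory$forward[n] <- 0.05     # within the deflection envelope
  fake$trajectory$v_forward[n] <- 0.5
  expect_identical(classify_outcome(fake), "stopped")
})

test_that("run_grid produces one record per scenario x point", {
  web <- fx_small_web()
  m <- fx_materials()
  sc <- climate_scenarios()[c("humidity_medium", "temperature_medium",
                              "humidity_high")]
  grid <- impact_points(fx_small_params(), 3L)
  res <- run_grid(web, m, sc, grid, small_cfg(), projectile())
  expect_s3_class(res, "web_result_table")
  rec <- res$records
  expect_identical(nrow(rec), 9L)
  expect_setequal(unique(rec$scenario), names(sc))
  expect_true(all(rec$status == "ok"))
  expect_true(all(rec$outcome %in% c("stopped", "pass_through")))
  # the two zero-delta mediums are the same physical run
  a <- rec[rec$scenario == "humidity_medium", -1]
  b <- rec[rec$scenario == "temperature_medium", -1]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
  # strain-fraction matrices are per scenario, one column per point
  expect_identical(dim(res$strain_fractions$humidity_medium),
                   c(nrow(web$links), 3L))
  expect_true(all(!is.na(res$strain_fractions$humidity_high)))
})

test_that("parallel and serial grids agree exactly", {
  skip_on_os("windows")            # forked workers
  web <- fx_small_web()
  m <- fx_materials()
  sc <- climate_scenarios()["humidity_medium"]
  grid <- impact_points(fx_small_params(), 3L)
  serial <- run_grid(web, m, sc, grid, small_cfg(), projectile(), cores = 1L)
  parallel <- run_grid(web, m, sc, grid, small_cfg(), projectile(), cores = 2L)
  expect_identical(serial$records, parallel$records)
  expect_identical(serial$strain_fractions, parallel$strain_fractions)
})

test_that("run_grid tolerates empty scenario sets and failing runs", {
  web <- fx_small_web()
  m <- fx_materials()
  empty <- run_grid(web, m, scenarios = list(),
                    grid = impact_points(fx_small_params(), 1L),
                    config = small_cfg())
  expect_identical(nrow(empty$records), 0L)
  # an unstable configuration is reported, not thrown
  bad <- small_cfg()
  bad$vmax_abort <- 0.5
  res <- run_grid(web, m, climate_scenarios()["humidity_medium"],
                  impact_points(fx_small_params(), 1L), bad, projectile())
  expect_identical(res$records$status, "failed")
  expect_match(res$records$message, "unstable")
  expect_true(is.na(res$records$outcome))
})

test_that("summary.web_result_table aggregates per scenario", {
  web <- fx_small_web()
  m <- fx_materials()
  sc <- climate_scenarios()[c("humidity_medium", "humidity_high")]
  res <- run_grid(web, m, sc, impact_points(fx_small_params(), 2L),
                  small_cfg(), projectile())
  s <- summary(res)
  expect_identical(nrow(s), 2L)
  expect_setequal(s$scenario, names(sc))
  expect_true(all(s$n == 2L))
  expect_equal(s$stopped + s$pass_through, s$n - s$failed)
  expect_true(all(s$peak_energy_max >= s$peak_energy_mean))
  expect_true(all(s$top_bin_links >= 0))
})

test_that("strain_fraction_histogram bins every link and flags skew", {
  web <- fx_small_web()
  m <- fx_materials()
  sim <- simulate_impact(web, m, projectile(), c(0, 0), small_cfg())
  h <- strain_fraction_histogram(sim)
  expect_identical(sum(h$counts), as.numeric(nrow(web$links)))
  expect_identical(nrow(h$counts), 1L)
  expect_true(is.finite(h$skewness))
  # table input: counts add up over scenarios and points
  res <- run_grid(web, m, climate_scenarios()["humidity_medium"],
                  impact_points(fx_small_params(), 2L), small_cfg())
  ht <- strain_fraction_histogram(res)
  expect_identical(sum(ht$counts), as.numeric(2L * nrow(web$links)))
  expect_error(strain_fraction_histogram(1:3), "impact_sim or web_result_table")
})

test_that("qualitative_report evaluates the documented ordering claims", {
  # a fabricated result table with a known pattern checks the flag logic
  # without hours of simulation
  mk <- function(scenario, outcome, broken, peak) {
    data.frame(scenario = scenario, point = seq_along(outcome), u = 0, v = 0,
               outcome = outcome, broken_count = broken,
               peak_strain_energy = peak, max_strain_fraction = 0.5,
               final_forward_velocity = 0, final_forward_position = 0,
               status = "ok", message = "")
  }
  rec <- rbind(
    mk("temperature_low", c("stopped", "stopped"), c(0, 0), c(8e-4, 7e-4)),
    mk("temperature_medium", c("stopped", "stopped"), c(0, 0), c(8e-4, 7e-4)),
    mk("temperature_high", c("stopped", "stopped"), c(1, 0), c(8e-4, 7e-4)),
    mk("humidity_medium", c("stopped", "stopped"), c(0, 0), c(8e-4, 7e-4)),
    mk("humidity_low", c("pass_through", "pass_through"), c(2, 1), c(2e-4, 3e-4)),
    mk("humidity_high", c("pass_through", "pass_through"), c(1, 1), c(1e-4, 1e-4)))
  fr <- function(near) matrix(c(rep(near, 5), rep(0.1, 5)), ncol = 2)
  tab <- structure(list(records = rec,
                        strain_fractions = list(
                          temperature_low = fr(0.2), temperature_medium = fr(0.2),
                          temperature_high = fr(0.4), humidity_medium = fr(0.2),
                          humidity_low = fr(0.95), humidity_high = fr(0.95))),
                   class = "web_result_table")
  qr <- qualitative_report(tab)
  expect_true(qr$flags$temperature_all_stopped)
  expect_true(qr$flags$humidity_high_all_pass)
  expect_true(qr$flags$humidity_low_majority_pass)
  expect_true(qr$flags$humidity_extremes_more_breakage)
  expect_true(qr$flags$humidity_extremes_more_near_failure)
  expect_true(qr$flags$stopped_store_more_energy)
  # flipping the humidity-high outcomes flips the corresponding flag
  rec2 <- rec
  rec2$outcome[rec2$scenario == "humidity_high"] <- "stopped"
  tab2 <- tab; tab2$records <- rec2
  expect_false(qualitative_report(tab2)$flags$humidity_high_all_pass)
})
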