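test_that("a unit never runs two missions at once and timing is conserved", {
  region <- generate_region(3, 10, 0.3, seed = 2)
  sim <- simulate_operations(region, sim_config(horizon_days = 60, seed = 3))
  by_unit <- split(sim$missions, sim$missions$unit_id)
  for (mu in by_unit) {
    o <- order(mu$start_time)
    s <- as.numeric(mu$start_time)[o]
    e <- as.numeric(mu$end_time)[o]
    expect_true(all(e > s))
    if (nrow(mu) > 1) expect_true(all(s[-1] >= e[-length(e)]))
  }
  # response time at least the uncontended travel floor (minute rounding)
  rt <- response_time_minutes(sim$incidents)
  expect_true(all(rt >= floor(sim$ground_truth$true_travel_min) - 1))
})

test_that("every incident has exactly one primary mission; no secondaries when rate is 0", {
  cfg <- sim_config(horizon_days = 30, seed = 11, secondary_rate = 0)
  sim <- simulate_operations(single_unit_region(), cfg)
  expect_true(all(sim$missions$kind == "primary"))
  expect_equal(nrow(sim$missions), nrow(sim$incidents))
  expect_setequal(sim$missions$incident_id, sim$incidents$incident_id)
})

test_that("ground-truth busy flag matches brute-force recomputation from the mission log", {
  region <- generate_region(3, 10, 0.3, seed = 2)
  sim <- simulate_operations(region, sim_config(horizon_days = 45, seed = 5))
  gt <- sim$ground_truth
  m <- sim$missions
  pick <- seq_len(min(nrow(gt), 400))
  recomputed <- vapply(pick, function(i) {
    mu <- m[m$unit_id == gt$preferred_unit[i], ]
    t <- sim$incidents$call_time[i]
    any(mu$start_time <= t & t < mu$end_time &
          (is.na(mu$incident_id) |
             mu$incident_id != gt$incident_id[i]))
  }, logical(1))
  expect_equal(gt$truly_busy[pick], recomputed)
})

test_that("with zero injected delay, busy and free incidents respond alike within neighbourhoods", {
  region <- generate_region(10, 40, 0.3, seed = 21)
  sim <- simulate_operations(region,
                             sim_config(horizon_days = 260, seed = 22,
                                        delay_effect_min = 0))
  expect_gte(nrow(sim$incidents), 10000)
  d <- data.frame(rt = response_time_minutes(sim$incidents),
                  busy = as.numeric(sim$ground_truth$truly_busy),
                  nb = sim$incidents$nb_id)
  f <- lm(rt ~ busy + factor(nb), data = d)
  est <- summary(f)$coefficients["busy", ]
  expect_lt(abs(est[["Estimate"]]), 3 * est[["Std. Error"]])
})

test_that("busy fraction rises with mission duration and delay gap rises with the injected effect", {
  region <- generate_region(2, 6, 0.3, seed = 31)
  busy_frac <- vapply(c(log(25), log(55), log(110)), function(ml) {
    sim <- simulate_operations(region,
      sim_config(horizon_days = 40, seed = 32, occupancy_extra_meanlog = ml))
    mean(sim$ground_truth$truly_busy)
  }, numeric(1))
  expect_true(all(diff(busy_frac) > 0))

  gap <- vapply(c(0, 8), function(delta) {
    sim <- simulate_operations(region,
      sim_config(horizon_days = 120, seed = 33, delay_effect_min = delta))
    d <- data.frame(rt = response_time_minutes(sim$incidents),
                    busy = as.numeric(sim$ground_truth$truly_busy),
                    nb = sim$incidents$nb_id)
    coef(lm(rt ~ busy + factor(nb), data = d))[["busy"]]
  }, numeric(1))
  expect_gt(gap[2], gap[1])
})

test_that("an uncovered schedule is rejected with the first uncovered time", {
  region <- single_unit_region()
  region$units$shift_start <- 8
  region$units$shift_end <- 20
  expect_error(simulate_operations(region, sim_config(horizon_days = 10, seed = 1)),
               "no unit on shift", class = "ambusy_sim_error")
})

test_that("defect injection hits exact deterministic counts and is idempotent at zero rates", {
  region <- generate_region(2, 6, 0.3, seed = 41)
  sim <- simulate_operations(region, sim_config(horizon_days = 90, seed = 42))
  cfg0 <- sim_config(horizon_days = 90, seed = 42,
                     missing_coord_rate = 0, timestamp_error_rate = 0)
  out0 <- inject_defects(sim$incidents, cfg0)
  expect_identical(out0[names(sim$incidents)], sim$incidents)
  expect_true(all(out0$.defect == "none"))

  cfg <- sim_config(horizon_days = 90, seed = 42,
                    missing_coord_rate = 0.05, timestamp_error_rate = 0.02)
  out <- inject_defects(sim$incidents, cfg)
  n <- nrow(sim$incidents)
  expect_equal(sum(out$.defect == "missing_coords"), round(0.05 * n))
  expect_equal(sum(out$.defect == "timestamp"), round(0.02 * n))
  expect_true(all(is.na(out$lat[out$.defect == "missing_coords"])))
  bad_rt <- response_time_minutes(out[out$.defect == "timestamp", ])
  expect_true(all(bad_rt < 0 | bad_rt > 360))
})

test_that("every injected defect row is removed by the eligibility filter", {
  region <- generate_region(2, 6, 0.3, seed = 41)
  sim <- simulate_operations(region, sim_config(horizon_days = 90, seed = 42))
  cfg <- sim_config(horizon_days = 90, seed = 42,
                    missing_coord_rate = 0.08, timestamp_error_rate = 0.04)
  out <- inject_defects(sim$incidents, cfg)
  filt <- filter_incidents(out)
  defect_ids <- out$incident_id[out$.defect != "none"]
  expect_length(intersect(filt$eligible$incident_id, defect_ids), 0)
  clean_acute <- out$incident_id[out$.defect == "none" &
                                   out$urgency == "acute"]
  expect_setequal(filt$eligible$incident_id, clean_acute)
})

test_that("simulation is reproducible and writes round-trippable logs", {
  region <- generate_region(2, 6, 0.3, seed = 51)
  a <- simulate_operations(region, sim_config(horizon_days = 20, seed = 52))
  b <- simulate_operations(region, sim_config(horizon_days = 20, seed = 52))
  expect_identical(a$incidents, b$incidents)
  expect_identical(a$missions, b$missions)

  dir <- withr::local_tempdir()
  paths <- write_ems_logs(a, dir)
  expect_true(all(file.exists(paths)))
  inc <- read_incidents(paths[["incidents"]])
  mis <- read_missions(paths[["missions"]])
  expect_equal(as.data.frame(inc), as.data.frame(a$incidents), tolerance = 1e-12)
  expect_equal(as.data.frame(mis), as.data.frame(a$missions), tolerance = 1e-12)
})
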