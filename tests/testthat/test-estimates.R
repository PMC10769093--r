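test_that("candidate strata partition the cohort and small strata lose their intervals", {
  rows <- synthetic_rows(600, n_groups = 5, delta = 4, seed = 21)
  est <- stratified_estimates(rows, B = 100, seed = 1, min_n = 100,
                              strata = c("overall", "candidates"))
  n_parts <- est$n[est$stratum %in%
                     c("candidates=1", "candidates=2", "candidates>2")]
  expect_equal(sum(n_parts), est$n[est$stratum == "overall"])

  est2 <- stratified_estimates(rows, B = 100, seed = 1, min_n = 10000,
                               strata = c("overall", "urban"))
  expect_true(all(is.na(est2$delay_lower)))
  expect_true(all(!is.na(est2$delay_per_10pp)))
  expect_s3_class(est2, "ambusy_estimates")
})

test_that("rural and urban busy probabilities track the simulator's ground truth ordering", {
  run <- big_run()
  est <- stratified_estimates(run$rows, B = 100, seed = 5,
                              strata = c("overall", "urban"))
  gt <- dplyr::inner_join(run$sim$ground_truth,
                          run$sim$incidents[, c("incident_id", "urban")],
                          by = "incident_id")
  true_order <- mean(gt$truly_busy[gt$urban]) >
    mean(gt$truly_busy[!gt$urban])
  est_order <- est$mean_busy_probability[est$stratum == "urban"] >
    est$mean_busy_probability[est$stratum == "rural"]
  expect_equal(est_order, true_order)
  # intervals bracket their point estimates
  done <- est[est$replicates > 0, ]
  expect_true(all(done$delay_lower <= done$delay_per_10pp + 1e-9 &
                    done$delay_per_10pp <= done$delay_upper + 1e-9))
})

test_that("hourly estimates on a flat-intensity simulation stay consistent with the overall effect", {
  region <- generate_region(3, 10, 0.3, seed = 61)
  cfg <- sim_config(horizon_days = 150, seed = 62, delay_effect_min = 6,
                    hour_mult = rep(1, 24), dow_mult = rep(1, 7))
  sim <- simulate_operations(region, cfg)
  filt <- filter_incidents(sim$incidents)
  expo <- estimate_busy_exposure(filt$eligible, sim$missions,
                                 min_neighbors = 30)
  rows <- analysis_rows(filt$eligible, expo)
  est <- stratified_estimates(rows, B = 100, seed = 63, min_n = 30,
                              strata = c("overall", "hour"))
  overall <- est[est$stratum == "overall", ]
  hourly <- est[grepl("^hour=", est$stratum) & est$replicates > 0, ]
  se <- (hourly$delay_upper - hourly$delay_lower) / (2 * 1.96)
  z <- abs(hourly$delay_per_10pp - overall$delay_per_10pp) / se
  expect_true(all(z < 3 | is.na(z)))
})

test_that("the balance test finds nothing under independence and flags a planted association", {
  run <- big_run()
  rows <- run$rows

  null_res <- balance_test(rows, B = 100, seed = 71)
  expect_true(all(null_res$or_lower <= 1 & 1 <= null_res$or_upper))

  # plant: fire incidents twice as likely when the preferred unit is busy
  gt <- run$sim$ground_truth
  busy <- gt$truly_busy[match(rows$incident_id, gt$incident_id)]
  planted <- rows
  withr::with_seed(72, {
    flip <- busy & runif(nrow(planted)) < 0.25
    planted$incident_type[flip] <- "fire"
  })
  res <- balance_test(planted, types = "fire", B = 100, seed = 73)
  expect_gt(res$or_lower, 1)

  # absent types are skipped with a note
  expect_message(
    out <- balance_test(rows[rows$incident_type == "fire", ],
                        types = c("fire", "traffic accident"), B = 0),
    "skipped")
  expect_equal(out$incident_type, "fire")
})

test_that("excluding pandemic years reproduces homogeneous-period estimates and conserves counts", {
  rows <- synthetic_rows(4000, n_groups = 6, delta = 5, seed = 81,
                         years = 2019:2022)
  full <- stratified_estimates(rows, B = 100, seed = 82,
                               strata = "overall")
  sens <- covid_sensitivity(rows, B = 100, seed = 82, min_n = 100)
  expect_equal(attr(sens, "n_excluded") +
                 sens$n[sens$stratum == "overall"], nrow(rows))
  ov <- sens[sens$stratum == "overall", ]
  expect_gte(ov$delay_per_10pp, full$delay_lower)
  expect_lte(ov$delay_per_10pp, full$delay_upper)

  only_covid <- rows[rows$year %in% c(2020, 2021), ]
  expect_error(covid_sensitivity(only_covid), class = "ambusy_empty_error")
})

test_that("estimate and calibration plots build without evaluation errors", {
  rows <- synthetic_rows(600, n_groups = 5, delta = 4, seed = 91)
  est <- stratified_estimates(rows, B = 100, seed = 92, min_n = 100,
                              strata = c("overall", "urban"))
  p <- ggplot2::autoplot(est)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)

  run <- big_run()
  p2 <- plot_exposure_calibration(run$exposure, run$sim$ground_truth)
  expect_s3_class(p2, "ggplot")
  expect_s3_class(attr(p2, "calibration"), "tbl_df")
})
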