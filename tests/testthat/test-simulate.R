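test_that("LR pairs invert to the unique implied sensitivity/specificity", {
  ss <- lr_to_sens_spec(2, 0.5)
  expect_equal(ss$sensitivity, 2 / 3, tolerance = 1e-12)
  expect_equal(ss$specificity, 2 / 3, tolerance = 1e-12)
  # inversion reproduces the LR pair for random realizable cases
  set.seed(11)
  for (i in 1:20) {
    sens <- runif(1, 0.05, 0.95)
    spec <- runif(1, 0.05, 0.95)
    lrp <- sens / (1 - spec)
    lrn <- (1 - sens) / spec
    if (lrp <= lrn) next
    got <- lr_to_sens_spec(lrp, lrn)
    expect_equal(got$sensitivity, sens, tolerance = 1e-10)
    expect_equal(got$specificity, spec, tolerance = 1e-10)
  }
  expect_error(lr_to_sens_spec(1, 1, item = "flat_item"), "flat_item",
               class = "sah_config_error")
  expect_error(lr_to_sens_spec(0.5, 2, item = "inverted"), "inverted",
               class = "sah_config_error")
})

test_that("cohorts are seed-deterministic and respect boundary prevalences", {
  reg <- default_registry()
  cfg <- simulation_config(500, 0.075, reg, seed = 33)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  c2 <- simulate_cohort(simulation_config(500, 0.075, reg, seed = 34))
  expect_false(identical(a, c2))

  none <- simulate_cohort(simulation_config(300, 0, reg, seed = 1))
  expect_false(any(none$true_sah))
  all_sah <- simulate_cohort(simulation_config(300, 1, reg, seed = 1))
  expect_true(all(all_sah$true_sah))
  expect_true(all(a$hours >= 0))
})

test_that("marginal SAH frequency converges to the configured prevalence", {
  reg <- default_registry()
  n <- 50000
  prev <- 0.075
  co <- simulate_cohort(simulation_config(n, prev, reg, seed = 2024))
  se <- sqrt(prev * (1 - prev) / n)
  expect_lt(abs(mean(co$true_sah) - prev), 3 * se)
})

test_that("simulated CT results recover the stratified sensitivities", {
  reg <- load_registry(make_registry_doc(tests = list(
    noncontrast_ct = list(sensitivity = 0.94, specificity = 0.999,
                          stratified = stratified_bands))))
  co <- simulate_cohort(simulation_config(10000, 0.5, reg, seed = 99))
  sick <- co[co$true_sah, ]
  early <- sick[sick$hours < 6, ]
  late <- sick[sick$hours >= 6, ]
  expect_gt(nrow(early), 100)
  expect_gt(nrow(late), 100)
  # the <6 h band is perfectly sensitive: every diseased early scan positive
  expect_true(all(early$noncontrast_ct_result == "positive"))
  emp <- mean(late$noncontrast_ct_result == "positive")
  se <- sqrt(0.89 * 0.11 / nrow(late))
  expect_lt(abs(emp - 0.89), 3 * se)
})

test_that("a well-specified scorer is calibrated on its own cohorts", {
  reg <- default_registry()
  co <- score_cohort(simulate_cohort(simulation_config(30000, 0.075, reg,
                                                       seed = 5)), reg)
  cal <- evaluate_calibration(co, reg, n_bins = 10)
  expect_identical(nrow(cal), 10L)
  expect_identical(sum(cal$n), 30000L)
  occupied <- cal[cal$n > 0, ]
  expect_true(all(abs(occupied$observed_rate - occupied$mean_posterior) <=
                    3 * occupied$se + 1e-12))
  # empty bins are reported, not dropped
  expect_true(any(cal$n == 0))
})

test_that("a mis-specified prior produces detectable mis-calibration", {
  reg <- default_registry()
  # generate at double the prior the scorer assumes
  co <- simulate_cohort(simulation_config(30000, 2 * reg$prevalence, reg,
                                          seed = 6))
  co <- score_cohort(co, reg, prior = reg$prevalence)
  # under-prediction overall: observed SAH rate exceeds mean posterior
  expect_gt(mean(co$true_sah), mean(co$posttest))
})

test_that("single-patient and empty cohorts degrade gracefully", {
  reg <- default_registry()
  one <- score_cohort(simulate_cohort(simulation_config(1, 0.5, reg, seed = 3)),
                      reg)
  cal <- evaluate_calibration(one, reg, n_bins = 5)
  expect_identical(sum(cal$n), 1L)
  expect_identical(sum(cal$n > 0), 1L)

  empty <- simulate_cohort(simulation_config(0, 0.5, reg, seed = 3))
  cmp <- compare_strategies(empty, reg)
  expect_identical(cmp$n_lp, c(0L, 0L))
  expect_identical(cmp$sah_missed, c(0L, 0L))
})

test_that("zone-gated LP strategy performs fewer LPs when posteriors fall low", {
  reg <- default_registry()
  co <- score_cohort(simulate_cohort(simulation_config(20000, 0.005, reg,
                                                       seed = 8)), reg)
  cmp <- compare_strategies(co, reg)
  a <- cmp[cmp$strategy == "A_lp_all_ct_negative", ]
  b <- cmp[cmp$strategy == "B_lp_green_zone_only", ]
  expect_lt(b$n_lp, a$n_lp)
  # strategy A never misses a CT-negative SAH by construction
  expect_identical(a$sah_missed, 0L)
  # when every posterior clears the green boundary the strategies coincide
  thr <- reg$thresholds[["base_test_threshold"]] *
    reg$thresholds[["yellow_band_ratio"]]
  hi <- co[co$posttest >= thr, ]
  cmp_hi <- compare_strategies(hi, reg)
  expect_identical(cmp_hi$n_lp[1], cmp_hi$n_lp[2])
})

test_that("cohort CSV round-trips", {
  reg <- default_registry()
  co <- score_cohort(simulate_cohort(simulation_config(50, 0.2, reg, seed = 12)),
                     reg)
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  write_cohort_csv(co, tmp)
  back <- read_cohort_csv(tmp)
  expect_identical(back$true_sah, co$true_sah)
  expect_equal(back$posttest, co$posttest, tolerance = 1e-12)
  expect_identical(back$sudden_onset, co$sudden_onset)
})
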