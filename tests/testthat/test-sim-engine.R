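test_that("scenario construction resolves regimens and persistence", {
  tab <- fixture_effect_table()
  untr <- build_scenario(list(name = "untreated", drugs = character(0)), tab)
  expect_null(untr$regimen)
  expect_identical(untr$persistence$lambda, 0)
  dual <- build_scenario(list(name = "dual",
                              drugs = c("drugA 10", "drugB 5"), p1 = 0.5), tab)
  expect_identical(nrow(dual$regimen), 2L)
  expect_equal(dual$persistence$lambda, log(2), tolerance = 1e-12)
  expect_error(build_scenario(list(name = "x", drugs = "nosuchdrug 10"), tab),
               "not found")
  expect_error(build_scenario(list(name = "x",
                                   drugs = c("drugA 10", "drugC 20")), tab),
               "ACEi and ARB")
  expect_error(build_scenario(list(name = "x", drugs = "drugA"), tab),
               "'drug dose'")
})

test_that("event-day simulation matches its closed forms", {
  horizon <- 3650
  # zero hazard: always censored
  expect_true(all(is.na(simulate_event_day(rep(0, 10), rep(0, 10),
                                           rep(Inf, 10), runif(10), horizon))))
  # deterministic hand case: E = -log(u); h constant, no discontinuation
  u <- exp(-0.1)  # E = 0.1
  d <- simulate_event_day(0.02536, 0.02536, Inf, u, horizon)
  expect_identical(d, ceiling(0.1 * 365 / 0.02536))
  # 10-year event fraction at the calibration-anchor hazard
  n <- 100000
  set.seed(83)
  day <- simulate_event_day(rep(0.02536, n), rep(0.02536, n), rep(Inf, n),
                            runif(n), horizon)
  p_true <- 1 - exp(-0.2536)
  expect_lt(abs(mean(!is.na(day)) - p_true), 3 * sqrt(p_true * (1 - p_true) / n))
  expect_lt(abs(mean(!is.na(day)) - 0.224), 0.005)
  # change-point: hazard reverts after discontinuation; survival at the
  # horizon equals exp(-(H_on + H_off))
  disc <- rep(365, n)
  set.seed(85)
  day2 <- simulate_event_day(rep(0.05, n), rep(0.01, n), disc, runif(n), horizon)
  p2 <- 1 - exp(-(0.05 * 365 / 365 + 0.01 * (3650 - 365) / 365))
  expect_lt(abs(mean(!is.na(day2)) - p2), 3 * sqrt(p2 * (1 - p2) / n))
  # no event before the change point exceeds the on-treatment rate
  frac_before <- mean(day2 <= 365, na.rm = TRUE) * mean(!is.na(day2))
  expect_lt(abs(frac_before - (1 - exp(-0.05))), 0.005)
})

test_that("inverse-transform fast path is statistically identical to the daily cycle", {
  n <- 5000; horizon <- 730
  h_on <- rep(0.06, n); h_off <- rep(0.12, n); disc <- rep(180, n)
  set.seed(87)
  fast <- simulate_event_day(h_on, h_off, disc, runif(n), horizon)
  set.seed(88)
  slow <- simulate_event_day_daily(h_on, h_off, disc, horizon)
  p_fast <- mean(!is.na(fast)); p_slow <- mean(!is.na(slow))
  se <- sqrt(p_fast * (1 - p_fast) / n)
  expect_lt(abs(p_fast - p_slow), 3 * sqrt(2) * se)
  # mean event day agrees too
  se_day <- sd(fast, na.rm = TRUE) / sqrt(sum(!is.na(fast)))
  expect_lt(abs(mean(fast, na.rm = TRUE) - mean(slow, na.rm = TRUE)),
            3 * sqrt(2) * se_day)
})

test_that("Kaplan-Meier curve equals the empirical cumulative incidence", {
  horizon <- 3650
  expect_identical(km_curve(rep(NA_real_, 5), horizon)$estimate, c(0, 0))
  # hand-computed product limit: events at 100 and 500, three censored
  km <- km_curve(c(100, 500, NA, NA, NA), horizon)
  expect_equal(km$estimate[km$day == 500], 100 * (1 - 0.8 * 0.75),
               tolerance = 1e-12)
  expect_equal(km$estimate[nrow(km)], 40, tolerance = 1e-12)
  km_all <- km_curve(c(10, 20, 30), horizon)
  expect_equal(km_all$estimate[nrow(km_all)], 100, tolerance = 1e-12)
  # property: with administrative censoring only, KM = empirical incidence
  set.seed(91)
  days <- simulate_event_day(rep(0.03, 4000), rep(0.03, 4000),
                             rep(Inf, 4000), runif(4000), horizon)
  km2 <- km_curve(days, horizon)
  expect_equal(km2$estimate[nrow(km2)], 100 * mean(!is.na(days)),
               tolerance = 1e-9)
  expect_true(all(diff(km2$estimate) >= 0))
  expect_error(km_curve(c(10, 4000), horizon), "horizon")
})

test_that("run_scenario: oracle equivalence, determinism, and guards", {
  n <- 20000
  coh <- fixture_homogeneous_cohort(n)
  tab <- fixture_effect_table_sd0()
  cfg <- engine_config(n_sample = n, iterations = 3, master_seed = 7)
  h0 <- 0.025
  risks <- fixture_homogeneous_risks(n, h0)
  untr <- build_scenario(list(name = "untreated", drugs = character(0)), tab)
  res <- run_scenario(coh, risks, untr, tab, cfg)
  p <- 1 - exp(-10 * h0)
  se <- 100 * sqrt(p * (1 - p) / (n * cfg$iterations))
  expect_lt(abs(res$rate_10y - 100 * p), 3 * se)
  # treated: RR from an exactly-known regimen (sd 0)
  mono <- build_scenario(list(name = "mono", drugs = "drugA 10"), tab)
  res_m <- run_scenario(coh, risks, mono, tab, cfg)
  rr <- rr_from_delta(8.8)
  p_m <- 1 - exp(-10 * h0 * rr)
  expect_lt(abs(res_m$rate_10y - 100 * p_m), 3 * se)
  # rate at horizon equals the KM estimate at the horizon
  expect_equal(res$rate_10y, mean(res$iteration_rates), tolerance = 1e-12)
  # determinism from the master seed
  res2 <- run_scenario(coh, risks, untr, tab, cfg)
  expect_identical(res$iteration_rates, res2$iteration_rates)
  expect_identical(res$km, res2$km)
  # limit: overwhelming effect with full persistence drives the rate to ~0
  big <- tab; big$mean_delta_sbp <- 400
  big <- effect_table(as.data.frame(big))
  sat <- build_scenario(list(name = "sat", drugs = "drugA 10"), big)
  expect_lt(run_scenario(coh, risks, sat, big, cfg)$rate_10y, 0.1)
  expect_error(run_scenario(coh, risks, untr, tab,
                            engine_config(n_sample = n + 1, iterations = 1)),
               "exceeds cohort size")
  expect_error(run_scenario(coh[0, ], risks, untr, tab, cfg), "empty")
})

test_that("experiment: ordering, attenuation and reference handling", {
  n <- 30000
  coh <- generate_cohort(n, seed = 97)
  cal <- calibrate_risk_params(0.224, dispersion = 0.8, n = n, seed = 98)
  risks <- assign_untreated_risk(coh, cal, seed = 99)
  tab <- fixture_effect_table()
  cfg <- engine_config(n_sample = n, iterations = 2, master_seed = 11)
  scens <- list(
    build_scenario(list(name = "untreated", drugs = character(0)), tab),
    build_scenario(list(name = "mono", drugs = "drugA 10"), tab),
    build_scenario(list(name = "dual", drugs = c("drugA 10", "drugB 5")), tab),
    build_scenario(list(name = "dual_p50",
                        drugs = c("drugA 10", "drugB 5"), p1 = 0.5), tab))
  exp1 <- run_experiment(coh, risks, scens, cfg, tab)
  ov <- exp1$results[exp1$results$stratum == "overall", ]
  rate <- function(s) ov$rate_10y[ov$scenario == s]
  # common random numbers make the ordering hold per run, not just in mean
  expect_true(rate("untreated") >= rate("mono"))
  expect_true(rate("mono") >= rate("dual"))
  expect_true(rate("dual_p50") <= rate("untreated"))
  a <- function(s) ov$arr[ov$scenario == s]
  expect_identical(a("untreated"), 0)
  expect_true(a("dual_p50") >= 0 && a("dual_p50") <= a("dual"))
  # higher-risk stratum derives a larger ARR at the same regimen
  res <- exp1$results
  arr_of <- function(st) res$arr[res$stratum == st & res$scenario == "dual"]
  expect_gt(arr_of("ascvd"), arr_of("no_ascvd"))
  expect_gt(arr_of("diabetes"), arr_of("no_diabetes"))
  # single-scenario experiment: ARR column all zero
  exp0 <- run_experiment(coh, risks, scens[1], cfg, tab, subgroups = character(0))
  expect_true(all(exp0$results$arr == 0))
  expect_error(run_experiment(coh, risks, scens[2], cfg, tab), "reference")
  # output files
  od <- tempfile()
  run_experiment(coh, risks, scens[1:2], cfg, tab,
                 subgroups = character(0), out_dir = od)
  expect_true(all(file.exists(file.path(od, c("results.csv", "km_curves.csv",
                                              "summary.json", "run_log.txt")))))
  unlink(od, recursive = TRUE)
})

test_that("observed-timeline scenarios run and reduce to closed forms", {
  n <- 2000
  coh <- fixture_homogeneous_cohort(n)
  h0 <- 0.03
  risks <- fixture_homogeneous_risks(n, h0)
  tab <- fixture_effect_table_sd0()
  cfg <- engine_config(n_sample = n, iterations = 2, master_seed = 13)
  # empty timeline: everyone untreated, closed-form rate
  empty_tl <- data.frame(id = integer(0), start_day = integer(0),
                         end_day = integer(0), drug = character(0),
                         dose_mg = numeric(0))
  sc0 <- build_scenario(list(name = "practice", mode = "observed_timeline",
                             timeline = empty_tl), tab)
  r0 <- run_scenario(coh, risks, sc0, tab, cfg)
  p <- 1 - exp(-10 * h0)
  expect_lt(abs(r0$rate_10y - 100 * p),
            3 * 100 * sqrt(p * (1 - p) / (n * 2)))
  # whole-horizon monotherapy timeline matches the fixed-regimen scenario
  full_tl <- data.frame(id = seq_len(n), start_day = 1, end_day = 3650,
                        drug = "drugA", dose_mg = 10)
  sc1 <- build_scenario(list(name = "practice", mode = "observed_timeline",
                             timeline = full_tl), tab)
  r1 <- run_scenario(coh, risks, sc1, tab, cfg)
  rr <- rr_from_delta(8.8)
  p1 <- 1 - exp(-10 * h0 * rr)
  expect_lt(abs(r1$rate_10y - 100 * p1),
            3 * 100 * sqrt(p1 * (1 - p1) / (n * 2)))
  # stylized generator produces a valid, intermediate-rate timeline
  tl <- stylized_practice_timeline(coh, tab, seed = 17)
  expect_true(all(tl$end_day >= tl$start_day))
  sc2 <- build_scenario(list(name = "practice", mode = "observed_timeline",
                             timeline = tl), tab)
  r2 <- run_scenario(coh, risks, sc2, tab, cfg)
  expect_lte(r2$rate_10y, r0$rate_10y + 0.5)
  expect_gte(r2$rate_10y, r1$rate_10y - 0.5)
  expect_error(build_scenario(list(name = "x", mode = "observed_timeline"), tab),
               "timeline")
})
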