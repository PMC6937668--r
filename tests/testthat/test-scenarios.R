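test_that("prevalence ramps hit the published endpoints", {
  # 50% off 41.4% obesity; 30% and 50% off 16.2% smoking; 10% and 50% off
  # 46.0% inactivity, all by 2031
  expect_equal(round(100 * ramp_target(0.414, 0.5, 2031), 1), 20.7)
  expect_equal(round(100 * ramp_target(0.162, 0.3, 2031), 1), 11.3)
  expect_equal(round(100 * ramp_target(0.460, 0.1, 2031), 1), 41.4)
  expect_equal(round(100 * ramp_target(0.162, 0.5, 2031), 1), 8.1)
  expect_equal(round(100 * ramp_target(0.460, 0.5, 2031), 1), 23.0)
})

test_that("ramps are continuous, monotone and constant off the window", {
  tt <- seq(2010, 2050, 0.25)
  v <- ramp_target(0.46, 0.5, tt)
  expect_equal(v[tt <= 2016], rep(0.46, sum(tt <= 2016)))
  expect_equal(v[tt >= 2031], rep(0.23, sum(tt >= 2031)))
  expect_true(all(diff(v) <= 0))
  expect_lt(max(abs(diff(v[tt >= 2016 & tt <= 2031]))), 0.005)
  expect_equal(ramp_target(0.46, 0.5, 2023.5), 0.345)  # midpoint
  expect_equal(ramp_target(0.30, 0, 2040), 0.30)       # halt is the identity
})

test_that("forcings are built per targeted factor with the WHO 2031 levels", {
  base <- c(obesity = 0.414, smoking = 0.162, inactivity = 0.460)
  who <- scenario_spec("who", reductions = c(obesity = 0, smoking = 0.3,
                                             inactivity = 0.1))
  f <- build_forcing(who, base)
  at2031 <- vapply(f$factors, t2dprev:::factor_target_at, numeric(1),
                   t = 2031)
  expect_equal(round(100 * unname(at2031), 1), c(41.4, 11.3, 41.4))

  empty <- build_forcing(scenario_spec("none"), base)
  expect_length(empty$factors, 0)
  expect_null(empty$pa)

  comb <- build_forcing(scenario_spec("comb",
    reductions = c(obesity = 0.5, smoking = 0.5, inactivity = 0.5),
    pa_intensity = "vigorous"), base)
  at2031 <- vapply(comb$factors, t2dprev:::factor_target_at, numeric(1),
                   t = 2031)
  expect_equal(round(100 * unname(at2031), 1), c(20.7, 8.1, 23.0))
  expect_equal(comb$pa$rr, 0.61)
  expect_equal(comb$pa$coverage, 0.25)

  expect_error(scenario_spec("bad", pa_intensity = "gentle"), "vigorous")
  # purity: identical specs give identical forcings
  expect_identical(f, build_forcing(who, base))
})

test_that("scale-up variants clone the ramp window correctly", {
  sp <- scenario_spec("ob40", reductions = c(obesity = 0.4))
  vars <- scale_up_variants(sp, c(5, 10, 15, 20))
  expect_equal(vapply(vars, `[[`, 0, "ramp_end"), c(
    ob40_scaleup_5y = 2021, ob40_scaleup_10y = 2026,
    ob40_scaleup_15y = 2031, ob40_scaleup_20y = 2036))
  # endpoint of the 5-year variant: p0 * (1 - 0.4)
  expect_equal(ramp_target(0.414, 0.4, 2021, ramp_end = 2021), 0.414 * 0.6)
  expect_error(scale_up_variants(sp, 40), "hold horizon")
  expect_error(scale_up_variants(sp, -1), "positive")
})

test_that("the scenario library reproduces the published scenario set", {
  lib <- scenario_library()
  expect_length(lib, 26)
  expect_true(all(c("who_gap", "obesity_halt", "obesity_minus_50",
                    "smoking_minus_30", "inactivity_minus_10",
                    "combined_minus_50", "pa_vigorous", "pa_walking",
                    "combined_minus_50_pa_vigorous") %in% names(lib)))
  expect_equal(lib$who_gap$reductions,
               c(obesity = 0, smoking = 0.3, inactivity = 0.1))
})

test_that("the controller leaves a stationary baseline untouched", {
  fl <- flat_setup()
  halt <- run_scenario(fl$params, fl$state,
                       scenario_spec("halt_all",
                                     reductions = c(obesity = 0, smoking = 0,
                                                    inactivity = 0)))
  # multipliers stay at 1 when the target equals the drift-free prevalence
  expect_lt(max(abs(halt$control_log$mult_eta - 1)), 1e-6)
  expect_lt(max(abs(halt$control_log$mult_rho - 1)), 1e-6)
})

test_that("prevalence targets are tracked within 0.2 percentage points", {
  fit <- demo_fit()
  for (nm in c("obesity_minus_50", "smoking_minus_30", "inactivity_minus_10",
               "who_gap", "combined_minus_50")) {
    tr <- demo_scenario(scenario_library()[[nm]])
    for (k in names(tr$forcing$factors)) {
      f <- tr$forcing$factors[[k]]
      ach <- vapply(tr$times, function(y) risk_prevalence(tr, k, y),
                    numeric(1))
      tgt <- t2dprev:::factor_target_at(f, tr$times)
      expect_lt(max(abs(ach - tgt)), 0.002)
    }
  }
})

test_that("an unattainable target saturates the bounds and warns", {
  fit <- demo_fit()
  sp <- scenario_spec("crash", reductions = c(obesity = 1),
                      ramp_end = 2018, hold_until = 2050)
  expect_warning(
    run_scenario(fit$params, demo_state(), sp, t1 = 2024),
    "deviates from target")
})

test_that("PA coverage ramps to 25% among susceptibles and holds", {
  tr <- demo_scenario(scenario_library()$pa_vigorous)
  m <- t2dprev:::stratum_maps()
  cov <- function(y) {
    N <- tr$counts[which(tr$times == y), ]
    sus <- m$st < 3L & m$age_i %in% 4:13
    sum(N[m$st == 2L & m$age_i %in% 4:13]) / sum(N[sus])
  }
  expect_equal(cov(2031), 0.25, tolerance = 0.005 / 0.25)
  for (y in c(2035, 2040, 2050))
    expect_lt(abs(cov(y) - 0.25), 0.005)
  # linearity on the ramp: roughly half coverage midway
  expect_lt(abs(cov(2024) - 0.25 * (2024 - 2016) / 15), 0.005)
})

test_that("deeper reductions avert at least as much at every year", {
  base <- demo_baseline()
  t10 <- demo_scenario(scenario_library()$inactivity_minus_10)
  t30 <- demo_scenario(scenario_library()$inactivity_minus_30)
  for (y in seq(2018, 2050, 4)) {
    a10 <- cases_averted(base, t10, c(2016, y))$count
    a30 <- cases_averted(base, t30, c(2016, y))$count
    expect_gte(a30, a10)
  }
})
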