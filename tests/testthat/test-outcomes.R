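test_that("prevalence and counts come from the stated numerator/denominator", {
  tr <- fake_trajectory(cases = 24043, population = 144066)
  expect_equal(case_counts(tr, 2016),
               c(cases = 24043, population = 144066))
  expect_equal(prevalence(tr, 2016), 24043 / 144066)
  z <- fake_trajectory(cases = 0, population = 1000)
  expect_equal(prevalence(z, 2016), 0)
  expect_error(prevalence(tr, 2030.5), "reporting grid")
  # invariant under uniform scaling of all counts
  tr2 <- tr; tr2$counts <- tr$counts * 3.7
  expect_equal(prevalence(tr2, 2016), prevalence(tr, 2016))
})

test_that("averted burden is the baseline-minus-scenario cumulant difference", {
  b <- fake_trajectory(1000, 10000, annual_deaths = 500)
  b$cum_cases[2, 7] <- 100
  s <- fake_trajectory(1000, 10000, annual_deaths = 450)
  s$cum_cases[2, 7] <- 80
  ca <- cases_averted(b, s, c(2016, 2017))
  expect_equal(ca$count, 20)
  expect_equal(ca$proportion, 0.20)
  da <- deaths_averted(b, s, c(2016, 2017))
  expect_equal(da$count, 50)
  expect_equal(da$proportion, 0.10)
  same <- cases_averted(b, b, c(2016, 2017))
  expect_equal(same$count, 0)
  expect_equal(same$proportion, 0)
  s2 <- s; s2$times <- c(2016, 2018)
  expect_error(cases_averted(b, s2, c(2016, 2017)), "mismatched")
  s3 <- s; s3$counts[1, 1] <- s3$counts[1, 1] + 5
  expect_error(cases_averted(b, s3, c(2016, 2017)), "initial state")
})

test_that("relative reduction is computed on unrounded prevalences", {
  expect_equal(relative_reduction(0.20, 0.18), 0.10)
  expect_equal(relative_reduction(0.3, 0.3), 0)
  expect_error(relative_reduction(0, 0.1), "positive")
})

test_that("case-fatality uses annual deaths over mid-year prevalent cases", {
  tr <- fake_trajectory(cases = 24043, population = 144066,
                        annual_deaths = 206)
  expect_equal(round(case_fatality_rate(tr, 2016), 1), 8.6)
  z <- fake_trajectory(cases = 0, population = 1000, annual_deaths = 0)
  expect_error(case_fatality_rate(z, 2016), "no prevalent cases")
  nodeaths <- fake_trajectory(cases = 500, population = 1000)
  expect_equal(case_fatality_rate(nodeaths, 2016), 0)
})

test_that("longer windows avert at least as much", {
  base <- demo_baseline()
  tr <- demo_scenario(scenario_library()$obesity_minus_30)
  a31 <- cases_averted(base, tr, c(2016, 2031))$count
  a50 <- cases_averted(base, tr, c(2016, 2050))$count
  expect_gte(a50, a31)
  expect_gt(a31, 0)
  # proportions land in [0, 1] for a hazard-reducing intervention
  for (w in list(c(2016, 2031), c(2016, 2050))) {
    pa <- cases_averted(base, tr, w)$proportion
    expect_gte(pa, 0); expect_lte(pa, 1)
  }
})

test_that("the suite report has the published layout and a clean baseline row", {
  lib <- scenario_library()[c("obesity_halt", "obesity_minus_50")]
  rep <- table1_report(demo_fit()$params, demo_state(), library = lib)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$scenario[1], "baseline")
  b <- rep[1, ]
  expect_true(all(unlist(b[c("cases_averted_mid", "deaths_averted_mid",
                             "cases_averted_end", "deaths_averted_end",
                             "rel_red_mid", "rel_red_end")]) == 0))
  expect_true(all(rep$status == "ok"))
  i50 <- rep$scenario == "obesity_minus_50"
  ih <- rep$scenario == "obesity_halt"
  expect_gt(rep$cases_averted_end[i50], rep$cases_averted_end[ih])
  # deaths lag incidence: proportion of deaths averted < proportion of cases
  expect_lt(rep$prop_deaths_end[i50], rep$prop_cases_end[i50])
  fm <- format_report(rep)
  expect_match(fm$prev_2031[1], "^[0-9.]+%$")
})

test_that("a failing scenario is reported, not fatal", {
  lib <- scenario_library()["obesity_halt"]
  lib$broken <- scenario_spec("broken", reductions = c(obesity = 0.2))
  lib$broken$target_bands <- 999  # invalid band set breaks the run
  rep <- table1_report(demo_fit()$params, demo_state(), library = lib)
  expect_equal(nrow(rep), 3)
  expect_match(rep$status[rep$scenario == "broken"], "failed")
  expect_true(all(rep$status[rep$scenario != "broken"] == "ok"))
})

test_that("percentages round half-up at one decimal", {
  expect_equal(t2dprev:::round_half_up(8.567, 1), 8.6)
  expect_equal(t2dprev:::round_half_up(12.25, 1), 12.3)
  expect_equal(t2dprev:::round_half_up(16.687, 1), 16.7)
})
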