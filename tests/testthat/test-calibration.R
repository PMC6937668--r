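# model-consistent targets: measure a truth run at the target rows
model_targets <- function(truth, targets, state) {
  yr <- sort(unique(c(targets$year, targets$year[targets$quantity == "cfr"] + 1)))
  tr <- simulate_t2d(truth, state, 2016, max(yr), times = yr,
                     method = "lsoda", rtol = 1e-8, atol = 1e-10)
  tg <- targets
  tg$value <- t2dprev:::measure_targets(tr, targets)
  tg
}

test_that("the loss vanishes at the generating parameters", {
  truth <- demo_seed_params()
  tg <- model_targets(truth, demo_targets(), demo_state())
  expect_lt(t2d_loss(truth, tg, demo_state(), rtol = 1e-8, atol = 1e-10),
            1e-10)
})

test_that("the loss is the documented weighted residual sum", {
  fit <- demo_fit()
  expect_equal(fit$loss, sum(fit$residuals$weighted^2),
               tolerance = 1e-12)
  expect_equal(fit$residuals$weighted,
               sqrt(fit$residuals$weight) * fit$residuals$residual,
               tolerance = 1e-12)
  # prevalence residuals are absolute; population and cfr are relative
  pop <- fit$residuals[fit$residuals$quantity == "population", ]
  expect_equal(pop$residual, (pop$model - pop$value) / pop$value,
               tolerance = 1e-12)
})

test_that("the loss is linear in weights and invariant to target order", {
  truth <- demo_seed_params()
  tg <- model_targets(perturb_params(truth, 0.1, seed = 5),
                      demo_targets(), demo_state())
  l1 <- t2d_loss(truth, tg, demo_state())
  tg2 <- tg; tg2$weight <- 2 * tg2$weight
  expect_equal(t2d_loss(truth, tg2, demo_state()), 2 * l1,
               tolerance = 1e-10)
  set.seed(8)
  tg3 <- tg[sample(nrow(tg)), ]
  expect_equal(t2d_loss(truth, tg3, demo_state()), l1, tolerance = 1e-10)
  expect_gt(l1, 0)
})

test_that("calibration from the truth start stays at the optimum", {
  truth <- demo_seed_params()
  tg <- model_targets(truth, demo_targets(), demo_state())
  fit <- t2d_fit(tg, demo_demog(), init = truth, initial = demo_state(),
                 maxiter = 20)
  expect_lt(fit$loss, 1e-10)
  expect_true(all(abs(fit$theta - 1) < 1e-4))
  expect_true(fit$converged)
})

test_that("calibration of the default synthetic world converges", {
  fit <- demo_fit()
  expect_true(fit$converged)
  expect_false(fit$boundary)
  expect_equal(fit$n_restarts_used, 1)
  # fitted scales stay near the analytic seeds
  expect_true(all(fit$theta > 0.5 & fit$theta < 2))
  # the calibrated baseline reproduces the anchored 2016 prevalence and a
  # monotone rise
  pr <- vapply(2016:2050, function(y) prevalence(demo_baseline(), y),
               numeric(1))
  expect_lt(abs(pr[1] - 0.167), 0.003)
  expect_true(all(diff(pr) > 0))
  expect_true(pr[35] > 0.16 && pr[35] < 0.25)
})

test_that("noisy targets degrade recovery gracefully", {
  demog <- demo_demog()
  truth <- demo_seed_params()
  clean <- model_targets(truth, demo_targets(), demo_state())
  errs <- c()
  for (i in 1:5) {
    tg <- clean
    keep <- tg$sex %in% c("female", "male")
    set.seed(100 + i)
    tg$value[keep] <- pmin(pmax(
      tg$value[keep] + rnorm(sum(keep), 0, 0.005), 0), 1)
    fit <- t2d_fit(tg, demog, init = truth, initial = demo_state(),
                   maxiter = 25)
    errs <- c(errs, abs(fit$theta - 1))
  }
  expect_lt(median(errs), 0.15)
})

test_that("an infeasible target ends at a flagged boundary, never silently", {
  tg <- demo_targets()
  tg$value[tg$quantity == "smoking" & tg$sex %in% c("female", "male")] <- 0.99
  fit <- t2d_fit(tg, demo_demog(), initial = demo_state(), upper = 1.2,
                 maxiter = 15)
  expect_true(fit$boundary || !fit$converged)
  expect_gt(fit$loss, 1)
})

test_that("restarts are seeded and the multi-start result is deterministic", {
  truth <- demo_seed_params()
  tg <- model_targets(truth, demo_targets(), demo_state())
  f1 <- t2d_fit(tg, demo_demog(), init = truth, initial = demo_state(),
                n_restarts = 2, seed = 7, maxiter = 8)
  f2 <- t2d_fit(tg, demo_demog(), init = truth, initial = demo_state(),
                n_restarts = 2, seed = 7, maxiter = 8)
  expect_identical(f1$theta, f2$theta)
  expect_equal(f1$n_restarts_used, 2)
})

test_that("fit methods expose the standard modelling interface", {
  fit <- demo_fit()
  expect_s3_class(fit, "t2d_fit")
  expect_named(coef(fit))
  expect_length(residuals(fit), nrow(fit$residuals))
  expect_equal(deviance(fit), fit$loss)
  s <- summary(fit)
  expect_s3_class(s, "summary.t2d_fit")
  expect_output(print(fit), "Calibrated")
  pr <- predict(fit, years = c(2016, 2020), type = "prevalence")
  expect_equal(pr$year, c(2016, 2020))
  expect_true(all(pr$value > 0.1 & pr$value < 0.3))
  tr <- simulate(fit, scenario = scenario_library()$obesity_halt, t1 = 2020)
  expect_s3_class(tr, "t2d_trajectory")
  expect_error(simulate(fit, nsim = 5), "deterministic")
  f <- tempfile(fileext = ".png")
  grDevices::png(f); plot(fit, t1 = 2030); grDevices::dev.off()
  expect_true(file.exists(f)); unlink(f)
})
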