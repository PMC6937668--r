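test_that("the synthetic demography matches its anchors and is young", {
  demog <- demo_demog()
  cfg <- demo_cfg()
  tot16 <- sum(demog$pyramid[4:13, ])
  expect_equal(tot16, cfg$pop_15_64_2016, tolerance = 1e-9)
  proj <- project_population(demog, c(2016, 2050))
  expect_lt(abs(proj[["2016"]] - cfg$pop_15_64_2016) / cfg$pop_15_64_2016,
            0.01)
  expect_lt(abs(proj[["2050"]] - cfg$pop_15_64_2050) / cfg$pop_15_64_2050,
            0.01)
  w <- rowSums(demog$pyramid)
  median_band <- which(cumsum(w) / sum(w) >= 0.5)[1]
  expect_lt(t2dprev:::AGE_MID[median_band], 30)
  expect_true(all(diff(demog$mu[, 1]) > 0))  # mortality increases with age
})

test_that("doubling the entry flow doubles the youngest-band inflow exactly", {
  demog <- demo_demog()
  f1 <- t2dprev:::demography_rhs(demog$mu, demog$entry0, demog$entry_growth,
                                 2016)
  f2 <- t2dprev:::demography_rhs(demog$mu, 2 * demog$entry0,
                                 demog$entry_growth, 2016)
  y <- as.vector(demog$pyramid)
  d1 <- f1(2020, y, NULL)[[1]]
  d2 <- f2(2020, y, NULL)[[1]]
  extra <- d2 - d1
  expect_equal(extra[c(1, 17)],
               unname(demog$entry0 * exp(demog$entry_growth * 4)),
               tolerance = 1e-12)
  expect_equal(extra[-c(1, 17)], rep(0, 30))
})

test_that("infeasible population anchors are refused", {
  cfg <- t2d_config(pop_15_64_2050 = 5e6)
  expect_error(generate_demography(cfg), "infeasible")
})

test_that("noiseless targets reproduce the configured aggregates exactly", {
  cfg <- demo_cfg()
  tg <- demo_targets()
  demog <- demo_demog()
  w <- demog$pyramid[4:13, ]
  for (q in c("obesity", "smoking", "inactivity", "t2dm")) {
    rows <- tg[tg$quantity == q & tg$year == 2016, ]
    v <- matrix(rows$value, ncol = 2)  # bands x sex (female first)
    agg <- sum(w[, 1] * v[, 1] + w[, 2] * v[, 2]) / sum(w)
    want <- if (q == "t2dm") cfg$t2dm_prev_2016 else cfg$prev_2016[[q]]
    expect_equal(agg, want, tolerance = 1e-9)
  }
  # T2DM prevalence increases with age
  t2 <- tg[tg$quantity == "t2dm" & tg$year == 2016 & tg$sex == "male", ]
  expect_true(all(diff(t2$value) > 0))
})

test_that("target generation is deterministic given a seed", {
  cfg <- t2d_config(seed = 9L, noise_sd = 0.5)
  demog <- generate_demography(cfg)
  a <- generate_targets(cfg, demog)
  b <- generate_targets(cfg, demog)
  expect_identical(a$value, b$value)
  c2 <- t2d_config(seed = 10L, noise_sd = 0.5)
  expect_false(identical(generate_targets(c2, demog)$value, a$value))
})

test_that("noisy targets are unbiased around the noiseless values", {
  demog <- demo_demog()
  clean <- demo_targets()
  nrep <- 200
  eligible <- which(clean$sex %in% c("female", "male") &
                      clean$value > 0.1 & clean$value < 0.9)
  pick <- eligible[c(1, 11, 21)]
  acc <- matrix(0, nrep, length(pick))
  for (i in seq_len(nrep)) {
    cfg <- t2d_config(seed = 1000L + i, noise_sd = 0.5)
    acc[i, ] <- generate_targets(cfg, demog)$value[pick]
  }
  se <- 0.005 / sqrt(nrep)
  expect_true(all(abs(colMeans(acc) - clean$value[pick]) < 3 * se))
})

test_that("the initial state matches pyramid and targets with independent factors", {
  cfg <- demo_cfg(); tg <- demo_targets(); demog <- demo_demog()
  st <- demo_state()
  m <- t2dprev:::stratum_maps()
  expect_equal(sum(st), sum(demog$pyramid), tolerance = 1e-9)
  # PA compartments empty at 2016
  expect_equal(sum(st[m$st == 2L]), 0)
  # per-band marginals reproduce the 2016 targets to numerical identity
  rows <- tg[tg$year == 2016 & tg$sex %in% c("female", "male"), ]
  set.seed(4)
  for (r in sample(nrow(rows), 40)) {
    is <- match(rows$sex[r], c("female", "male"))
    ia <- match(rows$age_band[r], t2dprev:::AGE_BANDS)
    mask <- m$sex_i == is & m$age_i == ia
    num <- if (rows$quantity[r] == "t2dm") mask & m$st == 3L
           else mask & m$on[, rows$quantity[r]]
    expect_equal(sum(st[num]) / sum(st[mask]), rows$value[r],
                 tolerance = 1e-12)
  }
  # joint cell equals the product of marginals within a (sex, age) cell
  mask <- m$sex_i == 2L & m$age_i == 9L
  p_ob <- sum(st[mask & m$on[, "obesity"]]) / sum(st[mask])
  p_sm <- sum(st[mask & m$on[, "smoking"]]) / sum(st[mask])
  joint <- sum(st[mask & m$on[, "obesity"] & m$on[, "smoking"]]) / sum(st[mask])
  expect_equal(joint, p_ob * p_sm, tolerance = 1e-12)
})

test_that("configs survive a YAML round trip", {
  cfg <- t2d_config(seed = 3L, noise_sd = 0.25)
  f <- tempfile(fileext = ".yaml")
  write_config(cfg, f)
  cfg2 <- read_config(f)
  expect_equal(unclass(cfg2), unclass(cfg), tolerance = 1e-12)
  unlink(f)
})

test_that("population accounting closes against the demography-only projection", {
  # exact when there is no excess mortality; bounded in general
  p <- demo_seed_params()
  st <- demo_state()
  p0 <- p; p0$nu[] <- 0
  tr0 <- simulate_t2d(p0, st, 2016, 2040)
  dem <- project_population(demo_demog(), c(2030, 2040), bands = 1:16)
  expect_equal(sum(tr0$counts[15, ]), dem[["2030"]], tolerance = 1e-7)
  tr <- simulate_t2d(p, st, 2016, 2040)
  for (i in c(15, 25)) {
    tot <- sum(tr$counts[i, ])
    cd <- sum(tr$cum_deaths[i, ])
    dm <- dem[[as.character(tr$times[i])]]
    expect_lte(tot, dm * (1 + 1e-9))
    expect_gte(tot, (dm - cd) * (1 - 1e-9))
  }
})
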