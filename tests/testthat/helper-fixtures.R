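# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; no stored data.

.fx <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# default synthetic configuration and derived inputs
demo_cfg <- function() memo("cfg", t2d_config(seed = 1L))

demo_demog <- function() memo("demog", generate_demography(demo_cfg()))

demo_targets <- function()
  memo("targets", generate_targets(demo_cfg(), demo_demog()))

demo_state <- function()
  memo("state",
       generate_initial_state(demo_cfg(), demo_targets(), demo_demog()))

demo_seed_params <- function()
  memo("seed_params", default_params(demo_demog(), demo_targets(), demo_cfg()))

# the calibrated synthetic configuration used by scenario/outcome tests
demo_fit <- function()
  memo("fit", t2d_fit(demo_targets(), demo_demog(), initial = demo_state()))

demo_baseline <- function()
  memo("baseline",
       run_scenario(demo_fit()$params, demo_state(), NULL))

# scenario trajectories, memoised by name so ordering and tracking tests
# share runs
demo_scenario <- function(spec) {
  memo(paste0("scen_", spec$name),
       run_scenario(demo_fit()$params, demo_state(), spec))
}

# a drift-free world: flat risk-factor age gradients, stationary demography,
# no excess mortality -- aggregate risk-factor prevalence is constant in time
flat_setup <- function() {
  memo("flat", {
    cfg <- t2d_config(age_gradients = list(
      obesity = list(mid = 30, steep = 0),
      smoking = list(mid = 35, steep = 0),
      inactivity = list(mid = 38, steep = 0),
      t2dm = list(mid = 48, steep = 0.13)))
    demog <- generate_demography(cfg)
    mu <- demog$mu
    pyr <- matrix(0, 16, 2)
    pyr[1, ] <- demog$entry0 / (0.2 + mu[1, ])
    for (a in 2:15) pyr[a, ] <- 0.2 * pyr[a - 1, ] / (0.2 + mu[a, ])
    pyr[16, ] <- 0.2 * pyr[15, ] / mu[16, ]
    demog$pyramid <- pyr
    demog$entry_growth <- 0
    targets <- generate_targets(cfg, demog)
    st <- generate_initial_state(cfg, targets, demog)
    p <- default_params(demog, targets, cfg)
    p$nu[] <- 0
    list(cfg = cfg, demog = demog, targets = targets, state = st, params = p)
  })
}

# small fabricated trajectory with prescribed adult case/population counts
# and a prescribed annual death increment; exercises the outcome accessors
# on exactly known numbers
fake_trajectory <- function(cases, population, annual_deaths = 0,
                            years = c(2016, 2017)) {
  n <- length(years)
  counts <- matrix(0, n, 768)
  i_sus <- stratum_index("female", "30-34")
  i_t2d <- stratum_index("female", "30-34", disease = "t2dm")
  counts[, i_sus] <- population - cases
  counts[, i_t2d] <- cases
  cc <- matrix(0, n, 32)
  cd <- matrix(0, n, 32)
  # all flow lives in the (female, 30-34) cell, inside the 15-64 window
  cd[, 7] <- (seq_len(n) - 1) * annual_deaths
  colnames(cc) <- colnames(cd) <- t2dprev:::sa_labels()
  structure(list(times = years, counts = counts, cum_cases = cc,
                 cum_deaths = cd, params = NULL, forcing = NULL,
                 control_log = NULL), class = "t2d_trajectory")
}
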