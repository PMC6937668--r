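# Synthetic Qatar-like inputs: a young, rapidly ageing national population,
# 2016 risk-factor and T2DM prevalence targets with configurable age
# gradients and sex ratios, and the 2016 compartment occupancy. Everything
# every other module consumes can be generated here, reproducibly, with no
# external data.

#' Configuration of the synthetic study population
#'
#' Defaults encode the study conditions: a 15-64 population of 144,066 in
#' 2016 growing to 221,627 by 2050 (201,499 in 2031), 2016 aggregate
#' prevalences of 41.4% (obesity), 16.2% (smoking), 46.0% (physical
#' inactivity) and 16.7% (T2DM), and a 2016 T2DM case-fatality rate of 8.6
#' per 1000 person-years. Age gradients are logistic in age (midpoint in
#' years, steepness /year); sex ratios are female:male prevalence ratios.
#'
#' @param seed integer seed for any noisy generation (mandatory).
#' @param pop_15_64_2016,pop_15_64_2031,pop_15_64_2050 population anchors,
#'   persons.
#' @param prev_2016 named vector of 2016 aggregate risk-factor prevalences.
#' @param t2dm_prev_2016 2016 aggregate T2DM prevalence.
#' @param cfr_2016 2016 T2DM case-fatality rate, deaths per prevalent case
#'   per year.
#' @param age_gradients per-quantity logistic parameters
#'   \code{list(mid=, steep=)}.
#' @param sex_ratio female:male odds ratios per quantity.
#' @param pyramid age-pyramid shape: band weights decay as
#'   \code{exp(-0.5 (age / scale)^2)}, a broad young base thinning with age.
#' @param mortality Gompertz background mortality: hazard
#'   \code{m0 * exp(slope * age)}, females scaled by \code{female_mult}.
#' @param rho_priors fixed cessation/remission hazards per factor, /year.
#' @param male_frac male share of demographic entries.
#' @param target_years years at which calibration targets are laid down
#'   (age-specific prevalences are held constant across them, the baseline
#'   assumption).
#' @param noise_sd Gaussian noise added to prevalence targets, percentage
#'   points (0 = noiseless).
#' @return A \code{t2d_config} object.
#' @export
t2d_config <- function(seed = 1L,
                       pop_15_64_2016 = 144066,
                       pop_15_64_2031 = 201499,
                       pop_15_64_2050 = 221627,
                       prev_2016 = c(obesity = 0.414, smoking = 0.162,
                                     inactivity = 0.460),
                       t2dm_prev_2016 = 0.167,
                       cfr_2016 = 0.0086,
                       age_gradients = list(
                         obesity = list(mid = 30, steep = 0.08),
                         smoking = list(mid = 35, steep = 0.05),
                         inactivity = list(mid = 38, steep = 0.06),
                         t2dm = list(mid = 48, steep = 0.13)),
                       sex_ratio = c(obesity = 1.25, smoking = 0.08,
                                     inactivity = 1.3, t2dm = 1.0),
                       pyramid = list(scale = 32),
                       mortality = list(m0 = 4e-4, slope = 0.075,
                                        female_mult = 0.85),
                       rho_priors = c(obesity = 0.02, smoking = 0.04,
                                      inactivity = 0.05),
                       male_frac = 0.512,
                       target_years = c(2016, 2019, 2026, 2036, 2046),
                       noise_sd = 0) {
  stopifnot(all(prev_2016 >= 0 & prev_2016 <= 1),
            t2dm_prev_2016 >= 0, t2dm_prev_2016 <= 1,
            pop_15_64_2016 > 0, pop_15_64_2050 > 0,
            noise_sd >= 0)
  if (noise_sd > 0 && (is.null(seed) || is.na(seed)))
    stop("a seed is mandatory for noisy target generation")
  structure(list(seed = as.integer(seed),
                 pop_15_64_2016 = pop_15_64_2016,
                 pop_15_64_2031 = pop_15_64_2031,
                 pop_15_64_2050 = pop_15_64_2050,
                 prev_2016 = prev_2016[FACTORS],
                 t2dm_prev_2016 = t2dm_prev_2016,
                 cfr_2016 = cfr_2016,
                 age_gradients = age_gradients,
                 sex_ratio = sex_ratio,
                 pyramid = pyramid, mortality = mortality,
                 rho_priors = rho_priors, male_frac = male_frac,
                 target_years = target_years, noise_sd = noise_sd),
            class = "t2d_config")
}

#' Read/write a synthetic configuration
#' @param cfg a \code{t2d_config}.
#' @param file YAML path.
#' @export
write_config <- function(cfg, file) {
  x <- unclass(cfg)
  # yaml drops names of atomic vectors; store them as maps
  for (nm in c("prev_2016", "sex_ratio", "rho_priors"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, file, precision = 15)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  x <- yaml::read_yaml(file)
  do.call(t2d_config, list(
    seed = x$seed, pop_15_64_2016 = x$pop_15_64_2016,
    pop_15_64_2031 = x$pop_15_64_2031, pop_15_64_2050 = x$pop_15_64_2050,
    prev_2016 = unlist(x$prev_2016), t2dm_prev_2016 = x$t2dm_prev_2016,
    cfr_2016 = x$cfr_2016, age_gradients = x$age_gradients,
    sex_ratio = unlist(x$sex_ratio), pyramid = x$pyramid,
    mortality = x$mortality, rho_priors = unlist(x$rho_priors),
    male_frac = x$male_frac, target_years = unlist(x$target_years),
    noise_sd = x$noise_sd))
}

# Demography-only dynamics: entry + aging + background mortality on the
# 16 x 2 (age, sex) grid. Used to solve the entry growth rate and to audit
# the full model's population total.
demography_rhs <- function(mu, entry0, g, t_ref) {
  arate <- c(rep(0.2, N_AGE - 1L), 0)
  function(t, y, parms) {
    N <- matrix(y, N_AGE, 2L)
    ag <- arate * N
    d <- -mu * N - ag
    d[2:N_AGE, ] <- d[2:N_AGE, ] + ag[1:(N_AGE - 1L), ]
    d[1, ] <- d[1, ] + entry0 * exp(g * (t - t_ref))
    list(as.vector(d))
  }
}

#' Project the demography-only population
#'
#' Integrates entry, aging and background mortality (no disease) from the
#' 2016 pyramid and returns the 15-64 total at each requested year.
#'
#' @param demog a \code{t2d_demography} from [generate_demography()].
#' @param years calendar years (>= 2016).
#' @param bands age-band indices to total (default 15-64).
#' @return Named numeric vector of person totals.
#' @export
project_population <- function(demog, years = c(2016, 2031, 2050),
                               bands = ADULT_BANDS) {
  f <- demography_rhs(demog$mu, demog$entry0, demog$entry_growth, demog$t_ref)
  tt <- sort(unique(c(demog$t_ref, years)))
  sol <- deSolve::ode(as.vector(demog$pyramid), tt, f, NULL,
                      method = "lsoda", rtol = 1e-10, atol = 1e-8)
  tot <- apply(sol[, -1, drop = FALSE], 1, function(y)
    sum(matrix(y, N_AGE, 2L)[bands, ]))
  stats::setNames(tot[match(years, tt)], years)
}

#' Generate the synthetic demography
#'
#' Builds a young age/sex pyramid (lognormal in age, median under 30) scaled
#' so the 2016 15-64 total matches the configured anchor, a Gompertz
#' background-mortality schedule increasing with age, and an exponentially
#' growing entry flow whose growth rate is solved so the demography-only
#' projection hits the 2050 15-64 anchor. Errors if no growth rate in
#' [-0.15, 0.15]/yr can reconcile the two anchors under zero migration.
#'
#' @param cfg a \code{t2d_config}.
#' @return A \code{t2d_demography}: list with \code{pyramid} (16 x 2 counts,
#'   2016), \code{mu} (16 x 2 hazards), \code{entry0}, \code{entry_growth},
#'   \code{t_ref}.
#' @export
generate_demography <- function(cfg) {
  w <- exp(-0.5 * (AGE_MID / cfg$pyramid$scale)^2)
  w <- w / sum(w)
  pyramid <- cbind(female = w * (1 - cfg$male_frac), male = w * cfg$male_frac)
  scale <- cfg$pop_15_64_2016 / sum(pyramid[ADULT_BANDS, ])
  pyramid <- pyramid * scale
  mu <- cbind(female = cfg$mortality$m0 * cfg$mortality$female_mult *
                exp(cfg$mortality$slope * AGE_MID),
              male = cfg$mortality$m0 * exp(cfg$mortality$slope * AGE_MID))
  entry0 <- pyramid[1, ] * (0.2 + mu[1, ])
  d0 <- list(pyramid = pyramid, mu = mu, entry0 = entry0,
             entry_growth = 0, t_ref = 2016)
  class(d0) <- "t2d_demography"
  gap <- function(g) {
    d0$entry_growth <- g
    unname(project_population(d0, 2050)) - cfg$pop_15_64_2050
  }
  lo <- gap(-0.15); hi <- gap(0.15)
  if (sign(lo) == sign(hi))
    stop("infeasible population anchors: no entry growth rate in ",
         "[-0.15, 0.15]/yr reaches the 2050 total under zero migration")
  g <- stats::uniroot(gap, c(-0.15, 0.15), tol = 1e-10)$root
  d0$entry_growth <- g
  d0
}

#' @export
print.t2d_demography <- function(x, ...) {
  tot <- sum(x$pyramid[ADULT_BANDS, ])
  cat(sprintf("Synthetic demography: 15-64 total %.0f (%d), entry growth %.4f /yr\n",
              tot, x$t_ref, x$entry_growth))
  invisible(x)
}

# Logistic-in-age prevalence on the logit scale: p(a, sex) =
# plogis(alpha_sex + steep * (a - mid)), with the female intercept offset by
# log(sex ratio) (an odds ratio) and the common intercept solved so the
# pyramid-weighted 15-64 aggregate equals the configured value exactly.
# Returns a 16 x 2 matrix of band prevalences.
prevalence_curve <- function(target, grad, ratio, pyramid) {
  w <- pyramid[ADULT_BANDS, ]
  lin <- grad$steep * (AGE_MID - grad$mid)
  agg <- function(alpha) {
    pf <- stats::plogis(alpha + log(ratio) + lin)
    pm <- stats::plogis(alpha + lin)
    sum(w[, 1] * pf[ADULT_BANDS] + w[, 2] * pm[ADULT_BANDS]) / sum(w) - target
  }
  alpha <- stats::uniroot(agg, c(-30, 30), tol = 1e-14)$root
  out <- cbind(female = stats::plogis(alpha + log(ratio) + lin),
               male = stats::plogis(alpha + lin))
  if (any(out > 0.98))
    stop("configured gradient/sex ratio pushes a band prevalence above 0.98")
  out
}

#' Generate sex- and age-specific calibration targets
#'
#' Lays down prevalence targets for T2DM, obesity, smoking and physical
#' inactivity per sex and 5-year band (15-19 ... 60-64) whose
#' pyramid-weighted 15-64 aggregates equal the configured 2016 values
#' exactly (noiselessly) or in expectation (with seeded Gaussian noise).
#' Age-specific values are repeated across the configured target years,
#' encoding the baseline assumption of constant age-specific prevalence.
#' Population anchors (2016/2031/2050) and the 2016 case-fatality rate are
#' appended as additional target rows.
#'
#' @param cfg a \code{t2d_config}.
#' @param demog a \code{t2d_demography}; generated from \code{cfg} if NULL.
#' @return A \code{t2d_targets} data frame with columns \code{quantity},
#'   \code{sex}, \code{age_band}, \code{year}, \code{value}, \code{weight};
#'   attributes \code{cfg}, \code{demog} and \code{curves} (full 16-band
#'   prevalence matrices used to build initial states).
#' @export
generate_targets <- function(cfg, demog = NULL) {
  if (is.null(demog)) demog <- generate_demography(cfg)
  qty <- c(FACTORS, "t2dm")
  agg <- c(cfg$prev_2016, t2dm = cfg$t2dm_prev_2016)
  curves <- lapply(stats::setNames(qty, qty), function(q)
    prevalence_curve(agg[[q]], cfg$age_gradients[[q]], cfg$sex_ratio[[q]],
                     demog$pyramid))
  rows <- list()
  for (q in qty) for (s in 1:2) {
    rows[[length(rows) + 1L]] <- data.frame(
      quantity = q, sex = SEXES[s],
      age_band = rep(AGE_BANDS[ADULT_BANDS], times = length(cfg$target_years)),
      year = rep(cfg$target_years, each = length(ADULT_BANDS)),
      value = rep(curves[[q]][ADULT_BANDS, s], times = length(cfg$target_years)),
      weight = 1)
  }
  tg <- do.call(rbind, rows)
  if (cfg$noise_sd > 0) {
    set.seed(cfg$seed)
    tg$value <- pmin(pmax(
      tg$value + stats::rnorm(nrow(tg), 0, cfg$noise_sd / 100), 0), 1)
  }
  extra <- data.frame(
    quantity = c(rep("population", 3), "cfr"),
    sex = "all", age_band = "15-64",
    year = c(2016, 2031, 2050, 2016),
    value = c(cfg$pop_15_64_2016, cfg$pop_15_64_2031, cfg$pop_15_64_2050,
              cfg$cfr_2016),
    weight = 1)
  tg <- rbind(tg, extra)
  rownames(tg) <- NULL
  attr(tg, "cfg") <- cfg
  attr(tg, "demog") <- demog
  attr(tg, "curves") <- curves
  class(tg) <- c("t2d_targets", "data.frame")
  tg
}

#' Targets CSV round trip
#'
#' @param targets a \code{t2d_targets} data frame.
#' @param file CSV path (columns quantity, sex, age_band, year, value,
#'   weight).
#' @export
write_targets <- function(targets, file) {
  utils::write.csv(as.data.frame(unclass(targets))[
    , c("quantity", "sex", "age_band", "year", "value", "weight")],
    file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_targets
#' @export
read_targets <- function(file) {
  tg <- utils::read.csv(file, stringsAsFactors = FALSE, comment.char = "#")
  class(tg) <- c("t2d_targets", "data.frame")
  tg
}

#' Build the 2016 compartment occupancy
#'
#' Distributes the demographic pyramid over the 768 compartments so that the
#' T2DM and per-factor prevalences of every sex/age band match the 2016
#' targets exactly (bands outside the target range follow the generator's
#' full age curves), with risk-factor combinations filled by within-stratum
#' independence and all PA-intervention compartments empty.
#'
#' @param cfg a \code{t2d_config}.
#' @param targets a \code{t2d_targets} from [generate_targets()].
#' @param demog a \code{t2d_demography}; taken from the targets if NULL.
#' @return Numeric vector of 768 compartment counts (persons).
#' @export
generate_initial_state <- function(cfg, targets, demog = NULL) {
  if (is.null(demog)) demog <- attr(targets, "demog")
  curves <- attr(targets, "curves")
  if (is.null(curves))
    stop("targets lack generator curves; rebuild with generate_targets()")
  # overwrite curve values with (possibly noisy) 2016 target rows
  t16 <- targets[targets$year == 2016 & targets$sex %in% SEXES, ]
  for (r in seq_len(nrow(t16))) {
    ia <- match(t16$age_band[r], AGE_BANDS)
    is <- match(t16$sex[r], SEXES)
    curves[[t16$quantity[r]]][ia, is] <- t16$value[r]
  }
  if (any(unlist(curves) < 0 | unlist(curves) > 1))
    stop("target prevalences imply negative occupancies")
  N <- numeric(N_STRATA)
  for (is in 1:2) for (ia in 1:N_AGE) {
    n <- demog$pyramid[ia, is]
    pk <- vapply(FACTORS, function(q) curves[[q]][ia, is], numeric(1))
    pi_d <- curves[["t2dm"]][ia, is]
    for (ob in 0:1) for (sm in 0:1) for (inac in 0:1) {
      frac <- (if (ob) pk[1] else 1 - pk[1]) *
        (if (sm) pk[2] else 1 - pk[2]) *
        (if (inac) pk[3] else 1 - pk[3])
      i_sus <- stratum_index(SEXES[is], AGE_BANDS[ia], ob == 1, sm == 1,
                             inac == 1, "susceptible", "none")
      N[i_sus] <- n * frac * (1 - pi_d)
      N[i_sus + 2L] <- n * frac * pi_d
    }
  }
  N
}
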