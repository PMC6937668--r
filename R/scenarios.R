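# Intervention scenarios: declarative specs translated into time-dependent
# forcing of the model. Risk-factor scenarios prescribe an aggregate 15-64
# prevalence trajectory (linear ramp from the 2016 level to the target by the
# end of scale-up, then held); the PA scenario prescribes a linear coverage
# ramp. Targets are enforced by a per-step proportional feedback controller
# on the acquisition/cessation hazards of susceptible compartments.

#' Declare an intervention scenario
#'
#' @param name scenario label.
#' @param reductions named numeric vector with any of
#'   \code{obesity}, \code{smoking}, \code{inactivity}: the relative
#'   reduction F in [0, 1] of that factor's aggregate prevalence achieved by
#'   the end of scale-up (0 = halt at the 2016 level). Omitted factors are
#'   untargeted.
#' @param ramp_start,ramp_end scale-up window (default 2016-2031).
#' @param hold_until year through which the achieved level is maintained.
#' @param pa_intensity optional physical-activity intervention intensity
#'   ("vigorous", "low", "moderate", "leisure", "walking").
#' @param pa_coverage target PA coverage among 15-64 susceptibles by
#'   \code{ramp_end} (default 0.25).
#' @param target_ages two-element numeric, age range targeted (default
#'   c(15, 64), mapping to bands 15-19 ... 60-64).
#' @return A \code{t2d_scenario} object.
#' @export
scenario_spec <- function(name, reductions = numeric(0), ramp_start = 2016,
                          ramp_end = 2031, hold_until = 2050,
                          pa_intensity = NULL, pa_coverage = 0.25,
                          target_ages = c(15, 64)) {
  if (length(reductions)) {
    if (!all(names(reductions) %in% FACTORS))
      stop("reductions must be named by: ", paste(FACTORS, collapse = ", "))
    if (any(reductions < 0 | reductions > 1))
      stop("relative reductions must lie in [0, 1]")
  }
  if (!(ramp_start < ramp_end && ramp_end <= hold_until))
    stop("need ramp_start < ramp_end <= hold_until")
  if (pa_coverage < 0 || pa_coverage > 1)
    stop("pa_coverage must lie in [0, 1]")
  if (!is.null(pa_intensity)) pa_relative_risk(pa_intensity)  # validates
  bands <- which(AGE_LOW >= target_ages[1] & AGE_LOW + 4 <= target_ages[2])
  structure(list(name = name, reductions = reductions,
                 ramp_start = ramp_start, ramp_end = ramp_end,
                 hold_until = hold_until, pa_intensity = pa_intensity,
                 pa_coverage = pa_coverage, target_bands = bands),
            class = "t2d_scenario")
}

#' @export
print.t2d_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  if (length(x$reductions))
    cat("  reductions:", paste(sprintf("%s %.0f%%", names(x$reductions),
                                       100 * x$reductions), collapse = ", "),
        "\n")
  if (!is.null(x$pa_intensity))
    cat(sprintf("  PA intervention: %s (RR %.2f), coverage %.0f%%\n",
                x$pa_intensity, pa_relative_risk(x$pa_intensity),
                100 * x$pa_coverage))
  cat(sprintf("  scale-up %d-%d, hold to %d\n", x$ramp_start, x$ramp_end,
              x$hold_until))
  invisible(x)
}

#' Linear prevalence-target ramp
#'
#' Target prevalence trajectory of a risk factor under a relative reduction
#' F: constant at the 2016 level before \code{ramp_start}, decreasing
#' linearly to \code{p0 * (1 - F)} at \code{ramp_end}, constant thereafter.
#'
#' @param p0 baseline prevalence (fraction in [0, 1]).
#' @param F relative reduction in [0, 1] (0 = halt).
#' @param t calendar year(s).
#' @param ramp_start,ramp_end scale-up window.
#' @return Target prevalence fraction(s).
#' @examples
#' ramp_target(0.414, 0.5, 2031)  # 0.207
#' @export
ramp_target <- function(p0, F, t, ramp_start = 2016, ramp_end = 2031) {
  stopifnot(p0 >= 0, p0 <= 1, F >= 0, F <= 1)
  frac <- pmin(pmax((t - ramp_start) / (ramp_end - ramp_start), 0), 1)
  p0 * (1 - F * frac)
}

#' Instantiate the time-dependent forcing of a scenario
#'
#' Turns a declarative scenario into the forcing consumed by
#' [simulate_t2d()]: one prevalence-target function per targeted risk factor
#' (anchored at the supplied baseline 2016 aggregate prevalences) and, if a
#' PA intervention is declared, a linear coverage ramp with its
#' intensity-specific relative risk. Untargeted factors carry no forcing.
#'
#' @param spec a \code{t2d_scenario}.
#' @param baseline_2016 named vector of 2016 aggregate 15-64 prevalences
#'   (fractions) for the targeted factors.
#' @param denominator "all" (default) to enforce targets on whole-population
#'   prevalence, or "susceptible" to use diabetes-free denominators.
#' @return A \code{t2d_forcing} object.
#' @export
build_forcing <- function(spec, baseline_2016, denominator = c("all", "susceptible")) {
  denominator <- match.arg(denominator)
  factors <- list()
  for (k in names(spec$reductions)) {
    p0 <- baseline_2016[[k]]
    if (is.null(p0) || is.na(p0)) stop("baseline_2016 lacks factor ", k)
    stopifnot(p0 >= 0, p0 <= 1)
    factors[[k]] <- list(p0 = p0, F = unname(spec$reductions[[k]]),
                         ramp_start = spec$ramp_start,
                         ramp_end = spec$ramp_end,
                         hold_until = spec$hold_until)
  }
  pa <- NULL
  if (!is.null(spec$pa_intensity)) {
    pa <- list(intensity = spec$pa_intensity,
               rr = pa_relative_risk(spec$pa_intensity),
               coverage = spec$pa_coverage,
               ramp_start = spec$ramp_start, ramp_end = spec$ramp_end)
  }
  structure(list(name = spec$name, factors = factors, pa = pa,
                 target_bands = spec$target_bands,
                 denominator = denominator),
            class = "t2d_forcing")
}

factor_target_at <- function(f, t) ramp_target(f$p0, f$F, t, f$ramp_start, f$ramp_end)

pa_coverage_at <- function(pa, t) {
  frac <- pmin(pmax((t - pa$ramp_start) / (pa$ramp_end - pa$ramp_start), 0), 1)
  pa$coverage * frac
}

# One controller step: closed-form proportional correction of the
# acquisition/cessation hazards so the aggregate prevalence of each targeted
# factor moves to its target at the end of the step. With acquisition scaled
# by 1/x and cessation by x, the required x solves C x^2 + B x - A = 0 where
# A and C are the current acquisition/cessation flows (persons/yr) among
# targeted susceptibles and B absorbs the baseline drift; x is clamped to
# [0.1, 10] so both multipliers stay within [0, 10].
controller_step <- function(N, ts, te, params, forcing, base_rhs, target_bands) {
  m <- stratum_maps()
  dt <- te - ts
  d0 <- base_rhs(ts, c(N, numeric(64L)), NULL)[[1]][1:N_STRATA]
  in_band <- m$age_i %in% target_bands
  den_all <- forcing$denominator != "susceptible"
  mask_den <- if (den_all) in_band else in_band & m$st < 3L
  Ntot <- sum(N[mask_den]); dden <- sum(d0[mask_den])

  mult_eta <- c(1, 1, 1); mult_rho <- c(1, 1, 1)
  logs <- list()
  for (k in names(forcing$factors)) {
    j <- match(k, FACTORS)
    f <- forcing$factors[[k]]
    mask_num <- mask_den & m$on[, k]
    P <- sum(N[mask_num]) / Ntot
    dP0 <- (sum(d0[mask_num]) - P * dden) / Ntot
    req <- (factor_target_at(f, te) - P) / dt
    ck <- req - dP0
    act <- m$st < 3L & in_band
    ev <- as.vector(params$eta[[k]])[m$sa]
    rv <- as.vector(params$rho[[k]])[m$sa]
    A <- sum(ev[act & !m$on[, k]] * N[act & !m$on[, k]])
    C <- sum(rv[act & m$on[, k]] * N[act & m$on[, k]])
    B <- ck * Ntot + A - C
    x <- if (C > 1e-12) (-B + sqrt(B^2 + 4 * A * C)) / (2 * C)
         else if (B > 1e-12) A / B else 10
    x <- min(max(x, 0.1), 10)
    mult_eta[j] <- 1 / x
    mult_rho[j] <- x
    logs[[k]] <- data.frame(time = te, factor = k,
                            target = factor_target_at(f, te),
                            mult_eta = 1 / x, mult_rho = x)
  }

  pa_rate <- 0
  if (!is.null(forcing$pa)) {
    sus <- m$st < 3L & in_band
    is1 <- m$st == 1L & in_band
    is2 <- m$st == 2L & in_band
    Stot <- sum(N[sus]); S1 <- sum(N[is1])
    cov <- sum(N[is2]) / Stot
    dcov0 <- (sum(d0[is2]) - cov * sum(d0[sus])) / Stot
    req <- (pa_coverage_at(forcing$pa, te) - cov) / dt
    if (S1 > 0) pa_rate <- min(max((req - dcov0) * Stot / S1, 0), 10)
  }
  list(mult_eta = mult_eta, mult_rho = mult_rho, pa_rate = pa_rate,
       log = if (length(logs)) do.call(rbind, logs) else NULL)
}

# Post-run audit: warn when a targeted prevalence trajectory was not tracked
# within 0.2 percentage points at some reporting year (e.g. because the
# multiplier bounds saturated).
check_tracking <- function(traj, forcing) {
  if (is.null(forcing) || !length(forcing$factors)) return(invisible(NULL))
  for (k in names(forcing$factors)) {
    f <- forcing$factors[[k]]
    ach <- vapply(traj$times, function(y)
      risk_prevalence(traj, k, y,
                      denominator = forcing$denominator,
                      bands = forcing$target_bands), numeric(1))
    tgtv <- factor_target_at(f, traj$times)
    err <- max(abs(ach - tgtv))
    if (err > 0.002)
      warning(sprintf(
        "scenario '%s': %s prevalence deviates from target by up to %.2f pp",
        forcing$name, k, 100 * err), call. = FALSE)
  }
  invisible(NULL)
}

#' Scale-up-duration variants of a scenario
#'
#' Clones a scenario with scale-up durations of the given lengths
#' (\code{ramp_end = ramp_start + duration}), holding everything else fixed.
#'
#' @param spec a \code{t2d_scenario}.
#' @param durations vector of positive scale-up durations, years.
#' @return A named list of \code{t2d_scenario} objects.
#' @export
scale_up_variants <- function(spec, durations = c(5, 10, 15, 20)) {
  if (any(durations <= 0)) stop("durations must be positive")
  out <- lapply(durations, function(d) {
    if (spec$ramp_start + d > spec$hold_until)
      stop("duration ", d, " pushes scale-up past the hold horizon")
    s <- spec
    s$ramp_end <- spec$ramp_start + d
    s$name <- sprintf("%s_scaleup_%dy", spec$name, d)
    s
  })
  stats::setNames(out, vapply(out, `[[`, "", "name"))
}

#' Bundled scenario library
#'
#' The full set of modelled interventions: the WHO Global Action Plan for
#' NCDs combination (halt obesity, reduce smoking by 30% and physical
#' inactivity by 10%), per-factor halt and 10-50% relative reductions,
#' the simultaneous 50% reduction of all three factors, the five
#' physical-activity intensities at 25% coverage, and the combined
#' 50%-reduction-plus-vigorous-PA scenario. All use the default 2016-2031
#' scale-up held to 2050.
#'
#' @return A named list of \code{t2d_scenario} objects.
#' @export
scenario_library <- function() {
  lib <- list(
    who_gap = scenario_spec("who_gap",
      reductions = c(obesity = 0, smoking = 0.3, inactivity = 0.1))
  )
  for (k in FACTORS) {
    lib[[paste0(k, "_halt")]] <-
      scenario_spec(paste0(k, "_halt"), reductions = stats::setNames(0, k))
    for (F in seq(0.1, 0.5, 0.1)) {
      nm <- sprintf("%s_minus_%d", k, round(100 * F))
      lib[[nm]] <- scenario_spec(nm, reductions = stats::setNames(F, k))
    }
  }
  lib$combined_minus_50 <- scenario_spec("combined_minus_50",
    reductions = c(obesity = 0.5, smoking = 0.5, inactivity = 0.5))
  for (it in c("vigorous", "low", "moderate", "leisure", "walking")) {
    nm <- paste0("pa_", it)
    lib[[nm]] <- scenario_spec(nm, pa_intensity = it)
  }
  lib$combined_minus_50_pa_vigorous <- scenario_spec(
    "combined_minus_50_pa_vigorous",
    reductions = c(obesity = 0.5, smoking = 0.5, inactivity = 0.5),
    pa_intensity = "vigorous")
  lib
}

#' Run a single scenario from a calibrated model
#'
#' Builds the scenario's forcing from the 2016 aggregate prevalences implied
#' by the initial state and integrates the model over the observation
#' period.
#'
#' @param params a \code{t2d_params} object (e.g. from a fitted model).
#' @param initial 2016 compartment counts.
#' @param spec a \code{t2d_scenario}, or NULL for the no-intervention
#'   baseline.
#' @param t0,t1 observation window.
#' @param ... passed to [simulate_t2d()].
#' @return A \code{t2d_trajectory}.
#' @export
run_scenario <- function(params, initial, spec = NULL, t0 = 2016, t1 = 2050,
                         ...) {
  if (is.null(spec)) return(simulate_t2d(params, initial, t0, t1, ...))
  base <- state_prevalences(initial, bands = spec$target_bands)
  forcing <- build_forcing(spec, base)
  simulate_t2d(params, initial, t0, t1, forcing = forcing, ...)
}

# Aggregate prevalences (risk factors and T2DM) of a raw state vector.
state_prevalences <- function(N, bands = ADULT_BANDS, denominator = "all") {
  m <- stratum_maps()
  mask <- m$age_i %in% bands
  if (denominator == "susceptible") mask <- mask & m$st < 3L
  tot <- sum(N[mask])
  out <- vapply(FACTORS, function(k) sum(N[mask & m$on[, k]]) / tot, numeric(1))
  c(out, t2dm = sum(N[mask & m$st == 3L]) / tot)
}
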