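# Outcome measures: prevalence series, cumulative incident cases and
# T2DM-related deaths, averted burden against a counterfactual baseline,
# relative prevalence reductions, and case-fatality rates.

time_row <- function(traj, year) {
  i <- which(abs(traj$times - year) < 1e-9)
  if (!length(i))
    stop("year ", year, " is not on the trajectory's reporting grid")
  i[1]
}

band_cols <- function(bands) {
  # columns of the 32-wide (sex, age) flow matrices for the given bands
  c(bands, 16L + bands)
}

#' T2DM prevalence at a reporting year
#'
#' Prevalent T2DM cases divided by total population over the age range,
#' both sexes combined.
#'
#' @param traj a \code{t2d_trajectory}.
#' @param year reporting year (must be on the grid).
#' @param bands age-band indices (default 15-64, i.e. bands 15-19 ... 60-64).
#' @return Prevalence as a fraction.
#' @export
prevalence <- function(traj, year, bands = ADULT_BANDS) {
  m <- stratum_maps()
  N <- traj$counts[time_row(traj, year), ]
  mask <- m$age_i %in% bands
  sum(N[mask & m$st == 3L]) / sum(N[mask])
}

#' Aggregate risk-factor prevalence at a reporting year
#'
#' @param traj a \code{t2d_trajectory}.
#' @param factor "obesity", "smoking" or "inactivity".
#' @param year reporting year.
#' @param denominator "all" (whole population) or "susceptible".
#' @param bands age-band indices (default 15-64).
#' @return Prevalence as a fraction.
#' @export
risk_prevalence <- function(traj, factor, year, denominator = "all",
                            bands = ADULT_BANDS) {
  factor <- match.arg(factor, FACTORS)
  m <- stratum_maps()
  N <- traj$counts[time_row(traj, year), ]
  mask <- m$age_i %in% bands
  if (identical(denominator, "susceptible")) mask <- mask & m$st < 3L
  sum(N[mask & m$on[, factor]]) / sum(N[mask])
}

#' Prevalent T2DM case count and population total
#'
#' @inheritParams prevalence
#' @return Named vector with \code{cases} and \code{population} (persons).
#' @export
case_counts <- function(traj, year, bands = ADULT_BANDS) {
  m <- stratum_maps()
  N <- traj$counts[time_row(traj, year), ]
  mask <- m$age_i %in% bands
  c(cases = sum(N[mask & m$st == 3L]), population = sum(N[mask]))
}

cumulative_flow <- function(traj, what, year, bands = ADULT_BANDS) {
  M <- if (what == "cases") traj$cum_cases else traj$cum_deaths
  sum(M[time_row(traj, year), band_cols(bands)])
}

check_paired <- function(baseline, scen) {
  if (!isTRUE(all.equal(baseline$times, scen$times)))
    stop("trajectories have mismatched reporting grids")
  if (max(abs(baseline$counts[1, ] - scen$counts[1, ])) > 1e-6)
    stop("trajectories do not share an initial state")
}

averted <- function(baseline, scen, window, what, bands) {
  check_paired(baseline, scen)
  cum <- function(traj) {
    cumulative_flow(traj, what, window[2], bands) -
      cumulative_flow(traj, what, window[1], bands)
  }
  b <- cum(baseline)
  count <- b - cum(scen)
  list(count = count, proportion = count / b)
}

#' T2DM cases averted by an intervention
#'
#' Difference in cumulative incident T2DM cases between the baseline and the
#' scenario trajectory over a window, and that difference as a proportion of
#' the baseline's cumulative incidence. Incident cases are integrals of the
#' incidence flow, so deaths and aging cannot masquerade as prevention.
#'
#' @param baseline,scen \code{t2d_trajectory} objects sharing grid and
#'   initial state.
#' @param window two-element year vector, default c(2016, 2050).
#' @param bands age-band indices (default 15-64).
#' @return List with \code{count} (persons) and \code{proportion}.
#' @export
cases_averted <- function(baseline, scen, window = c(2016, 2050),
                          bands = ADULT_BANDS) {
  averted(baseline, scen, window, "cases", bands)
}

#' T2DM-related deaths averted by an intervention
#'
#' As [cases_averted()], applied to the cumulative T2DM-related
#' excess-death flow.
#'
#' @inheritParams cases_averted
#' @export
deaths_averted <- function(baseline, scen, window = c(2016, 2050),
                           bands = ADULT_BANDS) {
  averted(baseline, scen, window, "deaths", bands)
}

#' Relative reduction of a prevalence
#'
#' \code{(p_base - p_scen) / p_base}, computed on unrounded prevalences.
#'
#' @param p_base baseline prevalence (> 0).
#' @param p_scen scenario prevalence.
#' @return Fractional reduction.
#' @export
relative_reduction <- function(p_base, p_scen) {
  if (any(p_base <= 0)) stop("baseline prevalence must be positive")
  (p_base - p_scen) / p_base
}

#' Case-fatality rate of T2DM
#'
#' Annual T2DM-related deaths during the calendar year starting at
#' \code{year}, divided by mid-year prevalent T2DM cases (average of the two
#' bracketing grid points), per 1000 persons per year.
#'
#' @param traj a \code{t2d_trajectory} whose grid contains \code{year} and
#'   \code{year + 1}.
#' @param year calendar year.
#' @param bands age-band indices (default 15-64).
#' @return Deaths per 1000 prevalent cases per year.
#' @export
case_fatality_rate <- function(traj, year, bands = ADULT_BANDS) {
  d <- cumulative_flow(traj, "deaths", year + 1, bands) -
    cumulative_flow(traj, "deaths", year, bands)
  cases <- (case_counts(traj, year, bands)["cases"] +
              case_counts(traj, year + 1, bands)["cases"]) / 2
  if (cases <= 0) stop("no prevalent cases at year ", year)
  unname(1000 * d / cases)
}

# round half up at k decimals (report convention; R's round() is half-even)
round_half_up <- function(x, k = 1) floor(x * 10^k + 0.5) / 10^k

#' Scenario suite report
#'
#' Runs the no-intervention baseline plus every scenario in a library and
#' tabulates, per scenario: T2DM prevalence at the end of scale-up (2031)
#' and at 2050, the relative prevalence reduction against baseline, and the
#' number and proportion of T2DM cases and T2DM-related deaths averted over
#' the intermediate (2016-2031) and long-term (2016-2050) windows. A failing
#' scenario is marked failed with its diagnostic; the run continues.
#'
#' @param params a calibrated \code{t2d_params}.
#' @param initial 2016 compartment counts.
#' @param library named list of \code{t2d_scenario} objects (default
#'   [scenario_library()]).
#' @param t0,t1 observation window.
#' @param mid_year end of the intermediate window (default 2031).
#' @param ... passed to [simulate_t2d()].
#' @return A data frame with one row per scenario plus the baseline row;
#'   attribute \code{"trajectories"} holds the trajectory list.
#' @export
table1_report <- function(params, initial, library = scenario_library(),
                          t0 = 2016, t1 = 2050, mid_year = 2031, ...) {
  base <- run_scenario(params, initial, NULL, t0, t1, ...)
  p_base_mid <- prevalence(base, mid_year)
  p_base_end <- prevalence(base, t1)
  rows <- list(data.frame(
    scenario = "baseline", status = "ok",
    prev_mid = p_base_mid, rel_red_mid = 0,
    cases_averted_mid = 0, prop_cases_mid = 0,
    deaths_averted_mid = 0, prop_deaths_mid = 0,
    prev_end = p_base_end, rel_red_end = 0,
    cases_averted_end = 0, prop_cases_end = 0,
    deaths_averted_end = 0, prop_deaths_end = 0))
  trajs <- list(baseline = base)
  for (nm in names(library)) {
    row <- tryCatch({
      tr <- run_scenario(params, initial, library[[nm]], t0, t1, ...)
      trajs[[nm]] <- tr
      ca_m <- cases_averted(base, tr, c(t0, mid_year))
      da_m <- deaths_averted(base, tr, c(t0, mid_year))
      ca_e <- cases_averted(base, tr, c(t0, t1))
      da_e <- deaths_averted(base, tr, c(t0, t1))
      pm <- prevalence(tr, mid_year); pe <- prevalence(tr, t1)
      data.frame(
        scenario = nm, status = "ok",
        prev_mid = pm, rel_red_mid = relative_reduction(p_base_mid, pm),
        cases_averted_mid = ca_m$count, prop_cases_mid = ca_m$proportion,
        deaths_averted_mid = da_m$count, prop_deaths_mid = da_m$proportion,
        prev_end = pe, rel_red_end = relative_reduction(p_base_end, pe),
        cases_averted_end = ca_e$count, prop_cases_end = ca_e$proportion,
        deaths_averted_end = da_e$count, prop_deaths_end = da_e$proportion)
    }, error = function(e) {
      r <- rows[[1]][0, ]
      r[1, "scenario"] <- nm
      r[1, "status"] <- paste("failed:", conditionMessage(e))
      r
    })
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "trajectories") <- trajs
  out
}

#' Format a suite report for printing
#'
#' Rounds prevalences and proportions to one decimal per cent (half-up,
#' computed on unrounded values) and counts to whole persons.
#'
#' @param report output of [table1_report()].
#' @return A data frame of formatted columns.
#' @export
format_report <- function(report) {
  pc <- function(x) sprintf("%.1f%%", round_half_up(100 * x, 1))
  data.frame(
    scenario = report$scenario,
    prev_2031 = pc(report$prev_mid),
    rel_red_2031 = pc(report$rel_red_mid),
    cases_averted_2031 = round(report$cases_averted_mid),
    prop_cases_2031 = pc(report$prop_cases_mid),
    deaths_averted_2031 = round(report$deaths_averted_mid),
    prop_deaths_2031 = pc(report$prop_deaths_mid),
    prev_2050 = pc(report$prev_end),
    rel_red_2050 = pc(report$rel_red_end),
    cases_averted_2050 = round(report$cases_averted_end),
    prop_cases_2050 = pc(report$prop_cases_end),
    deaths_averted_2050 = round(report$deaths_averted_end),
    prop_deaths_2050 = pc(report$prop_deaths_end))
}
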