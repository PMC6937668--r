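# Deterministic dynamics of the stratified T2DM model.
#
# State vector: 768 compartment counts (persons) followed by 2 x 32
# cumulative-flow accumulators per (sex, age band): incident T2DM cases and
# T2DM-related excess deaths. All flows conserve persons between source and
# sink compartments except demographic entry (source outside) and the two
# mortality flows (sink outside).

sa_labels <- function() {
  as.vector(outer(AGE_BANDS, SEXES, function(a, s) paste(s, a, sep = ".")))
}

# Build the ODE right-hand side as a closure over precomputed per-compartment
# rate vectors. Controller multipliers (mult_eta, mult_rho, one per risk
# factor) and the PA recruitment rate act only on susceptible compartments in
# the scenario's target age bands.
make_rhs <- function(params, mult_eta = c(1, 1, 1), mult_rho = c(1, 1, 1),
                     pa_rate = 0, target_bands = ADULT_BANDS) {
  m <- stratum_maps()
  sus <- m$st < 3L
  tgt <- sus & (m$age_i %in% target_bands)
  mu_vec <- as.vector(params$mu)[m$sa]
  aging_vec <- params$aging_rate[m$age_i]
  nu_vec <- as.vector(params$nu)[m$sa] * (m$st == 3L)

  out_rate <- vector("list", 3L)
  for (j in seq_along(FACTORS)) {
    k <- FACTORS[j]
    ev <- as.vector(params$eta[[k]])[m$sa]
    rv <- as.vector(params$rho[[k]])[m$sa]
    me <- ifelse(tgt, mult_eta[j], 1)
    mr <- ifelse(tgt, mult_rho[j], 1)
    out_rate[[j]] <- ifelse(m$on[, k], rv * mr, ev * me)
  }

  rrp <- params$rr["obesity"]^m$on[, "obesity"] *
    params$rr["smoking"]^m$on[, "smoking"] *
    params$rr["inactivity"]^m$on[, "inactivity"]
  haz_sus <- as.vector(params$lambda0)[m$sa] * rrp
  haz1 <- haz_sus[m$i_sus1]
  haz2 <- haz_sus[m$i_sus2] * params$rr_pa
  pa_vec <- pa_rate * as.numeric((m$age_i %in% target_bands)[m$i_sus1])

  e0 <- params$entry0; g <- params$entry_growth; tr <- params$t_ref
  flip <- m$flip; i1 <- m$i_sus1; i2 <- m$i_sus2
  it1 <- m$t2dm_of_sus1; it2 <- m$t2dm_of_sus2; it <- m$i_t2dm
  isrc <- m$i_age_src; idst <- m$i_age_dst; ie <- m$entry_idx

  function(t, y, parms) {
    N <- y[1:N_STRATA]
    d <- -mu_vec * N
    ag <- aging_vec * N
    d <- d - ag
    d[idst] <- d[idst] + ag[isrc]
    for (j in 1:3) {
      f <- out_rate[[j]] * N
      d <- d - f
      d[flip[[j]]] <- d[flip[[j]]] + f
    }
    f1 <- haz1 * N[i1]
    f2 <- haz2 * N[i2]
    d[i1] <- d[i1] - f1
    d[i2] <- d[i2] - f2
    d[it1] <- d[it1] + f1
    d[it2] <- d[it2] + f2
    fd <- nu_vec * N
    d <- d - fd
    if (pa_rate > 0) {
      fr <- pa_vec * N[i1]
      d[i1] <- d[i1] - fr
      d[i2] <- d[i2] + fr
    }
    d[ie[1]] <- d[ie[1]] + e0[1] * exp(g * (t - tr))
    d[ie[2]] <- d[ie[2]] + e0[2] * exp(g * (t - tr))
    list(c(d,
           .colSums(f1 + f2, 8L, 32L),
           .colSums(fd[it], 8L, 32L)))
  }
}

#' Time-derivative of the compartment counts
#'
#' Evaluates the model's flow ledger at one instant: demographic entry into
#' the youngest band, aging between adjacent bands, background mortality,
#' per-factor risk acquisition and cessation, T2DM incidence under
#' multiplicative relative risks, T2DM-related excess mortality, and
#' (optionally) physical-activity-intervention recruitment.
#'
#' @param t calendar year.
#' @param counts numeric vector of 768 compartment counts in the canonical
#'   ordering of [enumerate_strata()].
#' @param params a \code{t2d_params} object.
#' @param mult_eta,mult_rho per-factor multipliers on acquisition/cessation
#'   hazards applied to susceptible compartments in \code{target_bands}.
#' @param pa_rate recruitment hazard (/year) from susceptible/no-intervention
#'   to susceptible/PA-active compartments in \code{target_bands}.
#' @param target_bands integer age-band indices targeted by interventions
#'   (default bands 15-19 ... 60-64).
#' @return A list with \code{counts} (derivative, persons/year),
#'   \code{cases} and \code{deaths} (incidence and excess-death flow rates
#'   per sex/age band, persons/year).
#' @export
model_derivative <- function(t, counts, params, mult_eta = c(1, 1, 1),
                             mult_rho = c(1, 1, 1), pa_rate = 0,
                             target_bands = ADULT_BANDS) {
  stopifnot(length(counts) == N_STRATA)
  f <- make_rhs(params, mult_eta, mult_rho, pa_rate, target_bands)
  d <- f(t, c(counts, numeric(64L)), NULL)[[1]]
  list(counts = d[1:N_STRATA],
       cases = stats::setNames(d[N_STRATA + 1:32], sa_labels()),
       deaths = stats::setNames(d[N_STRATA + 33:64], sa_labels()))
}

# Clamp tiny negative counts (solver noise) to zero; abort on anything below
# -neg_tol, naming the offending time and compartment.
guard_negative <- function(N, time, neg_tol = 1e-9) {
  worst <- min(N)
  if (worst < -neg_tol) {
    i <- which.min(N)
    s <- enumerate_strata()[i, ]
    stop(sprintf(
      "negative compartment count %.3e at year %.2f in (%s, %s, ob=%d sm=%d ia=%d, %s/%s)",
      worst, time, s$sex, s$age_band, s$obese, s$smoker, s$inactive,
      s$disease, s$intervention))
  }
  pmax(N, 0)
}

#' Integrate the compartmental model over time
#'
#' Numerically integrates the model's ODE system from an initial compartment
#' occupancy, simultaneously accumulating incident T2DM cases and
#' T2DM-related deaths per sex and age band. Under a scenario forcing the
#' integration proceeds in short control steps (default half a year): at the
#' start of each step a proportional feedback controller rescales
#' acquisition/cessation hazards of the targeted risk factors (susceptible
#' compartments in the target bands only) and sets the PA recruitment rate
#' so that aggregate prevalence and coverage track their target trajectories.
#'
#' The default solver is an adaptive explicit Runge-Kutta pair
#' (Dormand-Prince, \code{"ode45"}) with relative tolerance 1e-8 and absolute
#' tolerance 1e-10; \code{method = "rk4"} gives a fixed-step classical RK4
#' on steps of \code{rk4_dt} for cross-checking. Results are deterministic
#' given identical inputs.
#'
#' @param params a \code{t2d_params} object.
#' @param initial numeric vector of 768 nonnegative compartment counts.
#' @param t0,t1 start and end calendar years (t0 < t1).
#' @param forcing optional \code{t2d_forcing} from [build_forcing()]; NULL
#'   means the no-intervention baseline.
#' @param times reporting grid (default yearly from t0 to t1); under a
#'   forcing, must lie on the control grid.
#' @param method \code{"ode45"} (adaptive, default), \code{"rk4"}
#'   (fixed step), or any \code{deSolve} method name.
#' @param rtol,atol solver tolerances.
#' @param control_dt controller step, years.
#' @param rk4_dt fixed step for \code{method = "rk4"}, years.
#' @param neg_tol abort threshold for negative counts (persons).
#' @return A \code{t2d_trajectory}: list with \code{times}, \code{counts}
#'   (time x 768 matrix), \code{cum_cases} and \code{cum_deaths}
#'   (time x 32 matrices, persons), the \code{params} and \code{forcing}
#'   used, and a controller \code{control_log}.
#' @export
simulate_t2d <- function(params, initial, t0 = 2016, t1 = 2050, forcing = NULL,
                         times = NULL, method = "ode45", rtol = 1e-8,
                         atol = 1e-10, control_dt = 0.5, rk4_dt = 0.01,
                         neg_tol = 1e-9) {
  stopifnot(t0 < t1, length(initial) == N_STRATA)
  if (any(initial < 0)) stop("initial compartment counts must be nonnegative")
  if (is.null(times)) times <- seq(t0, t1, by = 1)
  stopifnot(min(times) >= t0, max(times) <= t1)

  active <- !is.null(forcing) &&
    (length(forcing$factors) > 0 || !is.null(forcing$pa))
  if (!active) {
    out <- run_segment(params, initial, sort(unique(c(t0, times, t1))),
                       method, rtol, atol, rk4_dt)
    return(new_trajectory(out, times, params, forcing, NULL, neg_tol))
  }

  grid <- seq(t0, t1, by = control_dt)
  if (abs(grid[length(grid)] - t1) > 1e-9)
    stop("control_dt must divide the horizon t1 - t0")
  if (!all(vapply(times, function(tt) any(abs(grid - tt) < 1e-9), logical(1))))
    stop("reporting times must lie on the controller grid")

  tb <- if (!is.null(forcing$target_bands)) forcing$target_bands else ADULT_BANDS
  y <- c(initial, numeric(64L))
  keep <- matrix(NA_real_, nrow = length(grid), ncol = N_STATE)
  keep[1, ] <- y
  log_rows <- list()
  base_rhs <- make_rhs(params, target_bands = tb)
  pa_params <- params
  if (!is.null(forcing$pa)) pa_params$rr_pa <- forcing$pa$rr

  for (s in seq_len(length(grid) - 1L)) {
    ts <- grid[s]; te <- grid[s + 1L]
    ctl <- controller_step(y[1:N_STRATA], ts, te, params, forcing, base_rhs, tb)
    rhs <- make_rhs(pa_params, ctl$mult_eta, ctl$mult_rho, ctl$pa_rate, tb)
    sol <- deSolve::ode(y = y, times = c(ts, te), func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
    ist <- attr(sol, "istate")
    if (!is.null(ist) && ist[1] < 0)
      stop(sprintf("solver failure in control step [%.2f, %.2f]", ts, te))
    y <- sol[nrow(sol), -1]
    y[1:N_STRATA] <- guard_negative(y[1:N_STRATA], te, neg_tol)
    keep[s + 1L, ] <- y
    log_rows[[s]] <- ctl$log
  }

  sel <- vapply(times, function(tt) which.min(abs(grid - tt)), integer(1))
  out <- cbind(time = grid[sel], keep[sel, , drop = FALSE])
  traj <- new_trajectory(out, times, pa_params, forcing,
                         do.call(rbind, log_rows), neg_tol)
  check_tracking(traj, forcing)
  traj
}

run_segment <- function(params, initial, times, method, rtol, atol, rk4_dt) {
  y <- c(initial, numeric(64L))
  rhs <- make_rhs(params)
  if (method == "rk4") {
    tt <- sort(unique(c(seq(min(times), max(times), by = rk4_dt), times)))
    sol <- deSolve::ode(y = y, times = tt, func = rhs, parms = NULL,
                        method = "rk4")
  } else {
    sol <- deSolve::ode(y = y, times = times, func = rhs, parms = NULL,
                        method = method, rtol = rtol, atol = atol)
  }
  ist <- attr(sol, "istate")
  if (!is.null(ist) && ist[1] < 0) stop("ODE solver failure")
  sol
}

new_trajectory <- function(sol, times, params, forcing, control_log, neg_tol) {
  tt <- sol[, 1]
  idx <- vapply(times, function(x) which.min(abs(tt - x)), integer(1))
  counts <- sol[idx, 1 + 1:N_STRATA, drop = FALSE]
  for (r in seq_len(nrow(counts)))
    counts[r, ] <- guard_negative(counts[r, ], tt[idx][r], neg_tol)
  cc <- sol[idx, 1 + N_STRATA + 1:32, drop = FALSE]
  cd <- sol[idx, 1 + N_STRATA + 33:64, drop = FALSE]
  colnames(cc) <- colnames(cd) <- sa_labels()
  structure(list(times = times, counts = unname(counts),
                 cum_cases = cc, cum_deaths = cd,
                 params = params, forcing = forcing,
                 control_log = control_log),
            class = "t2d_trajectory")
}

#' @export
print.t2d_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf("T2DM model trajectory: %d reporting years (%.0f-%.0f)\n",
              n, min(x$times), max(x$times)))
  cat(sprintf("  15-64 T2DM prevalence: %.1f%% -> %.1f%%\n",
              100 * prevalence(x, x$times[1]), 100 * prevalence(x, x$times[n])))
  cat(sprintf("  cumulative cases %.0f, cumulative T2DM deaths %.0f\n",
              sum(x$cum_cases[n, ]), sum(x$cum_deaths[n, ])))
  invisible(x)
}

#' Tidy export of a trajectory
#'
#' @param x a \code{t2d_trajectory}.
#' @param row.names,optional unused, for S3 compatibility.
#' @param what \code{"counts"} for one row per (year, compartment) or
#'   \code{"flows"} for cumulative cases/deaths per (year, sex, age band).
#' @param ... unused.
#' @export
as.data.frame.t2d_trajectory <- function(x, row.names = NULL, optional = FALSE,
                                         what = c("counts", "flows"), ...) {
  what <- match.arg(what)
  if (what == "counts") {
    s <- enumerate_strata()
    nt <- length(x$times)
    out <- s[rep(seq_len(N_STRATA), times = nt), ]
    out <- cbind(year = rep(x$times, each = N_STRATA), out,
                 count = as.vector(t(x$counts)))
    rownames(out) <- NULL
    out
  } else {
    lab <- sa_labels()
    parts <- strsplit(lab, ".", fixed = TRUE)
    data.frame(
      year = rep(x$times, each = 32L),
      sex = vapply(parts, `[`, "", 1)[rep(1:32, length(x$times))],
      age_band = vapply(parts, `[`, "", 2)[rep(1:32, length(x$times))],
      cum_cases = as.vector(t(x$cum_cases)),
      cum_deaths = as.vector(t(x$cum_deaths))
    )
  }
}

#' Write trajectory CSVs
#'
#' Writes the tidy per-compartment counts and the cumulative flow table to
#' two CSV files.
#'
#' @param traj a \code{t2d_trajectory}.
#' @param counts_file,flows_file output paths.
#' @export
write_trajectory <- function(traj, counts_file, flows_file = NULL) {
  utils::write.csv(as.data.frame(traj, what = "counts"), counts_file,
                   row.names = FALSE)
  if (!is.null(flows_file))
    utils::write.csv(as.data.frame(traj, what = "flows"), flows_file,
                     row.names = FALSE)
  invisible(traj)
}
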