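# Calibration: bounded nonlinear least squares (Levenberg-Marquardt via
# minpack.lm) of the unknown rate scales against sex- and age-specific
# prevalence targets, population anchors and the case-fatality rate.
#
# Fitted vector (log scale, multipliers on the initial parameter set):
# sex-specific scales of lambda0 and of each factor's acquisition hazard, a
# shared smoking-cessation scale, a T2DM-mortality scale, and an entry-flow
# scale. Cessation hazards for obesity and inactivity are fixed priors:
# acquisition and cessation are jointly only weakly identified by prevalence
# trajectories, so one of the pair is pinned.

THETA_NAMES <- c("lambda0_female", "lambda0_male",
                 "eta_obesity_female", "eta_obesity_male",
                 "eta_smoking_female", "eta_smoking_male",
                 "eta_inactivity_female", "eta_inactivity_male",
                 "rho_smoking", "nu", "entry")

#' Apply fitted scale multipliers to a parameter set
#'
#' @param params a \code{t2d_params}.
#' @param theta named multipliers (natural scale) over the fitted blocks;
#'   see \code{t2dprev:::THETA_NAMES}.
#' @return The rescaled \code{t2d_params}.
#' @export
apply_theta <- function(params, theta) {
  th <- stats::setNames(rep(1, length(THETA_NAMES)), THETA_NAMES)
  th[names(theta)] <- theta
  p <- params
  p$lambda0[, 1] <- p$lambda0[, 1] * th["lambda0_female"]
  p$lambda0[, 2] <- p$lambda0[, 2] * th["lambda0_male"]
  for (k in FACTORS) {
    p$eta[[k]][, 1] <- p$eta[[k]][, 1] * th[paste0("eta_", k, "_female")]
    p$eta[[k]][, 2] <- p$eta[[k]][, 2] * th[paste0("eta_", k, "_male")]
  }
  p$rho$smoking <- p$rho$smoking * th["rho_smoking"]
  p$nu <- p$nu * th["nu"]
  p$entry0 <- p$entry0 * th["entry"]
  p
}

#' Randomly perturb the fitted parameter blocks
#'
#' Multiplies each fitted block by an independent uniform factor in
#' \code{[1 - frac, 1 + frac]}; used to start parameter-recovery
#' experiments away from the truth.
#'
#' @param params a \code{t2d_params}.
#' @param frac half-width of the multiplicative perturbation.
#' @param seed integer seed.
#' @return The perturbed \code{t2d_params}.
#' @export
perturb_params <- function(params, frac = 0.2, seed = 1) {
  set.seed(seed)
  th <- stats::runif(length(THETA_NAMES), 1 - frac, 1 + frac)
  apply_theta(params, stats::setNames(th, THETA_NAMES))
}

#' Analytic starting parameter set
#'
#' Seeds every rate family from the synthetic targets: acquisition hazards
#' from the per-band quasi-stationary balance of acquisition, cessation and
#' aging inflow; the baseline incidence hazard from the analogous T2DM
#' balance divided by the expected relative-risk multiplier of the band's
#' risk-factor mix; the T2DM mortality scale from the configured
#' case-fatality rate. These seeds put the nonlinear least-squares fit close
#' to its optimum.
#'
#' @param demog a \code{t2d_demography}.
#' @param targets a \code{t2d_targets} (with generator curves attached).
#' @param cfg a \code{t2d_config}; taken from the targets if NULL.
#' @return A \code{t2d_params}.
#' @export
default_params <- function(demog, targets, cfg = NULL) {
  if (is.null(cfg)) cfg <- attr(targets, "cfg")
  curves <- attr(targets, "curves")
  if (is.null(curves)) stop("targets lack generator curves")
  rr <- c(obesity = 4.3, smoking = 1.4, inactivity = 1.4)
  eta <- rho <- list()
  for (k in FACTORS) {
    rho[[k]] <- matrix(cfg$rho_priors[[k]], N_AGE, 2L,
                       dimnames = list(NULL, SEXES))
    eta[[k]] <- matrix(0, N_AGE, 2L, dimnames = list(NULL, SEXES))
  }
  lambda0 <- matrix(0, N_AGE, 2L, dimnames = list(NULL, SEXES))
  nu_shape <- exp(0.04 * (AGE_MID - 50))
  nu <- cbind(female = nu_shape, male = nu_shape)

  for (s in 1:2) {
    for (a in 1:N_AGE) {
      q <- if (a == 1) demog$entry0[s] / demog$pyramid[1, s]
           else 0.2 * demog$pyramid[a - 1, s] / demog$pyramid[a, s]
      for (k in FACTORS) {
        p <- curves[[k]][a, s]
        pp <- if (a == 1) 0 else curves[[k]][a - 1, s]
        eta[[k]][a, s] <- max((cfg$rho_priors[[k]] * p - q * (pp - p)) /
                                max(1 - p, 0.05), 1e-5)
      }
      pi_d <- curves[["t2dm"]][a, s]
      pp <- if (a == 1) 0 else curves[["t2dm"]][a - 1, s]
      lam_eff <- max((cfg$cfr_2016 * pi_d * (1 - pi_d) -
                        q * (pp - pi_d)) / max(1 - pi_d, 0.05), 1e-6)
      e_rr <- prod(1 + vapply(FACTORS, function(k)
        curves[[k]][a, s] * (rr[[k]] - 1), numeric(1)))
      lambda0[a, s] <- lam_eff / e_rr
    }
  }
  # nu scale: match the configured case-fatality rate over the 2016 state
  pi_w <- curves[["t2dm"]][ADULT_BANDS, ] * demog$pyramid[ADULT_BANDS, ]
  cfr_unit <- sum(nu[ADULT_BANDS, ] * pi_w) / sum(pi_w)
  nu <- nu * (cfg$cfr_2016 / cfr_unit)

  t2d_params(entry0 = demog$entry0, entry_growth = demog$entry_growth,
             t_ref = demog$t_ref, mu = demog$mu, lambda0 = lambda0,
             eta = eta, rho = rho, nu = nu, rr = rr, rr_pa = 1)
}

# Per-target model measurement from a baseline trajectory. Prevalence rows
# use whole-population denominators; population rows are persons; cfr rows
# are deaths per prevalent case per year (fraction).
measure_targets <- function(traj, targets) {
  m <- stratum_maps()
  out <- numeric(nrow(targets))
  for (r in seq_len(nrow(targets))) {
    q <- targets$quantity[r]; yr <- targets$year[r]
    if (q == "population") {
      out[r] <- unname(case_counts(traj, yr)["population"])
    } else if (q == "cfr") {
      out[r] <- case_fatality_rate(traj, yr) / 1000
    } else {
      if (targets$sex[r] == "all") {
        bands <- if (targets$age_band[r] == "15-64") ADULT_BANDS
                 else match(targets$age_band[r], AGE_BANDS)
        out[r] <- if (q == "t2dm") prevalence(traj, yr, bands)
                  else risk_prevalence(traj, q, yr, bands = bands)
      } else {
        is <- match(targets$sex[r], SEXES)
        ia <- match(targets$age_band[r], AGE_BANDS)
        N <- traj$counts[time_row(traj, yr), ]
        mask <- m$sex_i == is & m$age_i == ia
        num <- if (q == "t2dm") mask & m$st == 3L else mask & m$on[, q]
        out[r] <- sum(N[num]) / sum(N[mask])
      }
    }
  }
  out
}

# Weighted residual vector: absolute for prevalence fractions, relative for
# population and case-fatality rows (different units/magnitudes).
target_residuals <- function(traj, targets) {
  model <- measure_targets(traj, targets)
  rel <- targets$quantity %in% c("population", "cfr")
  raw <- ifelse(rel, (model - targets$value) / targets$value,
                model - targets$value)
  list(model = model, raw = raw, weighted = sqrt(targets$weight) * raw)
}

#' Calibration loss
#'
#' Simulates the no-intervention baseline under \code{params} and returns
#' the weighted sum of squared residuals against the targets (prevalence
#' residuals on the fraction scale; population and case-fatality residuals
#' relative).
#'
#' @param params a \code{t2d_params}.
#' @param targets a \code{t2d_targets}.
#' @param initial 2016 compartment counts.
#' @param rtol,atol solver tolerances for the inner simulations.
#' @param method deSolve method.
#' @return Nonnegative scalar loss.
#' @export
t2d_loss <- function(params, targets, initial, rtol = 1e-6, atol = 1e-8,
                     method = "lsoda") {
  r <- fit_residuals(params, targets, initial, rtol, atol, method)
  sum(r$weighted^2)
}

fit_sim_years <- function(targets) {
  sort(unique(c(targets$year, targets$year[targets$quantity == "cfr"] + 1)))
}

fit_residuals <- function(params, targets, initial, rtol, atol, method) {
  yr <- fit_sim_years(targets)
  traj <- simulate_t2d(params, initial, t0 = min(yr), t1 = max(yr),
                       times = yr, method = method, rtol = rtol, atol = atol,
                       neg_tol = 1e-6)
  target_residuals(traj, targets)
}

#' Fit the compartmental model to calibration targets
#'
#' Bounded Levenberg-Marquardt nonlinear least squares over the fitted rate
#' scales (log-transformed), started from an analytic seed (or a supplied
#' initial parameter set) plus seeded log-uniform multi-start perturbations.
#' The best of all starts is returned; the procedure is deterministic given
#' the seed.
#'
#' @param targets a \code{t2d_targets} (from [generate_targets()] or
#'   [read_targets()] with generator attributes).
#' @param demog a \code{t2d_demography}; taken from the targets if NULL.
#' @param init initial \code{t2d_params}; [default_params()] if NULL.
#' @param initial 2016 compartment counts;
#'   [generate_initial_state()] if NULL.
#' @param lower,upper bounds on the scale multipliers (natural scale)
#'   relative to \code{init}.
#' @param n_restarts total number of starts (>= 1); restarts beyond the
#'   first perturb the start log-uniformly within +/-50%.
#' @param seed integer seed for the restart perturbations.
#' @param maxiter Levenberg-Marquardt iteration cap per start.
#' @param rtol,atol,method inner-simulation solver settings (the default
#'   tolerances trade accuracy for speed during fitting; see the package
#'   vignette).
#' @return A \code{t2d_fit} object: the calibrated parameters plus
#'   residuals, loss, convergence diagnostics and provenance. Methods:
#'   \code{print}, \code{summary}, \code{coef} (fitted scale multipliers),
#'   \code{residuals}, \code{deviance}, \code{predict} (baseline prevalence
#'   or population series), \code{simulate} (baseline or scenario
#'   trajectory), \code{plot}.
#' @export
t2d_fit <- function(targets, demog = NULL, init = NULL, initial = NULL,
                    lower = 0.2, upper = 5, n_restarts = 1, seed = 1,
                    maxiter = 50, rtol = 1e-6, atol = 1e-8,
                    method = "lsoda") {
  if (is.null(demog)) demog <- attr(targets, "demog")
  if (is.null(demog)) stop("supply a demography (or targets carrying one)")
  cfg <- attr(targets, "cfg")
  if (is.null(init)) init <- default_params(demog, targets, cfg)
  if (is.null(initial)) initial <- generate_initial_state(cfg, targets, demog)
  stopifnot(n_restarts >= 1, lower > 0, upper > lower)

  np <- length(THETA_NAMES)
  resid_fn <- function(ltheta) {
    p <- apply_theta(init, stats::setNames(exp(ltheta), THETA_NAMES))
    fit_residuals(p, targets, initial, rtol, atol, method)$weighted
  }
  starts <- list(rep(0, np))
  if (n_restarts > 1) {
    for (i in 2:n_restarts) {
      set.seed(seed + i - 1L)
      starts[[i]] <- stats::runif(np, log(0.5), log(1.5))
      starts[[i]] <- pmin(pmax(starts[[i]], log(lower)), log(upper))
    }
  }
  runs <- list(); errs <- character(0)
  for (i in seq_along(starts)) {
    r <- tryCatch(
      withCallingHandlers(
        minpack.lm::nls.lm(par = starts[[i]], lower = rep(log(lower), np),
                           upper = rep(log(upper), np), fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = maxiter, ftol = 1e-12, ptol = 1e-10)),
        warning = function(w) {
          # iteration-cap notices are reported via the result object instead
          if (grepl("lmdif|lmder|maxiter", conditionMessage(w)))
            invokeRestart("muffleWarning")
        }),
      error = function(e) e)
    if (inherits(r, "error")) errs <- c(errs, conditionMessage(r))
    else runs[[length(runs) + 1L]] <- r
  }
  if (!length(runs))
    stop("all ", n_restarts, " calibration starts failed: ",
         paste(errs, collapse = " | "))
  best <- runs[[which.min(vapply(runs, stats::deviance, numeric(1)))]]
  ltheta <- best$par
  theta <- stats::setNames(exp(ltheta), THETA_NAMES)
  params <- apply_theta(init, theta)
  res <- fit_residuals(params, targets, initial, rtol, atol, method)
  at_bound <- abs(ltheta - log(lower)) < 1e-8 | abs(ltheta - log(upper)) < 1e-8
  structure(list(
    params = params, theta = theta,
    residuals = cbind(as.data.frame(unclass(targets))[
      , c("quantity", "sex", "age_band", "year", "value", "weight")],
      model = res$model, residual = res$raw, weighted = res$weighted),
    loss = sum(res$weighted^2),
    converged = best$info %in% 1:3,
    boundary = any(at_bound),
    n_restarts_used = length(starts), seed = seed,
    optimizer = list(info = best$info, message = best$message,
                     niter = best$niter, lower = lower, upper = upper,
                     maxiter = maxiter, rtol = rtol, atol = atol),
    init_params = init, targets = targets, demog = demog,
    initial = initial), class = "t2d_fit")
}

#' @export
print.t2d_fit <- function(x, ...) {
  cat("Calibrated T2DM compartmental model\n")
  cat(sprintf("  loss %.4g over %d targets; converged: %s%s\n", x$loss,
              nrow(x$residuals), x$converged,
              if (x$boundary) " (at parameter bound)" else ""))
  cat("  fitted scale multipliers:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
summary.t2d_fit <- function(object, ...) {
  r <- object$residuals
  by_q <- do.call(rbind, lapply(split(r$residual, r$quantity), function(v)
    data.frame(n = length(v), rmse = sqrt(mean(v^2)), max_abs = max(abs(v)))))
  out <- list(theta = object$theta, loss = object$loss,
              converged = object$converged, boundary = object$boundary,
              n_restarts_used = object$n_restarts_used, seed = object$seed,
              by_quantity = by_q, optimizer = object$optimizer)
  class(out) <- "summary.t2d_fit"
  out
}

#' @export
print.summary.t2d_fit <- function(x, ...) {
  cat("Calibration summary\n")
  cat(sprintf("  loss %.4g; converged %s; %d start(s), seed %d\n",
              x$loss, x$converged, x$n_restarts_used, x$seed))
  cat("  residuals by target quantity (prevalence fractions; population/cfr relative):\n")
  print(round(x$by_quantity, 5))
  cat("  fitted multipliers:\n")
  print(round(x$theta, 4))
  invisible(x)
}

#' @export
coef.t2d_fit <- function(object, ...) object$theta

#' @export
residuals.t2d_fit <- function(object, ...) object$residuals$residual

#' @export
deviance.t2d_fit <- function(object, ...) object$loss

#' Baseline projections from a calibrated model
#'
#' @param object a \code{t2d_fit}.
#' @param years reporting years.
#' @param type \code{"prevalence"} (15-64 T2DM prevalence),
#'   \code{"population"} (15-64 persons), or \code{"cfr"} (per 1000/yr).
#' @param ... unused.
#' @return data frame with \code{year} and \code{value}.
#' @export
predict.t2d_fit <- function(object, years = 2016:2050,
                            type = c("prevalence", "population", "cfr"),
                            ...) {
  type <- match.arg(type)
  traj <- baseline_trajectory(object)
  val <- vapply(years, function(y) switch(type,
    prevalence = prevalence(traj, y),
    population = unname(case_counts(traj, y)["population"]),
    cfr = case_fatality_rate(traj, y)), numeric(1))
  data.frame(year = years, value = val)
}

baseline_trajectory <- function(fit) {
  simulate_t2d(fit$params, fit$initial, 2016, 2051)
}

#' Simulate a trajectory from a calibrated model
#'
#' Deterministic model: \code{nsim} must be 1. With \code{scenario = NULL}
#' returns the no-intervention baseline, otherwise runs the given
#' intervention scenario.
#'
#' @param object a \code{t2d_fit}.
#' @param nsim number of trajectories (must be 1; the model is
#'   deterministic).
#' @param seed ignored (kept for the generic's signature).
#' @param scenario a \code{t2d_scenario} or NULL.
#' @param t0,t1 observation window.
#' @param ... passed to [simulate_t2d()].
#' @return A \code{t2d_trajectory}.
#' @export
simulate.t2d_fit <- function(object, nsim = 1, seed = NULL, scenario = NULL,
                             t0 = 2016, t1 = 2050, ...) {
  if (nsim != 1) stop("the model is deterministic; nsim must be 1")
  run_scenario(object$params, object$initial, scenario, t0, t1, ...)
}

#' @export
plot.t2d_fit <- function(x, t1 = 2050, ...) {
  pr <- predict(x, years = 2016:t1, type = "prevalence")
  graphics::plot(pr$year, 100 * pr$value, type = "l", lwd = 2,
                 xlab = "year", ylab = "T2DM prevalence, 15-64 (%)",
                 main = "Baseline projection", ...)
  invisible(x)
}

#' Serialise a fit result
#'
#' Writes the fitted multipliers, loss, convergence diagnostics, seed,
#' bounds and tolerances to JSON, and optionally the full parameter set and
#' per-target residuals alongside.
#'
#' @param fit a \code{t2d_fit}.
#' @param file JSON path.
#' @param params_file,residuals_file optional companion outputs.
#' @export
write_fit <- function(fit, file, params_file = NULL, residuals_file = NULL) {
  x <- list(theta = as.list(fit$theta), loss = fit$loss,
            converged = fit$converged, boundary = fit$boundary,
            n_restarts_used = fit$n_restarts_used, seed = fit$seed,
            optimizer = fit$optimizer,
            package = as.character(utils::packageVersion("t2dprev")))
  jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  if (!is.null(params_file)) write_params(fit$params, params_file)
  if (!is.null(residuals_file))
    utils::write.csv(fit$residuals, residuals_file, row.names = FALSE)
  invisible(file)
}
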