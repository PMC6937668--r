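# ParameterSet: all demographic, risk-factor, incidence and mortality rates.
# Rate matrices are 16 (age bands) x 2 (female, male), units /year.

#' Relative risk of developing T2DM under the physical-activity intervention
#'
#' The intensity ladder used for the explicit physical-activity intervention:
#' participation multiplies the T2DM incidence hazard of a susceptible person
#' by an intensity-specific relative risk below one.
#'
#' @param intensity one of "vigorous", "low", "moderate", "leisure",
#'   "walking".
#' @return The relative risk (0.61, 0.66, 0.68, 0.74 or 0.85).
#' @examples
#' pa_relative_risk("vigorous")  # 0.61
#' @export
pa_relative_risk <- function(intensity) {
  ladder <- c(vigorous = 0.61, low = 0.66, moderate = 0.68,
              leisure = 0.74, walking = 0.85)
  if (!all(intensity %in% names(ladder)))
    stop("unknown physical-activity intensity '", intensity,
         "'; valid: ", paste(names(ladder), collapse = ", "))
  unname(ladder[intensity])
}

#' Construct a model parameter set
#'
#' Bundles every rate of the compartmental model: demographic entry and
#' background mortality, per-factor acquisition/cessation hazards, the
#' baseline T2DM incidence hazard with multiplicative relative risks, the
#' T2DM-related excess mortality hazard, and the physical-activity
#' intervention relative risk. Rate matrices are indexed age band (rows,
#' 0-4 ... 75+) by sex (columns female, male); all rates are per year.
#'
#' @param entry0 persons/year entering the 0-4 band at \code{t_ref}, named
#'   vector \code{c(female=, male=)}.
#' @param entry_growth exponential growth rate of the entry flow, /year.
#' @param t_ref reference calendar year for the entry flow.
#' @param mu background mortality hazard, 16 x 2 matrix.
#' @param lambda0 baseline T2DM incidence hazard for risk-free,
#'   non-intervention susceptibles, 16 x 2 matrix.
#' @param eta named list (obesity, smoking, inactivity) of acquisition
#'   hazards, 16 x 2 matrices.
#' @param rho named list of cessation/remission hazards, 16 x 2 matrices.
#' @param nu T2DM-related excess mortality hazard, 16 x 2 matrix.
#' @param rr relative risks multiplying \code{lambda0}, named vector
#'   \code{c(obesity=, smoking=, inactivity=)}, each >= 1.
#' @param rr_pa relative risk of the physical-activity intervention,
#'   0 < rr_pa <= 1.
#' @param aging_rate per-band aging rate, /year (1/bandwidth; 0 for 75+).
#' @return An object of class \code{t2d_params}.
#' @export
t2d_params <- function(entry0, entry_growth, t_ref = 2016,
                       mu, lambda0, eta, rho, nu,
                       rr = c(obesity = 4.3, smoking = 1.4, inactivity = 1.4),
                       rr_pa = 1,
                       aging_rate = c(rep(0.2, N_AGE - 1L), 0)) {
  p <- list(entry0 = entry0, entry_growth = entry_growth, t_ref = t_ref,
            mu = mu, lambda0 = lambda0, eta = eta, rho = rho, nu = nu,
            rr = rr, rr_pa = rr_pa, aging_rate = aging_rate)
  class(p) <- "t2d_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  chk_mat <- function(m, nm) {
    if (!is.matrix(m) || !all(dim(m) == c(N_AGE, 2L)))
      stop(nm, " must be a ", N_AGE, " x 2 matrix")
    if (any(m < 0)) stop(nm, " must be nonnegative")
  }
  chk_mat(p$mu, "mu"); chk_mat(p$lambda0, "lambda0"); chk_mat(p$nu, "nu")
  for (k in FACTORS) {
    chk_mat(p$eta[[k]], paste0("eta$", k))
    chk_mat(p$rho[[k]], paste0("rho$", k))
  }
  if (length(p$entry0) != 2L || any(p$entry0 < 0))
    stop("entry0 must be a nonnegative vector (female, male)")
  if (any(p$rr[FACTORS] < 1))
    stop("risk-factor relative risks must be >= 1")
  if (p$rr_pa <= 0 || p$rr_pa > 1)
    stop("rr_pa must be in (0, 1]")
  invisible(p)
}

#' @export
print.t2d_params <- function(x, ...) {
  cat("T2DM compartmental model parameter set\n")
  cat(sprintf("  entry (%d): female %.0f, male %.0f /yr; growth %.4f /yr\n",
              x$t_ref, x$entry0[1], x$entry0[2], x$entry_growth))
  cat(sprintf("  relative risks: obesity %.2f, smoking %.2f, inactivity %.2f; PA %.2f\n",
              x$rr["obesity"], x$rr["smoking"], x$rr["inactivity"], x$rr_pa))
  cat(sprintf("  lambda0 range: %.4g - %.4g /yr; nu range: %.4g - %.4g /yr\n",
              min(x$lambda0), max(x$lambda0), min(x$nu), max(x$nu)))
  invisible(x)
}

#' Serialise / deserialise a parameter set
#'
#' Writes a parameter set to YAML (or JSON, by file extension). Rate
#' matrices are stored as named per-sex vectors along the 16 age bands,
#' with units of /year; keys are namespaced by rate family.
#'
#' @param params a \code{t2d_params} object.
#' @param file path ending in .yaml/.yml or .json.
#' @return \code{read_params} returns a \code{t2d_params} object.
#' @export
write_params <- function(params, file) {
  mat2l <- function(m) list(female = as.numeric(m[, 1]), male = as.numeric(m[, 2]))
  x <- list(
    units = "per year; entry in persons/year",
    age_bands = AGE_BANDS,
    demography = list(entry0 = as.list(stats::setNames(as.numeric(params$entry0), SEXES)),
                      entry_growth = params$entry_growth, t_ref = params$t_ref,
                      aging_rate = as.numeric(params$aging_rate),
                      mu = mat2l(params$mu)),
    incidence = list(lambda0 = mat2l(params$lambda0),
                     rr = as.list(params$rr), rr_pa = params$rr_pa),
    risk_transitions = list(
      eta = lapply(params$eta, mat2l),
      rho = lapply(params$rho, mat2l)),
    mortality_t2dm = list(nu = mat2l(params$nu))
  )
  if (grepl("\\.json$", file)) {
    jsonlite::write_json(x, file, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, file, precision = 15)
  }
  invisible(file)
}

#' @rdname write_params
#' @param file path to a file written by \code{write_params}.
#' @export
read_params <- function(file) {
  x <- if (grepl("\\.json$", file)) jsonlite::read_json(file, simplifyVector = TRUE)
       else yaml::read_yaml(file)
  l2mat <- function(l) cbind(female = as.numeric(l$female), male = as.numeric(l$male))
  t2d_params(
    entry0 = stats::setNames(as.numeric(unlist(x$demography$entry0)), SEXES),
    entry_growth = x$demography$entry_growth,
    t_ref = x$demography$t_ref,
    mu = l2mat(x$demography$mu),
    lambda0 = l2mat(x$incidence$lambda0),
    eta = lapply(x$risk_transitions$eta, l2mat)[FACTORS],
    rho = lapply(x$risk_transitions$rho, l2mat)[FACTORS],
    nu = l2mat(x$mortality_t2dm$nu),
    rr = unlist(x$incidence$rr)[FACTORS],
    rr_pa = x$incidence$rr_pa,
    aging_rate = as.numeric(x$demography$aging_rate)
  )
}

#' T2DM incidence hazard of a susceptible compartment
#'
#' Composes the baseline incidence hazard with the multiplicative relative
#' risks of the compartment's risk factors (assumed independent) and, for
#' intervention participants, the physical-activity relative risk:
#' \deqn{\lambda = \lambda_0(sex, age)\; RR_{ob}^{[obese]} RR_{sm}^{[smoker]}
#'   RR_{ia}^{[inactive]}\; RR_{pa}^{[pa\_active]}.}
#'
#' @param stratum a single row of [enumerate_strata()] (or a list with the
#'   same fields); must be a susceptible compartment.
#' @param params a \code{t2d_params} object.
#' @return The incidence hazard, /year.
#' @export
incidence_hazard <- function(stratum, params) {
  if (stratum$disease != "susceptible")
    stop("incidence_hazard is defined only for susceptible compartments")
  i_sex <- match(stratum$sex, SEXES)
  i_age <- match(as.character(stratum$age_band), AGE_BANDS)
  unname(params$lambda0[i_age, i_sex] *
    params$rr["obesity"]^as.integer(stratum$obese) *
    params$rr["smoking"]^as.integer(stratum$smoker) *
    params$rr["inactivity"]^as.integer(stratum$inactive) *
    params$rr_pa^as.integer(stratum$intervention == "pa_active"))
}
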