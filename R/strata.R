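#' Enumerate the model's compartments
#'
#' Returns the full stratification table of the compartmental model: 2 sexes
#' x 16 five-year age bands (0-4 ... 75+) x 8 joint risk-factor combinations
#' (obesity, smoking, physical inactivity) x 3 effective disease/intervention
#' states (susceptible without intervention, susceptible under the
#' physical-activity intervention, T2DM). Only susceptible compartments carry
#' an intervention label, so the product is 2 x 16 x 8 x 3 = 768 compartments.
#'
#' The row order is the canonical flat ordering used throughout the package:
#' the disease/intervention state varies fastest, then inactivity, smoking,
#' obesity, then age band, then sex. Row 1 is therefore
#' (female, 0-4, no risk factors, susceptible, no intervention).
#'
#' @return A data frame with one row per compartment and columns
#'   \code{sex}, \code{age_band}, \code{obese}, \code{smoker},
#'   \code{inactive} (logical), \code{disease} (\code{"susceptible"} or
#'   \code{"t2dm"}), and \code{intervention} (\code{"none"} or
#'   \code{"pa_active"}).
#' @examples
#' s <- enumerate_strata()
#' nrow(s)  # 768
#' s[1, ]
#' @export
enumerate_strata <- function() {
  if (!is.null(.t2d_env$strata)) return(.t2d_env$strata)
  g <- expand.grid(
    state = factor(STATES, levels = STATES),
    inactive = c(FALSE, TRUE),
    smoker = c(FALSE, TRUE),
    obese = c(FALSE, TRUE),
    age_band = factor(AGE_BANDS, levels = AGE_BANDS, ordered = TRUE),
    sex = factor(SEXES, levels = SEXES),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  s <- data.frame(
    sex = g$sex,
    age_band = g$age_band,
    obese = g$obese,
    smoker = g$smoker,
    inactive = g$inactive,
    disease = ifelse(g$state == "t2dm", "t2dm", "susceptible"),
    intervention = ifelse(g$state == "sus_pa", "pa_active", "none"),
    stringsAsFactors = FALSE
  )
  stopifnot(nrow(s) == N_STRATA)
  .t2d_env$strata <- s
  s
}

#' Flat index of a compartment
#'
#' Maps a compartment description to its position in the canonical flat
#' ordering of [enumerate_strata()]; the inverse of indexing the enumeration
#' table by row. Vectorised over all arguments.
#'
#' @param sex "female" or "male".
#' @param age_band one of the 5-year band labels "0-4" ... "70-74", "75+".
#' @param obese,smoker,inactive logical risk-factor indicators.
#' @param disease "susceptible" or "t2dm".
#' @param intervention "none" or "pa_active"; "pa_active" is only valid for
#'   susceptible compartments.
#' @return Integer positions in 1..768.
#' @export
stratum_index <- function(sex, age_band, obese = FALSE, smoker = FALSE,
                          inactive = FALSE, disease = "susceptible",
                          intervention = "none") {
  i_sex <- match(sex, SEXES)
  i_age <- match(age_band, AGE_BANDS)
  if (anyNA(i_sex)) stop("unknown sex; valid: ", paste(SEXES, collapse = ", "))
  if (anyNA(i_age)) stop("unknown age_band; valid: ", paste(AGE_BANDS, collapse = ", "))
  st <- ifelse(disease == "t2dm", 3L,
               ifelse(intervention == "pa_active", 2L, 1L))
  if (any(disease == "t2dm" & intervention == "pa_active"))
    stop("t2dm compartments carry no intervention label")
  (i_sex - 1L) * (N_AGE * 24L) + (i_age - 1L) * 24L +
    as.integer(obese) * 12L + as.integer(smoker) * 6L +
    as.integer(inactive) * 3L + st
}

# Precomputed index machinery shared by the rhs and the controllers.
# All maps are simple strides in the canonical ordering; they are derived
# from enumerate_strata() once and cached.
stratum_maps <- function() {
  if (!is.null(.t2d_env$maps)) return(.t2d_env$maps)
  s <- enumerate_strata()
  sex_i <- as.integer(s$sex)            # 1 female, 2 male
  age_i <- as.integer(s$age_band)       # 1..16
  sa <- (sex_i - 1L) * N_AGE + age_i    # 1..32, ages within sex (col-major 16x2)
  st <- ifelse(s$disease == "t2dm", 3L, ifelse(s$intervention == "pa_active", 2L, 1L))
  on <- cbind(obesity = s$obese, smoking = s$smoker, inactivity = s$inactive)
  flip <- list(
    obesity = seq_len(N_STRATA) + ifelse(s$obese, -12L, 12L),
    smoking = seq_len(N_STRATA) + ifelse(s$smoker, -6L, 6L),
    inactivity = seq_len(N_STRATA) + ifelse(s$inactive, -3L, 3L)
  )
  i_sus1 <- which(st == 1L)
  i_sus2 <- which(st == 2L)
  i_t2dm <- which(st == 3L)
  maps <- list(
    sex_i = sex_i, age_i = age_i, sa = sa, st = st, on = on, flip = flip,
    i_sus1 = i_sus1, i_sus2 = i_sus2, i_t2dm = i_t2dm,
    t2dm_of_sus1 = i_sus1 + 2L, t2dm_of_sus2 = i_sus2 + 1L,
    i_age_src = which(age_i < N_AGE),
    i_age_dst = which(age_i < N_AGE) + 24L,
    entry_idx = c(stratum_index("female", "0-4"), stratum_index("male", "0-4")),
    adult = age_i %in% ADULT_BANDS
  )
  .t2d_env$maps <- maps
  maps
}
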