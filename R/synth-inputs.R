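# Synthetic model inputs.
#
# These stand in, with matching structure, for the English data the analysis
# is normally parameterised from: a survey-based baseline cohort, registry
# incidence used as calibration targets, FIT pilot test characteristics,
# programme uptake statistics, NHS unit costs and utility tables. All values
# are synthetic and chosen to be epidemiologically plausible; none are
# measurements.

# --- parametric natural-history family --------------------------------------

#' Default calibratable parameter vector
#'
#' The natural-history model is generated from a seven-parameter family:
#' a log-linear-in-age onset hazard (normal to low-risk adenoma) with
#' intercept `log_onset` (log annual hazard at age 50, males) and slope
#' `onset_slope` per year, plateauing at age 85; a female age shift
#' `sex_shift` (the female hazard at age a equals the male hazard at
#' a - sex_shift, encoding that CRC arises earlier in men); constant annual
#' probabilities `p_lr_hr` (low- to high-risk adenoma), `p_hr_crc`
#' (high-risk adenoma to stage-A CRC) and `p_prog` (each CRC stage
#' transition); and `pres_scale`, a multiplier on the stage-specific
#' symptomatic presentation probabilities (0.08, 0.18, 0.35, 0.60 for
#' stages A-D).
#'
#' @return Named numeric vector of the seven parameters (with a placeholder
#'   `log_onset`; [default_theta()] solves the calibrated value).
#' @keywords internal
theta_template <- function() {
  c(log_onset = -7, onset_slope = 0.07, sex_shift = 4,
    p_lr_hr = 0.05, p_hr_crc = 0.04, p_prog = 0.35, pres_scale = 1)
}

.pres_base <- c(0.08, 0.18, 0.35, 0.60)
.surv_stage_base <- c(0.02, 0.06, 0.18, 0.45)
.surv_yfd_mult <- c(1.2, 1.0, 0.75, 0.55, 0.4, 0.25)

#' Synthetic life table
#'
#' Gompertz all-cause (non-CRC) annual death probabilities by age and sex,
#' with lower female mortality.
#'
#' @param ages Integer ages (default 30:100).
#' @param female_factor Multiplier on the male death probability for females
#'   (default 0.75; 1 gives a unisex table).
#' @return Matrix `[age, sex]` of annual death probabilities.
#' @export
synth_life_table <- function(ages = 30:100, female_factor = 0.75) {
  q_m <- pmin(0.6, exp(-10.2 + 0.092 * ages))
  cbind(q_m, female_factor * q_m)
}

#' Build natural-history parameters from the parametric family
#'
#' Expands a seven-parameter vector (see [theta_template()]) into the dense
#' age/sex-indexed probability tables of an [nh_params()] object. CRC
#' survival after diagnosis is stage- and year-from-diagnosis-specific
#' (annual death probabilities 0.02/0.06/0.18/0.45 for stages A-D, scaled by
#' a declining year-from-diagnosis multiplier) and the life table is the
#' synthetic Gompertz table.
#'
#' @param theta Named numeric vector overriding entries of the calibrated
#'   default ([default_theta()]).
#' @param ages Ages covered by the tables.
#' @param plateau_age Age at which the onset hazard stops rising.
#' @param female_mortality_factor Passed to [synth_life_table()].
#' @return An [nh_params()] object.
#' @export
#' @examples
#' p <- synth_nh_params()
#' p
synth_nh_params <- function(theta = NULL, ages = 30:100, plateau_age = 85,
                            female_mortality_factor = 0.75) {
  base <- default_theta()
  if (!is.null(theta)) {
    bad <- setdiff(names(theta), names(base))
    if (length(bad)) stop("unknown theta entries: ", paste(bad, collapse = ", "), call. = FALSE)
    base[names(theta)] <- theta
  }
  .nh_params_from_theta(base, ages = ages, plateau_age = plateau_age,
                        female_mortality_factor = female_mortality_factor)
}

.nh_params_from_theta <- function(theta, ages = 30:100, plateau_age = 85,
                                  female_mortality_factor = 0.75) {
  n_age <- length(ages)
  onset_hazard <- function(x) {
    exp(theta[["log_onset"]] + theta[["onset_slope"]] * (pmin(x, plateau_age) - 50))
  }
  p_onset_m <- pmin(0.99, 1 - exp(-onset_hazard(ages)))
  p_onset_f <- pmin(0.99, 1 - exp(-onset_hazard(ages - theta[["sex_shift"]])))

  progression <- array(0, c(n_age, 2L, 6L))
  progression[, 1L, 1L] <- p_onset_m
  progression[, 2L, 1L] <- p_onset_f
  progression[, , 2L] <- theta[["p_lr_hr"]]
  progression[, , 3L] <- theta[["p_hr_crc"]]
  for (s in 4:6) progression[, , s] <- theta[["p_prog"]]

  presentation <- array(0, c(n_age, 2L, 4L))
  for (stg in 1:4) presentation[, , stg] <- pmin(0.95, theta[["pres_scale"]] * .pres_base[stg])

  crc_survival <- array(0, c(n_age, 2L, 4L, 6L))
  for (stg in 1:4) for (b in 1:6) {
    crc_survival[, , stg, b] <- pmin(0.95, .surv_stage_base[stg] * .surv_yfd_mult[b])
  }

  nh_params(progression, presentation, crc_survival,
            synth_life_table(ages, female_factor = female_mortality_factor),
            ages = ages)
}

# Cache for the internally calibrated default parameter vector.
.crcstrat_cache <- new.env(parent = emptyenv())

#' Internally calibrated default natural-history parameters
#'
#' Solves the two free quantities of the parametric family so that the
#' ten-year cumulative incidence constraint holds exactly in the
#' deterministic cohort model: `log_onset` is root-found so that male
#' cumulative incidence over ages 56-66 equals `cum_incidence`, then
#' `sex_shift` so that the female value over ages 60-70 matches it. With
#' `sex_effect = 0` the shift is zero and both sexes share one disease
#' process; other values scale the solved shift proportionally, so raising
#' `sex_effect` never lowers the male:female incidence ratio.
#'
#' @param cum_incidence Target ten-year cumulative incidence (default 0.0085,
#'   i.e. 0.85%).
#' @param sex_effect Multiplier on the solved female age shift.
#' @return Named numeric parameter vector (see [theta_template()]).
#' @export
default_theta <- function(cum_incidence = 0.0085, sex_effect = 1) {
  key <- paste0("theta_", format(cum_incidence, digits = 12), "_", format(sex_effect, digits = 12))
  if (!is.null(.crcstrat_cache[[key]])) return(.crcstrat_cache[[key]])
  theta <- theta_template()
  theta[["sex_shift"]] <- 0
  f_male <- function(lo) {
    theta[["log_onset"]] <- lo
    cohort_cumulative_incidence(.nh_params_from_theta(theta), "male", 56, 10) - cum_incidence
  }
  theta[["log_onset"]] <- stats::uniroot(f_male, c(-12, -3), tol = 1e-10)$root
  if (sex_effect != 0) {
    f_female <- function(s) {
      th <- theta
      th[["sex_shift"]] <- s
      cohort_cumulative_incidence(.nh_params_from_theta(th), "female", 60, 10) - cum_incidence
    }
    shift_base <- stats::uniroot(f_female, c(0, 10), tol = 1e-8)$root
    theta[["sex_shift"]] <- sex_effect * shift_base
  }
  .crcstrat_cache[[key]] <- theta
  theta
}

#' Default prior ranges for calibration
#'
#' Box priors over the seven parameters of the natural-history family, wide
#' enough to contain the generating values with room to spare.
#'
#' @return Tibble with columns `parameter`, `lower`, `upper`.
#' @export
default_prior_ranges <- function() {
  tibble::tibble(
    parameter = names(theta_template()),
    lower = c(-10, 0.02, 0, 0.005, 0.005, 0.10, 0.4),
    upper = c(-4, 0.12, 8, 0.15, 0.15, 0.70, 2.0)
  )
}

# --- FIT and colonoscopy test characteristics --------------------------------

#' Synthetic FIT and colonoscopy test characteristics
#'
#' FIT sensitivity by underlying lesion state, sex and positivity threshold
#' (20/80/120 micrograms haemoglobin per gram of faeces), FIT specificity by
#' sex and threshold, colonoscopy sensitivity by lesion class, and
#' per-colonoscopy complication probabilities. Sensitivity is higher and
#' specificity lower in men than women at every threshold, and lowering the
#' threshold raises sensitivity and lowers specificity, matching the known
#' sex- and threshold-dependence of FIT performance.
#'
#' @return An object of class `test_chars` with elements `sensitivity`
#'   (array `[lesion state 2..7, sex, threshold]`), `specificity`
#'   (matrix `[sex, threshold]`), `colonoscopy_sensitivity` (named vector for
#'   lesion classes `low`, `high`, `crc`), and `complications` (named vector
#'   `perforation`, `major_bleed`, `death`).
#' @export
#' @examples
#' chars <- synth_test_characteristics()
#' chars$specificity
synth_test_characteristics <- function() {
  thr <- c("FIT20", "FIT80", "FIT120")
  lesions <- health_states()[2:7]
  sens <- array(0, c(6L, 2L, 3L), dimnames = list(lesions, .sex_levels, thr))
  #                      LR    HR    A     B     C     D
  sens[, 1, "FIT20"]  <- c(0.16, 0.52, 0.90, 0.93, 0.95, 0.96)
  sens[, 2, "FIT20"]  <- c(0.12, 0.43, 0.86, 0.90, 0.93, 0.95)
  sens[, 1, "FIT80"]  <- c(0.10, 0.40, 0.84, 0.88, 0.91, 0.93)
  sens[, 2, "FIT80"]  <- c(0.075, 0.32, 0.79, 0.84, 0.88, 0.91)
  sens[, 1, "FIT120"] <- c(0.07, 0.32, 0.78, 0.83, 0.87, 0.90)
  sens[, 2, "FIT120"] <- c(0.05, 0.25, 0.72, 0.78, 0.83, 0.87)
  spec <- matrix(c(0.900, 0.925,
                   0.945, 0.960,
                   0.965, 0.975),
                 2, 3, dimnames = list(.sex_levels, thr))
  structure(
    list(
      sensitivity = sens,
      specificity = spec,
      colonoscopy_sensitivity = c(low = 0.80, high = 0.92, crc = 0.97),
      complications = c(perforation = 6e-4, major_bleed = 1.2e-3, death = 6e-5)
    ),
    class = "test_chars"
  )
}

# --- uptake ------------------------------------------------------------------

#' Synthetic screening uptake table
#'
#' Probability of returning a FIT kit when invited, by sex and age band;
#' lower in men at every age, rising modestly with age. Follow-up
#' colonoscopy attendance uses the same table scaled by `followup_factor`.
#'
#' @param followup_factor Multiplier applied to the kit-return probability to
#'   obtain follow-up colonoscopy attendance (default 0.85).
#' @return A list of class `uptake_table`: `table` (tibble `sex`, `age_lo`,
#'   `age_hi`, `p`), `followup_factor`.
#' @export
synth_uptake_table <- function(followup_factor = 0.85) {
  tab <- tibble::tibble(
    sex = rep(.sex_levels, each = 3),
    age_lo = rep(c(40L, 55L, 65L), 2),
    age_hi = rep(c(54L, 64L, 80L), 2),
    p = c(0.52, 0.56, 0.59, 0.60, 0.63, 0.66)
  )
  structure(list(table = tab, followup_factor = followup_factor),
            class = "uptake_table")
}

.uptake_prob <- function(uptake, sexi, age) {
  tab <- uptake$table
  out <- numeric(length(sexi))
  sex_chr <- .sex_levels[sexi]
  for (i in seq_len(nrow(tab))) {
    hit <- sex_chr == tab$sex[i] & age >= tab$age_lo[i] & age <= tab$age_hi[i]
    out[hit] <- tab$p[i]
  }
  out
}

# --- economic inputs ---------------------------------------------------------

#' Synthetic economic inputs
#'
#' Unit costs for screening procedures and complications, CRC treatment
#' costs by age band, stage at diagnosis and year from diagnosis, baseline
#' utilities by age with additive decrements for a CRC diagnosis (by stage)
#' and for an endoscopy complication, discount rates, and the
#' willingness-to-pay threshold. All values are synthetic placeholders with
#' the structure of English tariff and utility tables.
#'
#' @param discount_costs,discount_qalys Annual discount rates (default 0.035).
#' @param wtp Willingness to pay per QALY (default 20000).
#' @return A list of class `econ_inputs`.
#' @export
#' @examples
#' synth_economic_inputs()$unit_costs
synth_economic_inputs <- function(discount_costs = 0.035,
                                  discount_qalys = 0.035,
                                  wtp = 20000) {
  stopifnot(discount_costs >= 0, discount_costs <= 0.10,
            discount_qalys >= 0, discount_qalys <= 0.10, wtp > 0)
  yr0 <- c(11000, 17000, 24000, 29000)
  yr14 <- c(1800, 2600, 3800, 6000)
  yr5 <- c(600, 800, 1200, 2500)
  treatment <- tibble::tibble(
    age_lo = rep(c(30L, 70L), each = 12),
    age_hi = rep(c(69L, 100L), each = 12),
    stage = rep(rep(stage_labels(), 3), 2),
    yfd_lo = rep(rep(c(0L, 1L, 5L), each = 4), 2),
    yfd_hi = rep(rep(c(0L, 4L, 100L), each = 4), 2),
    cost = c(yr0, yr14, yr5, 0.9 * c(yr0, yr14, yr5))
  )
  utilities <- tibble::tibble(
    age_lo = c(30L, 40L, 50L, 60L, 70L, 80L, 90L),
    age_hi = c(39L, 49L, 59L, 69L, 79L, 89L, 100L),
    utility = c(0.94, 0.92, 0.90, 0.87, 0.83, 0.79, 0.75)
  )
  structure(
    list(
      unit_costs = c(fit_kit = 6, colonoscopy = 550, polypectomy = 160,
                     perforation = 3500, major_bleed = 2200),
      crc_treatment = treatment,
      utilities = utilities,
      utility_decrements = c(A = 0.05, B = 0.10, C = 0.17, D = 0.28,
                             complication = 0.10),
      discount_rate_costs = discount_costs,
      discount_rate_qalys = discount_qalys,
      wtp = wtp,
      late_stages = c("C", "D")
    ),
    class = "econ_inputs"
  )
}

# --- calibration targets ------------------------------------------------------

#' Synthetic calibration targets
#'
#' Age/sex-specific clinical incidence rates, adenoma prevalence and
#' undiagnosed CRC prevalence generated exactly from the internally
#' calibrated natural-history parameters, plus two cumulative-incidence
#' constraint rows (males from age 56 and females from age 60 over ten
#' years, both equal to the configured constraint, 0.85% by default). The
#' cumulative-incidence rows carry a higher weight so calibration pins that
#' quantity tightly.
#'
#' @param params Generating [nh_params()]; defaults to the internally
#'   calibrated synthetic truth.
#' @param bands Age bands for the rate/prevalence targets.
#' @param tolerance Named relative-error acceptance bound per target class.
#' @return A tibble of class `calibration_targets` with columns `class`,
#'   `sex`, `age_lo`, `age_hi`, `value`, `weight` and a `tolerance`
#'   attribute.
#' @export
synth_targets <- function(params = synth_nh_params(),
                          bands = default_age_bands(),
                          tolerance = c(incidence = 0.05,
                                        adenoma_prevalence = 0.05,
                                        undiagnosed_crc_prevalence = 0.05,
                                        cum_incidence = 0.05)) {
  core <- nh_summaries(params, bands)
  core$weight <- 1
  cum_index <- tibble::tibble(
    class = "cum_incidence",
    sex = .sex_levels,
    age_lo = c(56L, 60L),
    age_hi = c(66L, 70L)
  )
  cum <- .summaries_for_index(params, cum_index)
  cum$weight <- 10
  out <- dplyr::bind_rows(core, cum)
  class(out) <- c("calibration_targets", class(tibble::tibble()))
  attr(out, "tolerance") <- tolerance
  out
}

# --- bundle -------------------------------------------------------------------

#' Scenario configuration for the synthetic inputs
#'
#' @param threshold FIT positivity threshold label (`"FIT20"`, `"FIT80"`,
#'   `"FIT120"`) or the numeric threshold in micrograms per gram.
#' @param cum_incidence Ten-year cumulative incidence constraint used to
#'   calibrate the synthetic natural history (default 0.0085).
#' @param sex_effect Multiplier on the female onset age shift; 0 removes all
#'   sex differences from the disease process.
#' @param discount_costs,discount_qalys,wtp Passed to
#'   [synth_economic_inputs()].
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(threshold = "FIT120", cum_incidence = 0.0085,
                         sex_effect = 1, discount_costs = 0.035,
                         discount_qalys = 0.035, wtp = 20000) {
  structure(
    list(threshold = .match_threshold(threshold),
         cum_incidence = cum_incidence, sex_effect = sex_effect,
         discount_costs = discount_costs, discount_qalys = discount_qalys,
         wtp = wtp),
    class = "synth_config"
  )
}

#' Generate the full set of synthetic model inputs
#'
#' One call producing everything the downstream modules need: the
#' internally calibrated natural-history truth and its parameter vector,
#' calibration prior ranges and targets, FIT/colonoscopy test
#' characteristics, the uptake table and the economic inputs.
#'
#' @param config A [synth_config()].
#' @return A list of class `synth_inputs` with elements `nh_params`, `theta`,
#'   `prior_ranges`, `targets`, `test_chars`, `uptake`, `econ`, `config`.
#' @export
#' @examples
#' inputs <- synth_inputs()
#' names(inputs)
synth_inputs <- function(config = synth_config()) {
  if (!inherits(config, "synth_config")) config <- do.call(synth_config, config)
  theta <- default_theta(cum_incidence = config$cum_incidence,
                         sex_effect = config$sex_effect)
  # the symmetry switch removes every sex difference from the target-generating
  # process, including the life table (incidence rates carry a (1 - q) factor
  # from within-cycle ordering, so identical targets need identical mortality)
  params <- .nh_params_from_theta(
    theta,
    female_mortality_factor = if (config$sex_effect == 0) 1 else 0.75
  )
  structure(
    list(
      nh_params = params,
      theta = theta,
      prior_ranges = default_prior_ranges(),
      targets = synth_targets(params),
      test_chars = synth_test_characteristics(),
      uptake = synth_uptake_table(),
      econ = synth_economic_inputs(discount_costs = config$discount_costs,
                                   discount_qalys = config$discount_qalys,
                                   wtp = config$wtp),
      config = config
    ),
    class = "synth_inputs"
  )
}
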