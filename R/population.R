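# Synthetic baseline cohort.
#
# Every simulated person enters the model at age 30 with normal colorectal
# epithelium; the only baseline characteristics carried are sex and a
# persistent screening-uptake propensity (a single uniform draw per person
# compared against the sex/age-specific uptake threshold at each invitation,
# which reproduces the never-attender correlation that independent
# per-episode draws destroy).

#' Configuration for the baseline cohort
#'
#' @param n Number of individuals (>= 0).
#' @param female_fraction Probability that an individual is female.
#' @param seed Integer seed making the cohort reproducible.
#' @param uptake_model `"persistent_propensity"` (default: one uptake
#'   propensity drawn per person, compared to the sex/age uptake threshold at
#'   each invitation) or `"per_episode_bernoulli"` (independent draw per
#'   invitation).
#' @return A list of class `population_config`.
#' @export
#' @examples
#' population_config(n = 1000, seed = 7)
population_config <- function(n = 100000, female_fraction = 0.5, seed = 1,
                              uptake_model = c("persistent_propensity",
                                               "per_episode_bernoulli")) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 0 || n != floor(n)) {
    stop("n must be a nonnegative integer", call. = FALSE)
  }
  .assert_prob(female_fraction, "female_fraction")
  structure(
    list(n = as.integer(n), female_fraction = female_fraction,
         seed = as.integer(seed), uptake_model = match.arg(uptake_model)),
    class = "population_config"
  )
}

#' Generate the baseline cohort
#'
#' Draws `n` individuals, all aged 30 with normal epithelium, alive and
#' undiagnosed; sex is assigned by independent Bernoulli draws with
#' probability `female_fraction`. Identical configurations (including seed)
#' produce identical cohorts.
#'
#' @param config A [population_config()].
#' @return A tibble with one row per individual: `id`, `sex`, `age`, `state`,
#'   `uptake_propensity`, `surveillance_due`, `years_since_dx`, `dx_stage`,
#'   `dx_route`, `alive`, `cause_of_death`.
#' @export
#' @examples
#' pop <- generate_population(population_config(n = 5, seed = 1))
#' pop
generate_population <- function(config) {
  if (!inherits(config, "population_config")) config <- do.call(population_config, config)
  n <- config$n
  pop <- .with_seed(config$seed, {
    female <- stats::runif(n) < config$female_fraction
    propensity <- stats::runif(n)
    tibble::tibble(
      id = seq_len(n),
      sex = index_to_sex(ifelse(female, 2L, 1L)),
      age = rep(30L, n),
      state = index_to_state(rep(.ST_NORMAL, n)),
      uptake_propensity = propensity,
      surveillance_due = rep(NA_integer_, n),
      years_since_dx = rep(NA_integer_, n),
      dx_stage = factor(rep(NA_character_, n), levels = stage_labels()),
      dx_route = factor(rep("none", n), levels = c("screen", "clinical", "none")),
      alive = rep(TRUE, n),
      cause_of_death = factor(rep("none", n), levels = c("CRC", "other", "none"))
    )
  })
  attr(pop, "uptake_model") <- config$uptake_model
  pop
}
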