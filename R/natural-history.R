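# Exported natural-history operations on population tibbles.

#' Advance a population one natural-history cycle
#'
#' Applies one annual cycle of the unscreened disease model to a population
#' tibble: every living individual ages by one year, may die of other causes,
#' may progress one step along the adenoma-carcinoma chain, undiagnosed CRC
#' may present symptomatically, and diagnosed individuals face stage-specific
#' CRC mortality. The returned event counts reconcile exactly with the state
#' deltas between the input and output populations.
#'
#' @param population Population tibble (all individuals must share one age,
#'   as the cohort enters the model at age 30 together).
#' @param params An [nh_params()] object.
#' @param cycle_index Integer cycle number (used to index the event streams;
#'   cycle `t` takes the cohort from age `30 + t - 1` to `30 + t`).
#' @param seed Integer seed for the event streams.
#' @return A list with `population` (updated tibble, ages incremented) and
#'   `events` (one-row tibble: `other_deaths`, `progressions`,
#'   `presentations`, `crc_deaths`).
#' @export
#' @examples
#' pop <- generate_population(population_config(n = 100, seed = 1))
#' step <- advance_cycle(pop, synth_nh_params(), cycle_index = 1, seed = 1)
#' step$events
advance_cycle <- function(population, params, cycle_index, seed = 1) {
  if (nrow(population) == 0) {
    return(list(population = population,
                events = tibble::tibble(other_deaths = 0L, progressions = 0L,
                                        presentations = 0L, crc_deaths = 0L)))
  }
  st <- .init_state(population)
  age <- st$age + 1L
  ai <- .age_index(age[1], params)
  if (!all(age == age[1])) stop("all individuals must share one age", call. = FALSE)
  ai <- rep(ai, st$n)
  st <- .reset_cycle_scratch(st)
  st <- .step_other_death(st, params, cycle_index, seed, ai)
  st <- .step_progression(st, params, cycle_index, seed, ai)
  st <- .step_presentation(st, params, cycle_index, seed, ai)
  st <- .step_crc_death(st, params, cycle_index, seed, ai)
  st$age <- age
  list(
    population = .state_to_population(st),
    events = tibble::tibble(
      other_deaths = st$events_other_death,
      progressions = st$events_progression,
      presentations = st$events_presentation,
      crc_deaths = st$events_crc_death
    )
  )
}

#' Cumulative CRC incidence from simulated life summaries
#'
#' Proportion of individuals of the given sex who were alive and undiagnosed
#' at `from_age` and were diagnosed with CRC (any route) within `horizon`
#' years, computed from a [simulate_strategy()] result.
#'
#' @param results A `strategy_result` tibble (needs `sex`, `dx_age`,
#'   `death_age` columns).
#' @param sex `"male"` or `"female"`.
#' @param from_age Conditioning age (>= 30).
#' @param horizon Follow-up window in years (>= 0).
#' @return A proportion in `[0, 1]`.
#' @export
cumulative_incidence <- function(results, sex, from_age, horizon) {
  stopifnot(from_age >= 30, horizon >= 0)
  sexi <- sex_to_index(sex)
  eligible <- sex_to_index(results$sex) == sexi &
    (is.na(results$death_age) | results$death_age > from_age) &
    (is.na(results$dx_age) | results$dx_age > from_age)
  n_elig <- sum(eligible)
  if (n_elig == 0) {
    stop("no individuals of the requested sex are alive and undiagnosed at age ",
         from_age, call. = FALSE)
  }
  events <- eligible & !is.na(results$dx_age) &
    results$dx_age > from_age & results$dx_age <= from_age + horizon
  sum(events) / n_elig
}
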