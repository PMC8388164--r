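# Exported screening-pathway operations.
#
# These wrap the vectorised engine steps for use on population tibbles; the
# lifetime simulation calls the same internals directly.

#' FIT result for tested individuals
#'
#' Returns `"positive"` with probability equal to the sex/threshold-specific
#' sensitivity for the individual's underlying lesion state, or one minus the
#' specificity for individuals with normal epithelium. Individuals must be
#' alive, undiagnosed, and have returned the kit.
#'
#' @param individual One or more population rows (tibble).
#' @param chars Test characteristics ([synth_test_characteristics()]).
#' @param threshold FIT threshold label.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return Character vector, `"positive"` or `"negative"` per row.
#' @export
#' @examples
#' pop <- generate_population(population_config(n = 3, seed = 1))
#' fit_result(pop, synth_test_characteristics(), "FIT120", seed = 1)
fit_result <- function(individual, chars, threshold, seed = NULL) {
  if (any(as.character(individual$dx_route) != "none") || any(!individual$alive)) {
    stop("FIT offered to a diagnosed or dead individual", call. = FALSE)
  }
  thr_i <- .threshold_index(threshold)
  s <- state_to_index(individual$state)
  sexi <- sex_to_index(individual$sex)
  p <- ifelse(s >= 2L,
              chars$sensitivity[cbind(pmin(s, 7L) - 1L, sexi, thr_i)],
              1 - chars$specificity[cbind(sexi, rep(thr_i, length(sexi)))])
  draw <- function() stats::runif(length(p)) < p
  pos <- if (is.null(seed)) draw() else .with_seed(seed, draw())
  ifelse(pos, "positive", "negative")
}

#' Colonoscopy follow-up after a positive FIT
#'
#' Performs the follow-up colonoscopy for attending individuals: the lesion
#' (if any) is detected with the class-specific colonoscopy sensitivity;
#' detected adenomas are removed (the individual returns to the normal state
#' and high-risk removals are scheduled for surveillance), detected CRC is
#' diagnosed at the current underlying stage with route `"screen"`.
#' Perforation, major bleed and procedural death are drawn independently;
#' a procedural death is attributed to other-cause mortality.
#'
#' @inheritParams fit_result
#' @param policy A [surveillance_policy()].
#' @param cycle_index Cycle at which the colonoscopy happens (anchors the
#'   surveillance due date; default 0).
#' @return A list: `individual` (updated rows), `outcome` (character:
#'   `"adenoma_removed"`, `"crc_diagnosed"`, `"clear"`, or
#'   `"complication_death"`), `complications` (tibble with `perforation`,
#'   `major_bleed`, `death` flags per row).
#' @export
colonoscopy_followup <- function(individual, chars, seed = NULL,
                                 policy = surveillance_policy(),
                                 cycle_index = 0) {
  st <- .init_state(individual)
  st <- .reset_cycle_scratch(st)
  run <- function() {
    u_det <- stats::runif(st$n)
    u_perf <- stats::runif(st$n)
    u_bleed <- stats::runif(st$n)
    u_death <- stats::runif(st$n)
    list(u_det, u_perf, u_bleed, u_death)
  }
  u <- if (is.null(seed)) run() else .with_seed(seed, run())
  p_det <- numeric(st$n)
  p_det[st$state == .ST_AD_LR] <- chars$colonoscopy_sensitivity[["low"]]
  p_det[st$state == .ST_AD_HR] <- chars$colonoscopy_sensitivity[["high"]]
  p_det[st$state >= .ST_CRC_A] <- chars$colonoscopy_sensitivity[["crc"]]
  det <- u[[1]] < p_det & st$state >= .ST_AD_LR
  rem <- det & st$state <= .ST_AD_HR
  rem_high <- det & st$state == .ST_AD_HR
  found_crc <- det & st$state >= .ST_CRC_A

  st$n_col <- st$n_col + 1L
  st$state[rem] <- .ST_NORMAL
  st$n_polyp[rem] <- st$n_polyp[rem] + 1L
  if (!is.na(policy$high)) {
    st$in_surv[rem_high] <- TRUE
    st$surv_due[rem_high] <- cycle_index + policy$high
  }
  st <- .diagnose(st, found_crc, 1L, cycle_index)
  perf <- u[[2]] < chars$complications[["perforation"]]
  bleed <- u[[3]] < chars$complications[["major_bleed"]]
  cdeath <- u[[4]] < chars$complications[["death"]]
  st$n_perf[perf] <- st$n_perf[perf] + 1L
  st$n_bleed[bleed] <- st$n_bleed[bleed] + 1L
  st$alive[cdeath] <- FALSE
  st$death_cause[cdeath] <- 2L
  st$death_cycle[cdeath] <- cycle_index
  st$comp_death <- cdeath

  outcome <- rep("clear", st$n)
  outcome[rem] <- "adenoma_removed"
  outcome[found_crc] <- "crc_diagnosed"
  outcome[cdeath] <- "complication_death"
  list(
    individual = .state_to_population(st),
    outcome = outcome,
    complications = tibble::tibble(perforation = perf, major_bleed = bleed,
                                   death = cdeath)
  )
}

#' Run one routine screening episode
#'
#' Applies the full invitation -> FIT -> colonoscopy pathway for one cycle to
#' the individuals of the population who are at one of the strategy's
#' invitation ages: only alive, undiagnosed individuals not under
#' surveillance are invited; kit return follows the configured uptake model;
#' positives attend follow-up colonoscopy with the scaled uptake probability.
#'
#' @param population Population tibble (a single shared age).
#' @param strategy A `screening_strategy`.
#' @param cycle_index Cycle number (anchors surveillance due dates and the
#'   event streams); the episode happens at the population's current age.
#' @param chars Test characteristics.
#' @param uptake_table Uptake object ([synth_uptake_table()]).
#' @param seed Integer seed.
#' @param policy A [surveillance_policy()].
#' @param uptake_model `"persistent_propensity"` or `"per_episode_bernoulli"`.
#' @return A list with `population` (updated tibble) and `log` (one-row
#'   tibble of episode counts: invitations, kits returned, positives,
#'   colonoscopies, adenomas removed, screen-detected CRC, complications).
#' @export
run_screening_episode <- function(population, strategy, cycle_index, chars,
                                  uptake_table, seed = 1,
                                  policy = surveillance_policy(),
                                  uptake_model = "persistent_propensity") {
  if (nrow(population) == 0) {
    return(list(population = population, log = .empty_episode_log(cycle_index)))
  }
  st <- .init_state(population)
  if (!all(st$age == st$age[1])) stop("all individuals must share one age", call. = FALSE)
  age <- st$age[1]
  assign <- .strategy_assignment(strategy, population)
  st <- .reset_cycle_scratch(st)
  st <- .step_screening(st, cycle_index, age, assign, .threshold_index(strategy$threshold),
                        chars, uptake_table, uptake_model, policy, seed)
  log <- tibble::as_tibble(c(list(cycle = cycle_index, age = age),
                             as.list(st$episode_log)))
  list(population = .state_to_population(st), log = log)
}

.empty_episode_log <- function(cycle_index) {
  tibble::tibble(cycle = cycle_index, age = NA_integer_, invitations = 0,
                 kits_returned = 0, positives = 0, colonoscopies = 0,
                 adenomas_removed = 0, screen_detected_crc = 0,
                 perforations = 0, major_bleeds = 0, complication_deaths = 0)
}
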