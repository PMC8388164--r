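# Individual-level simulation engine.
#
# The engine holds the population as a list of parallel vectors and advances
# it one annual cycle at a time. Within-cycle event order is fixed (required
# for reproducibility): (1) other-cause death, (2) natural-history
# progression, (3) screening episode and any due surveillance colonoscopies,
# (4) symptomatic presentation, (5) CRC death among the diagnosed,
# (6) cost/QALY accrual at cycle end. Screening sits between progression and
# presentation so that screen detection pre-empts symptomatic presentation
# within the same year.
#
# All random draws come from (cycle, stream)-indexed uniform vectors aligned
# with individual positions, so two strategies simulated with the same seed
# share their event streams exactly (common random numbers): an individual's
# outcome diverges between strategies only where the strategies themselves
# make it diverge.

.STREAMS <- c(other_death = 1, progression = 2, kit = 3, fit = 4,
              col_attend = 5, col_detect = 6, col_perf = 7, col_bleed = 8,
              col_death = 9, surv_attend = 10, surv_detect = 11,
              surv_perf = 12, surv_bleed = 13, surv_death = 14,
              presentation = 15, crc_death = 16)

# --- state conversion --------------------------------------------------------

.init_state <- function(population) {
  n <- nrow(population)
  s <- state_to_index(population$state)
  alive <- population$alive & s < .ST_DEATH_CRC
  death_cause <- rep(0L, n)
  death_cause[s == .ST_DEATH_CRC] <- 1L
  death_cause[s == .ST_DEATH_OTHER] <- 2L
  cod <- as.character(population$cause_of_death)
  death_cause[cod == "CRC"] <- 1L
  death_cause[cod == "other"] <- 2L
  dx_route <- match(as.character(population$dx_route), c("screen", "clinical", "none"))
  dx_route[dx_route == 3L] <- 0L
  dx_stage <- match(as.character(population$dx_stage), stage_labels())
  ysd <- population$years_since_dx
  dx_cycle <- ifelse(is.na(ysd), NA_integer_,
                     as.integer(population$age) - 30L - as.integer(ysd))
  list(
    n = n, id = population$id, sexi = sex_to_index(population$sex),
    age = as.integer(population$age),
    alive = alive, state = pmin(s, 7L),
    diagnosed = dx_route > 0L, dx_stage = dx_stage, dx_cycle = dx_cycle,
    dx_route = dx_route, death_cause = death_cause,
    death_cycle = rep(NA_integer_, n),
    propensity = population$uptake_propensity,
    in_surv = !is.na(population$surveillance_due),
    surv_due = as.integer(population$surveillance_due),
    surv_clear = rep(0L, n),
    invited = rep(0L, n), n_fit = rep(0L, n), n_col = rep(0L, n),
    n_polyp = rep(0L, n), n_perf = rep(0L, n), n_bleed = rep(0L, n),
    comp_death = rep(FALSE, n),
    cost = rep(0, n), qaly = rep(0, n)
  )
}

.state_to_population <- function(st) {
  s <- st$state
  s[!st$alive & st$death_cause == 1L] <- .ST_DEATH_CRC
  s[!st$alive & st$death_cause == 2L] <- .ST_DEATH_OTHER
  tibble::tibble(
    id = st$id,
    sex = index_to_sex(st$sexi),
    age = st$age,
    state = index_to_state(s),
    uptake_propensity = st$propensity,
    surveillance_due = ifelse(st$in_surv, st$surv_due, NA_integer_),
    years_since_dx = ifelse(is.na(st$dx_cycle), NA_integer_,
                            st$age - 30L - st$dx_cycle),
    dx_stage = factor(stage_labels()[st$dx_stage], levels = stage_labels()),
    dx_route = factor(c("screen", "clinical", "none")[ifelse(st$dx_route == 0L, 3L, st$dx_route)],
                      levels = c("screen", "clinical", "none")),
    alive = st$alive,
    cause_of_death = factor(c("CRC", "other", "none")[ifelse(st$death_cause == 0L, 3L, st$death_cause)],
                            levels = c("CRC", "other", "none"))
  )
}

# --- event sub-steps ---------------------------------------------------------

.step_other_death <- function(st, params, cycle, seed, ai) {
  q <- params$life_table[cbind(ai, st$sexi)]
  u <- .cycle_runif(st$n, seed, cycle, .STREAMS[["other_death"]])
  die <- st$alive & u < q
  st$alive[die] <- FALSE
  st$death_cause[die] <- 2L
  st$death_cycle[die] <- cycle
  st$events_other_death <- sum(die)
  st
}

.step_progression <- function(st, params, cycle, seed, ai) {
  p <- params$progression[cbind(ai, st$sexi, pmin(st$state, 6L))]
  u <- .cycle_runif(st$n, seed, cycle, .STREAMS[["progression"]])
  adv <- st$alive & !st$diagnosed & st$state <= 6L & u < p
  st$state[adv] <- st$state[adv] + 1L
  st$events_progression <- sum(adv)
  st
}

.diagnose <- function(st, who, route, cycle) {
  st$diagnosed[who] <- TRUE
  st$dx_stage[who] <- st$state[who] - 3L
  st$dx_cycle[who] <- cycle
  st$dx_route[who] <- route
  st$in_surv[who] <- FALSE
  st$surv_due[who] <- NA_integer_
  st
}

.step_presentation <- function(st, params, cycle, seed, ai) {
  idx <- st$alive & !st$diagnosed & st$state >= .ST_CRC_A
  p <- numeric(st$n)
  if (any(idx)) {
    p[idx] <- params$presentation[cbind(ai[idx], st$sexi[idx], st$state[idx] - 3L)]
  }
  u <- .cycle_runif(st$n, seed, cycle, .STREAMS[["presentation"]])
  pres <- idx & u < p
  st <- .diagnose(st, pres, 2L, cycle)
  st$events_presentation <- sum(pres)
  st
}

.step_crc_death <- function(st, params, cycle, seed, ai) {
  idx <- st$alive & st$diagnosed
  q <- numeric(st$n)
  if (any(idx)) {
    band <- .yfd_band(cycle - st$dx_cycle[idx])
    q[idx] <- params$crc_survival[cbind(ai[idx], st$sexi[idx], st$dx_stage[idx], band)]
  }
  u <- .cycle_runif(st$n, seed, cycle, .STREAMS[["crc_death"]])
  die <- idx & u < q
  st$alive[die] <- FALSE
  st$death_cause[die] <- 1L
  st$death_cycle[die] <- cycle
  st$events_crc_death <- sum(die)
  st
}

# Complications of a performed colonoscopy; `who` is a logical vector of the
# individuals scoped this cycle. Complication death is attributed to
# death_other so that CRC mortality stays interpretable.
.apply_complications <- function(st, who, chars, cycle, seed, streams) {
  u_perf <- .cycle_runif(st$n, seed, cycle, streams[1])
  u_bleed <- .cycle_runif(st$n, seed, cycle, streams[2])
  u_death <- .cycle_runif(st$n, seed, cycle, streams[3])
  perf <- who & u_perf < chars$complications[["perforation"]]
  bleed <- who & u_bleed < chars$complications[["major_bleed"]]
  cdeath <- who & u_death < chars$complications[["death"]]
  st$n_perf[perf] <- st$n_perf[perf] + 1L
  st$n_bleed[bleed] <- st$n_bleed[bleed] + 1L
  st$cyc_perf <- st$cyc_perf | perf
  st$cyc_bleed <- st$cyc_bleed | bleed
  st$alive[cdeath] <- FALSE
  st$death_cause[cdeath] <- 2L
  st$death_cycle[cdeath] <- cycle
  st$comp_death <- st$comp_death | cdeath
  st
}

.step_screening <- function(st, cycle, age, assign, thr_i, chars, uptake,
                            uptake_model, policy, seed) {
  invited <- st$alive & !st$diagnosed & !st$in_surv &
    !is.na(assign$start) & age >= assign$start & age <= assign$end &
    (age - assign$start) %% 2L == 0L
  st$invited[invited] <- st$invited[invited] + 1L
  log <- list(invitations = sum(invited))
  if (!any(invited)) {
    st$episode_log <- c(log, kits_returned = 0, positives = 0, colonoscopies = 0,
                        adenomas_removed = 0, screen_detected_crc = 0,
                        perforations = 0, major_bleeds = 0, complication_deaths = 0)
    return(st)
  }
  up <- .uptake_prob(uptake, st$sexi, age)
  if (uptake_model == "persistent_propensity") {
    ret <- invited & st$propensity <= up
  } else {
    u_kit <- .cycle_runif(st$n, seed, cycle, .STREAMS[["kit"]])
    ret <- invited & u_kit < up
  }
  st$n_fit[ret] <- st$n_fit[ret] + 1L
  st$cyc_kit <- st$cyc_kit | ret

  u_fit <- .cycle_runif(st$n, seed, cycle, .STREAMS[["fit"]])
  p_pos <- numeric(st$n)
  lesion <- st$state >= 2L
  p_pos[ret & lesion] <- chars$sensitivity[cbind(st$state[ret & lesion] - 1L,
                                                 st$sexi[ret & lesion],
                                                 rep(thr_i, sum(ret & lesion)))]
  p_pos[ret & !lesion] <- 1 - chars$specificity[cbind(st$sexi[ret & !lesion],
                                                      rep(thr_i, sum(ret & !lesion)))]
  positive <- ret & u_fit < p_pos

  pf <- pmin(1, up * uptake$followup_factor)
  u_att <- .cycle_runif(st$n, seed, cycle, .STREAMS[["col_attend"]])
  att <- positive & u_att < pf
  st$n_col[att] <- st$n_col[att] + 1L
  st$cyc_col[att] <- st$cyc_col[att] + 1L

  u_det <- .cycle_runif(st$n, seed, cycle, .STREAMS[["col_detect"]])
  p_det <- numeric(st$n)
  p_det[att & st$state == .ST_AD_LR] <- chars$colonoscopy_sensitivity[["low"]]
  p_det[att & st$state == .ST_AD_HR] <- chars$colonoscopy_sensitivity[["high"]]
  p_det[att & st$state >= .ST_CRC_A] <- chars$colonoscopy_sensitivity[["crc"]]
  det <- att & u_det < p_det

  rem_low <- det & st$state == .ST_AD_LR
  rem_high <- det & st$state == .ST_AD_HR
  found_crc <- det & st$state >= .ST_CRC_A

  st$state[rem_low | rem_high] <- .ST_NORMAL
  st$n_polyp[rem_low | rem_high] <- st$n_polyp[rem_low | rem_high] + 1L
  st$cyc_polyp[rem_low | rem_high] <- st$cyc_polyp[rem_low | rem_high] + 1L
  if (!is.na(policy$high)) {
    st$in_surv[rem_high] <- TRUE
    st$surv_due[rem_high] <- cycle + policy$high
    st$surv_clear[rem_high] <- 0L
  }
  if (!is.na(policy$low)) {
    st$in_surv[rem_low] <- TRUE
    st$surv_due[rem_low] <- cycle + policy$low
    st$surv_clear[rem_low] <- 0L
  }
  st <- .diagnose(st, found_crc, 1L, cycle)
  st <- .apply_complications(st, att, chars, cycle, seed,
                             .STREAMS[c("col_perf", "col_bleed", "col_death")])
  st$events_screen_dx <- sum(found_crc)
  st$episode_log <- c(log,
                      kits_returned = sum(ret), positives = sum(positive),
                      colonoscopies = sum(att),
                      adenomas_removed = sum(rem_low | rem_high),
                      screen_detected_crc = sum(found_crc),
                      perforations = sum(att & st$cyc_perf),
                      major_bleeds = sum(att & st$cyc_bleed),
                      complication_deaths = sum(att & st$comp_death &
                                                  !is.na(st$death_cycle) & st$death_cycle == cycle))
  st
}

.step_surveillance <- function(st, cycle, age, chars, uptake, policy, seed) {
  due <- st$alive & !st$diagnosed & st$in_surv & !is.na(st$surv_due) &
    st$surv_due <= cycle
  if (!any(due)) return(st)
  pf <- pmin(1, .uptake_prob(uptake, st$sexi, age) * uptake$followup_factor)
  u_att <- .cycle_runif(st$n, seed, cycle, .STREAMS[["surv_attend"]])
  att <- due & u_att < pf
  miss <- due & !att
  st$surv_due[miss] <- cycle + 1L
  if (any(att)) {
    st$n_col[att] <- st$n_col[att] + 1L
    st$cyc_col[att] <- st$cyc_col[att] + 1L
    u_det <- .cycle_runif(st$n, seed, cycle, .STREAMS[["surv_detect"]])
    p_det <- numeric(st$n)
    p_det[att & st$state == .ST_AD_LR] <- chars$colonoscopy_sensitivity[["low"]]
    p_det[att & st$state == .ST_AD_HR] <- chars$colonoscopy_sensitivity[["high"]]
    p_det[att & st$state >= .ST_CRC_A] <- chars$colonoscopy_sensitivity[["crc"]]
    det <- att & u_det < p_det

    found_crc <- det & st$state >= .ST_CRC_A
    rem_high <- det & st$state == .ST_AD_HR
    rem_low <- det & st$state == .ST_AD_LR
    clear <- att & !det

    st$state[rem_low | rem_high] <- .ST_NORMAL
    st$n_polyp[rem_low | rem_high] <- st$n_polyp[rem_low | rem_high] + 1L
    st$cyc_polyp[rem_low | rem_high] <- st$cyc_polyp[rem_low | rem_high] + 1L
    st$surv_clear[rem_low | rem_high] <- 0L
    st$surv_due[rem_high] <- cycle + policy$high
    st$surv_due[rem_low] <- cycle + policy$interval

    st$surv_clear[clear] <- st$surv_clear[clear] + 1L
    discharge <- clear & st$surv_clear >= policy$discharge_after
    continue <- clear & !discharge
    st$in_surv[discharge] <- FALSE
    st$surv_due[discharge] <- NA_integer_
    st$surv_due[continue] <- cycle + policy$interval

    st <- .diagnose(st, found_crc, 1L, cycle)
    st$events_screen_dx <- (st$events_screen_dx %||% 0L) + sum(found_crc)
    st <- .apply_complications(st, att, chars, cycle, seed,
                               .STREAMS[c("surv_perf", "surv_bleed", "surv_death")])
  }
  st
}

# --- accrual -----------------------------------------------------------------

.utility_by_age <- function(econ, ages) {
  out <- numeric(length(ages))
  for (i in seq_len(nrow(econ$utilities))) {
    hit <- ages >= econ$utilities$age_lo[i] & ages <= econ$utilities$age_hi[i]
    out[hit] <- econ$utilities$utility[i]
  }
  out
}

.treatment_cost <- function(econ, age, stage, yfd) {
  out <- numeric(length(age))
  tab <- econ$crc_treatment
  stg <- stage_labels()[stage]
  for (i in seq_len(nrow(tab))) {
    hit <- age >= tab$age_lo[i] & age <= tab$age_hi[i] &
      stg == tab$stage[i] & yfd >= tab$yfd_lo[i] & yfd <= tab$yfd_hi[i]
    out[hit] <- tab$cost[i]
  }
  out
}

.step_accrue <- function(st, econ, cycle, age, u_base) {
  uc <- econ$unit_costs
  cost <- st$cyc_kit * uc[["fit_kit"]] +
    st$cyc_col * uc[["colonoscopy"]] +
    st$cyc_polyp * uc[["polypectomy"]] +
    st$cyc_perf * uc[["perforation"]] +
    st$cyc_bleed * uc[["major_bleed"]]
  treat <- st$diagnosed & (st$alive | (!is.na(st$death_cycle) & st$death_cycle == cycle))
  if (any(treat)) {
    w <- which(treat)
    cost[w] <- cost[w] + .treatment_cost(econ, rep(age, length(w)),
                                         st$dx_stage[w], cycle - st$dx_cycle[w])
  }
  decr <- econ$utility_decrements
  u <- rep(u_base, st$n)
  dxed <- st$diagnosed
  u[dxed] <- u[dxed] - decr[st$dx_stage[dxed]]
  comp <- st$cyc_perf | st$cyc_bleed
  u[comp] <- u[comp] - decr[["complication"]]
  u <- pmax(0, u)
  u[!st$alive] <- 0
  st$cost <- st$cost + cost / (1 + econ$discount_rate_costs)^cycle
  st$qaly <- st$qaly + u / (1 + econ$discount_rate_qalys)^cycle
  st
}

.reset_cycle_scratch <- function(st) {
  st$cyc_kit <- rep(FALSE, st$n)
  st$cyc_col <- rep(0L, st$n)
  st$cyc_polyp <- rep(0L, st$n)
  st$cyc_perf <- rep(FALSE, st$n)
  st$cyc_bleed <- rep(FALSE, st$n)
  st$events_screen_dx <- 0L
  st
}

# --- full lifetime simulation ------------------------------------------------

#' Default post-polypectomy surveillance policy
#'
#' Maps the model's two adenoma risk classes onto a colonoscopic surveillance
#' schedule: low-risk removals return to routine screening (no surveillance),
#' high-risk removals are re-examined after `high` years and then every
#' `interval` years until `discharge_after` consecutive clear examinations.
#'
#' @param low Offset in years to the first surveillance colonoscopy after a
#'   low-risk polypectomy, or `NA` for none (the default: return to routine
#'   screening).
#' @param high Offset after a high-risk polypectomy (default 1 year).
#' @param interval Interval between subsequent surveillance exams (default 3).
#' @param discharge_after Consecutive clear exams before discharge (default 2).
#' @return A list of class `surveillance_policy`.
#' @export
surveillance_policy <- function(low = NA, high = 1, interval = 3,
                                discharge_after = 2) {
  structure(list(low = low, high = high, interval = interval,
                 discharge_after = discharge_after),
            class = "surveillance_policy")
}

#' Offset to the next surveillance colonoscopy
#'
#' Deterministic lookup of the configured surveillance policy for an adenoma
#' risk class, applied immediately after polypectomy.
#'
#' @param risk_class `"low"` or `"high"`.
#' @param policy A [surveillance_policy()].
#' @return Offset in years, or `NA` if the class returns to routine screening.
#' @export
#' @examples
#' schedule_surveillance("high", surveillance_policy())
schedule_surveillance <- function(risk_class, policy = surveillance_policy()) {
  if (!is.character(risk_class) || length(risk_class) != 1 ||
      !risk_class %in% c("low", "high")) {
    stop("risk_class must be 'low' or 'high'", call. = FALSE)
  }
  if (risk_class == "low") policy$low else policy$high
}

#' Simulate a cohort's lifetime under a screening strategy
#'
#' Advances every individual from age 30 to `horizon_age` (or death) through
#' the natural-history model, the FIT screening pathway of `strategy` (if
#' given), post-polypectomy surveillance, and discounted cost/QALY accrual.
#' Simulations with the same seed share their random event streams across
#' strategies (common random numbers), so paired strategy differences are
#' free of most Monte-Carlo noise.
#'
#' @param population Baseline cohort tibble from [generate_population()].
#' @param nh_params An [nh_params()] object.
#' @param strategy A `screening_strategy`, or `NULL` for no screening.
#' @param test_chars [synth_test_characteristics()]-shaped object (required
#'   when screening).
#' @param uptake [synth_uptake_table()]-shaped object (required when
#'   screening).
#' @param econ [synth_economic_inputs()]-shaped object.
#' @param seed Integer seed for all event streams.
#' @param horizon_age Simulate to this age or death, whichever first.
#' @param policy A [surveillance_policy()].
#' @param record_history If `TRUE`, attach a per-individual per-cycle event
#'   history (attribute `"history"`); intended for small cohorts.
#' @return A tibble of class `strategy_result`, one row per individual, with
#'   lifetime discounted `cost` and `qaly`, diagnosis and death fields, and
#'   resource counts. Attributes: `"strategy"`, `"seed"`, `"tallies"` (per
#'   cycle/sex occupancy counts), `"episode_logs"` (per-cycle screening
#'   counts), and optionally `"history"`.
#' @export
simulate_strategy <- function(population, nh_params, strategy = NULL,
                              test_chars = NULL, uptake = NULL, econ = NULL,
                              seed = 1, horizon_age = 100,
                              policy = surveillance_policy(),
                              record_history = FALSE) {
  econ <- econ %||% synth_economic_inputs()
  if (!is.null(strategy) && (is.null(test_chars) || is.null(uptake))) {
    stop("test_chars and uptake are required when a strategy is simulated",
         call. = FALSE)
  }
  st <- .init_state(population)
  if (st$n == 0) return(.empty_result(strategy, seed))
  stopifnot(all(st$age == 30L))
  assign <- if (!is.null(strategy)) .strategy_assignment(strategy, population)
  thr_i <- if (!is.null(strategy)) .threshold_index(strategy$threshold)
  uptake_model <- attr(population, "uptake_model") %||% "persistent_propensity"
  n_cycles <- horizon_age - 30L
  u_age <- .utility_by_age(econ, (30L + 1L):(30L + n_cycles))
  tallies <- vector("list", n_cycles)
  episode_logs <- vector("list", n_cycles)
  history <- if (record_history) vector("list", n_cycles)

  for (cycle in seq_len(n_cycles)) {
    age <- 30L + cycle
    ai <- rep(.age_index(age, nh_params), st$n)
    alive_start <- st$alive
    dx_before <- st$diagnosed
    st <- .reset_cycle_scratch(st)
    st <- .step_other_death(st, nh_params, cycle, seed, ai)
    st <- .step_progression(st, nh_params, cycle, seed, ai)
    if (!is.null(strategy)) {
      st <- .step_screening(st, cycle, age, assign, thr_i, test_chars, uptake,
                            uptake_model, policy, seed)
      episode_logs[[cycle]] <- tibble::as_tibble(c(list(cycle = cycle, age = age),
                                                   as.list(st$episode_log)))
      st <- .step_surveillance(st, cycle, age, test_chars, uptake, policy, seed)
    }
    st <- .step_presentation(st, nh_params, cycle, seed, ai)
    st <- .step_crc_death(st, nh_params, cycle, seed, ai)
    st <- .step_accrue(st, econ, cycle, age, u_age[cycle])

    new_dx <- st$diagnosed & !dx_before
    tallies[[cycle]] <- tibble::tibble(
      cycle = cycle, age = age, sex = .sex_levels,
      alive_start = c(sum(alive_start & st$sexi == 1L), sum(alive_start & st$sexi == 2L)),
      new_dx = c(sum(new_dx & st$sexi == 1L), sum(new_dx & st$sexi == 2L)),
      alive = c(sum(st$alive & st$sexi == 1L), sum(st$alive & st$sexi == 2L)),
      adenoma_lr = c(sum(st$alive & !st$diagnosed & st$state == .ST_AD_LR & st$sexi == 1L),
                     sum(st$alive & !st$diagnosed & st$state == .ST_AD_LR & st$sexi == 2L)),
      adenoma_hr = c(sum(st$alive & !st$diagnosed & st$state == .ST_AD_HR & st$sexi == 1L),
                     sum(st$alive & !st$diagnosed & st$state == .ST_AD_HR & st$sexi == 2L)),
      crc_undx = c(sum(st$alive & !st$diagnosed & st$state >= .ST_CRC_A & st$sexi == 1L),
                   sum(st$alive & !st$diagnosed & st$state >= .ST_CRC_A & st$sexi == 2L))
    )
    if (record_history) {
      was_alive <- alive_start
      history[[cycle]] <- tibble::tibble(
        id = st$id[was_alive], cycle = cycle, age = age,
        alive_at_end = st$alive[was_alive],
        diagnosed = st$diagnosed[was_alive],
        dx_stage = factor(stage_labels()[st$dx_stage[was_alive]], levels = stage_labels()),
        years_since_dx = ifelse(st$diagnosed[was_alive],
                                cycle - st$dx_cycle[was_alive], NA_integer_),
        fit_kits = as.integer(st$cyc_kit[was_alive]),
        colonoscopies = st$cyc_col[was_alive],
        polypectomies = st$cyc_polyp[was_alive],
        perforation = st$cyc_perf[was_alive],
        major_bleed = st$cyc_bleed[was_alive]
      )
    }
    if (!any(st$alive)) break
  }

  res <- tibble::tibble(
    id = st$id,
    sex = index_to_sex(st$sexi),
    cost = st$cost,
    qaly = st$qaly,
    crc_case = st$diagnosed,
    dx_stage = factor(stage_labels()[st$dx_stage], levels = stage_labels()),
    dx_route = factor(c("screen", "clinical", "none")[ifelse(st$dx_route == 0L, 3L, st$dx_route)],
                      levels = c("screen", "clinical", "none")),
    late_stage = st$diagnosed & stage_labels()[st$dx_stage] %in% econ$late_stages,
    crc_death = st$death_cause == 1L,
    dx_age = ifelse(is.na(st$dx_cycle), NA_integer_, 30L + st$dx_cycle),
    death_age = ifelse(is.na(st$death_cycle), NA_integer_, 30L + st$death_cycle),
    episodes_offered = st$invited,
    n_fit_kits = st$n_fit,
    n_colonoscopies = st$n_col,
    n_polypectomies = st$n_polyp,
    n_perforations = st$n_perf,
    n_major_bleeds = st$n_bleed,
    complication_death = st$comp_death
  )
  res$late_stage[is.na(res$late_stage)] <- FALSE
  class(res) <- c("strategy_result", class(res))
  attr(res, "strategy") <- if (is.null(strategy)) "no_screening" else strategy$name
  attr(res, "seed") <- seed
  attr(res, "tallies") <- dplyr::bind_rows(tallies)
  if (!is.null(strategy)) attr(res, "episode_logs") <- dplyr::bind_rows(episode_logs)
  if (record_history) attr(res, "history") <- dplyr::bind_rows(history)
  res
}

.empty_result <- function(strategy, seed) {
  res <- tibble::tibble(
    id = integer(), sex = index_to_sex(integer()), cost = numeric(),
    qaly = numeric(), crc_case = logical(),
    dx_stage = factor(character(), levels = stage_labels()),
    dx_route = factor(character(), levels = c("screen", "clinical", "none")),
    late_stage = logical(), crc_death = logical(),
    dx_age = integer(), death_age = integer(), episodes_offered = integer(),
    n_fit_kits = integer(), n_colonoscopies = integer(),
    n_polypectomies = integer(), n_perforations = integer(),
    n_major_bleeds = integer(), complication_death = logical()
  )
  class(res) <- c("strategy_result", class(res))
  attr(res, "strategy") <- if (is.null(strategy)) "no_screening" else strategy$name
  attr(res, "seed") <- seed
  res
}
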