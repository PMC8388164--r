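# Deterministic cohort engine.
#
# Because every per-cycle event probability in the unscreened model depends
# only on (state, age, sex), the expected state occupancy of the
# microsimulation is computable exactly by forward-propagating a cohort
# vector through the same within-cycle event sequence the individual-level
# engine uses: other-cause death, chain progression, symptomatic
# presentation, CRC death, then the year-from-diagnosis clock advances.
# This is what calibration evaluates (noiseless and ~1000x faster than a
# microsimulated loss) and what the incidence/prevalence target generator
# emits.
#
# Cohort state layout (33 states per sex):
#   1..7   undiagnosed chain (normal .. CRC D)
#   8..31  diagnosed, indexed by (stage 1..4) x (years-from-dx band 0..5+)
#   32     death from CRC
#   33     death from other causes

.CO_N <- 33L
.co_dx_index <- function(stage, yfd_band) 7L + (stage - 1L) * 6L + yfd_band

# One annual cycle on an occupancy vector; returns the updated vector plus
# the alive mass at cycle start and the flow of new diagnoses.
.cohort_step <- function(v, ai, si, params) {
  alive_start <- sum(v[1:31])
  # 1. other-cause death
  q <- params$life_table[ai, si]
  dying <- v[1:31] * q
  v[1:31] <- v[1:31] - dying
  v[33L] <- v[33L] + sum(dying)
  # 2. progression along the chain (simultaneous single-step update)
  adv <- v[1:6] * params$progression[ai, si, ]
  v[1:6] <- v[1:6] - adv
  v[2:7] <- v[2:7] + adv
  # 3. symptomatic presentation of undiagnosed CRC
  pres <- v[4:7] * params$presentation[ai, si, ]
  v[4:7] <- v[4:7] - pres
  dx0 <- .co_dx_index(1:4, 1L)
  v[dx0] <- v[dx0] + pres
  new_dx <- sum(pres)
  # 4. CRC death among the diagnosed
  for (stg in 1:4) {
    idx <- .co_dx_index(stg, 1:6)
    dcrc <- v[idx] * params$crc_survival[ai, si, stg, ]
    v[idx] <- v[idx] - dcrc
    v[32L] <- v[32L] + sum(dcrc)
  }
  # 5. advance the year-from-diagnosis clock
  for (stg in 1:4) {
    idx <- .co_dx_index(stg, 1:6)
    x <- v[idx]
    v[idx] <- c(0, x[1:4], x[5] + x[6])
  }
  list(v = v, alive_start = alive_start, new_dx = new_dx)
}

#' Expected state occupancy of an unscreened cohort
#'
#' Propagates a disease-free cohort of the given sex from age 30 through the
#' annual-cycle natural-history model, returning the exact expected occupancy
#' the microsimulation converges to. Row `age` describes the cohort at the
#' end of the cycle in which it reaches that age.
#'
#' @param params An [nh_params()] object.
#' @param sex `"male"` or `"female"`.
#' @param to_age Last age to propagate to (default 100).
#' @return A tibble with one row per age: `alive_start` (alive fraction at
#'   cycle start), `new_dx` (fraction newly diagnosed during the cycle),
#'   occupancy fractions `normal`, `adenoma_lr`, `adenoma_hr`, `crc_undx`,
#'   `crc_dx`, `death_crc`, `death_other`, and `alive`.
#' @export
#' @examples
#' occ <- cohort_occupancy(synth_nh_params(), "male", to_age = 70)
#' occ[occ$age == 60, ]
cohort_occupancy <- function(params, sex, to_age = 100) {
  si <- sex_to_index(sex)
  from_age <- min(params$ages)
  stopifnot(to_age > from_age, to_age <= max(params$ages))
  v <- numeric(.CO_N)
  v[.ST_NORMAL] <- 1
  ages <- (from_age + 1L):to_age
  out <- matrix(0, length(ages), 10)
  for (k in seq_along(ages)) {
    ai <- .age_index(ages[k], params)
    st <- .cohort_step(v, ai, si, params)
    v <- st$v
    dx_mass <- sum(v[8:31])
    out[k, ] <- c(ages[k], st$alive_start, st$new_dx, v[1], v[2], v[3],
                  sum(v[4:7]), dx_mass, v[32], v[33])
  }
  tibble::tibble(
    age = as.integer(out[, 1]), alive_start = out[, 2], new_dx = out[, 3],
    normal = out[, 4], adenoma_lr = out[, 5], adenoma_hr = out[, 6],
    crc_undx = out[, 7], crc_dx = out[, 8],
    death_crc = out[, 9], death_other = out[, 10],
    alive = 1 - out[, 9] - out[, 10]
  )
}

#' Exact cumulative CRC incidence for an unscreened cohort
#'
#' Expected proportion of individuals alive and undiagnosed at `from_age` who
#' are clinically diagnosed with CRC within `horizon` years, computed from the
#' deterministic cohort propagation (the microsimulation estimate of the same
#' quantity converges to this value).
#'
#' @inheritParams cohort_occupancy
#' @param from_age Conditioning age.
#' @param horizon Follow-up window in years.
#' @return A proportion in `[0, 1]`.
#' @export
#' @examples
#' cohort_cumulative_incidence(synth_nh_params(), "male", 56, 10)
cohort_cumulative_incidence <- function(params, sex, from_age, horizon) {
  stopifnot(from_age >= min(params$ages), horizon >= 0)
  if (horizon == 0) return(0)
  occ <- cohort_occupancy(params, sex, to_age = from_age + horizon)
  at <- occ[occ$age == from_age, ]
  eligible <- at$normal + at$adenoma_lr + at$adenoma_hr + at$crc_undx
  events <- sum(occ$new_dx[occ$age > from_age & occ$age <= from_age + horizon])
  events / eligible
}

# Build the full one-step transition matrix over the 33 cohort states at a
# given (age, sex), composed in the engine's within-cycle order. Used by the
# calibration summaries only indirectly; exported for model checking.

#' One-step cohort transition matrix
#'
#' The 33-state one-cycle transition matrix (undiagnosed chain, diagnosed
#' states by stage and year from diagnosis, two death states) at a given age
#' and sex, composed in the same within-cycle event order as the simulation
#' engine. Rows sum to 1.
#'
#' @inheritParams transition_distribution
#' @return A 33 x 33 matrix.
#' @export
cohort_transition_matrix <- function(age, sex, params) {
  ai <- .age_index(age, params)
  si <- sex_to_index(sex)
  m <- matrix(0, .CO_N, .CO_N)
  for (s in 1:.CO_N) {
    v <- numeric(.CO_N)
    v[s] <- 1
    m[s, ] <- .cohort_step(v, ai, si, params)$v
  }
  m
}

# --- summaries used by calibration -----------------------------------------

default_age_bands <- function() {
  lo <- seq(40L, 80L, by = 5L)
  tibble::tibble(age_lo = lo, age_hi = lo + 4L)
}

# Compute, from one occupancy table per sex, the summary value matching each
# row of a (class, sex, age_lo, age_hi) target index.
.summaries_for_index <- function(params, index) {
  sexes <- unique(as.character(index$sex))
  to_age <- max(index$age_hi)
  occ <- lapply(sexes, function(s) cohort_occupancy(params, s, to_age = to_age))
  names(occ) <- sexes
  value <- numeric(nrow(index))
  for (i in seq_len(nrow(index))) {
    o <- occ[[as.character(index$sex[i])]]
    lo <- index$age_lo[i]; hi <- index$age_hi[i]
    rows <- o$age >= lo & o$age <= hi
    value[i] <- switch(
      as.character(index$class[i]),
      incidence = sum(o$new_dx[rows]) / sum(o$alive_start[rows]),
      adenoma_prevalence = sum(o$adenoma_lr[rows] + o$adenoma_hr[rows]) / sum(o$alive[rows]),
      undiagnosed_crc_prevalence = sum(o$crc_undx[rows]) / sum(o$alive[rows]),
      cum_incidence = {
        at <- o[o$age == lo, ]
        eligible <- at$normal + at$adenoma_lr + at$adenoma_hr + at$crc_undx
        sum(o$new_dx[o$age > lo & o$age <= hi]) / eligible
      },
      stop("unknown target class: ", index$class[i], call. = FALSE)
    )
  }
  out <- index[c("class", "sex", "age_lo", "age_hi")]
  out$value <- value
  tibble::as_tibble(out)
}

#' Natural-history model summaries for calibration
#'
#' Age-band incidence rates (clinical diagnoses per person-year), adenoma
#' prevalence, and undiagnosed CRC prevalence by sex, computed exactly from
#' the deterministic cohort propagation of the unscreened model.
#'
#' @param params An [nh_params()] object.
#' @param bands Tibble with `age_lo`, `age_hi` columns (default 5-year bands
#'   40-84).
#' @return A tibble with columns `class`, `sex`, `age_lo`, `age_hi`, `value`.
#' @export
nh_summaries <- function(params, bands = default_age_bands()) {
  index <- tidyr::expand_grid(
    class = c("incidence", "adenoma_prevalence", "undiagnosed_crc_prevalence"),
    sex = .sex_levels,
    bands
  )
  .summaries_for_index(params, index)
}
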