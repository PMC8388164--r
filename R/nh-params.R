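# Natural-history parameter container.
#
# All annual event probabilities are stored as dense arrays indexed by age
# (single-year, typically 30..100) and sex, so the simulation engine can pull
# a whole cohort's probabilities with one indexed lookup per cycle.

#' Construct a natural-history parameter set
#'
#' Bundles the four probability tables that drive the annual-cycle disease
#' model: progression probabilities along the adenoma-carcinoma chain,
#' stage-specific symptomatic presentation probabilities, annual CRC death
#' probabilities after diagnosis (by stage at diagnosis and year from
#' diagnosis), and all-cause (non-CRC) mortality from a life table.
#'
#' @param progression Numeric array `[age, sex, from-state 1..6]`; entry is the
#'   annual probability of advancing one step along the chain
#'   normal -> low-risk adenoma -> high-risk adenoma -> CRC A -> B -> C -> D.
#' @param presentation Numeric array `[age, sex, stage 1..4]`; annual
#'   probability that an undiagnosed CRC of the given stage presents
#'   symptomatically and is clinically diagnosed.
#' @param crc_survival Numeric array `[age, sex, stage at diagnosis 1..4,
#'   year-from-diagnosis band 1..6]` (bands: 0, 1, 2, 3, 4, 5+ years); annual
#'   probability of CRC death after diagnosis.
#' @param life_table Numeric matrix `[age, sex]`; annual probability of death
#'   from causes other than CRC.
#' @param ages Integer vector of ages covered by the tables (default 30:100).
#' @return An object of class `nh_params`.
#' @seealso [synth_nh_params()] to build a parametric synthetic set,
#'   [transition_distribution()] for the one-step kernel.
#' @export
nh_params <- function(progression, presentation, crc_survival, life_table,
                      ages = 30:100) {
  n_age <- length(ages)
  stopifnot(
    identical(dim(progression), c(n_age, 2L, 6L)),
    identical(dim(presentation), c(n_age, 2L, 4L)),
    identical(dim(crc_survival), c(n_age, 2L, 4L, 6L)),
    identical(dim(life_table), c(n_age, 2L))
  )
  .assert_prob(progression, "progression probabilities")
  .assert_prob(presentation, "presentation probabilities")
  .assert_prob(crc_survival, "CRC survival probabilities")
  .assert_prob(life_table, "life-table probabilities")
  structure(
    list(progression = progression, presentation = presentation,
         crc_survival = crc_survival, life_table = life_table,
         ages = as.integer(ages)),
    class = "nh_params"
  )
}

#' @export
print.nh_params <- function(x, ...) {
  cat("<nh_params> annual transition tables, ages", min(x$ages), "-", max(x$ages), "\n")
  cat("  mean onset probability (normal -> low-risk adenoma), male age 60:",
      signif(x$progression[match(60, x$ages), 1, 1], 3), "\n")
  invisible(x)
}

.age_index <- function(age, params) {
  i <- match(age, params$ages)
  if (anyNA(i)) {
    stop("age ", paste(age[is.na(i)], collapse = ", "),
         " outside the life table range [", min(params$ages), ", ",
         max(params$ages), "]", call. = FALSE)
  }
  i
}

.yfd_band <- function(years_from_dx) pmin(years_from_dx, 5L) + 1L

#' One-step natural-history transition distribution
#'
#' Returns the one-cycle probability distribution over the nine health states
#' for an undiagnosed individual, combining other-cause mortality (applied
#' first within the cycle) with progression along the adenoma-carcinoma
#' chain. Death states are absorbing; symptomatic presentation and
#' post-diagnosis CRC survival are separate kernels and carry no mass here.
#'
#' @param state Health state (label, factor or 1..9 code).
#' @param age Integer age in years; must lie within the life-table range.
#' @param sex `"male"` or `"female"`.
#' @param params An [nh_params()] object.
#' @return Named numeric vector of length 9 summing to 1.
#' @export
#' @examples
#' p <- synth_nh_params()
#' transition_distribution("adenoma_low_risk", 60, "male", p)
transition_distribution <- function(state, age, sex, params) {
  s <- state_to_index(state)
  stopifnot(length(s) == 1, length(age) == 1)
  out <- stats::setNames(numeric(9), health_states())
  if (s >= .ST_DEATH_CRC) {       # absorbing
    out[s] <- 1
    return(out)
  }
  ai <- .age_index(age, params)
  si <- sex_to_index(sex)
  q <- params$life_table[ai, si]
  p_adv <- if (s <= 6L) params$progression[ai, si, s] else 0
  out[.ST_DEATH_OTHER] <- q
  out[s] <- (1 - q) * (1 - p_adv)
  if (s <= 6L) out[s + 1L] <- (1 - q) * p_adv
  out
}
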