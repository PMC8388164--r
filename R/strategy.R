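# Screening strategy construction under the equal-mean-episode constraint.
#
# Strategies are biennial FIT invitation schedules. The comparator (current
# English programme shape) invites everyone at ages 60-74, eight episodes.
# Stratified strategies move the start age by sex while keeping the mean
# number of offered episodes equal to the uniform strategy at the mean start
# age: even start ages end at 74 for everyone; odd start ages end at 73 for
# men and 75 for women.

#' Build a biennial invitation schedule
#'
#' @param start_age First invitation age.
#' @param last_age Final invitation age; `last_age - start_age` must be a
#'   multiple of `interval` (an indivisible span forces an explicit end-age
#'   choice rather than silently truncating).
#' @param interval Years between invitations (default 2).
#' @return Integer vector of invitation ages, inclusive of both ends.
#' @export
#' @examples
#' build_schedule(60, 74)  # the 8-episode comparator schedule
#' build_schedule(56, 74)  # 10 episodes
build_schedule <- function(start_age, last_age, interval = 2) {
  stopifnot(length(start_age) == 1, length(last_age) == 1, interval >= 1)
  if (start_age > last_age) stop("start_age must not exceed last_age", call. = FALSE)
  if ((last_age - start_age) %% interval != 0) {
    stop("(last_age - start_age) must be divisible by the interval; ",
         "choose the end age explicitly", call. = FALSE)
  }
  seq(as.integer(start_age), as.integer(last_age), by = as.integer(interval))
}

.end_age_for_start <- function(start_age, sex) {
  if (start_age %% 2 == 0) 74L else if (sex == "male") 73L else 75L
}

new_screening_strategy <- function(name, threshold, male_schedule,
                                   female_schedule, assignment) {
  for (sched in list(male_schedule, female_schedule)) {
    stopifnot(length(sched) >= 1, all(diff(sched) == 2), all(sched >= 40), all(sched <= 80))
  }
  structure(
    list(name = name, threshold = .match_threshold(threshold),
         male_schedule = as.integer(male_schedule),
         female_schedule = as.integer(female_schedule),
         assignment = assignment),
    class = "screening_strategy"
  )
}

#' @export
print.screening_strategy <- function(x, ...) {
  cat("<screening_strategy>", x$name, "(", x$threshold, ")\n")
  if (x$assignment$type == "random") {
    cat("  random assignment: fraction", x$assignment$fraction, "from age",
        x$assignment$early_start, ", remainder from age", x$assignment$late_start, "\n")
  } else {
    cat("  male:  ", paste(range(x$male_schedule), collapse = "-"),
        "(", length(x$male_schedule), "episodes )\n")
    cat("  female:", paste(range(x$female_schedule), collapse = "-"),
        "(", length(x$female_schedule), "episodes )\n")
  }
  invisible(x)
}

#' Sex-stratified biennial screening strategy
#'
#' Men and women start at (possibly) different ages; end ages follow the
#' episode-parity rule: strategies starting at even ages end at 74 for both
#' sexes, strategies starting at odd ages end at 73 for men and 75 for
#' women, so that male and female episode counts average to the uniform
#' comparator's count on a balanced population.
#'
#' @param male_start,female_start First invitation ages; must have the same
#'   parity (their difference must be even).
#' @param threshold FIT threshold label.
#' @param name Optional strategy label.
#' @return A `screening_strategy` object.
#' @export
#' @examples
#' make_sex_stratified(56, 60)  # 10 male episodes, 8 female
#' make_sex_stratified(57, 59)  # 9 episodes each
make_sex_stratified <- function(male_start, female_start, threshold = "FIT120",
                                name = NULL) {
  if ((male_start - female_start) %% 2 != 0) {
    stop("male and female start ages must differ by an even number of years ",
         "(mixed parity breaks the episode-parity end rule)", call. = FALSE)
  }
  male_sched <- build_schedule(male_start, .end_age_for_start(male_start, "male"))
  female_sched <- build_schedule(female_start, .end_age_for_start(female_start, "female"))
  name <- name %||% sprintf("stratified_%d_%d", male_start, female_start)
  new_screening_strategy(name, threshold, male_sched, female_sched,
                         assignment = list(type = "by_sex"))
}

#' Uniform (unstratified) biennial screening strategy
#'
#' Everyone starts at the same age; the end age follows the same parity rule
#' as [make_sex_stratified()] (even starts end at 74 for all).
#'
#' @param start_age First invitation age for everyone.
#' @inheritParams make_sex_stratified
#' @return A `screening_strategy` object.
#' @export
#' @examples
#' make_uniform(60)  # the comparator: ages 60-74, 8 episodes
make_uniform <- function(start_age, threshold = "FIT120", name = NULL) {
  s <- make_sex_stratified(start_age, start_age, threshold = threshold,
                           name = name %||% sprintf("uniform_%d", start_age))
  s$assignment <- list(type = "uniform")
  s
}

#' Randomly stratified screening strategy
#'
#' A random fraction of the population (independent of sex) starts on the
#' early schedule, the remainder on the late schedule; assignment is
#' reproducible from the seed.
#'
#' @param fraction Probability of assignment to the early schedule.
#' @param early_start,late_start First invitation ages of the two schedules.
#' @param threshold FIT threshold label.
#' @param seed Integer seed for the assignment draws.
#' @param name Optional strategy label.
#' @return A `screening_strategy` object.
#' @export
#' @examples
#' make_random_stratified(0.5, 56, 60, seed = 1)
make_random_stratified <- function(fraction, early_start, late_start,
                                   threshold = "FIT120", seed = 1, name = NULL) {
  .assert_prob(fraction, "fraction")
  early <- build_schedule(early_start, .end_age_for_start(early_start, "male"))
  late <- build_schedule(late_start, .end_age_for_start(late_start, "male"))
  name <- name %||% sprintf("random_%d_%d", early_start, late_start)
  new_screening_strategy(name, threshold, early, late,
                         assignment = list(type = "random", fraction = fraction,
                                           seed = as.integer(seed),
                                           early_start = early_start,
                                           late_start = late_start,
                                           early = as.integer(early),
                                           late = as.integer(late)))
}

# Resolve per-individual invitation schedules: returns list(start, end, len)
# aligned with the population rows. Random assignment is a deterministic
# function of the strategy seed and the individual's position.
.strategy_assignment <- function(strategy, population) {
  sexi <- sex_to_index(population$sex)
  n <- length(sexi)
  if (strategy$assignment$type == "random") {
    early <- .with_seed(strategy$assignment$seed,
                        stats::runif(n) < strategy$assignment$fraction)
    e <- strategy$assignment$early
    l <- strategy$assignment$late
    list(start = ifelse(early, e[1], l[1]),
         end = ifelse(early, e[length(e)], l[length(l)]),
         len = ifelse(early, length(e), length(l)))
  } else {
    m <- strategy$male_schedule
    f <- strategy$female_schedule
    list(start = ifelse(sexi == 1L, m[1], f[1]),
         end = ifelse(sexi == 1L, m[length(m)], f[length(f)]),
         len = ifelse(sexi == 1L, length(m), length(f)))
  }
}

#' Mean offered screening episodes per person
#'
#' Population-weighted mean of per-individual schedule lengths. An episode is
#' counted when offered, regardless of uptake: resource parity between
#' strategies is about programme size, and returned kits are reported
#' separately.
#'
#' @param strategy A `screening_strategy`.
#' @param population A population tibble ([generate_population()]).
#' @return Mean episodes per person.
#' @export
#' @examples
#' pop <- generate_population(population_config(n = 1000, seed = 1))
#' mean_episode_count(make_uniform(58), pop)  # 9 for any composition
mean_episode_count <- function(strategy, population) {
  if (nrow(population) == 0) stop("population is empty", call. = FALSE)
  mean(.strategy_assignment(strategy, population)$len)
}

#' Check resource parity between two strategies
#'
#' Two strategies use approximately equal screening resources when their mean
#' offered episode counts on the shared population differ by at most
#' `tolerance`.
#'
#' @param strategy_a,strategy_b `screening_strategy` objects.
#' @param population Shared population tibble.
#' @param tolerance Maximum allowed difference in mean episodes (default 0.1).
#' @return A list of class `parity_report` with elements `pass`, `mean_a`,
#'   `mean_b`, `difference`, `tolerance`.
#' @export
#' @examples
#' pop <- generate_population(population_config(n = 10000, seed = 1))
#' assert_resource_parity(make_uniform(58), make_sex_stratified(56, 60), pop)
assert_resource_parity <- function(strategy_a, strategy_b, population,
                                   tolerance = 0.1) {
  a <- mean_episode_count(strategy_a, population)
  b <- mean_episode_count(strategy_b, population)
  structure(
    list(pass = abs(a - b) <= tolerance, mean_a = a, mean_b = b,
         difference = a - b, tolerance = tolerance,
         names = c(strategy_a$name, strategy_b$name)),
    class = "parity_report"
  )
}

#' @export
print.parity_report <- function(x, ...) {
  cat("<parity_report>", x$names[1], "vs", x$names[2], "\n")
  cat(sprintf("  mean episodes: %.3f vs %.3f (|diff| %.3f, tolerance %.3f) -> %s\n",
              x$mean_a, x$mean_b, abs(x$difference), x$tolerance,
              if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
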