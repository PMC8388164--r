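# Health-economic measures: discounting, accrual, ICER, NMB, per-100k rates,
# and the incremental comparison table.

#' Discount an amount
#'
#' Standard annual discounting anchored at model start:
#' `amount / (1 + rate)^years`.
#'
#' @param amount Numeric amount(s).
#' @param years_from_start Nonnegative years since model start.
#' @param rate Annual discount rate.
#' @return Discounted amount(s).
#' @export
#' @examples
#' discount(100, 1, 0.035)  # 96.618...
discount <- function(amount, years_from_start, rate) {
  if (any(years_from_start < 0)) stop("years_from_start must be >= 0", call. = FALSE)
  amount / (1 + rate)^years_from_start
}

#' Accrue discounted costs and QALYs from a per-cycle history
#'
#' Applies the engine's accrual rules to a recorded event history (see
#' `record_history` in [simulate_strategy()]): procedure and complication
#' costs in the cycle they occur, CRC treatment costs by age band, stage and
#' year from diagnosis for every cycle the individual starts alive after
#' diagnosis, and a utility-weighted life year (baseline utility minus the
#' stage decrement while diagnosed and the complication decrement in the
#' event year, floored at zero) for every cycle the individual ends alive.
#' Everything is discounted to model start at cycle end.
#'
#' @param individual_history Tibble with one row per (id, cycle): columns
#'   `id`, `cycle`, `age`, `alive_at_end`, `diagnosed`, `dx_stage`,
#'   `years_since_dx`, `fit_kits`, `colonoscopies`, `polypectomies`,
#'   `perforation`, `major_bleed`.
#' @param inputs An `econ_inputs` object ([synth_economic_inputs()]).
#' @return Tibble with one row per `id`: `cost`, `qaly` (both discounted).
#' @export
accrue <- function(individual_history, inputs) {
  h <- individual_history
  uc <- inputs$unit_costs
  needed <- c("fit_kit", "colonoscopy", "polypectomy", "perforation", "major_bleed")
  if (!all(needed %in% names(uc))) {
    stop("unit cost table is missing keys: ",
         paste(setdiff(needed, names(uc)), collapse = ", "), call. = FALSE)
  }
  cost <- h$fit_kits * uc[["fit_kit"]] + h$colonoscopies * uc[["colonoscopy"]] +
    h$polypectomies * uc[["polypectomy"]] + h$perforation * uc[["perforation"]] +
    h$major_bleed * uc[["major_bleed"]]
  dxed <- h$diagnosed
  if (any(dxed)) {
    cost[dxed] <- cost[dxed] +
      .treatment_cost(inputs, h$age[dxed], match(as.character(h$dx_stage[dxed]), stage_labels()),
                      h$years_since_dx[dxed])
  }
  u <- .utility_by_age(inputs, h$age)
  decr <- inputs$utility_decrements
  u[dxed] <- u[dxed] - decr[match(as.character(h$dx_stage[dxed]), stage_labels())]
  comp <- h$perforation | h$major_bleed
  u[comp] <- u[comp] - decr[["complication"]]
  u <- pmax(0, u)
  u[!h$alive_at_end] <- 0
  out <- tibble::tibble(
    id = h$id,
    cost = discount(cost, h$cycle, inputs$discount_rate_costs),
    qaly = discount(u, h$cycle, inputs$discount_rate_qalys)
  )
  dplyr::summarise(dplyr::group_by(out, .data$id),
                   cost = sum(.data$cost), qaly = sum(.data$qaly),
                   .groups = "drop")
}

#' Incremental cost-effectiveness ratio
#'
#' `delta_cost / delta_qaly` when both increments are positive; `"dominant"`
#' when the strategy saves money and gains QALYs, `"dominated"` when it costs
#' more and gains nothing, `"equivalent"` when both increments are zero. When
#' both increments are negative the ratio is returned (south-west quadrant;
#' interpret against willingness to pay with the inequality reversed).
#'
#' @param delta_cost,delta_qaly Increments versus the declared comparator.
#' @return A number, or one of `"dominant"`, `"dominated"`, `"equivalent"`.
#' @export
#' @examples
#' icer(0.55, 0.0004)   # 1375
#' icer(-1, 0.001)      # "dominant"
icer <- function(delta_cost, delta_qaly) {
  stopifnot(length(delta_cost) == 1, length(delta_qaly) == 1)
  if (delta_cost == 0 && delta_qaly == 0) return("equivalent")
  if (delta_cost <= 0 && delta_qaly > 0) return("dominant")
  if (delta_cost > 0 && delta_qaly <= 0) return("dominated")
  if (delta_cost <= 0 && delta_qaly <= 0) return(delta_cost / delta_qaly)
  delta_cost / delta_qaly
}

#' Net monetary benefit
#'
#' `wtp * delta_qaly - delta_cost` at the stated willingness to pay.
#'
#' @inheritParams icer
#' @param wtp Willingness to pay per QALY (> 0).
#' @return Net monetary benefit in currency units.
#' @export
#' @examples
#' nmb(0.55, 0.0004, 20000)  # 7.45
nmb <- function(delta_cost, delta_qaly, wtp) {
  stopifnot(wtp > 0)
  wtp * delta_qaly - delta_cost
}

#' Rate per 100,000 population
#'
#' @param count Event count(s).
#' @param n_population Population size (> 0).
#' @return `count * 1e5 / n_population`.
#' @export
#' @examples
#' per_100k(5, 1000)  # 500
per_100k <- function(count, n_population) {
  if (any(n_population <= 0)) stop("n_population must be > 0", call. = FALSE)
  count * 1e5 / n_population
}

.stratum_summary <- function(res, stratum) {
  rows <- if (stratum == "overall") rep(TRUE, nrow(res)) else as.character(res$sex) == stratum
  r <- res[rows, ]
  n <- nrow(r)
  tibble::tibble(
    stratum = stratum,
    n = n,
    cost_pp = mean(r$cost),
    qaly_pp = mean(r$qaly),
    crc_cases_100k = per_100k(sum(r$crc_case), n),
    late_stage_100k = per_100k(sum(r$late_stage), n),
    crc_deaths_100k = per_100k(sum(r$crc_death), n),
    fit_kits_100k = per_100k(sum(r$n_fit_kits), n),
    colonoscopies_100k = per_100k(sum(r$n_colonoscopies), n)
  )
}

#' Compare strategies against a comparator
#'
#' Builds the incremental table: per strategy and stratum (male, female,
#' overall), mean discounted cost and QALYs per person, CRC cases, late-stage
#' (C/D) cases and CRC deaths per 100,000, FIT kits and colonoscopies per
#' 100,000, and — versus the comparator — incremental cost, incremental
#' QALYs, the ICER and the net monetary benefit at the inputs'
#' willingness-to-pay. All strategies must have been simulated on the same
#' population with the same seed (common random numbers), so increments are
#' paired differences.
#'
#' @param results Named list of `strategy_result` tibbles
#'   ([simulate_strategy()]); names are the strategy labels.
#' @param comparator Name of the comparator entry in `results`.
#' @param inputs An `econ_inputs` object (supplies `wtp`).
#' @return A tibble of class `crc_comparison` with one row per (strategy,
#'   stratum); attributes `comparator` and `wtp`.
#' @export
compare_strategies <- function(results, comparator, inputs = synth_economic_inputs()) {
  if (is.null(names(results)) || any(names(results) == "")) {
    stop("results must be a named list of strategy results", call. = FALSE)
  }
  if (!comparator %in% names(results)) {
    stop("comparator '", comparator, "' not found among results", call. = FALSE)
  }
  strata <- c("male", "female", "overall")
  summaries <- purrr::map(results, function(res) {
    dplyr::bind_rows(purrr::map(strata, ~ .stratum_summary(res, .x)))
  })
  comp <- summaries[[comparator]]
  out <- purrr::imap(summaries, function(s, name) {
    s$strategy <- name
    s$d_cost <- s$cost_pp - comp$cost_pp
    s$d_qaly <- s$qaly_pp - comp$qaly_pp
    s$d_crc_cases_100k <- s$crc_cases_100k - comp$crc_cases_100k
    s$d_late_stage_100k <- s$late_stage_100k - comp$late_stage_100k
    s$d_crc_deaths_100k <- s$crc_deaths_100k - comp$crc_deaths_100k
    s$d_colonoscopies_100k <- s$colonoscopies_100k - comp$colonoscopies_100k
    s$d_fit_kits_100k <- s$fit_kits_100k - comp$fit_kits_100k
    s$icer_label <- vapply(seq_len(nrow(s)), function(i) {
      if (name == comparator) return("comparator")
      as.character(icer(s$d_cost[i], s$d_qaly[i]))
    }, character(1))
    s$icer <- suppressWarnings(as.numeric(s$icer_label))
    s$nmb <- nmb(s$d_cost, s$d_qaly, inputs$wtp)
    s
  })
  out <- dplyr::bind_rows(out)
  out <- dplyr::relocate(out, "strategy")
  class(out) <- c("crc_comparison", class(tibble::tibble()))
  attr(out, "comparator") <- comparator
  attr(out, "wtp") <- inputs$wtp
  out
}

#' Simulate a set of strategies with common random numbers
#'
#' Convenience wrapper running [simulate_strategy()] for each strategy on the
#' shared population and seed, so the results are directly comparable with
#' [compare_strategies()].
#'
#' @param population Shared baseline cohort.
#' @param strategies Named list of `screening_strategy` objects (a `NULL`
#'   element simulates no screening).
#' @param inputs A `synth_inputs` bundle (or any list with `nh_params`,
#'   `test_chars`, `uptake`, `econ`).
#' @param seed Shared event-stream seed.
#' @param ... Passed to [simulate_strategy()].
#' @return Named list of `strategy_result` tibbles.
#' @export
evaluate_strategies <- function(population, strategies, inputs, seed = 1, ...) {
  purrr::map(strategies, function(s) {
    simulate_strategy(population, inputs$nh_params, s,
                      test_chars = inputs$test_chars, uptake = inputs$uptake,
                      econ = inputs$econ, seed = seed, ...)
  })
}
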