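# End-to-end orchestration: configuration, the base-case analysis bundle and
# the scenario grid.

#' Analysis run configuration
#'
#' @param n Individuals per arm.
#' @param female_fraction,uptake_model Passed to [population_config()].
#' @param threshold FIT threshold label for all strategies.
#' @param mean_start Mean screening start age of the stratified pair.
#' @param gap Years between male and female start ages (male starts
#'   `gap / 2` years before `mean_start`).
#' @param random_fraction Fraction assigned to the early schedule in the
#'   randomly stratified strategy (`NULL` drops that strategy).
#' @param include_uniform Include the unstratified reduced-start strategy.
#' @param discount Annual discount rate applied to costs and QALYs (scenario
#'   values 0.015, 0.035, 0.05).
#' @param wtp Willingness to pay per QALY.
#' @param sex_effect,cum_incidence Passed to [synth_config()].
#' @param psa_samples Number of PSA samples (0 skips the PSA).
#' @param psa_n Individuals per PSA sample.
#' @param output_dir Directory written by [run_analysis()].
#' @param seed Master seed; fans out to population, event and PSA streams.
#' @return A list of class `run_config`.
#' @export
run_config <- function(n = 100000, female_fraction = 0.5,
                       uptake_model = "persistent_propensity",
                       threshold = "FIT120", mean_start = 58, gap = 4,
                       random_fraction = 0.5, include_uniform = TRUE,
                       discount = 0.035, wtp = 20000,
                       sex_effect = 1, cum_incidence = 0.0085,
                       psa_samples = 0, psa_n = 20000,
                       output_dir = "crcstrat-output", seed = 1) {
  stopifnot(discount %in% c(0.015, 0.035, 0.05) || (discount >= 0 && discount <= 0.1))
  structure(
    list(n = n, female_fraction = female_fraction, uptake_model = uptake_model,
         threshold = .match_threshold(threshold), mean_start = mean_start,
         gap = gap, random_fraction = random_fraction,
         include_uniform = include_uniform, discount = discount, wtp = wtp,
         sex_effect = sex_effect, cum_incidence = cum_incidence,
         psa_samples = psa_samples, psa_n = psa_n,
         output_dir = output_dir, seed = seed),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' @param path Path to a YAML file whose keys match [run_config()] arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

# The strategy set of a configuration: the fixed-age comparator (start 60)
# plus the reduced-start uniform, sex-stratified and randomly stratified
# strategies at equal mean episodes.
.config_strategies <- function(config) {
  thr <- config$threshold
  strategies <- list(comparator_60 = make_uniform(60, thr, name = "comparator_60"))
  if (config$include_uniform) {
    s <- make_uniform(config$mean_start, thr)
    strategies[[s$name]] <- s
  }
  if (config$gap > 0) {
    s <- make_sex_stratified(config$mean_start - config$gap / 2,
                             config$mean_start + config$gap / 2, thr)
    strategies[[s$name]] <- s
  }
  if (!is.null(config$random_fraction) && config$gap > 0) {
    s <- make_random_stratified(config$random_fraction,
                                config$mean_start - config$gap / 2,
                                config$mean_start + config$gap / 2, thr,
                                seed = child_seed(config$seed, 5L))
    strategies[[s$name]] <- s
  }
  strategies
}

#' Run the full analysis and write the result bundle
#'
#' Generates the synthetic inputs and population, builds the configured
#' strategy set (fixed-age-60 comparator, reduced-start uniform,
#' sex-stratified and randomly stratified at equal mean episodes), simulates
#' all strategies with common random numbers, computes the incremental
#' comparison, optionally runs the PSA and CEAC, and writes everything as
#' CSV plus the resolved configuration (YAML) and a run log. Reruns with an
#' identical configuration produce byte-identical result CSVs.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `comparison`, `results`, `strategies`,
#'   `psa`, `ceac` and `paths`.
#' @export
run_analysis <- function(config = run_config()) {
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  inputs <- synth_inputs(synth_config(
    threshold = config$threshold, cum_incidence = config$cum_incidence,
    sex_effect = config$sex_effect, discount_costs = config$discount,
    discount_qalys = config$discount, wtp = config$wtp
  ))
  pop_cfg <- population_config(n = config$n,
                               female_fraction = config$female_fraction,
                               seed = child_seed(config$seed, 1L),
                               uptake_model = config$uptake_model)
  population <- generate_population(pop_cfg)
  strategies <- .config_strategies(config)
  if (length(strategies) > 2) {
    # the reduced-start strategies must match each other's programme size
    # (the fixed-age-60 comparator is one episode smaller by design)
    reference <- strategies[[2]]
    for (s in strategies[-(1:2)]) {
      parity <- assert_resource_parity(reference, s, population)
      if (!parity$pass) {
        warning("strategy ", s$name, " fails resource parity with ",
                reference$name, call. = FALSE)
      }
    }
  }
  ev_seed <- child_seed(config$seed, 2L)
  results <- evaluate_strategies(population, strategies, inputs, seed = ev_seed)
  paths <- character()

  if (length(strategies) > 1) {
    comparison <- compare_strategies(results, "comparator_60", inputs$econ)
    p <- file.path(config$output_dir, "incremental.csv")
    utils::write.csv(as.data.frame(comparison), p, row.names = FALSE)
    paths <- c(paths, p)
  } else {
    comparison <- NULL
  }
  summary_tab <- dplyr::bind_rows(purrr::imap(results, function(r, nm) {
    s <- dplyr::bind_rows(purrr::map(c("male", "female", "overall"),
                                     ~ .stratum_summary(r, .x)))
    s$strategy <- nm
    dplyr::relocate(s, "strategy")
  }))
  p <- file.path(config$output_dir, "results_summary.csv")
  utils::write.csv(as.data.frame(summary_tab), p, row.names = FALSE)
  paths <- c(paths, p)

  psa_res <- NULL
  ceac_tab <- NULL
  if (config$psa_samples > 0 && length(strategies) > 1) {
    psa_cfg <- population_config(n = config$psa_n,
                                 female_fraction = config$female_fraction,
                                 seed = child_seed(config$seed, 3L),
                                 uptake_model = config$uptake_model)
    psa_res <- run_psa(parameter_distributions(), strategies, psa_cfg,
                       n_samples = config$psa_samples,
                       seed = child_seed(config$seed, 4L), inputs = inputs)
    ceac_tab <- ceac(psa_res, wtp_grid = seq(0, 50000, by = 1000))
    p1 <- file.path(config$output_dir, "psa_samples.csv")
    p2 <- file.path(config$output_dir, "ceac.csv")
    utils::write.csv(as.data.frame(psa_res$samples), p1, row.names = FALSE)
    utils::write.csv(as.data.frame(ceac_tab), p2, row.names = FALSE)
    paths <- c(paths, p1, p2)
  }

  cfg_path <- file.path(config$output_dir, "resolved_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  log_path <- file.path(config$output_dir, "run_log.txt")
  writeLines(c(
    paste("crcstrat version:", as.character(utils::packageVersion("crcstrat"))),
    paste("master seed:", config$seed),
    paste("population seed:", child_seed(config$seed, 1L)),
    paste("event seed:", ev_seed),
    paste("strategies:", paste(names(strategies), collapse = ", "))
  ), log_path)
  invisible(list(comparison = comparison, results = results,
                 strategies = strategies, psa = psa_res, ceac = ceac_tab,
                 paths = c(paths, cfg_path, log_path)))
}

#' Scenario grid of stratified-versus-comparator increments
#'
#' One row per (threshold, mean start age, sex gap): the sex-stratified
#' strategy's incremental net monetary benefit, CRC cases and CRC deaths per
#' 100,000 versus the fixed-age-60 uniform comparator at the same threshold.
#' A zero gap reduces to the uniform strategy at the mean start age.
#'
#' @param grid Tibble with columns `threshold`, `mean_start`, `gap`.
#' @param n Individuals per arm.
#' @param seed Master seed.
#' @param config Optional [run_config()] supplying `n`, `seed` and the
#'   synthetic-input settings (overrides `n`/`seed` arguments).
#' @return A tibble of class `crc_grid`: grid columns plus `strategy`,
#'   `d_nmb`, `d_crc_cases_100k`, `d_crc_deaths_100k`, `d_qaly`, `d_cost`.
#' @export
scenario_grid <- function(grid, n = 100000, seed = 1, config = NULL) {
  stopifnot(nrow(grid) > 0)
  if (!is.null(config)) {
    n <- config$n
    seed <- config$seed
  }
  rows <- vector("list", nrow(grid))
  pop_cfg <- population_config(n = n, seed = child_seed(seed, 1L))
  population <- generate_population(pop_cfg)
  ev_seed <- child_seed(seed, 2L)
  for (i in seq_len(nrow(grid))) {
    thr <- .match_threshold(grid$threshold[i])
    ms <- grid$mean_start[i]
    gap <- grid$gap[i]
    inputs <- synth_inputs(synth_config(threshold = thr))
    strat <- if (gap == 0) make_uniform(ms, thr) else {
      make_sex_stratified(ms - gap / 2, ms + gap / 2, thr)
    }
    strategies <- list(comparator_60 = make_uniform(60, thr, name = "comparator_60"))
    strategies[[strat$name]] <- strat
    results <- evaluate_strategies(population, strategies, inputs, seed = ev_seed)
    cmp <- compare_strategies(results, "comparator_60", inputs$econ)
    row <- cmp[cmp$strategy == strat$name & cmp$stratum == "overall", ]
    rows[[i]] <- tibble::tibble(
      threshold = thr, mean_start = ms, gap = gap, strategy = strat$name,
      d_cost = row$d_cost, d_qaly = row$d_qaly, d_nmb = row$nmb,
      d_crc_cases_100k = row$d_crc_cases_100k,
      d_crc_deaths_100k = row$d_crc_deaths_100k
    )
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("crc_grid", class(tibble::tibble()))
  out
}
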