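# Probabilistic sensitivity analysis.
#
# Uncertain scalars are sampled independently from declared distribution
# families (beta for probabilities, gamma/lognormal for costs and
# multipliers), the strategy comparison is re-run per sample, and the
# cost-effectiveness acceptability curve summarises, at each willingness to
# pay, how often each strategy attains the highest net monetary benefit.
# Within a sample all strategies share one event-stream seed (common random
# numbers); the seed varies across samples.

#' Default parameter uncertainty distributions
#'
#' One row per uncertain scalar: FIT sensitivity (CRC and high-risk adenoma,
#' by sex) and specificity (by sex) at the analysis threshold, kit-return
#' uptake by sex, colonoscopy complication probabilities, unit costs, a CRC
#' treatment-cost multiplier, a utility-decrement multiplier and a
#' natural-history onset multiplier. Probability-valued parameters are beta;
#' cost-valued parameters are gamma; multipliers are lognormal centred on 1.
#'
#' @return Tibble of class `parameter_distributions` with columns
#'   `parameter`, `family`, `shape1`, `shape2`. For `beta` the shapes are the
#'   usual (alpha, beta); for `gamma`, (shape, rate); for `lognormal`,
#'   (meanlog, sdlog); for `fixed`, `shape1` is the value.
#' @export
parameter_distributions <- function() {
  beta_ms <- function(mean, ess) c(mean * ess, (1 - mean) * ess)
  rows <- list(
    c("fit_sens_crc_male", "beta", beta_ms(0.85, 150)),
    c("fit_sens_crc_female", "beta", beta_ms(0.80, 150)),
    c("fit_sens_hr_male", "beta", beta_ms(0.32, 150)),
    c("fit_sens_hr_female", "beta", beta_ms(0.25, 150)),
    c("fit_spec_male", "beta", beta_ms(0.965, 400)),
    c("fit_spec_female", "beta", beta_ms(0.975, 400)),
    c("uptake_male", "beta", beta_ms(0.56, 200)),
    c("uptake_female", "beta", beta_ms(0.63, 200)),
    c("perforation", "beta", beta_ms(6e-4, 10000)),
    c("major_bleed", "beta", beta_ms(1.2e-3, 10000)),
    c("colonoscopy_death", "beta", beta_ms(6e-5, 50000)),
    c("cost_fit_kit", "gamma", 25, 25 / 6),
    c("cost_colonoscopy", "gamma", 25, 25 / 550),
    c("crc_cost_multiplier", "gamma", 44.4, 44.4),
    c("utility_decrement_multiplier", "lognormal", 0, 0.15),
    c("nh_onset_multiplier", "lognormal", 0, 0.10)
  )
  out <- tibble::tibble(
    parameter = vapply(rows, `[[`, "", 1),
    family = vapply(rows, `[[`, "", 2),
    shape1 = as.numeric(vapply(rows, `[[`, "", 3)),
    shape2 = as.numeric(vapply(rows, `[[`, "", 4))
  )
  class(out) <- c("parameter_distributions", class(tibble::tibble()))
  out
}

#' Fix all distributions at their point estimates
#'
#' @param dists A [parameter_distributions()] tibble.
#' @return The same tibble with every family set to `fixed` at the
#'   distribution mean.
#' @export
fix_distributions <- function(dists) {
  mean_of <- function(family, s1, s2) {
    switch(family,
           beta = s1 / (s1 + s2),
           gamma = s1 / s2,
           lognormal = exp(s1 + s2^2 / 2),
           fixed = s1,
           stop("unknown family: ", family, call. = FALSE))
  }
  dists$shape1 <- vapply(seq_len(nrow(dists)),
                         function(i) mean_of(dists$family[i], dists$shape1[i], dists$shape2[i]),
                         numeric(1))
  dists$family <- "fixed"
  dists$shape2 <- 0
  dists
}

#' Sample one concrete parameter set
#'
#' Independent draws from each declared distribution; reproducible for a
#' fixed seed. Probability-valued draws are guaranteed to lie in `[0, 1]`
#' and cost-valued draws to be nonnegative by the families themselves.
#'
#' @param dists A [parameter_distributions()] tibble.
#' @param seed Integer seed.
#' @return A named numeric vector of sampled values.
#' @export
#' @examples
#' sample_parameters(parameter_distributions(), seed = 1)
sample_parameters <- function(dists, seed = 1) {
  ok <- dists$family %in% c("beta", "gamma", "lognormal", "fixed")
  if (!all(ok)) stop("invalid distribution family: ",
                     paste(unique(dists$family[!ok]), collapse = ", "), call. = FALSE)
  if (any(dists$family != "fixed" & (!is.finite(dists$shape1) | !is.finite(dists$shape2)))) {
    stop("non-finite distribution shape", call. = FALSE)
  }
  draw <- function() {
    vapply(seq_len(nrow(dists)), function(i) {
      switch(dists$family[i],
             beta = stats::rbeta(1, dists$shape1[i], dists$shape2[i]),
             gamma = stats::rgamma(1, shape = dists$shape1[i], rate = dists$shape2[i]),
             lognormal = stats::rlnorm(1, dists$shape1[i], dists$shape2[i]),
             fixed = dists$shape1[i])
    }, numeric(1))
  }
  stats::setNames(.with_seed(seed, draw()), dists$parameter)
}

.dist_means <- function(dists) {
  vapply(seq_len(nrow(dists)), function(i) {
    switch(dists$family[i],
           beta = dists$shape1[i] / (dists$shape1[i] + dists$shape2[i]),
           gamma = dists$shape1[i] / dists$shape2[i],
           lognormal = exp(dists$shape1[i] + dists$shape2[i]^2 / 2),
           fixed = dists$shape1[i],
           stop("unknown family: ", dists$family[i], call. = FALSE))
  }, numeric(1)) |> stats::setNames(dists$parameter)
}

#' Apply a sampled parameter set to the model inputs
#'
#' Each sampled value perturbs its base input multiplicatively through the
#' ratio of the draw to its distribution mean, so the distributions are
#' centred on the deterministic point estimates: a draw at the mean (as
#' produced by [fix_distributions()]) leaves the inputs exactly unchanged.
#' Probabilities are clipped to `[0, 1]` after scaling. FIT sensitivity and
#' specificity are perturbed at the threshold named in `inputs$config`.
#'
#' @param inputs A [synth_inputs()] bundle.
#' @param draws Named draws from [sample_parameters()].
#' @param dists The [parameter_distributions()] the draws came from (supplies
#'   the centring means).
#' @return A modified inputs bundle.
#' @export
apply_psa_sample <- function(inputs, draws, dists = parameter_distributions()) {
  ref <- .dist_means(dists)
  ratio <- function(nm) {
    if (is.null(draws[[nm]]) || !nm %in% names(ref)) 1 else unname(draws[[nm]] / ref[[nm]])
  }
  clip01 <- function(x) pmin(pmax(x, 0), 1)
  out <- inputs
  thr_i <- .threshold_index(inputs$config$threshold)
  chars <- inputs$test_chars
  for (si in 1:2) {
    sx <- .sex_levels[si]
    chars$sensitivity[3:6, si, thr_i] <-
      clip01(chars$sensitivity[3:6, si, thr_i] * ratio(paste0("fit_sens_crc_", sx)))
    chars$sensitivity[2, si, thr_i] <-
      clip01(chars$sensitivity[2, si, thr_i] * ratio(paste0("fit_sens_hr_", sx)))
    chars$specificity[si, thr_i] <-
      clip01(chars$specificity[si, thr_i] * ratio(paste0("fit_spec_", sx)))
    rows <- inputs$uptake$table$sex == sx
    out$uptake$table$p[rows] <-
      clip01(inputs$uptake$table$p[rows] * ratio(paste0("uptake_", sx)))
  }
  chars$complications[["perforation"]] <-
    clip01(chars$complications[["perforation"]] * ratio("perforation"))
  chars$complications[["major_bleed"]] <-
    clip01(chars$complications[["major_bleed"]] * ratio("major_bleed"))
  chars$complications[["death"]] <-
    clip01(chars$complications[["death"]] * ratio("colonoscopy_death"))
  out$test_chars <- chars

  econ <- inputs$econ
  econ$unit_costs[["fit_kit"]] <- econ$unit_costs[["fit_kit"]] * ratio("cost_fit_kit")
  econ$unit_costs[["colonoscopy"]] <- econ$unit_costs[["colonoscopy"]] * ratio("cost_colonoscopy")
  econ$crc_treatment$cost <- econ$crc_treatment$cost * ratio("crc_cost_multiplier")
  econ$utility_decrements <- pmin(econ$utility_decrements * ratio("utility_decrement_multiplier"), 1)
  out$econ <- econ

  p <- out$nh_params
  p$progression[, , 1] <- pmin(0.99, p$progression[, , 1] * ratio("nh_onset_multiplier"))
  out$nh_params <- p
  out
}

#' Run the probabilistic sensitivity analysis
#'
#' For each of `n_samples` parameter draws, rebuilds the model inputs,
#' simulates every strategy on the shared population with a sample-specific
#' event seed (common random numbers within the sample), and stores the
#' per-person mean discounted cost and QALYs per strategy.
#'
#' @param dists A [parameter_distributions()] tibble.
#' @param strategies Named list of `screening_strategy` objects.
#' @param population_config A [population_config()]; `n` is the number of
#'   individuals per sample.
#' @param n_samples Number of parameter samples (default 200).
#' @param seed Master seed; sample `s` draws parameters with seed
#'   `seed + s` and simulates with `child_seed(seed, s)`.
#' @param inputs Base inputs ([synth_inputs()]); rebuilt per sample.
#' @return A list of class `crc_psa`: `samples` (tibble `sample`, `strategy`,
#'   `cost`, `qaly`), `wtp`, `n_per_sample`.
#' @export
run_psa <- function(dists, strategies, population_config,
                    n_samples = 200, seed = 1, inputs = synth_inputs()) {
  stopifnot(n_samples >= 1)
  population <- generate_population(population_config)
  samples <- vector("list", n_samples)
  for (s in seq_len(n_samples)) {
    draws <- sample_parameters(dists, seed = seed + s)
    inputs_s <- apply_psa_sample(inputs, draws, dists)
    ev_seed <- child_seed(seed, s)
    res <- evaluate_strategies(population, strategies, inputs_s, seed = ev_seed)
    samples[[s]] <- tibble::tibble(
      sample = s,
      strategy = names(strategies),
      cost = vapply(res, function(r) mean(r$cost), numeric(1)),
      qaly = vapply(res, function(r) mean(r$qaly), numeric(1))
    )
  }
  structure(
    list(samples = dplyr::bind_rows(samples),
         wtp = inputs$econ$wtp,
         n_per_sample = population_config$n,
         strategies = names(strategies)),
    class = "crc_psa"
  )
}

#' Cost-effectiveness acceptability curve
#'
#' At each willingness-to-pay value, the probability that each strategy is
#' the most cost-effective option: the fraction of PSA samples in which it
#' attains the highest net monetary benefit (`wtp * qaly - cost`), with exact
#' ties split equally among the tied strategies.
#'
#' @param psa_result A `crc_psa` object from [run_psa()], or a tibble with
#'   columns `sample`, `strategy`, `cost`, `qaly`.
#' @param wtp_grid Willingness-to-pay grid (default 0 to 50,000 in steps of
#'   1,000).
#' @return A tibble of class `crc_ceac`: `wtp`, `strategy`, `probability`.
#'   Probabilities sum to 1 across strategies at each `wtp`.
#' @export
ceac <- function(psa_result, wtp_grid = seq(0, 50000, by = 1000)) {
  samples <- if (inherits(psa_result, "crc_psa")) psa_result$samples else psa_result
  if (nrow(samples) == 0) stop("no PSA samples", call. = FALSE)
  wide <- tidyr::pivot_wider(samples[c("sample", "strategy", "cost", "qaly")],
                             names_from = "strategy",
                             values_from = c("cost", "qaly"))
  strategies <- unique(samples$strategy)
  n_s <- length(strategies)
  n <- nrow(wide)
  cost <- as.matrix(wide[paste0("cost_", strategies)])
  qaly <- as.matrix(wide[paste0("qaly_", strategies)])
  out <- purrr::map(wtp_grid, function(w) {
    nmb_m <- w * qaly - cost
    best <- nmb_m == apply(nmb_m, 1, max)
    weights <- best / rowSums(best)
    tibble::tibble(wtp = w, strategy = strategies,
                   probability = unname(colSums(weights)) / n)
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("crc_ceac", class(tibble::tibble()))
  out
}
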