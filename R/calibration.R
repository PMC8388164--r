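# Calibration of the natural-history parameters to incidence/prevalence
# targets.
#
# The search matches model outputs (age/sex incidence, adenoma prevalence,
# undiagnosed CRC prevalence, cumulative-incidence constraints), not latent
# transition rates: identifiability of individual rates is not claimed.
# Scheme: Latin-hypercube screening over the box priors, then Nelder-Mead
# refinement from the best draw. LHS points are generated in fixed-size
# seeded blocks so a larger budget evaluates a superset of a smaller one,
# which makes "more budget never worsens the best loss" hold by construction
# for the screening stage. Any refinement budget left over after convergence
# is spent on further LHS points, so the number of evaluated parameter sets
# always equals the budget exactly.

#' Calibration loss
#'
#' Weighted sum of squared relative errors between simulated summaries and
#' targets, joined on (class, sex, age band). Zero if and only if every
#' summary matches its target exactly.
#'
#' @param simulated_summaries Tibble with columns `class`, `sex`, `age_lo`,
#'   `age_hi`, `value`.
#' @param targets A [synth_targets()]-shaped tibble (same index columns plus
#'   `value` and optionally `weight`).
#' @param weights Optional numeric vector overriding `targets$weight`.
#' @return Nonnegative scalar loss.
#' @export
#' @examples
#' t <- tibble::tibble(class = "incidence", sex = "male",
#'                     age_lo = 60, age_hi = 64, value = 0.010)
#' s <- t; s$value <- 0.012
#' calibration_loss(s, t)  # (0.2)^2 = 0.04
calibration_loss <- function(simulated_summaries, targets, weights = NULL) {
  key <- c("class", "sex", "age_lo", "age_hi")
  joined <- dplyr::inner_join(
    dplyr::rename(simulated_summaries[c(key, "value")], simulated = "value"),
    targets, by = key
  )
  if (nrow(joined) != nrow(targets) || nrow(joined) != nrow(simulated_summaries)) {
    stop("simulated summaries and targets do not share the same index",
         call. = FALSE)
  }
  w <- weights %||% joined$weight %||% rep(1, nrow(joined))
  rel <- (joined$simulated - joined$value) / pmax(abs(joined$value), 1e-12)
  sum(w * rel^2)
}

.target_rel_errors <- function(simulated, targets) {
  key <- c("class", "sex", "age_lo", "age_hi")
  joined <- dplyr::inner_join(
    dplyr::rename(simulated[c(key, "value")], simulated = "value"),
    targets, by = key
  )
  joined$rel_error <- (joined$simulated - joined$value) / pmax(abs(joined$value), 1e-12)
  tibble::as_tibble(joined)
}

# Summaries from a microsimulated cohort, using the per-cycle tallies.
.microsim_summaries <- function(params, index, n_sim, seed) {
  pop <- generate_population(population_config(n = n_sim, seed = seed))
  res <- simulate_strategy(pop, params, strategy = NULL, seed = seed,
                           horizon_age = max(index$age_hi))
  tal <- attr(res, "tallies")
  value <- numeric(nrow(index))
  for (i in seq_len(nrow(index))) {
    t <- tal[tal$sex == as.character(index$sex[i]), ]
    lo <- index$age_lo[i]; hi <- index$age_hi[i]
    rows <- t$age >= lo & t$age <= hi
    value[i] <- switch(
      as.character(index$class[i]),
      incidence = sum(t$new_dx[rows]) / sum(t$alive_start[rows]),
      adenoma_prevalence = sum(t$adenoma_lr[rows] + t$adenoma_hr[rows]) / sum(t$alive[rows]),
      undiagnosed_crc_prevalence = sum(t$crc_undx[rows]) / sum(t$alive[rows]),
      cum_incidence = cumulative_incidence(res, as.character(index$sex[i]), lo, hi - lo),
      stop("unknown target class: ", index$class[i], call. = FALSE)
    )
  }
  out <- index[c("class", "sex", "age_lo", "age_hi")]
  out$value <- value
  tibble::as_tibble(out)
}

# Latin-hypercube points in [0,1]^d, generated in fixed seeded blocks so the
# i-th point is independent of the total number requested.
.lhs_points <- function(n, d, seed, block_size = 100L) {
  n_blocks <- ceiling(n / block_size)
  pts <- matrix(0, n_blocks * block_size, d)
  for (b in seq_len(n_blocks)) {
    block <- .with_seed(child_seed(seed, 7717L + b), lhs::randomLHS(block_size, d))
    pts[((b - 1L) * block_size + 1L):(b * block_size), ] <- block
  }
  pts[seq_len(n), , drop = FALSE]
}

#' Calibrate natural-history parameters to targets
#'
#' Latin-hypercube screening over the prior box followed by Nelder-Mead
#' refinement of the best draw. Every evaluated parameter set is recorded; a
#' set is *accepted* when, for each target class, its largest absolute
#' relative error is within the class tolerance. The default loss evaluator
#' propagates the deterministic cohort model (the exact expectation of the
#' microsimulated summaries); `method = "microsim"` evaluates each set by
#' simulating `n_sim` individuals instead.
#'
#' @param targets A [synth_targets()] tibble.
#' @param prior_ranges Tibble `parameter`, `lower`, `upper` covering the
#'   seven parameters of the natural-history family (see
#'   [default_prior_ranges()]). A collapsed range (`lower == upper`) pins the
#'   parameter.
#' @param budget Total number of loss evaluations (>= 1).
#' @param n_sim Individuals per microsimulated loss evaluation (used only
#'   when `method = "microsim"`).
#' @param seed Integer seed for the whole search.
#' @param method `"cohort"` (deterministic, default) or `"microsim"`.
#' @param tolerance Named per-class relative-error acceptance bounds;
#'   defaults to the targets' `tolerance` attribute.
#' @param refine_frac Fraction of the budget reserved for Nelder-Mead
#'   refinement (default 0.4).
#' @return A list of class `calibration_result`: `accepted` (tibble of
#'   accepted parameter sets with losses, sorted by loss), `losses` (all
#'   evaluated losses, sorted), `best_theta`, `best_params` (an
#'   [nh_params()]), `best_loss`, `diagnostics` (per-target relative errors
#'   of the best set), `n_evaluations`, `converged` (TRUE if at least one
#'   set was accepted).
#' @export
calibrate <- function(targets, prior_ranges = default_prior_ranges(),
                      budget = 2000, n_sim = 20000, seed = 1,
                      method = c("cohort", "microsim"),
                      tolerance = NULL, refine_frac = 0.4) {
  method <- match.arg(method)
  stopifnot(budget >= 1)
  tolerance <- tolerance %||% attr(targets, "tolerance") %||%
    c(incidence = 0.05, adenoma_prevalence = 0.05,
      undiagnosed_crc_prevalence = 0.05, cum_incidence = 0.05)
  pr <- prior_ranges[match(names(theta_template()), prior_ranges$parameter), ]
  if (anyNA(pr$parameter)) stop("prior_ranges must cover all model parameters", call. = FALSE)
  stopifnot(all(pr$upper >= pr$lower))
  d <- nrow(pr)
  index <- targets[c("class", "sex", "age_lo", "age_hi")]

  classes <- sort(unique(as.character(targets$class)))
  evals <- new.env(parent = emptyenv())
  evals$theta <- vector("list", budget)
  evals$loss <- rep(NA_real_, budget)
  evals$maxerr <- matrix(NA_real_, budget, length(classes),
                         dimnames = list(NULL, classes))
  evals$k <- 0L
  eval_theta <- function(theta) {
    if (evals$k >= budget) rlang::abort("budget exhausted", class = "crcstrat_budget")
    params <- .nh_params_from_theta(theta)
    sim <- if (method == "cohort") {
      .summaries_for_index(params, index)
    } else {
      .microsim_summaries(params, index, n_sim = n_sim,
                          seed = child_seed(seed, 991L))
    }
    loss <- calibration_loss(sim, targets)
    d <- .target_rel_errors(sim, targets)
    evals$k <- evals$k + 1L
    evals$theta[[evals$k]] <- theta
    evals$loss[evals$k] <- loss
    evals$maxerr[evals$k, ] <- tapply(abs(d$rel_error), as.character(d$class), max)[classes]
    loss
  }
  from_unit <- function(u) {
    theta <- pr$lower + u * (pr$upper - pr$lower)
    names(theta) <- pr$parameter
    theta
  }

  n_refine <- if (budget >= 20) floor(refine_frac * budget) else 0L
  n_lhs <- budget - n_refine
  pts <- .lhs_points(budget, d, seed)   # enough for LHS + any leftover fill
  for (i in seq_len(n_lhs)) eval_theta(from_unit(pts[i, ]))

  if (n_refine > 0L) {
    best0 <- which.min(evals$loss[seq_len(evals$k)])
    start <- evals$theta[[best0]]
    free <- which(pr$upper > pr$lower)
    if (length(free) >= 1) {
      to_unit <- function(theta) (theta[free] - pr$lower[free]) / (pr$upper[free] - pr$lower[free])
      logit <- function(p) log(p / (1 - p))
      inv_logit <- function(x) 1 / (1 + exp(-x))
      fn <- function(z) {
        u <- rep(0, d)
        u[free] <- inv_logit(z)
        u[-free] <- 0
        th <- from_unit(u)
        th[-free] <- start[-free]
        eval_theta(th)
      }
      z0 <- logit(pmin(pmax(to_unit(start), 1e-6), 1 - 1e-6))
      tryCatch(
        stats::optim(z0, fn, method = "Nelder-Mead",
                     control = list(maxit = 10 * n_refine, reltol = 1e-10)),
        crcstrat_budget = function(e) NULL
      )
    }
    # spend any leftover budget on further LHS points
    i <- n_lhs
    while (evals$k < budget) {
      i <- i + 1L
      eval_theta(from_unit(pts[i, ]))
    }
  }

  loss <- evals$loss[seq_len(evals$k)]
  thetas <- do.call(rbind, evals$theta[seq_len(evals$k)])
  colnames(thetas) <- pr$parameter
  diag_for <- function(theta) {
    params <- .nh_params_from_theta(theta)
    .target_rel_errors(.summaries_for_index(params, index), targets)
  }
  if (length(tolerance) == 1 && is.null(names(tolerance))) {
    tolerance <- stats::setNames(rep(tolerance, length(classes)), classes)
  }
  tol_by_class <- tolerance[classes]
  if (anyNA(tol_by_class)) stop("tolerance must name every target class", call. = FALSE)
  accepted_flag <- vapply(seq_len(evals$k), function(i) {
    all(evals$maxerr[i, ] <= tol_by_class)
  }, logical(1))
  ord <- order(loss)
  accepted_idx <- ord[accepted_flag[ord]]
  accepted <- tibble::as_tibble(cbind(
    tibble::tibble(loss = loss[accepted_idx]),
    tibble::as_tibble(thetas[accepted_idx, , drop = FALSE])
  ))
  best <- ord[1]
  best_theta <- evals$theta[[best]]
  res <- structure(
    list(
      accepted = accepted,
      losses = sort(loss),
      best_theta = best_theta,
      best_params = .nh_params_from_theta(best_theta),
      best_loss = loss[best],
      diagnostics = diag_for(best_theta),
      n_evaluations = evals$k,
      tolerance = tolerance,
      converged = nrow(accepted) > 0
    ),
    class = "calibration_result"
  )
  if (!res$converged) {
    rlang::warn(sprintf("calibration failed: no parameter set met the tolerance within budget %d (best loss %.4g)",
                        budget, res$best_loss),
                class = "crcstrat_calibration_failure")
  }
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  evaluations: %d | accepted: %d | best loss: %.4g | %s\n",
              x$n_evaluations, nrow(x$accepted), x$best_loss,
              if (x$converged) "converged" else "FAILED"))
  cat(sprintf("  worst |relative error| of best set: %.3f\n",
              max(abs(x$diagnostics$rel_error))))
  invisible(x)
}
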