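# broom-style tidiers.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an incremental comparison
#'
#' @param x A `crc_comparison` from [compare_strategies()].
#' @param ... Unused.
#' @return A plain tibble, one row per (strategy, stratum).
#' @method tidy crc_comparison
#' @export
tidy.crc_comparison <- function(x, ...) {
  out <- x
  class(out) <- class(tibble::tibble())
  out
}

#' One-row summary of an incremental comparison
#'
#' @param x A `crc_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: comparator, willingness to pay, the strategy
#'   with the highest overall net monetary benefit and its NMB.
#' @method glance crc_comparison
#' @export
glance.crc_comparison <- function(x, ...) {
  ov <- x[x$stratum == "overall" & x$strategy != attr(x, "comparator"), ]
  best <- ov[which.max(ov$nmb), ]
  tibble::tibble(
    comparator = attr(x, "comparator"),
    wtp = attr(x, "wtp"),
    n_strategies = length(unique(x$strategy)),
    best_strategy = best$strategy,
    best_nmb = best$nmb
  )
}

#' Tidy PSA samples
#'
#' @param x A `crc_psa` from [run_psa()].
#' @param ... Unused.
#' @return The per-sample (strategy, cost, QALY) tibble.
#' @method tidy crc_psa
#' @export
tidy.crc_psa <- function(x, ...) x$samples

#' One-row summary of a PSA
#'
#' @param x A `crc_psa`.
#' @param ... Unused.
#' @return A one-row tibble with sample counts and per-strategy means folded
#'   into list columns.
#' @method glance crc_psa
#' @export
glance.crc_psa <- function(x, ...) {
  tibble::tibble(
    n_samples = length(unique(x$samples$sample)),
    n_per_sample = x$n_per_sample,
    n_strategies = length(x$strategies),
    wtp = x$wtp
  )
}

#' Tidy accepted calibration parameter sets
#'
#' @param x A `calibration_result` from [calibrate()].
#' @param ... Unused.
#' @return Tibble of accepted parameter sets with losses (sorted).
#' @method tidy calibration_result
#' @export
tidy.calibration_result <- function(x, ...) x$accepted

#' One-row summary of a calibration run
#'
#' @param x A `calibration_result`.
#' @param ... Unused.
#' @return A one-row tibble: evaluations, accepted count, best loss, worst
#'   absolute relative target error of the best set, convergence flag.
#' @method glance calibration_result
#' @export
glance.calibration_result <- function(x, ...) {
  tibble::tibble(
    n_evaluations = x$n_evaluations,
    n_accepted = nrow(x$accepted),
    best_loss = x$best_loss,
    worst_rel_error = max(abs(x$diagnostics$rel_error)),
    converged = x$converged
  )
}
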