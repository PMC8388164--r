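# Internal helpers shared across modules.

.sex_levels <- c("male", "female")

sex_to_index <- function(sex) {
  if (is.factor(sex)) sex <- as.character(sex)
  if (is.numeric(sex)) {
    if (!all(sex %in% c(1, 2))) stop("numeric sex codes must be 1 (male) or 2 (female)", call. = FALSE)
    return(as.integer(sex))
  }
  i <- match(sex, .sex_levels)
  if (anyNA(i)) stop("sex must be 'male' or 'female'", call. = FALSE)
  i
}

index_to_sex <- function(i) factor(.sex_levels[i], levels = .sex_levels)

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Deterministic per-(cycle, stream) uniform draws. Stream ids must stay
# below 1009 so that (cycle, stream) pairs map to distinct seeds.
.cycle_runif <- function(n, seed, cycle, stream) {
  set.seed((as.numeric(seed) + 1009 * cycle + stream) %% 2147483647)
  stats::runif(n)
}

#' Derive a reproducible child seed
#'
#' Fans a master seed out into independent child streams (one per
#' probabilistic-sensitivity-analysis sample, for example) while keeping the
#' result inside the 32-bit integer range R requires of `set.seed()`.
#'
#' @param seed Master integer seed.
#' @param i Positive integer index of the child stream.
#' @return An integer seed.
#' @export
#' @examples
#' child_seed(42, 1)
child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + as.numeric(i) * 100003) %% 2147483647)
}

.assert_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(what, " must lie in [0, 1]", call. = FALSE)
  }
  invisible(x)
}

.match_threshold <- function(threshold) {
  if (is.numeric(threshold)) threshold <- paste0("FIT", threshold)
  labels <- c("FIT20", "FIT80", "FIT120")
  if (!is.character(threshold) || length(threshold) != 1 || !threshold %in% labels) {
    stop("unknown FIT threshold label: must be one of FIT20, FIT80, FIT120",
         call. = FALSE)
  }
  threshold
}

.threshold_index <- function(threshold) {
  match(.match_threshold(threshold), c("FIT20", "FIT80", "FIT120"))
}
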