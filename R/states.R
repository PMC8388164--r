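# The nine-state adenoma-carcinoma disease model.
#
# Undiagnosed individuals progress along the strictly sequential chain
#   normal -> low-risk adenoma -> high-risk adenoma -> CRC A -> B -> C -> D
# and can die of other causes at any point; the two death states are
# absorbing. Diagnosis (by screening or symptomatic presentation) freezes the
# underlying stage and switches the individual onto stage-specific CRC
# survival.

.ST_NORMAL <- 1L
.ST_AD_LR <- 2L
.ST_AD_HR <- 3L
.ST_CRC_A <- 4L
.ST_CRC_D <- 7L
.ST_DEATH_CRC <- 8L
.ST_DEATH_OTHER <- 9L

#' Health states of the disease model
#'
#' @return Character vector of the nine health-state labels, in progression
#'   order: normal epithelium, low- and high-risk adenoma, colorectal cancer
#'   stages A-D, and death from CRC or from other causes.
#' @export
#' @examples
#' health_states()
health_states <- function() {
  c("normal", "adenoma_low_risk", "adenoma_high_risk",
    "crc_A", "crc_B", "crc_C", "crc_D", "death_crc", "death_other")
}

state_to_index <- function(state) {
  if (is.factor(state)) state <- as.character(state)
  if (is.numeric(state)) {
    if (!all(state %in% 1:9)) stop("numeric state codes must be in 1..9", call. = FALSE)
    return(as.integer(state))
  }
  i <- match(state, health_states())
  if (anyNA(i)) stop("unknown health state: ", paste(setdiff(state, health_states()), collapse = ", "),
                     call. = FALSE)
  i
}

index_to_state <- function(i) factor(health_states()[i], levels = health_states())

stage_labels <- function() c("A", "B", "C", "D")
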