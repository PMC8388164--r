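# Shared fixtures. The default synthetic inputs are deterministic (the
# internal root-finding is cached), so building them once per test run is
# cheap and every test sees the same model world.

the_inputs <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- synth_inputs()
    val
  }
})

small_pop <- function(n = 2000, seed = 1, female_fraction = 0.5, ...) {
  generate_population(population_config(n = n, seed = seed,
                                        female_fraction = female_fraction, ...))
}

# Natural-history parameters with every disease/death probability zeroed,
# as a frozen baseline that tests can selectively switch back on.
frozen_params <- function(ages = 30:100) {
  n_age <- length(ages)
  nh_params(
    progression = array(0, c(n_age, 2, 6)),
    presentation = array(0, c(n_age, 2, 4)),
    crc_survival = array(0, c(n_age, 2, 4, 6)),
    life_table = matrix(0, n_age, 2),
    ages = ages
  )
}

# Test characteristics with deterministic switches, for forced-path tests.
perfect_chars <- function(sensitivity = 1, specificity = 1,
                          colonoscopy = 1, complications = 0) {
  chars <- synth_test_characteristics()
  chars$sensitivity[] <- sensitivity
  chars$specificity[] <- specificity
  chars$colonoscopy_sensitivity[] <- colonoscopy
  chars$complications[] <- complications
  chars
}

full_uptake <- function() {
  up <- synth_uptake_table(followup_factor = 1)
  up$table$p <- 1
  up
}

# Brute-force one-step transition matrix over the nine states for the
# progression/other-death kernel, written independently of the package's
# vectorised implementation (explicit scalar loops from the model
# definition). Serves as the Markov oracle.
brute_force_matrix <- function(age, sex, params) {
  states <- health_states()
  m <- matrix(0, 9, 9, dimnames = list(states, states))
  si <- if (sex == "male") 1 else 2
  ai <- match(age, params$ages)
  q <- params$life_table[ai, si]
  for (s in 1:9) {
    if (s >= 8) {
      m[s, s] <- 1
      next
    }
    p_adv <- if (s <= 6) params$progression[ai, si, s] else 0
    m[s, 9] <- q
    m[s, s] <- (1 - q) * (1 - p_adv)
    if (s <= 6) m[s, s + 1] <- (1 - q) * p_adv
  }
  m
}
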