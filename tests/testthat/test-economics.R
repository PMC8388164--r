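test_that("discounting matches the closed form", {
  expect_equal(discount(100, 0, 0.035), 100)
  expect_equal(discount(100, 5, 0), 100)
  expect_equal(discount(100, 1, 0.035), 100 / 1.035, tolerance = 1e-12)
  expect_equal(discount(100, 2, 0.035), 100 / 1.035^2, tolerance = 1e-12)
  expect_error(discount(100, -1, 0.035), ">= 0")
})

test_that("accrual reproduces a hand-computed five-cycle history", {
  econ <- synth_economic_inputs()
  # one colonoscopy at cycle 2 (age 32), stage-A diagnosis at cycle 3,
  # alive throughout
  h <- tibble::tibble(
    id = 1L, cycle = 1:5, age = 31:35,
    alive_at_end = TRUE,
    diagnosed = c(FALSE, FALSE, TRUE, TRUE, TRUE),
    dx_stage = factor(c(NA, NA, "A", "A", "A"), levels = c("A", "B", "C", "D")),
    years_since_dx = c(NA, NA, 0L, 1L, 2L),
    fit_kits = c(0L, 1L, 0L, 0L, 0L),
    colonoscopies = c(0L, 1L, 0L, 0L, 0L),
    polypectomies = 0L,
    perforation = FALSE,
    major_bleed = FALSE
  )
  got <- accrue(h, econ)
  v <- 1 / 1.035
  # costs: kit + colonoscopy at cycle 2; treatment 11000 (yr 0) at cycle 3,
  # 1800 (yrs 1-4) at cycles 4 and 5
  exp_cost <- (6 + 550) * v^2 + 11000 * v^3 + 1800 * v^4 + 1800 * v^5
  # QALYs: baseline 0.94 (ages 31-35 in band 30-39), minus 0.05 while diagnosed
  exp_qaly <- 0.94 * (v + v^2) + (0.94 - 0.05) * (v^3 + v^4 + v^5)
  expect_equal(got$cost, exp_cost, tolerance = 1e-12)
  expect_equal(got$qaly, exp_qaly, tolerance = 1e-12)
})

test_that("accrual is linear in unit costs and leaves QALYs alone", {
  econ <- synth_economic_inputs()
  h <- tibble::tibble(
    id = 1L, cycle = 1:3, age = 31:33, alive_at_end = c(TRUE, TRUE, FALSE),
    diagnosed = FALSE,
    dx_stage = factor(NA_character_, levels = c("A", "B", "C", "D")),
    years_since_dx = NA_integer_,
    fit_kits = c(1L, 0L, 0L), colonoscopies = c(0L, 1L, 0L),
    polypectomies = c(0L, 1L, 0L), perforation = c(FALSE, TRUE, FALSE),
    major_bleed = FALSE
  )
  base <- accrue(h, econ)
  econ2 <- econ
  econ2$unit_costs <- econ$unit_costs * 2
  doubled <- accrue(h, econ2)
  expect_equal(doubled$cost, 2 * base$cost, tolerance = 1e-12)
  expect_equal(doubled$qaly, base$qaly)
  # dying at cycle 3 start+1: no QALY accrues for cycle 3
  expect_equal(base$qaly,
               discount(0.94, 1, 0.035) +
                 discount(max(0, 0.94 - 0.10), 2, 0.035),
               tolerance = 1e-12)
})

test_that("engine accrual equals history-based accrual", {
  inputs <- the_inputs()
  pop <- small_pop(n = 400, seed = 77)
  res <- simulate_strategy(pop, inputs$nh_params, make_uniform(58),
                           inputs$test_chars, inputs$uptake, inputs$econ,
                           seed = 78, record_history = TRUE)
  h <- attr(res, "history")
  via_history <- accrue(h, inputs$econ)
  merged <- dplyr::left_join(res, via_history, by = "id", suffix = c("", "_h"))
  merged$cost_h[is.na(merged$cost_h)] <- 0
  merged$qaly_h[is.na(merged$qaly_h)] <- 0
  expect_equal(merged$cost, merged$cost_h, tolerance = 1e-10)
  expect_equal(merged$qaly, merged$qaly_h, tolerance = 1e-10)
})

test_that("ICER quadrants and worked examples are right", {
  expect_equal(icer(-1, 0.001), "dominant")
  expect_equal(icer(1, -0.001), "dominated")
  expect_equal(icer(1, 0), "dominated")
  expect_equal(icer(0, 0), "equivalent")
  expect_equal(icer(0.55, 0.0004), 1375)
  expect_equal(icer(3.28, 0.0012), 2733.333, tolerance = 1e-4)
})

test_that("NMB matches its definition and the ICER decision rule", {
  expect_equal(nmb(0, 0, 20000), 0)
  expect_equal(nmb(0.55, 0.0004, 20000), 7.45)
  set.seed(1)
  for (i in 1:200) {
    dc <- stats::rnorm(1)
    dq <- stats::runif(1, 1e-6, 0.01)
    r <- icer(dc, dq)
    positive_nmb <- nmb(dc, dq, 20000) > 0
    if (identical(r, "dominant")) {
      expect_true(positive_nmb)
    } else {
      expect_equal(positive_nmb, r < 20000)
    }
  }
})

test_that("per-100k rates scale linearly", {
  expect_equal(per_100k(0, 123), 0)
  expect_equal(per_100k(5, 1000), 500)
  expect_equal(per_100k(7, 300) + per_100k(13, 300), per_100k(20, 300))
  expect_error(per_100k(1, 0), "> 0")
})

test_that("a strategy compared with itself under shared streams has zero increments", {
  inputs <- the_inputs()
  pop <- small_pop(n = 2000, seed = 55)
  s <- make_uniform(60)
  res <- list(
    a = simulate_strategy(pop, inputs$nh_params, s, inputs$test_chars,
                          inputs$uptake, inputs$econ, seed = 56),
    b = simulate_strategy(pop, inputs$nh_params, s, inputs$test_chars,
                          inputs$uptake, inputs$econ, seed = 56)
  )
  cmp <- compare_strategies(res, "a", inputs$econ)
  b <- cmp[cmp$strategy == "b", ]
  expect_true(all(b$d_cost == 0))
  expect_true(all(b$d_qaly == 0))
  expect_true(all(b$nmb == 0))
  expect_true(all(b$icer_label == "equivalent"))
})

test_that("overall increments are the stratum mean on a balanced population", {
  inputs <- the_inputs()
  pop <- small_pop(n = 2000, seed = 60)
  pop$sex <- factor(rep(c("male", "female"), 1000), levels = c("male", "female"))
  res <- evaluate_strategies(pop, list(comp = make_uniform(60),
                                       alt = make_uniform(58)),
                             inputs, seed = 61)
  cmp <- compare_strategies(res, "comp", inputs$econ)
  alt <- cmp[cmp$strategy == "alt", ]
  expect_equal(alt$d_qaly[alt$stratum == "overall"],
               mean(alt$d_qaly[alt$stratum %in% c("male", "female")]),
               tolerance = 1e-12)
  expect_equal(alt$d_cost[alt$stratum == "overall"],
               mean(alt$d_cost[alt$stratum %in% c("male", "female")]),
               tolerance = 1e-12)
})

test_that("discounting shrinks totals and higher rates shrink increments", {
  pop <- small_pop(n = 3000, seed = 65)
  run_at <- function(rate) {
    inputs <- synth_inputs(synth_config(discount_costs = rate, discount_qalys = rate))
    res <- evaluate_strategies(pop, list(comp = make_uniform(60),
                                         alt = make_uniform(58)),
                               inputs, seed = 66)
    cmp <- compare_strategies(res, "comp", inputs$econ)
    cmp[cmp$strategy == "alt" & cmp$stratum == "overall", ]
  }
  r0 <- run_at(0)
  r15 <- run_at(0.015)
  r35 <- run_at(0.035)
  r50 <- run_at(0.05)
  # undiscounted totals dominate discounted ones
  expect_gt(r0$qaly_pp, r35$qaly_pp)
  expect_gt(r0$cost_pp, r35$cost_pp)
  # identical event histories (same seed): increment magnitudes shrink as the
  # rate rises
  expect_gte(abs(r15$d_qaly), abs(r35$d_qaly))
  expect_gte(abs(r35$d_qaly), abs(r50$d_qaly))
  expect_gte(abs(r15$nmb), abs(r35$nmb))
  expect_gte(abs(r35$nmb), abs(r50$nmb))
})
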