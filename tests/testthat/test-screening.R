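test_that("FIT results follow sensitivity and specificity switches", {
  pop <- small_pop(n = 10, seed = 1)
  chars <- perfect_chars(sensitivity = 1, specificity = 1)
  crc <- pop
  crc$state <- index_to_state(rep(4L, 10))
  expect_true(all(fit_result(crc, chars, "FIT120", seed = 2) == "positive"))
  expect_true(all(fit_result(pop, chars, "FIT120", seed = 2) == "negative"))

  dxed <- pop
  dxed$dx_route <- factor(rep("clinical", 10), levels = c("screen", "clinical", "none"))
  expect_error(fit_result(dxed, chars, "FIT120", seed = 1), "diagnosed")
})

test_that("false-positive rate matches one minus specificity", {
  n <- 50000
  pop <- small_pop(n = n, seed = 6, female_fraction = 0)
  chars <- synth_test_characteristics()
  chars$specificity[] <- 0.95
  res <- fit_result(pop, chars, "FIT120", seed = 7)
  phat <- mean(res == "positive")
  se <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(phat - 0.05), 3 * se)
})

test_that("colonoscopy removes detected adenomas and schedules surveillance", {
  pop <- small_pop(n = 5, seed = 3)
  pop$state <- index_to_state(rep(3L, 5))  # high-risk adenoma
  chars <- perfect_chars()
  out <- colonoscopy_followup(pop, chars, seed = 9, cycle_index = 10)
  expect_true(all(out$outcome == "adenoma_removed"))
  expect_true(all(out$individual$state == "normal"))
  expect_true(all(out$individual$surveillance_due == 11))
  expect_false(any(out$complications$perforation))
  expect_false(any(out$complications$major_bleed))

  crc <- small_pop(n = 4, seed = 3)
  crc$state <- index_to_state(rep(6L, 4))  # stage C
  out2 <- colonoscopy_followup(crc, chars, seed = 9)
  expect_true(all(out2$outcome == "crc_diagnosed"))
  expect_true(all(out2$individual$dx_route == "screen"))
  expect_true(all(out2$individual$dx_stage == "C"))
})

test_that("complication counts follow the Bernoulli rate", {
  n <- 20000
  pop <- small_pop(n = n, seed = 4)
  chars <- perfect_chars()
  chars$complications[["perforation"]] <- 0.0005
  out <- colonoscopy_followup(pop, chars, seed = 5)
  k <- sum(out$complications$perforation)
  se <- sqrt(n * 0.0005 * 0.9995)
  expect_lt(abs(k - 10), 3 * se)
})

test_that("surveillance offsets are a policy lookup", {
  expect_true(is.na(schedule_surveillance("low")))
  expect_equal(schedule_surveillance("high"), 1)
  override <- surveillance_policy(low = 5, high = 3)
  expect_equal(schedule_surveillance("low", override), 5)
  expect_equal(schedule_surveillance("high", override), 3)
  expect_error(schedule_surveillance("intermediate"), "risk_class")
})

test_that("screening episodes respect uptake and eligibility", {
  inputs <- the_inputs()
  pop <- small_pop(n = 400, seed = 7)
  pop$age <- rep(60L, 400)
  strat <- make_uniform(60)

  zero_up <- synth_uptake_table()
  zero_up$table$p <- 0
  ep <- run_screening_episode(pop, strat, 30, inputs$test_chars, zero_up, seed = 2)
  expect_equal(ep$log$kits_returned, 0)
  expect_equal(ep$log$colonoscopies, 0)
  expect_gt(ep$log$invitations, 0)

  # nobody at an invitation age
  pop59 <- pop
  pop59$age <- rep(59L, 400)
  ep2 <- run_screening_episode(pop59, strat, 29, inputs$test_chars, inputs$uptake, seed = 2)
  expect_equal(ep2$log$invitations, 0)

  # diagnosed, dead, and under-surveillance individuals are never invited
  pop3 <- pop
  pop3$dx_route[1:50] <- "clinical"
  pop3$dx_stage[1:50] <- "A"
  pop3$alive[51:100] <- FALSE
  pop3$cause_of_death[51:100] <- "other"
  pop3$surveillance_due[101:150] <- 31L
  ep3 <- run_screening_episode(pop3, strat, 30, inputs$test_chars, full_uptake(),
                               seed = 2, uptake_model = "per_episode_bernoulli")
  expect_equal(ep3$log$invitations, 250)
})

test_that("a perfect pathway detects exactly the individuals with lesions", {
  pop <- small_pop(n = 200, seed = 19)
  pop$age <- rep(60L, 200)
  pop$state <- index_to_state(rep(c(1L, 2L, 3L, 4L, 1L), 40))
  strat <- make_uniform(60)
  ep <- run_screening_episode(pop, strat, 30, perfect_chars(), full_uptake(),
                              seed = 3, uptake_model = "per_episode_bernoulli")
  n_lesion <- sum(pop$state != "normal")
  expect_equal(ep$log$invitations, 200)
  expect_equal(ep$log$kits_returned, 200)
  expect_equal(ep$log$positives, n_lesion)   # specificity 1: no false positives
  expect_equal(ep$log$colonoscopies, n_lesion)
  expect_equal(ep$log$adenomas_removed, sum(pop$state %in% c("adenoma_low_risk", "adenoma_high_risk")))
  expect_equal(ep$log$screen_detected_crc, sum(pop$state == "crc_A"))
  # episode log internal consistency
  expect_lte(ep$log$positives, ep$log$kits_returned)
  expect_lte(ep$log$kits_returned, ep$log$invitations)
  expect_lte(ep$log$colonoscopies, ep$log$positives)
})

test_that("screening lowers lifetime CRC incidence under paired streams", {
  inputs <- the_inputs()
  pop <- small_pop(n = 30000, seed = 23)
  res0 <- simulate_strategy(pop, inputs$nh_params, NULL, econ = inputs$econ, seed = 31)
  res1 <- simulate_strategy(pop, inputs$nh_params, make_uniform(60),
                            inputs$test_chars, inputs$uptake, inputs$econ, seed = 31)
  expect_lt(mean(res1$crc_case), mean(res0$crc_case))
  expect_lt(mean(res1$crc_death), mean(res0$crc_death))
})

test_that("lowering the FIT threshold cannot lower expected positives", {
  # follows from the monotone sensitivity/specificity tables; checked on the
  # realised positivity of a fixed invited cohort with shared streams
  inputs <- the_inputs()
  pop <- small_pop(n = 20000, seed = 29)
  pop$age <- rep(60L, 20000)
  logs <- lapply(c("FIT120", "FIT80", "FIT20"), function(thr) {
    strat <- make_uniform(60, threshold = thr)
    run_screening_episode(pop, strat, 30, inputs$test_chars, inputs$uptake,
                          seed = 41)$log
  })
  expect_lte(logs[[1]]$positives, logs[[2]]$positives)
  expect_lte(logs[[2]]$positives, logs[[3]]$positives)
})
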