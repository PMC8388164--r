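test_that("run_analysis writes a reproducible result bundle", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  cfg <- run_config(n = 2000, psa_samples = 2, psa_n = 800,
                    output_dir = dir1, seed = 17)
  out <- run_analysis(cfg)
  expect_true(file.exists(file.path(dir1, "incremental.csv")))
  expect_true(file.exists(file.path(dir1, "results_summary.csv")))
  expect_true(file.exists(file.path(dir1, "psa_samples.csv")))
  expect_true(file.exists(file.path(dir1, "ceac.csv")))
  expect_true(file.exists(file.path(dir1, "resolved_config.yaml")))
  expect_s3_class(out$comparison, "crc_comparison")
  expect_equal(sort(unique(out$comparison$strategy)),
               sort(c("comparator_60", "uniform_58", "stratified_56_60",
                      "random_56_60")))
  # CEAC over 4 strategies sums to one everywhere
  sums <- tapply(out$ceac$probability, out$ceac$wtp, sum)
  expect_equal(as.numeric(sums), rep(1, length(sums)))

  cfg2 <- run_config(n = 2000, psa_samples = 2, psa_n = 800,
                     output_dir = dir2, seed = 17)
  run_analysis(cfg2)
  for (f in c("incremental.csv", "results_summary.csv", "psa_samples.csv", "ceac.csv")) {
    expect_identical(readLines(file.path(dir1, f)), readLines(file.path(dir2, f)),
                     info = f)
  }
})

test_that("a comparator-only configuration yields absolute results only", {
  dir <- withr::local_tempdir()
  cfg <- run_config(n = 500, gap = 0, include_uniform = FALSE,
                    random_fraction = NULL, psa_samples = 0,
                    output_dir = dir, seed = 18)
  out <- run_analysis(cfg)
  expect_null(out$comparison)
  expect_false(file.exists(file.path(dir, "incremental.csv")))
  expect_true(file.exists(file.path(dir, "results_summary.csv")))
})

test_that("scenario grid rows reduce to the underlying comparisons", {
  grid <- tibble::tibble(threshold = "FIT120", mean_start = c(58, 58),
                         gap = c(0, 4))
  g <- scenario_grid(grid, n = 3000, seed = 19)
  expect_equal(nrow(g), 2)
  expect_equal(g$strategy, c("uniform_58", "stratified_56_60"))
  # the gap-0 row equals a direct uniform-58 comparison on the same streams
  inputs <- synth_inputs()
  pop <- generate_population(population_config(n = 3000, seed = child_seed(19, 1)))
  res <- evaluate_strategies(pop, list(comparator_60 = make_uniform(60, name = "comparator_60"),
                                       uniform_58 = make_uniform(58)),
                             inputs, seed = child_seed(19, 2))
  cmp <- compare_strategies(res, "comparator_60", inputs$econ)
  row <- cmp[cmp$strategy == "uniform_58" & cmp$stratum == "overall", ]
  expect_equal(g$d_qaly[1], row$d_qaly)
  expect_equal(g$d_nmb[1], row$nmb)
})

test_that("YAML configuration round-trips", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n = 1234, threshold = "FIT80", mean_start = 54,
                        gap = 6, seed = 3), path)
  cfg <- read_run_config(path)
  expect_equal(cfg$n, 1234)
  expect_equal(cfg$threshold, "FIT80")
  expect_equal(cfg$mean_start, 54)
  expect_equal(cfg$gap, 6)
})

test_that("natural-history parameters and targets round-trip through CSV", {
  dir <- withr::local_tempdir()
  params <- synth_nh_params()
  write_nh_params(params, dir)
  back <- read_nh_params(dir)
  expect_equal(back$progression, params$progression, tolerance = 1e-12)
  expect_equal(back$presentation, params$presentation, tolerance = 1e-12)
  expect_equal(back$crc_survival, params$crc_survival, tolerance = 1e-12)
  expect_equal(back$life_table, params$life_table, tolerance = 1e-12,
               ignore_attr = TRUE)

  tpath <- file.path(dir, "targets.csv")
  targets <- synth_targets(params)
  write_targets(targets, tpath)
  back_t <- read_targets(tpath)
  expect_equal(back_t$value, targets$value, tolerance = 1e-12)
  expect_equal(back_t$class, targets$class)

  ipaths <- write_synth_inputs(synth_inputs(), file.path(dir, "bundle"))
  expect_true(all(file.exists(ipaths)))
})

test_that("tidiers and plots work on the result objects", {
  inputs <- synth_inputs()
  pop <- small_pop(n = 1000, seed = 20)
  res <- evaluate_strategies(pop, list(comp = make_uniform(60),
                                       alt = make_sex_stratified(56, 60)),
                             inputs, seed = 21)
  cmp <- compare_strategies(res, "comp", inputs$econ)
  td <- tidy(cmp)
  expect_s3_class(td, "tbl_df")
  gl <- glance(cmp)
  expect_equal(gl$comparator, "comp")
  p1 <- autoplot(cmp)
  expect_s3_class(p1, "ggplot")

  samples <- tidyr::expand_grid(sample = 1:5, strategy = c("comp", "alt"))
  samples$cost <- stats::runif(10)
  samples$qaly <- stats::runif(10)
  cv <- ceac(samples, c(0, 20000))
  expect_s3_class(autoplot(cv), "ggplot")

  g <- scenario_grid(tibble::tibble(threshold = "FIT120", mean_start = 58, gap = 4),
                     n = 500, seed = 22)
  expect_s3_class(autoplot(g), "ggplot")
})
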