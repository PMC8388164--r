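# CSV serialisation of model inputs.
#
# Every input table round-trips through plain CSV with stable, documented
# column names, so runs can be parameterised from files rather than the
# synthetic generators.

#' Convert natural-history parameters to tidy tables
#'
#' @param params An [nh_params()] object.
#' @return Named list of tibbles: `progression` (`age`, `sex`, `from_state`,
#'   `p`), `presentation` (`age`, `sex`, `stage`, `p`), `crc_survival`
#'   (`age`, `sex`, `stage`, `yfd_band`, `p`), `life_table` (`age`, `sex`,
#'   `p`).
#' @export
nh_params_tables <- function(params) {
  ages <- params$ages
  grid3 <- function(k, labels) {
    tidyr::expand_grid(age = ages, sex = .sex_levels, level = labels)
  }
  prog <- grid3(6, health_states()[1:6])
  names(prog)[3] <- "from_state"
  prog$p <- params$progression[cbind(match(prog$age, ages),
                                     sex_to_index(prog$sex),
                                     match(prog$from_state, health_states()))]
  pres <- grid3(4, stage_labels())
  names(pres)[3] <- "stage"
  pres$p <- params$presentation[cbind(match(pres$age, ages),
                                      sex_to_index(pres$sex),
                                      match(pres$stage, stage_labels()))]
  surv <- tidyr::expand_grid(age = ages, sex = .sex_levels,
                             stage = stage_labels(), yfd_band = 0:5)
  surv$p <- params$crc_survival[cbind(match(surv$age, ages),
                                      sex_to_index(surv$sex),
                                      match(surv$stage, stage_labels()),
                                      surv$yfd_band + 1L)]
  life <- tidyr::expand_grid(age = ages, sex = .sex_levels)
  life$p <- params$life_table[cbind(match(life$age, ages), sex_to_index(life$sex))]
  list(progression = prog, presentation = pres, crc_survival = surv,
       life_table = life)
}

#' Write natural-history parameters as CSV tables
#'
#' @param params An [nh_params()] object.
#' @param dir Output directory (created if needed).
#' @return (Invisibly) the written file paths.
#' @export
write_nh_params <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- nh_params_tables(params)
  paths <- vapply(names(tabs), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(tabs[[nm]]), p, row.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}

#' Read natural-history parameters from CSV tables
#'
#' Inverse of [write_nh_params()].
#'
#' @param dir Directory containing `progression.csv`, `presentation.csv`,
#'   `crc_survival.csv`, `life_table.csv`.
#' @return An [nh_params()] object.
#' @export
read_nh_params <- function(dir) {
  rd <- function(nm) tibble::as_tibble(utils::read.csv(file.path(dir, paste0(nm, ".csv"))))
  prog_t <- rd("progression")
  pres_t <- rd("presentation")
  surv_t <- rd("crc_survival")
  life_t <- rd("life_table")
  ages <- sort(unique(life_t$age))
  n_age <- length(ages)
  progression <- array(0, c(n_age, 2L, 6L))
  progression[cbind(match(prog_t$age, ages), sex_to_index(prog_t$sex),
                    match(prog_t$from_state, health_states()))] <- prog_t$p
  presentation <- array(0, c(n_age, 2L, 4L))
  presentation[cbind(match(pres_t$age, ages), sex_to_index(pres_t$sex),
                     match(pres_t$stage, stage_labels()))] <- pres_t$p
  crc_survival <- array(0, c(n_age, 2L, 4L, 6L))
  crc_survival[cbind(match(surv_t$age, ages), sex_to_index(surv_t$sex),
                     match(surv_t$stage, stage_labels()),
                     surv_t$yfd_band + 1L)] <- surv_t$p
  life_table <- matrix(0, n_age, 2L)
  life_table[cbind(match(life_t$age, ages), sex_to_index(life_t$sex))] <- life_t$p
  nh_params(progression, presentation, crc_survival, life_table, ages = ages)
}

#' Write calibration targets to CSV
#'
#' @param targets A [synth_targets()] tibble.
#' @param path Output CSV path.
#' @return (Invisibly) the path.
#' @export
write_targets <- function(targets, path) {
  utils::write.csv(as.data.frame(targets), path, row.names = FALSE)
  invisible(path)
}

#' Read calibration targets from CSV
#'
#' @param path CSV path written by [write_targets()].
#' @param tolerance Named per-class tolerance attribute to attach.
#' @return A `calibration_targets` tibble.
#' @export
read_targets <- function(path, tolerance = c(incidence = 0.05,
                                             adenoma_prevalence = 0.05,
                                             undiagnosed_crc_prevalence = 0.05,
                                             cum_incidence = 0.05)) {
  out <- tibble::as_tibble(utils::read.csv(path))
  class(out) <- c("calibration_targets", class(tibble::tibble()))
  attr(out, "tolerance") <- tolerance
  out
}

#' Write the full synthetic input bundle as CSV
#'
#' One table per input: natural-history parameters (subdirectory), targets,
#' FIT sensitivity/specificity, colonoscopy characteristics, uptake, unit
#' costs, CRC treatment costs and utilities.
#'
#' @param inputs A [synth_inputs()] bundle.
#' @param dir Output directory.
#' @return (Invisibly) the written paths.
#' @export
write_synth_inputs <- function(inputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_nh_params(inputs$nh_params, file.path(dir, "nh_params"))
  w <- function(df, nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(as.data.frame(df), p, row.names = FALSE)
    p
  }
  chars <- inputs$test_chars
  sens <- tidyr::expand_grid(state = health_states()[2:7], sex = .sex_levels,
                             threshold = c("FIT20", "FIT80", "FIT120"))
  sens$sensitivity <- chars$sensitivity[cbind(match(sens$state, health_states()) - 1L,
                                              sex_to_index(sens$sex),
                                              match(sens$threshold, c("FIT20", "FIT80", "FIT120")))]
  spec <- tidyr::expand_grid(sex = .sex_levels, threshold = c("FIT20", "FIT80", "FIT120"))
  spec$specificity <- chars$specificity[cbind(sex_to_index(spec$sex),
                                              match(spec$threshold, c("FIT20", "FIT80", "FIT120")))]
  paths <- c(paths,
             w(inputs$targets, "targets"),
             w(sens, "fit_sensitivity"),
             w(spec, "fit_specificity"),
             w(tibble::tibble(lesion_class = names(chars$colonoscopy_sensitivity),
                              sensitivity = unname(chars$colonoscopy_sensitivity)),
               "colonoscopy_sensitivity"),
             w(tibble::tibble(complication = names(chars$complications),
                              probability = unname(chars$complications)),
               "complication_probs"),
             w(inputs$uptake$table, "uptake"),
             w(tibble::tibble(item = names(inputs$econ$unit_costs),
                              cost = unname(inputs$econ$unit_costs)),
               "unit_costs"),
             w(inputs$econ$crc_treatment, "crc_treatment_costs"),
             w(inputs$econ$utilities, "utilities"))
  invisible(paths)
}
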