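#' Configuration for the synthetic dispensing-data generator
#'
#' Bundles every knob of the claims simulator: demographics (age 69.3 (8.9)
#' years, roughly half male, socioeconomic index 0.6 (1.1)), device and
#' medication allocation at initiation, dosing regimen (1-4 doses/day,
#' mean ~2), refill timing relative to supply exhaustion, a per-refill
#' discontinuation probability, post-discontinuation behaviour (restart /
#' switch / permanent stop probabilities and delays), comorbidity and
#' co-medication prevalences, and contamination rates that seed each
#' exclusion path of the cohort builder (likely-asthma co-medication,
#' dual initiation, death in year 1, missing essential fields).
#'
#' Refills are scheduled relative to the theoretical exhaustion of supply
#' (`refill_delay_range`, which may be negative: early refills create
#' stockpiles that exercise the carry-over logic). A discontinuation opens a
#' gap: restart delays start above 60 days so that a generated stop is a
#' true stop under the default gap threshold, while switch delays may be
#' shorter (a quick switch keeps the patient persistent on *any*
#' long-acting therapy but not on the initial product).
#'
#' @param n_patients number of patients to simulate.
#' @param seed integer RNG seed; identical config + seed gives identical
#'   output.
#' @param ... overrides for any default listed below.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients = 1000, seed = 1, ...) {
  cfg <- list(
    n_patients = n_patients,
    seed = seed,
    age_mean = 69.3, age_sd = 8.9,
    p_male = 0.49,
    ses_mean = 0.6, ses_sd = 1.1,
    device_allocation = c(single_dose_dpi = 0.123, multiple_dose_dpi = 0.584,
                          pmdi = 0.293),
    medication_allocation = c(formoterol = 0.47, salmeterol = 0.51,
                              indacaterol = 0.02),
    prescriber_allocation = c(general_practitioner = 0.80, specialist = 0.14,
                              other = 0.06),
    dosing_regimen_probs = c(`1` = 0.15, `2` = 0.72, `3` = 0.11, `4` = 0.02),
    supply_days_per_fill = 30,
    refill_delay_range = c(-7, 14),
    p_discontinue_per_fill = 0.15,
    device_hazard_multiplier = c(single_dose_dpi = 1, multiple_dose_dpi = 1,
                                 pmdi = 1),
    restart_delay_range = c(70, 300),
    switch_delay_range = c(10, 300),
    switch_matrix = c(restart_initial = 0.40, switch_within_dpi = 0.03,
                      switch_to_pmdi_laba = 0.04, switch_to_laba_ics = 0.30,
                      switch_to_lama = 0.08, permanent_discontinuation = 0.15),
    comorbidity_prevalences = c(
      osteoporosis = 0.040, diabetes = 0.143, ischaemic_heart_disease = 0.080,
      heart_failure = 0.163, dyslipidaemia = 0.260,
      other_cardiovascular = 0.560, depression = 0.094, dementia = 0.005,
      anxiety = 0.259, psychosis = 0.023, rheumatic_arthritis = 0.155,
      thyroid = 0.054),
    p_saba = 0.20,
    ocs_rate_yearly = 0.5,
    p_asthma_contaminant = 0.121,
    p_missing_field = 0.220,
    p_dual_initiator = 0.113,
    p_death_year1 = 0.020,
    index_year_range = c(1996, 2011),
    lookback_extra_range = c(0, 1000),
    followup_extra_range = c(0, 1000),
    generation_horizon_days = 730
  )
  cfg <- modifyList(cfg, list(...))
  validate_simulation_config(cfg)
  structure(cfg, class = c("simulation_config", "list"))
}

validate_simulation_config <- function(cfg) {
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      abort(paste0(what, " must be a probability vector summing to 1"),
            class = "copdpersist_config_error")
    }
  }
  check_probs(cfg$device_allocation, "device_allocation")
  check_probs(cfg$medication_allocation, "medication_allocation")
  check_probs(cfg$prescriber_allocation, "prescriber_allocation")
  check_probs(cfg$dosing_regimen_probs, "dosing_regimen_probs")
  check_probs(cfg$switch_matrix, "switch_matrix")
  rates <- c(cfg$p_male, cfg$p_discontinue_per_fill, cfg$p_saba,
             cfg$comorbidity_prevalences, cfg$p_asthma_contaminant,
             cfg$p_missing_field, cfg$p_dual_initiator, cfg$p_death_year1)
  if (any(rates < 0 | rates > 1)) {
    abort("all rates must lie in [0, 1]", class = "copdpersist_config_error")
  }
  contam <- cfg$p_asthma_contaminant + cfg$p_missing_field +
    cfg$p_dual_initiator + cfg$p_death_year1
  if (contam > 1) {
    abort("contamination rates must sum to at most 1",
          class = "copdpersist_config_error")
  }
  if (cfg$restart_delay_range[1] <= 60) {
    abort("restart delays must exceed 60 days so that a generated stop is a true gap",
          class = "copdpersist_config_error")
  }
  if (cfg$supply_days_per_fill < 1) {
    abort("supply_days_per_fill must be >= 1",
          class = "copdpersist_config_error")
  }
  invisible(cfg)
}

#' Default synthetic product-to-device map
#'
#' One product per (medication, device class): the device identity, not
#' brand granularity, drives the analysis. Covers the three mono-LABAs in
#' single- and multiple-dose DPI form (plus pMDI for formoterol and
#' salmeterol), a LABA/ICS fixed combination, an ICS, a LAMA and a
#' short-acting bronchodilator.
#'
#' @return Tibble with columns `product_id, device_class, medication_class`.
#' @export
default_device_map <- function() {
  tibble(
    product_id = c("formoterol_sd", "formoterol_md", "formoterol_pmdi",
                   "salmeterol_sd", "salmeterol_md", "salmeterol_pmdi",
                   "indacaterol_sd", "indacaterol_md",
                   "salmeterol_fluticasone_md", "budesonide_md",
                   "tiotropium_sd", "salbutamol_pmdi"),
    device_class = c("single_dose_dpi", "multiple_dose_dpi", "pmdi",
                     "single_dose_dpi", "multiple_dose_dpi", "pmdi",
                     "single_dose_dpi", "multiple_dose_dpi",
                     "multiple_dose_dpi", "multiple_dose_dpi",
                     "single_dose_dpi", "pmdi"),
    medication_class = c(rep("laba_mono", 8), "laba_ics_combo", "ics_mono",
                         "lama", "other")
  )
}

product_atc <- c(
  formoterol_sd = "R03AC13", formoterol_md = "R03AC13",
  formoterol_pmdi = "R03AC13", salmeterol_sd = "R03AC12",
  salmeterol_md = "R03AC12", salmeterol_pmdi = "R03AC12",
  indacaterol_sd = "R03AC18", indacaterol_md = "R03AC18",
  salmeterol_fluticasone_md = "R03AK06", budesonide_md = "R03BA02",
  tiotropium_sd = "R03BB04", salbutamol_pmdi = "R03AC02"
)

comorbidity_products <- tibble(
  comorbidity = c("osteoporosis", "diabetes", "ischaemic_heart_disease",
                  "heart_failure", "dyslipidaemia", "other_cardiovascular",
                  "depression", "dementia", "anxiety", "psychosis",
                  "rheumatic_arthritis", "thyroid"),
  product_id = c("alendronate", "metformin", "isosorbide_mononitrate",
                 "furosemide", "simvastatin", "metoprolol", "sertraline",
                 "piracetam", "diazepam", "olanzapine", "ibuprofen",
                 "levothyroxine"),
  atc_code = c("M05BA04", "A10BA02", "C01DA14", "C03CA01", "C10AA01",
               "C07AB02", "N06AB06", "N06BX03", "N05BA01", "N05AH03",
               "M01AE01", "H03AA01")
)

#' Calibrate the per-refill stopping probability to a target persistence
#'
#' Solves for the per-refill discontinuation probability that gives the
#' requested 1-year persistence with initial therapy under the gap rule.
#' Only stops whose theoretical supply end falls more than `gap_days`
#' before the horizon break persistence, so the patient is effectively at
#' risk at the fills whose coverage ends before `horizon - gap_days`. The
#' expected number of such fills is computed from the refill schedule
#' (supply days plus the positive part of the refill delay), with a normal
#' approximation for the schedule randomness at the boundary fill; the
#' stopping probability is then `1 - target^(1/n_at_risk)`.
#'
#' @param target_persistence desired 1-year initial-therapy persistence
#'   (fraction in (0, 1)).
#' @param config a [simulation_config()] supplying the refill schedule.
#' @param gap_days,horizon the gap rule the target refers to.
#' @return The per-refill stopping probability.
#' @export
calibrate_discontinuation <- function(target_persistence,
                                      config = simulation_config(),
                                      gap_days = 60, horizon = 365) {
  stopifnot(target_persistence > 0, target_persistence < 1)
  supply <- config$supply_days_per_fill
  delays <- pmax(seq(config$refill_delay_range[1],
                     config$refill_delay_range[2]), 0)
  mu <- supply + mean(delays)
  sg <- sqrt(mean(delays^2) - mean(delays)^2)
  cutoff <- horizon - gap_days
  kmax <- ceiling(2 * horizon / mu)
  k <- seq_len(kmax)
  # fill k's coverage ends at supply + sum of k increments ~ N(supply+k*mu, k*sg^2)
  p_at_risk <- pnorm(cutoff, supply + k * mu, pmax(sg * sqrt(k), 1e-9))
  n_at_risk <- 1 + sum(p_at_risk)   # index fill always ends before cutoff
  1 - target_persistence^(1 / n_at_risk)
}

#' Generate a synthetic dispensing population with ground truth
#'
#' Simulates patients, their LABA dispensing trajectories, co-medication and
#' contamination, and emits the three analysis inputs (patients,
#' dispensings, device map) plus a ground-truth table that records each
#' patient's true discontinuation day, post-gap action and expected
#' exclusion path. The ground truth is written alongside the data but never
#' consumed by the analysis pipeline, so parameter-recovery checks are not
#' circular.
#'
#' Trajectory model: fills of the index product are scheduled relative to
#' theoretical supply exhaustion; after each fill the patient stops with the
#' configured per-refill probability (optionally scaled per device class via
#' a proportional-hazards multiplier). A stopping patient samples one
#' post-gap action from `switch_matrix`; restart and switch fills then
#' continue uninterrupted to the generation horizon.
#'
#' @param config a [simulation_config()].
#' @return A list: `patients`, `dispensings`, `device_map`, `ground_truth`
#'   tibbles and the `config` used.
#' @export
generate_population <- function(config = simulation_config()) {
  validate_simulation_config(config)
  set.seed(config$seed)
  n <- config$n_patients
  supply <- config$supply_days_per_fill

  pid <- sprintf("P%06d", seq_len(n))
  contam_probs <- c(clean = 1 - config$p_asthma_contaminant -
                      config$p_missing_field - config$p_dual_initiator -
                      config$p_death_year1,
                    asthma = config$p_asthma_contaminant,
                    missing = config$p_missing_field,
                    dual = config$p_dual_initiator,
                    death = config$p_death_year1)
  contamination <- sample(names(contam_probs), n, replace = TRUE,
                          prob = contam_probs)
  # which patient-table field is blanked for missing-data contaminants
  missing_field <- ifelse(runif(n) < 0.5, "gender", "birth_date")

  age <- pmax(rnorm(n, config$age_mean, config$age_sd), 40)
  gender <- ifelse(runif(n) < config$p_male, "male", "female")
  ses <- rnorm(n, config$ses_mean, config$ses_sd)
  yr <- sample(seq(config$index_year_range[1], config$index_year_range[2]),
               n, replace = TRUE)
  index_date <- as.Date(sprintf("%d-01-01", yr)) + sample(0:364, n, TRUE)
  birth_date <- index_date - round(age * 365.25)
  reg_start <- index_date - 730 -
    sample_int(config$lookback_extra_range, n)
  reg_end <- index_date + 365 + sample_int(config$followup_extra_range, n)
  death_off <- ifelse(contamination == "death", sample(30:364, n, TRUE), NA)
  death_date <- index_date + death_off

  device <- sample(names(config$device_allocation), n, TRUE,
                   prob = config$device_allocation)
  medication <- character(n)
  med_p <- config$medication_allocation
  for (i in seq_len(n)) {
    p <- med_p
    if (device[i] != "single_dose_dpi") p["indacaterol"] <- 0
    medication[i] <- sample(names(p), 1, prob = p / sum(p))
  }
  regimen <- as.numeric(sample(names(config$dosing_regimen_probs), n, TRUE,
                               prob = config$dosing_regimen_probs))
  prescriber <- sample(names(config$prescriber_allocation), n, TRUE,
                       prob = config$prescriber_allocation)
  dev_suffix <- c(single_dose_dpi = "_sd", multiple_dose_dpi = "_md",
                  pmdi = "_pmdi")
  initial_product <- paste0(medication, dev_suffix[device])
  p_stop <- 1 - (1 - config$p_discontinue_per_fill) ^
    config$device_hazard_multiplier[device]

  # trajectory per patient -----------------------------------------------
  acc <- list()
  gt_disc <- rep(NA_real_, n)
  gt_cat <- rep(NA_character_, n)
  gt_event <- rep(NA_real_, n)
  horizon_gen <- config$generation_horizon_days

  for (i in seq_len(n)) {
    days <- numeric(0); prods <- character(0)
    d <- 0; e_prev <- -Inf
    stopped <- FALSE
    repeat {
      days <- c(days, d); prods <- c(prods, initial_product[i])
      e_prev <- max(d, e_prev) + supply
      if (runif(1) < p_stop[i]) { stopped <- TRUE; break }
      d <- e_prev + sample_int(config$refill_delay_range, 1)
      if (d > horizon_gen) break
    }
    if (stopped) {
      gt_disc[i] <- e_prev
      cat_i <- sample(names(config$switch_matrix), 1,
                      prob = config$switch_matrix)
      gt_cat[i] <- cat_i
      if (cat_i != "permanent_discontinuation") {
        delay <- if (cat_i == "restart_initial") {
          sample_int(config$restart_delay_range, 1)
        } else {
          sample_int(config$switch_delay_range, 1)
        }
        ev <- e_prev + delay
        gt_event[i] <- ev
        new_prod <- switch_target_product(cat_i, medication[i], device[i])
        d2 <- ev; e2 <- -Inf
        while (d2 <= horizon_gen) {
          days <- c(days, d2); prods <- c(prods, new_prod)
          e2 <- max(d2, e2) + supply
          d2 <- e2 + sample_int(config$refill_delay_range, 1)
        }
      }
    }
    # co-medication ---------------------------------------------------
    com <- runif(length(config$comorbidity_prevalences)) <
      config$comorbidity_prevalences
    for (cm in comorbidity_products$product_id[com]) {
      cd <- sample(10:350, 2)
      days <- c(days, cd); prods <- c(prods, rep(cm, 2))
    }
    if (runif(1) < config$p_saba) {
      days <- c(days, sample(5:350, 1)); prods <- c(prods, "salbutamol_pmdi")
    }
    n_ocs <- rpois(1, config$ocs_rate_yearly)
    if (n_ocs > 0) {
      days <- c(days, sample(5:360, n_ocs, replace = TRUE))
      prods <- c(prods, rep("prednisolone", n_ocs))
    }
    if (contamination[i] == "asthma") {
      days <- c(days, sample(10:350, 1)); prods <- c(prods, "cetirizine")
    }
    if (contamination[i] == "dual") {
      dual_prod <- if (medication[i] == "salmeterol") "budesonide_md" else "tiotropium_sd"
      days <- c(days, 0); prods <- c(prods, dual_prod)
    }
    if (contamination[i] == "death") {
      keep <- days < death_off[i]
      days <- days[keep]; prods <- prods[keep]
    }
    acc[[i]] <- list(days = days, prods = prods)
  }

  n_fills <- vapply(acc, function(x) length(x$days), integer(1))
  all_days <- unlist(lapply(acc, `[[`, "days"))
  all_prods <- unlist(lapply(acc, `[[`, "prods"))
  row_pid <- rep(pid, n_fills)
  row_idx <- rep(seq_len(n), n_fills)

  extra_atc <- c(setNames(comorbidity_products$atc_code,
                          comorbidity_products$product_id),
                 prednisolone = "H02AB06", cetirizine = "R06AE07")
  atc_lookup <- c(product_atc, extra_atc)
  inhaler <- all_prods %in% names(product_atc)
  units <- ifelse(inhaler, supply * regimen[row_idx], 30)
  pdd <- ifelse(inhaler, regimen[row_idx], 1)
  presc <- ifelse(all_days == 0 & inhaler, prescriber[row_idx],
                  "general_practitioner")

  dispensings <- tibble(
    patient_id = row_pid,
    dispense_date = index_date[row_idx] + all_days,
    atc_code = unname(atc_lookup[all_prods]),
    product_id = all_prods,
    units_dispensed = units,
    prescribed_daily_dose = pdd,
    prescriber = presc
  ) %>% arrange(.data$patient_id, .data$dispense_date, .data$product_id)

  is_missing <- contamination == "missing"
  patients <- tibble(
    patient_id = pid,
    birth_date = dplyr::if_else(is_missing & missing_field == "birth_date",
                                as.Date(NA), birth_date),
    gender = ifelse(is_missing & missing_field == "gender",
                    NA_character_, gender),
    ses_score = round(ses, 2),
    registration_start = reg_start,
    registration_end = reg_end,
    death_date = death_date
  )

  ground_truth <- tibble(
    patient_id = pid,
    contamination = contamination,
    missing_field = ifelse(is_missing, missing_field, NA_character_),
    age_at_index = age,
    index_day = index_date,
    initial_product = initial_product,
    initial_device = device,
    initial_medication = medication,
    dosing_regimen = regimen,
    true_discontinuation_day = gt_disc,
    true_switch_category = gt_cat,
    true_restart_day = ifelse(!is.na(gt_cat) & gt_cat == "restart_initial",
                              gt_event, NA_real_),
    true_event_day = gt_event,
    true_persistent_365 = true_persistence_flag(gt_disc, gt_cat, 60, 365),
    true_exclusion = true_exclusion_reason(contamination, missing_field,
                                           age, device)
  )

  list(patients = patients, dispensings = dispensings,
       device_map = default_device_map(), ground_truth = ground_truth,
       config = config)
}

# Gaps are truncated at the horizon. After a stop the initial product is
# refilled only on a restart, whose delay always exceeds the gap threshold,
# so a stop breaks 1-year initial-therapy persistence exactly when more
# than gap_days of the first year remain uncovered after it.
true_persistence_flag <- function(disc, cat, gap_days, horizon) {
  is.na(disc) | disc >= horizon - gap_days
}

true_exclusion_reason <- function(contamination, missing_field, age, device) {
  # mirrors the fixed filter order of apply_selection(); the age filter can
  # only fire when the birth date is known
  reason <- rep(NA_character_, length(contamination))
  age_known <- !(contamination == "missing" & missing_field == "birth_date")
  reason[age_known & age < 55] <- "underage"
  m <- is.na(reason)
  reason[m & contamination == "asthma"] <- "asthma_medication"
  m <- is.na(reason)
  reason[m & contamination == "missing"] <- "missing_essential_data"
  m <- is.na(reason)
  reason[m & contamination == "dual"] <- "dual_initiation"
  m <- is.na(reason)
  reason[m & contamination == "death"] <- "death_within_followup"
  m <- is.na(reason)
  reason[m & device == "pmdi"] <- "pmdi_initiation"
  reason
}

switch_target_product <- function(category, medication, device) {
  switch(category,
    restart_initial = paste0(medication,
                             c(single_dose_dpi = "_sd",
                               multiple_dose_dpi = "_md",
                               pmdi = "_pmdi")[device]),
    switch_within_dpi = paste0(medication,
                               if (device == "single_dose_dpi") "_md" else "_sd"),
    switch_to_pmdi_laba = if (medication == "indacaterol")
      "salmeterol_pmdi" else paste0(medication, "_pmdi"),
    switch_to_laba_ics = "salmeterol_fluticasone_md",
    switch_to_lama = "tiotropium_sd"
  )
}

sample_int <- function(range, n) {
  sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Write a generated population to a directory
#'
#' Writes `patients.csv`, `dispensings.csv`, `device_map.csv` and
#' `ground_truth.csv`.
#'
#' @param population list from [generate_population()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_population <- function(population, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_patients(population$patients, file.path(dir, "patients.csv"))
  write_dispensings(population$dispensings, file.path(dir, "dispensings.csv"))
  write_device_map(population$device_map, file.path(dir, "device_map.csv"))
  readr::write_csv(population$ground_truth, file.path(dir, "ground_truth.csv"),
                   na = "")
  invisible(dir)
}

#' Simulate two-arm survival data with a known hazard ratio
#'
#' Canonical exponential time-to-discontinuation data with administrative
#' censoring, used to study the frequentist properties (coverage, bias) of
#' the Cox device-effect estimator independently of the dispensing
#' generator.
#'
#' @param n_per_arm patients per device cohort.
#' @param hazard_ratio true hazard of the multiple-dose arm relative to the
#'   single-dose arm.
#' @param baseline_hazard events/day in the single-dose arm.
#' @param censor_day administrative censoring time.
#' @return Tibble: `patient_id`, `device_cohort`, `time`, `event`.
#' @export
simulate_survival_arms <- function(n_per_arm = 1000, hazard_ratio = 1,
                                   baseline_hazard = 0.0044,
                                   censor_day = 365) {
  t0 <- rexp(n_per_arm, baseline_hazard)
  t1 <- rexp(n_per_arm, baseline_hazard * hazard_ratio)
  tt <- c(t0, t1)
  tibble(
    patient_id = sprintf("S%05d", seq_len(2 * n_per_arm)),
    device_cohort = rep(c("single_dose_dpi", "multiple_dose_dpi"),
                        each = n_per_arm),
    time = pmin(tt, censor_day),
    event = as.integer(tt <= censor_day)
  )
}
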