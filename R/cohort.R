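#' Find LABA treatment initiations
#'
#' Treatment initiation is a patient's first dispensing of an inhaled
#' mono-LABA (salmeterol, formoterol or indacaterol). At most one event is
#' returned per patient. A patient who is dispensed a second long-acting
#' product on the index date is flagged as a dual-initiation candidate
#' (initiating two types of inhaled medication on the same date), which the
#' selection cascade later excludes.
#'
#' @param dispensings dispensing tibble (see [read_dispensings()]).
#' @param config an [atc_config()].
#' @param device_map product-to-device tibble; used to attach the initial
#'   device class.
#' @return Tibble of initiation events: `patient_id`, `index_date`,
#'   `initial_atc`, `initial_product`, `initial_device`,
#'   `initial_prescriber`, `dosing_regimen`, `dual_candidate`.
#' @export
find_initiations <- function(dispensings, config = atc_config(),
                             device_map = default_device_map()) {
  laba <- dispensings[atc_matches(dispensings$atc_code, config$laba_mono), ,
                      drop = FALSE]
  if (nrow(laba) == 0) {
    return(tibble(patient_id = character(0), index_date = as.Date(character(0)),
                  initial_atc = character(0), initial_product = character(0),
                  initial_device = character(0),
                  initial_prescriber = character(0),
                  dosing_regimen = numeric(0), dual_candidate = logical(0)))
  }
  first <- laba %>%
    arrange(.data$patient_id, .data$dispense_date, .data$product_id) %>%
    group_by(.data$patient_id) %>%
    slice(1) %>%
    ungroup()
  # another long-acting product dispensed on the index date?
  la <- dispensings[atc_matches(dispensings$atc_code, config$long_acting), ,
                    drop = FALSE]
  dual <- la %>%
    left_join(first[, c("patient_id", "dispense_date", "product_id")] %>%
                rename(index_date = "dispense_date",
                       initial_product = "product_id"),
              by = "patient_id") %>%
    filter(.data$dispense_date == .data$index_date,
           .data$product_id != .data$initial_product) %>%
    distinct(.data$patient_id)
  first %>%
    left_join(device_map[, c("product_id", "device_class")], by = "product_id") %>%
    mutate(dual_candidate = .data$patient_id %in% dual$patient_id) %>%
    select(patient_id = "patient_id", index_date = "dispense_date",
           initial_atc = "atc_code", initial_product = "product_id",
           initial_device = "device_class",
           initial_prescriber = "prescriber",
           dosing_regimen = "prescribed_daily_dose", "dual_candidate")
}

#' Apply the new-user selection cascade
#'
#' Filters LABA initiators into the analysis cohort, in a fixed order, and
#' records an auditable exclusion flow (one removal reason per patient: the
#' first failing filter):
#'
#' 1. `underage` — age at index below the inclusion floor (55 years,
#'    inclusive by default; only evaluable when the birth date is known);
#' 2. `not_naive` — any long-acting respiratory dispensing in the 730 days
#'    before the index date;
#' 3. `incomplete_registration` — database registration does not cover
#'    \[index - 730, index + 365\];
#' 4. `asthma_medication` — typical asthma medication (antihistamines,
#'    anti-allergics, leukotriene antagonists, omalizumab) dispensed within
#'    1 year after initiation;
#' 5. `missing_essential_data` — gender, birth date, dosing regimen or
#'    units unavailable (from the readers' reject lists or NA fields);
#' 6. `dual_initiation` — a second long-acting product on the index date;
#' 7. `death_within_followup` — death in the year after initiation;
#' 8. `pmdi_initiation` — started a pressurised metered-dose inhaler; the
#'    final cohort is the DPI initiators, split into single-dose and
#'    multiple-dose device cohorts.
#'
#' @param patients patient tibble (may contain NA gender/birth_date, which
#'   count as missing essential data).
#' @param dispensings full dispensing tibble.
#' @param initiations tibble from [find_initiations()].
#' @param config an [atc_config()].
#' @param patient_rejects,dispensing_rejects optional reject tibbles from
#'   the readers; rejected patient rows and dispensing rows with missing
#'   dose/units feed filter 5.
#' @param min_age inclusion age floor in years (default 55).
#' @param age_strict if `TRUE`, require age strictly above `min_age`.
#' @param lookback_days,followup_days washout and follow-up windows in days.
#' @return A list: `cohort` (tibble with initiation, patient and
#'   `device_cohort`, `initial_medication` columns) and `flow` (tibble
#'   `filter`, `n_removed`, `n_remaining`).
#' @export
apply_selection <- function(patients, dispensings, initiations,
                            config = atc_config(),
                            patient_rejects = NULL,
                            dispensing_rejects = NULL,
                            min_age = 55, age_strict = FALSE,
                            lookback_days = 730, followup_days = 365) {
  cand <- left_join(initiations, patients, by = "patient_id")
  known <- cand$patient_id %in% patients$patient_id
  if (!is.null(patient_rejects) && nrow(patient_rejects) > 0) {
    rej <- patient_rejects[match(cand$patient_id, patient_rejects$patient_id), ]
    fill_in <- !known & !is.na(rej$patient_id)
    for (col in c("birth_date", "gender", "ses_score", "registration_start",
                  "registration_end", "death_date")) {
      if (col %in% names(rej)) cand[[col]][fill_in] <- rej[[col]][fill_in]
    }
    known <- known | fill_in
  }
  if (any(!known)) {
    abort(paste0("dispensings reference patient(s) absent from the patient table: ",
                 paste(head(cand$patient_id[!known], 5), collapse = ", ")),
          class = "copdpersist_integrity_error")
  }

  age <- as.numeric(cand$index_date - cand$birth_date) / 365.25
  fail_age <- !is.na(age) &
    (if (age_strict) age <= min_age else age < min_age)

  la <- dispensings[atc_matches(dispensings$atc_code, config$long_acting), ,
                    drop = FALSE]
  la <- left_join(la, cand[, c("patient_id", "index_date")], by = "patient_id")
  prior <- la %>%
    filter(!is.na(.data$index_date),
           .data$dispense_date >= .data$index_date - .env$lookback_days,
           .data$dispense_date < .data$index_date) %>%
    distinct(.data$patient_id)
  fail_naive <- cand$patient_id %in% prior$patient_id

  fail_reg <- !is.na(cand$registration_start) & !is.na(cand$registration_end) &
    (cand$registration_start > cand$index_date - lookback_days |
       cand$registration_end < cand$index_date + followup_days)

  asthma <- dispensings[atc_matches(dispensings$atc_code,
                                    config$asthma_exclusion), , drop = FALSE]
  asthma <- left_join(asthma, cand[, c("patient_id", "index_date")],
                      by = "patient_id")
  asthma <- asthma %>%
    filter(!is.na(.data$index_date),
           .data$dispense_date > .data$index_date,
           .data$dispense_date <= .data$index_date + .env$followup_days) %>%
    distinct(.data$patient_id)
  fail_asthma <- cand$patient_id %in% asthma$patient_id

  miss_ids <- character(0)
  if (!is.null(patient_rejects) && nrow(patient_rejects) > 0) {
    miss_ids <- c(miss_ids, patient_rejects$patient_id)
  }
  if (!is.null(dispensing_rejects) && nrow(dispensing_rejects) > 0) {
    essential <- c("missing_pdd", "bad_pdd", "missing_units", "bad_units")
    miss_ids <- c(miss_ids,
                  dispensing_rejects$patient_id[
                    dispensing_rejects$reason %in% essential])
  }
  fail_missing <- is.na(cand$gender) | is.na(cand$birth_date) |
    is.na(cand$dosing_regimen) | cand$patient_id %in% miss_ids

  fail_dual <- cand$dual_candidate
  fail_death <- !is.na(cand$death_date) &
    cand$death_date <= cand$index_date + followup_days
  fail_pmdi <- !is.na(cand$initial_device) & cand$initial_device == "pmdi"

  filters <- list(
    underage = fail_age,
    not_naive = fail_naive,
    incomplete_registration = fail_reg,
    asthma_medication = fail_asthma,
    missing_essential_data = fail_missing,
    dual_initiation = fail_dual,
    death_within_followup = fail_death,
    pmdi_initiation = fail_pmdi
  )
  remaining <- rep(TRUE, nrow(cand))
  flow <- tibble(filter = "laba_initiators", n_removed = 0L,
                 n_remaining = nrow(cand))
  reason <- rep(NA_character_, nrow(cand))
  for (nm in names(filters)) {
    hit <- remaining & filters[[nm]]
    reason[hit] <- nm
    remaining <- remaining & !hit
    flow <- bind_rows(flow, tibble(filter = nm, n_removed = sum(hit),
                                   n_remaining = sum(remaining)))
  }
  cohort <- cand[remaining, , drop = FALSE] %>%
    mutate(age_years = age[remaining],
           device_cohort = .data$initial_device,
           initial_medication = laba_medication(.data$initial_atc)) %>%
    select(-"dual_candidate")
  attr(cohort, "exclusion_reasons") <-
    tibble(patient_id = cand$patient_id[!remaining],
           reason = reason[!remaining])
  list(cohort = cohort, flow = flow)
}
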