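#' Flag ATC-proxy comorbidities for one patient
#'
#' Comorbidity is proxied by chronic medication use: at least two
#' dispensings matching the comorbidity's ATC prefix set within 1 year
#' after treatment initiation. The cardiovascular proxies are hierarchical:
#' a patient using other cardiovascular drugs (C02/C03/C07/C08/C09) counts
#' as "other cardiovascular disorders" only when none of the specific
#' proxies — heart failure (digoxin C01AA05 / loop diuretics C03C),
#' ischaemic heart disease (C01DA) or dyslipidaemia (C10) — fired.
#'
#' @param fills one patient's dispensing tibble.
#' @param index_date the patient's index `Date`.
#' @param config an [atc_config()].
#' @param min_fills chronic-use threshold (default 2 dispensings).
#' @return Named logical vector, one element per comorbidity.
#' @export
flag_comorbidities <- function(fills, index_date, config = atc_config(),
                               min_fills = 2) {
  day <- as.numeric(fills$dispense_date - index_date)
  in_window <- day > 0 & day <= 365
  codes <- fills$atc_code[in_window]
  flags <- vapply(config$comorbidity_map, function(prefixes) {
    sum(atc_matches(codes, prefixes)) >= min_fills
  }, logical(1))
  if (flags[["other_cardiovascular"]] &&
      (flags[["heart_failure"]] || flags[["ischaemic_heart_disease"]] ||
         flags[["dyslipidaemia"]])) {
    flags[["other_cardiovascular"]] <- FALSE
  }
  flags
}

#' Count short oral-corticosteroid courses in year 1
#'
#' Each OCS dispensing counts as one short course; the rate is per year
#' (the window is the year after initiation).
#'
#' @inheritParams flag_comorbidities
#' @return Courses per year (numeric).
#' @export
count_ocs_courses <- function(fills, index_date, config = atc_config()) {
  day <- as.numeric(fills$dispense_date - index_date)
  sum(atc_matches(fills$atc_code, config$ocs) & day > 0 & day <= 365)
}

#' Any short-acting bronchodilator fill in year 1?
#'
#' @inheritParams flag_comorbidities
#' @return Logical.
#' @export
flag_saba <- function(fills, index_date, config = atc_config()) {
  day <- as.numeric(fills$dispense_date - index_date)
  any(atc_matches(fills$atc_code, config$saba) & day > 0 & day <= 365)
}

#' Build the per-patient covariate table
#'
#' One row per cohort member with the patient-characteristic covariates
#' used for cohort comparison and Cox adjustment: demographics,
#' socioeconomic index, initial prescriber, the twelve ATC-proxy
#' comorbidity flags and their count, short-acting bronchodilator use,
#' yearly short OCS courses, initial medication, dosing regimen (the
#' prescribed daily dose of the index dispensing) and device cohort.
#'
#' @param cohort cohort tibble from [apply_selection()].
#' @param dispensings full dispensing tibble.
#' @param config an [atc_config()].
#' @return A covariate tibble, one row per patient.
#' @export
build_covariates <- function(cohort, dispensings, config = atc_config()) {
  by_pat <- split(dispensings, dispensings$patient_id)
  empty <- dispensings[0, , drop = FALSE]
  rows <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    fills <- by_pat[[cohort$patient_id[i]]]
    if (is.null(fills)) fills <- empty
    idx <- cohort$index_date[i]
    flags <- flag_comorbidities(fills, idx, config)
    rows[[i]] <- tibble(
      patient_id = cohort$patient_id[i],
      age_years = cohort$age_years[i],
      gender = cohort$gender[i],
      ses_score = cohort$ses_score[i],
      prescriber_specialist = cohort$initial_prescriber[i] == "specialist",
      !!!as.list(flags),
      n_comorbidities = sum(flags),
      saba_any = flag_saba(fills, idx, config),
      ocs_courses_yearly = count_ocs_courses(fills, idx, config),
      initial_medication = cohort$initial_medication[i],
      dosing_regimen = cohort$dosing_regimen[i],
      device_cohort = cohort$device_cohort[i]
    )
  }
  bind_rows(rows)
}
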