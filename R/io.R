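#' Read pharmacy dispensing records
#'
#' Reads a long-format dispensing CSV (one row per dispensing event) and
#' splits it into parsed records and a rejects table. Rows whose essential
#' fields cannot be parsed (missing daily dose, missing units, malformed
#' dates or ATC codes, ...) are never silently dropped: they are returned
#' with a reason code so downstream cohort selection can count them as
#' "no complete information" exclusions.
#'
#' Expected columns: `patient_id, dispense_date, atc_code, product_id,
#' units_dispensed, prescribed_daily_dose, prescriber`. Dates are ISO-8601.
#'
#' @param path path to a CSV file.
#' @return A list with `records` (tibble of parsed rows, dates as `Date`)
#'   and `rejects` (tibble with the raw fields plus a `reason` column).
#' @export
read_dispensings <- function(path) {
  raw <- read_raw_csv(path, c("patient_id", "dispense_date", "atc_code",
                              "product_id", "units_dispensed",
                              "prescribed_daily_dose", "prescriber"))
  date <- parse_iso_date(raw$dispense_date)
  units <- suppressWarnings(as.numeric(raw$units_dispensed))
  pdd <- suppressWarnings(as.numeric(raw$prescribed_daily_dose))
  atc_ok <- !is.na(raw$atc_code) & is_valid_atc(raw$atc_code)

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, code) ifelse(is.na(reason) & cond, code, reason)
  reason <- flag(is.na(raw$patient_id) | raw$patient_id == "", "missing_patient_id")
  reason <- flag(is.na(date), "bad_dispense_date")
  reason <- flag(!atc_ok, "bad_atc_code")
  reason <- flag(is.na(raw$product_id) | raw$product_id == "", "missing_product_id")
  reason <- flag(is.na(raw$units_dispensed) | raw$units_dispensed == "", "missing_units")
  reason <- flag(is.na(units) | units < 1, "bad_units")
  reason <- flag(is.na(raw$prescribed_daily_dose) | raw$prescribed_daily_dose == "",
                 "missing_pdd")
  reason <- flag(is.na(pdd) | pdd <= 0, "bad_pdd")

  ok <- is.na(reason)
  records <- tibble(
    patient_id = raw$patient_id[ok],
    dispense_date = date[ok],
    atc_code = toupper(raw$atc_code[ok]),
    product_id = raw$product_id[ok],
    units_dispensed = units[ok],
    prescribed_daily_dose = pdd[ok],
    prescriber = parse_prescriber(raw$prescriber[ok])
  )
  rejects <- raw[!ok, , drop = FALSE]
  rejects$reason <- reason[!ok]
  list(records = records, rejects = as_tibble(rejects))
}

#' Read the patient table
#'
#' Patients without parseable gender or birth date are returned as rejects
#' (with any fields that did parse retained), matching the missing-data
#' handling of the cohort builder: such patients are excluded from the
#' analysis cohort, with the exclusion counted explicitly.
#'
#' Expected columns: `patient_id, birth_date, gender, ses_score,
#' registration_start, registration_end, death_date` (death_date may be
#' empty).
#'
#' @param path path to a CSV file.
#' @return A list with `records` and `rejects` tibbles; rejects carry a
#'   `reason` code plus parsed `birth_date`/registration dates where
#'   available (NA where unparseable).
#' @export
read_patients <- function(path) {
  raw <- read_raw_csv(path, c("patient_id", "birth_date", "gender",
                              "ses_score", "registration_start",
                              "registration_end", "death_date"))
  birth <- parse_iso_date(raw$birth_date)
  reg_start <- parse_iso_date(raw$registration_start)
  reg_end <- parse_iso_date(raw$registration_end)
  death <- parse_iso_date(raw$death_date)
  gender <- tolower(trimws(ifelse(is.na(raw$gender), "", raw$gender)))
  gender[!gender %in% c("male", "female")] <- NA_character_
  ses <- suppressWarnings(as.numeric(raw$ses_score))

  reason <- rep(NA_character_, nrow(raw))
  flag <- function(cond, code) ifelse(is.na(reason) & cond, code, reason)
  reason <- flag(is.na(raw$patient_id) | raw$patient_id == "", "missing_patient_id")
  reason <- flag(is.na(birth), "missing_birth_date")
  reason <- flag(is.na(gender), "missing_gender")
  reason <- flag(is.na(reg_start) | is.na(reg_end), "missing_registration")

  ok <- is.na(reason)
  records <- tibble(
    patient_id = raw$patient_id[ok],
    birth_date = birth[ok],
    gender = gender[ok],
    ses_score = ses[ok],
    registration_start = reg_start[ok],
    registration_end = reg_end[ok],
    death_date = death[ok]
  )
  rejects <- tibble(
    patient_id = raw$patient_id[!ok],
    reason = reason[!ok],
    birth_date = birth[!ok],
    gender = gender[!ok],
    ses_score = ses[!ok],
    registration_start = reg_start[!ok],
    registration_end = reg_end[!ok],
    death_date = death[!ok]
  )
  list(records = records, rejects = rejects)
}

#' Read the product-to-device mapping table
#'
#' Maps each inhaler product to its device class (single-dose DPI,
#' multiple-dose DPI or pMDI) and medication class. Exact duplicate rows are
#' deduplicated; a product mapped to two different classes is an error,
#' because device identity drives the cohort definition.
#'
#' @param path path to a CSV with columns `product_id, device_class,
#'   medication_class`.
#' @return A tibble with one row per product.
#' @export
read_device_map <- function(path) {
  raw <- read_raw_csv(path, c("product_id", "device_class", "medication_class"))
  dev_ok <- raw$device_class %in% c("single_dose_dpi", "multiple_dose_dpi", "pmdi")
  med_ok <- raw$medication_class %in%
    c("laba_mono", "laba_ics_combo", "ics_mono", "lama", "other")
  if (!all(dev_ok) || !all(med_ok)) {
    abort("device map contains unknown device_class or medication_class values",
          class = "copdpersist_schema_error")
  }
  out <- distinct(as_tibble(raw))
  dup <- out$product_id[duplicated(out$product_id)]
  if (length(dup) > 0) {
    abort(paste0("conflicting device map entries for product(s): ",
                 paste(unique(dup), collapse = ", ")),
          class = "copdpersist_schema_error")
  }
  out
}

#' Write dispensing / patient / device-map tables to CSV
#'
#' Inverse of the readers; dates are written ISO-8601 so a write-then-read
#' round trip is the identity on all fields.
#'
#' @param x tibble as produced by the corresponding reader (or the
#'   generator).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dispensings <- function(x, path) {
  readr::write_csv(x[, c("patient_id", "dispense_date", "atc_code",
                         "product_id", "units_dispensed",
                         "prescribed_daily_dose", "prescriber")], path)
  invisible(path)
}

#' @rdname write_dispensings
#' @export
write_patients <- function(x, path) {
  readr::write_csv(x[, c("patient_id", "birth_date", "gender", "ses_score",
                         "registration_start", "registration_end",
                         "death_date")], path, na = "")
  invisible(path)
}

#' @rdname write_dispensings
#' @export
write_device_map <- function(x, path) {
  readr::write_csv(x[, c("product_id", "device_class", "medication_class")],
                   path)
  invisible(path)
}

# -- internal helpers ---------------------------------------------------------

read_raw_csv <- function(path, required_cols) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "copdpersist_io_error")
  }
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  missing <- setdiff(required_cols, names(raw))
  if (length(missing) > 0) {
    abort(paste0("missing mandatory column(s): ", paste(missing, collapse = ", ")),
          class = "copdpersist_schema_error")
  }
  for (col in required_cols) {
    raw[[col]] <- trimws(raw[[col]])
    raw[[col]][raw[[col]] == ""] <- NA_character_
  }
  raw[, required_cols, drop = FALSE]
}

parse_iso_date <- function(x) {
  as.Date(x, format = "%Y-%m-%d", optional = TRUE)
}

parse_prescriber <- function(x) {
  x <- tolower(ifelse(is.na(x), "other", x))
  ifelse(x %in% c("general_practitioner", "specialist"), x, "other")
}
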