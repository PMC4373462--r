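#' Select the switching-analysis subcohort
#'
#' Switching patterns in the year after a discontinuation can only be
#' observed with sufficient follow-up, so the switching analysis uses the
#' subcohort of patients registered for at least 2 years after the index
#' date who had at least `min_prescriptions` long-acting dispensings in the
#' first year (one-time users, e.g. a single fill for an incident
#' exacerbation, are excluded).
#'
#' @param cohort cohort tibble from [apply_selection()].
#' @param dispensings full dispensing tibble.
#' @param config an [atc_config()].
#' @param min_prescriptions minimum long-acting dispensings in year 1
#'   (default 2).
#' @param followup_days required registration after index (default 730).
#' @return The qualifying subset of `cohort`.
#' @export
select_switching_subcohort <- function(cohort, dispensings,
                                       config = atc_config(),
                                       min_prescriptions = 2,
                                       followup_days = 730) {
  la <- dispensings[atc_matches(dispensings$atc_code, config$long_acting), ,
                    drop = FALSE]
  counts <- la %>%
    left_join(cohort[, c("patient_id", "index_date")], by = "patient_id") %>%
    filter(!is.na(.data$index_date),
           .data$dispense_date >= .data$index_date,
           .data$dispense_date <= .data$index_date + 365) %>%
    count(.data$patient_id, name = "n_la")
  cohort %>%
    left_join(counts, by = "patient_id") %>%
    filter(!is.na(.data$n_la), .data$n_la >= .env$min_prescriptions,
           .data$registration_end >= .data$index_date + .env$followup_days) %>%
    select(-"n_la")
}

switch_categories <- c("restart_initial", "switch_within_dpi",
                       "switch_to_pmdi_laba", "switch_to_laba_ics",
                       "switch_to_lama", "permanent_discontinuation")

#' Classify the first post-gap action of a non-persistent patient
#'
#' Examines long-acting fills in the year after the discontinuation day
#' (`(discontinuation_day, discontinuation_day + window]`) and classifies
#' the earliest one: a refill of the initial product is a restart; the same
#' medication in the other dry-powder device class is a within-DPI switch;
#' any mono-LABA in a pMDI is a pMDI switch; a fixed LABA/ICS combination
#' or a LAMA is a class switch. No such fill in the window is permanent
#' discontinuation of long-acting therapy. ICS mono-therapy fills are not
#' bronchodilator actions and are ignored. Same-day fills are resolved by
#' the fixed priority restart > within-DPI > pMDI > LABA/ICS > LAMA (the
#' most conservative reading, continuation, wins).
#'
#' @param initiation one-row initiation tibble (needs `index_date`,
#'   `initial_product`, `initial_atc`, `initial_device`).
#' @param persistence one-row result from [assess_persistence()]; must be
#'   non-persistent.
#' @param fills the patient's dispensing tibble.
#' @param device_map product-to-device tibble.
#' @param config an [atc_config()].
#' @param window days after discontinuation to search (default 365).
#' @param restart_same_product if `TRUE` (default) a restart requires the
#'   identical product; otherwise the same medication (ATC-7) in the same
#'   device class also counts.
#' @return One-row tibble `category`, `event_day`.
#' @export
classify_switch <- function(initiation, persistence, fills, device_map,
                            config = atc_config(), window = 365,
                            restart_same_product = TRUE) {
  if (persistence$persistent) {
    abort("classify_switch() applies to non-persistent patients only",
          class = "copdpersist_arg_error")
  }
  disc <- persistence$discontinuation_day
  day <- as.numeric(fills$dispense_date - initiation$index_date)
  cand <- fills[atc_matches(fills$atc_code, config$long_acting) &
                  day > disc & day <= disc + window, , drop = FALSE]
  cand_day <- day[atc_matches(fills$atc_code, config$long_acting) &
                    day > disc & day <= disc + window]
  if (nrow(cand) == 0) {
    return(tibble(category = "permanent_discontinuation",
                  event_day = NA_real_))
  }
  dm <- device_map[match(cand$product_id, device_map$product_id), ]
  if (any(is.na(dm$device_class))) {
    missing <- unique(cand$product_id[is.na(dm$device_class)])
    abort(paste0("product(s) absent from device map: ",
                 paste(missing, collapse = ", ")),
          class = "copdpersist_classification_error")
  }
  cat <- character(nrow(cand))
  same_prod <- cand$product_id == initiation$initial_product
  same_atc <- toupper(cand$atc_code) == toupper(initiation$initial_atc)
  is_dpi <- dm$device_class %in% c("single_dose_dpi", "multiple_dose_dpi")
  for (j in seq_len(nrow(cand))) {
    cat[j] <- if (same_prod[j]) {
      "restart_initial"
    } else if (dm$medication_class[j] == "laba_mono") {
      if (dm$device_class[j] == "pmdi" &&
          initiation$initial_device != "pmdi") {
        "switch_to_pmdi_laba"
      } else if (is_dpi[j] && same_atc[j] &&
                 dm$device_class[j] != initiation$initial_device) {
        "switch_within_dpi"
      } else if (same_atc[j] &&
                 dm$device_class[j] == initiation$initial_device &&
                 !restart_same_product) {
        # same medication and device class, different product id: counts as
        # a restart only under the relaxed restart definition
        "restart_initial"
      } else {
        NA_character_  # mono-LABA action outside the taxonomy
      }
    } else if (dm$medication_class[j] == "laba_ics_combo") {
      "switch_to_laba_ics"
    } else if (dm$medication_class[j] == "lama") {
      "switch_to_lama"
    } else {
      NA_character_   # ICS mono etc.: not a bronchodilator action
    }
  }
  keep <- !is.na(cat)
  if (!any(keep)) {
    return(tibble(category = "permanent_discontinuation",
                  event_day = NA_real_))
  }
  cand_day <- cand_day[keep]; cat <- cat[keep]
  first_day <- min(cand_day)
  at_first <- cat[cand_day == first_day]
  prio <- match(at_first, switch_categories)
  tibble(category = at_first[which.min(prio)], event_day = first_day)
}

#' Classify switching for every non-persistent subcohort member
#'
#' @param subcohort tibble from [select_switching_subcohort()].
#' @param persistence per-patient tibble from [cohort_persistence()].
#' @param dispensings full dispensing tibble.
#' @inheritParams classify_switch
#' @return Tibble `patient_id`, `category`, `event_day` (one row per
#'   non-persistent subcohort member).
#' @export
cohort_switch_outcomes <- function(subcohort, persistence, dispensings,
                                   device_map = default_device_map(),
                                   config = atc_config(), window = 365,
                                   restart_same_product = TRUE) {
  pres <- persistence[match(subcohort$patient_id, persistence$patient_id), ]
  idx <- which(!pres$persistent)
  by_pat <- split(dispensings, dispensings$patient_id)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    fills <- by_pat[[subcohort$patient_id[i]]]
    res <- classify_switch(subcohort[i, ], pres[i, ], fills, device_map,
                           config, window, restart_same_product)
    out[[k]] <- mutate(res, patient_id = subcohort$patient_id[i])
  }
  bind_rows(out) %>% select("patient_id", "category", "event_day")
}

#' Summarise switching patterns by device cohort
#'
#' @param outcomes tibble from [cohort_switch_outcomes()].
#' @param cohort cohort tibble carrying `patient_id`, `device_cohort`.
#' @return Tibble with one row per (device cohort, category): `n` and
#'   `fraction`; fractions sum to 1 within each cohort. An `overall` cohort
#'   row set is included.
#' @export
summarize_switching <- function(outcomes, cohort) {
  joined <- left_join(outcomes,
                      cohort[, c("patient_id", "device_cohort")],
                      by = "patient_id")
  tally <- function(df, label) {
    counts <- table(factor(df$category, levels = switch_categories))
    tibble(device_cohort = label, category = switch_categories,
           n = as.integer(counts),
           fraction = as.numeric(counts) / max(sum(counts), 1))
  }
  bind_rows(
    tally(joined, "overall"),
    bind_rows(lapply(split(joined, joined$device_cohort),
                     function(df) tally(df, df$device_cohort[1])))
  )
}
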