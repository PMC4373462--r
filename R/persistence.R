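#' Build a medication supply timeline from refills
#'
#' Converts a patient's ordered dispensing events into coverage intervals.
#' Each fill contributes `units_dispensed / prescribed_daily_dose` days of
#' supply (the refill-gap method's central quantity). With
#' `carry_over = TRUE` (default) surplus supply from an early refill is
#' stockpiled: a fill's coverage starts at the later of its dispense day and
#' the theoretical end of the previous coverage. With `carry_over = FALSE`
#' coverage always starts on the dispense day and overlapping supply is
#' simply merged (no stockpiling).
#'
#' All intervals are half-open `[start, end)` in days since the index date.
#'
#' @param fills tibble of one patient's dispensings, sorted by date. Either
#'   pre-computed columns `day` (days since index) and `duration` (days of
#'   supply), or raw reader columns `dispense_date`, `units_dispensed`,
#'   `prescribed_daily_dose` together with `index_date`.
#' @param carry_over logical; stockpile surplus supply (default `TRUE`).
#' @param index_date the index `Date`, required when `fills` carries raw
#'   dispense dates.
#' @return A tibble of class `supply_timeline` with columns `start`, `end`
#'   and `fill_ids` (list of contributing row indices), sorted and
#'   non-overlapping.
#' @examples
#' f <- tibble::tibble(day = c(0, 20), duration = c(30, 30))
#' build_supply_timeline(f)                     # [0,30) [30,60)
#' build_supply_timeline(f, carry_over = FALSE) # [0,50)
#' @export
build_supply_timeline <- function(fills, carry_over = TRUE, index_date = NULL) {
  if (!all(c("day", "duration") %in% names(fills))) {
    if (is.null(index_date)) {
      abort("supply index_date required when fills carry raw dispense dates",
            class = "copdpersist_arg_error")
    }
    fills <- mutate(fills,
                    day = as.numeric(.data$dispense_date - .env$index_date),
                    duration = .data$units_dispensed / .data$prescribed_daily_dose)
  }
  if (any(!is.finite(fills$duration) | fills$duration <= 0)) {
    abort("non-positive days of supply (check prescribed_daily_dose > 0)",
          class = "copdpersist_validation_error")
  }
  iv <- timeline_intervals(fills$day, fills$duration, carry_over)
  new_supply_timeline(tibble(start = iv$start, end = iv$end,
                             fill_ids = iv$fill_ids), carry_over)
}

# interval arithmetic core, base R for speed in per-patient loops
timeline_intervals <- function(day, dur, carry_over) {
  n <- length(day)
  if (n == 0) {
    return(list(start = numeric(0), end = numeric(0), fill_ids = list()))
  }
  o <- order(day)
  day <- day[o]; dur <- dur[o]
  if (carry_over) {
    # end_i = max(day_i, end_{i-1}) + dur_i, closed form via cumulative sums
    cdur <- cumsum(dur)
    end <- cummax(day - c(0, cdur[-n])) + cdur
    start <- pmax(day, c(-Inf, end[-n]))
    gap_before <- c(Inf, start[-1] - end[-n])
  } else {
    start <- day
    end <- day + dur
    run_end <- cummax(end)
    gap_before <- c(Inf, start[-1] - run_end[-n])
  }
  grp <- cumsum(gap_before > 0)
  s <- tapply(start, grp, min)
  e <- tapply(end, grp, max)
  list(start = as.numeric(s), end = as.numeric(e),
       fill_ids = unname(split(o, grp)))
}

# gap scan core: returns list(persistent, disc, gap). Only uncovered time
# inside [0, horizon) counts, so every gap — leading, internal or trailing —
# is truncated at the horizon; the 1-year outcome is a function of year-1
# coverage only.
gap_scan <- function(start, end, gap_days, horizon) {
  n <- length(start)
  if (n == 0) return(list(persistent = FALSE, disc = 0, gap = NA_real_))
  if (min(start[1], horizon) > gap_days) {
    return(list(persistent = FALSE, disc = 0, gap = min(start[1], horizon)))
  }
  gap_pos <- end
  gap_len <- pmax(pmin(c(start[-1], horizon), horizon) - end, 0)
  hit <- which(gap_len > gap_days & gap_pos < horizon)
  if (length(hit) == 0) {
    seen <- gap_len[gap_pos < horizon]
    return(list(persistent = TRUE, disc = NA_real_,
                gap = if (length(seen)) max(seen) else NA_real_))
  }
  list(persistent = FALSE, disc = gap_pos[hit[1]], gap = gap_len[hit[1]])
}

new_supply_timeline <- function(tbl, carry_over) {
  structure(tbl, class = c("supply_timeline", class(tbl)),
            carry_over = carry_over)
}

#' Assess persistence from a supply timeline
#'
#' Scans the gaps between consecutive coverage intervals, plus the trailing
#' gap from the end of the last coverage to the horizon, and declares the
#' patient non-persistent at the first gap strictly longer than `gap_days`
#' whose preceding coverage ends before the horizon. A gap of exactly
#' `gap_days` days is allowed. The discontinuation day is the theoretical
#' end of the last covered interval before the first disqualifying gap.
#' Only uncovered time inside the 1-year window counts: every gap is
#' truncated at the horizon, so gaps that open on or after the horizon are
#' ignored and a gap straddling the horizon contributes only its in-window
#' part. This keeps the outcome a function of first-year coverage alone and
#' makes persistence monotone under added coverage (switching dominance).
#'
#' @param timeline a `supply_timeline` (see [build_supply_timeline()]).
#' @param gap_days maximum permissible gap, in days (default 60).
#' @param horizon observation horizon in days since index (default 365).
#' @return One-row tibble: `persistent`, `discontinuation_day` (NA when
#'   persistent), `first_gap_length`, `gap_days`, `horizon`.
#' @examples
#' tl <- build_supply_timeline(tibble::tibble(day = 0, duration = 30))
#' assess_persistence(tl)   # non-persistent at day 30
#' @export
assess_persistence <- function(timeline, gap_days = 60, horizon = 365) {
  stopifnot(gap_days >= 1, horizon >= 1)
  g <- gap_scan(timeline$start, timeline$end, gap_days, horizon)
  persistence_row(g$persistent, g$disc, g$gap, gap_days, horizon)
}

persistence_row <- function(persistent, disc, gap, gap_days, horizon) {
  tibble(persistent = persistent,
         discontinuation_day = disc,
         first_gap_length = gap,
         gap_days = gap_days, horizon = horizon)
}

#' Assess persistence with any long-acting medication (switching allowed)
#'
#' Pools every long-acting respiratory fill (LABA mono, LABA/ICS
#' combination, ICS, LAMA) into one supply timeline before applying the gap
#' rule, so a patient who switches device or medication class without a
#' disqualifying gap still counts as persistent. Pointwise this can only
#' improve on initial-therapy persistence.
#'
#' @param fills one patient's dispensing tibble (reader columns).
#' @param index_date the patient's index `Date`.
#' @param config an [atc_config()].
#' @inheritParams assess_persistence
#' @inheritParams build_supply_timeline
#' @return As [assess_persistence()].
#' @export
assess_persistence_any <- function(fills, index_date, config = atc_config(),
                                   gap_days = 60, horizon = 365,
                                   carry_over = TRUE) {
  la <- fills[atc_matches(fills$atc_code, config$long_acting) &
                fills$dispense_date >= index_date, , drop = FALSE]
  tl <- build_supply_timeline(la, carry_over = carry_over,
                              index_date = index_date)
  assess_persistence(tl, gap_days = gap_days, horizon = horizon)
}

#' Per-patient persistence over a cohort
#'
#' Applies the refill-gap method to every cohort member. With
#' `scope = "initial_product"` only fills of the index product feed the
#' timeline (persistence with initial therapy); with
#' `scope = "any_long_acting"` all long-acting fills are pooled (switching
#' allowed).
#'
#' @param cohort cohort tibble from [apply_selection()] (needs `patient_id`,
#'   `index_date`, `initial_product`).
#' @param dispensings full dispensing tibble.
#' @param config an [atc_config()].
#' @param scope `"initial_product"` or `"any_long_acting"`.
#' @inheritParams assess_persistence
#' @inheritParams build_supply_timeline
#' @return Tibble with one row per patient: `patient_id` plus the
#'   [assess_persistence()] columns.
#' @export
cohort_persistence <- function(cohort, dispensings, config = atc_config(),
                               gap_days = 60, horizon = 365,
                               carry_over = TRUE,
                               scope = c("initial_product", "any_long_acting")) {
  scope <- match.arg(scope)
  disp <- dispensings[dispensings$patient_id %in% cohort$patient_id, ,
                      drop = FALSE]
  if (scope == "any_long_acting") {
    disp <- disp[atc_matches(disp$atc_code, config$long_acting), ,
                 drop = FALSE]
  }
  if (any(disp$prescribed_daily_dose <= 0)) {
    abort("non-positive prescribed_daily_dose in dispensings",
          class = "copdpersist_validation_error")
  }
  pid_split <- split(seq_len(nrow(disp)), disp$patient_id)
  n <- nrow(cohort)
  persistent <- logical(n); disc <- numeric(n); gap <- numeric(n)
  for (i in seq_len(n)) {
    rows <- pid_split[[cohort$patient_id[i]]]
    idx <- cohort$index_date[i]
    day <- as.numeric(disp$dispense_date[rows] - idx)
    keep <- day >= 0
    if (scope == "initial_product") {
      keep <- keep & disp$product_id[rows] == cohort$initial_product[i]
    }
    day <- day[keep]; rows <- rows[keep]
    dur <- disp$units_dispensed[rows] / disp$prescribed_daily_dose[rows]
    iv <- timeline_intervals(day, dur, carry_over)
    g <- gap_scan(iv$start, iv$end, gap_days, horizon)
    persistent[i] <- g$persistent; disc[i] <- g$disc; gap[i] <- g$gap
  }
  tibble(patient_id = cohort$patient_id, persistent = persistent,
         discontinuation_day = ifelse(persistent, NA_real_, disc),
         first_gap_length = gap, gap_days = gap_days, horizon = horizon)
}

#' Summarise cohort persistence
#'
#' @param results per-patient tibble from [cohort_persistence()].
#' @param cohort cohort tibble carrying `patient_id` and `device_cohort`.
#' @return Tibble with persistent fraction overall and per device cohort.
#' @export
summarize_persistence <- function(results, cohort) {
  joined <- left_join(results, cohort[, c("patient_id", "device_cohort")],
                      by = "patient_id")
  overall <- tibble(device_cohort = "overall",
                    n = nrow(joined),
                    n_persistent = sum(joined$persistent),
                    persistent_pct = 100 * mean(joined$persistent))
  per <- joined %>%
    group_by(.data$device_cohort) %>%
    summarise(n = dplyr::n(), n_persistent = sum(.data$persistent),
              persistent_pct = 100 * mean(.data$persistent),
              .groups = "drop")
  bind_rows(overall, per)
}
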