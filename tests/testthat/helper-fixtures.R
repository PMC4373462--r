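# Shared fixtures and independent oracles for the test suite.

# one dispensing row; days are offsets from a fixed anchor date
anchor_date <- as.Date("2005-06-01")

make_fill <- function(pid = "P1", day = 0, atc = "R03AC13",
                      product = "formoterol_md", units = 60, pdd = 2,
                      prescriber = "general_practitioner") {
  tibble::tibble(patient_id = pid, dispense_date = anchor_date + day,
                 atc_code = atc, product_id = product,
                 units_dispensed = units, prescribed_daily_dose = pdd,
                 prescriber = prescriber)
}

make_fills <- function(days, ...) {
  dplyr::bind_rows(lapply(days, function(d) make_fill(day = d, ...)))
}

make_patient <- function(pid = "P1", birth = "1940-01-01", gender = "male",
                         ses = 0.5, reg_start = "1995-01-01",
                         reg_end = "2012-12-31", death = NA) {
  tibble::tibble(patient_id = pid, birth_date = as.Date(birth),
                 gender = gender, ses_score = ses,
                 registration_start = as.Date(reg_start),
                 registration_end = as.Date(reg_end),
                 death_date = as.Date(death))
}

# Day-by-day stock oracle for the refill-gap supply model. Returns the set
# of covered days in [0, n_days). Carry-over: a running stock of supply
# days is topped up at each fill and decremented one per covered day.
# Without carry-over a day is covered iff some fill's own window covers it.
oracle_covered_days <- function(day, dur, carry_over, n_days = 800) {
  covered <- logical(n_days)
  if (carry_over) {
    topup <- numeric(n_days)
    for (i in seq_along(day)) {
      t <- day[i] + 1
      if (t >= 1 && t <= n_days) topup[t] <- topup[t] + dur[i]
    }
    stock <- 0
    for (t in seq_len(n_days)) {
      stock <- stock + topup[t]
      if (stock > 0) {
        covered[t] <- TRUE
        stock <- stock - 1
      }
    }
  } else {
    for (i in seq_along(day)) {
      lo <- max(day[i], 0)
      hi <- min(day[i] + dur[i] - 1, n_days - 1)
      if (hi >= lo) covered[(lo + 1):(hi + 1)] <- TRUE
    }
  }
  which(covered) - 1L
}

timeline_covered_days <- function(tl, n_days = 800) {
  out <- integer(0)
  for (i in seq_len(nrow(tl))) {
    lo <- max(ceiling(tl$start[i]), 0)
    hi <- min(ceiling(tl$end[i]) - 1, n_days - 1)
    if (hi >= lo) out <- c(out, lo:hi)
  }
  sort(unique(out))
}

# two-sided Fisher exact p by full hypergeometric enumeration
# (point-probability method) for a 2x2 table given as c(a, b, c, d) rows
# (a, b) / (c, d)
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b      # row 1 total
  n <- c + d      # row 2 total
  k <- a + c      # column 1 total
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# small clean simulation (no contamination) for property tests
clean_sim_config <- function(n = 300, seed = 1, ...) {
  simulation_config(n_patients = n, seed = seed,
                    p_asthma_contaminant = 0, p_missing_field = 0,
                    p_dual_initiator = 0, p_death_year1 = 0, ...)
}

build_cohort_from <- function(pop) {
  init <- find_initiations(pop$dispensings, device_map = pop$device_map)
  apply_selection(pop$patients, pop$dispensings, init)
}
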