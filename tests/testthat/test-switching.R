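dmap <- default_device_map()

mk_initiation <- function(product = "indacaterol_sd", atc = "R03AC18",
                          device = "single_dose_dpi") {
  tibble::tibble(patient_id = "P1", index_date = anchor_date,
                 initial_atc = atc, initial_product = product,
                 initial_device = device)
}

mk_persistence <- function(disc = 30) {
  tibble::tibble(persistent = FALSE, discontinuation_day = disc,
                 first_gap_length = 100, gap_days = 60, horizon = 365)
}

run_sel <- function(patients, disp) {
  init <- find_initiations(disp, device_map = dmap)
  apply_selection(patients, disp, init)
}

test_that("the subcohort needs 2-year follow-up and two long-acting fills", {
  pats <- dplyr::bind_rows(
    make_patient("A"),                                    # qualifies
    make_patient("B"),                                    # one fill only
    make_patient("C", reg_end = as.character(anchor_date + 540)))  # 18 months
  disp <- dplyr::bind_rows(
    make_fill("A"), make_fill("A", day = 40),
    make_fill("B"),
    make_fill("C"), make_fill("C", day = 40))
  sel <- run_sel(pats, disp)
  sub <- select_switching_subcohort(sel$cohort, disp)
  expect_equal(sub$patient_id, "A")
})

test_that("the first post-gap fill determines the switch category", {
  # single-dose formoterol initiator; multiple-dose formoterol at +40 days
  ini <- mk_initiation("formoterol_sd", "R03AC13")
  fills <- dplyr::bind_rows(
    make_fill(day = 0, product = "formoterol_sd"),
    make_fill(day = 70, product = "formoterol_md"))
  out <- classify_switch(ini, mk_persistence(30), fills, dmap)
  expect_equal(out$category, "switch_within_dpi")
  expect_equal(out$event_day, 70)

  # LABA in a pMDI
  fills$product_id[2] <- "formoterol_pmdi"
  out <- classify_switch(ini, mk_persistence(30), fills, dmap)
  expect_equal(out$category, "switch_to_pmdi_laba")

  # LABA/ICS combination and LAMA class switches
  fills2 <- dplyr::bind_rows(
    make_fill(day = 0, product = "formoterol_sd"),
    make_fill(day = 100, atc = "R03AK06", product = "salmeterol_fluticasone_md"))
  expect_equal(classify_switch(ini, mk_persistence(30), fills2, dmap)$category,
               "switch_to_laba_ics")
  fills2$product_id[2] <- "tiotropium_sd"; fills2$atc_code[2] <- "R03BB04"
  expect_equal(classify_switch(ini, mk_persistence(30), fills2, dmap)$category,
               "switch_to_lama")

  # nothing in the window: permanent discontinuation
  alone <- make_fill(day = 0, product = "formoterol_sd")
  out <- classify_switch(ini, mk_persistence(30), alone, dmap)
  expect_equal(out$category, "permanent_discontinuation")
  expect_true(is.na(out$event_day))
})

test_that("same-day ties resolve by the fixed conservative priority", {
  ini <- mk_initiation("formoterol_sd", "R03AC13")
  fills <- dplyr::bind_rows(
    make_fill(day = 0, product = "formoterol_sd"),
    make_fill(day = 120, product = "formoterol_sd"),
    make_fill(day = 120, atc = "R03BB04", product = "tiotropium_sd"))
  out <- classify_switch(ini, mk_persistence(30), fills, dmap)
  expect_equal(out$category, "restart_initial")
  # without the restart fill, the tie partner decides
  out2 <- classify_switch(ini, mk_persistence(30), fills[-2, ], dmap)
  expect_equal(out2$category, "switch_to_lama")
})

test_that("fills outside the post-gap window never change the category", {
  ini <- mk_initiation("formoterol_sd", "R03AC13")
  base <- dplyr::bind_rows(
    make_fill(day = 0, product = "formoterol_sd"),
    make_fill(day = 200, product = "formoterol_md"))
  out <- classify_switch(ini, mk_persistence(30), base, dmap)
  # add fills before the gap and beyond the window
  noisy <- dplyr::bind_rows(
    base,
    make_fill(day = 20, product = "formoterol_sd"),
    make_fill(day = 30 + 366, atc = "R03BB04", product = "tiotropium_sd"))
  out2 <- classify_switch(ini, mk_persistence(30), noisy, dmap)
  expect_equal(out2$category, out$category)
  expect_equal(out2$event_day, out$event_day)
})

test_that("ICS mono-therapy is not a bronchodilator action", {
  ini <- mk_initiation("formoterol_sd", "R03AC13")
  fills <- dplyr::bind_rows(
    make_fill(day = 0, product = "formoterol_sd"),
    make_fill(day = 100, atc = "R03BA02", product = "budesonide_md"))
  expect_equal(classify_switch(ini, mk_persistence(30), fills, dmap)$category,
               "permanent_discontinuation")
})

test_that("an unmapped inhaler product raises a classification error", {
  ini <- mk_initiation("formoterol_sd", "R03AC13")
  fills <- dplyr::bind_rows(
    make_fill(day = 0, product = "formoterol_sd"),
    make_fill(day = 100, product = "mystery_inhaler"))
  expect_error(classify_switch(ini, mk_persistence(30), fills, dmap),
               "mystery_inhaler",
               class = "copdpersist_classification_error")
})

test_that("classification recovers the generator's ground truth", {
  pop <- generate_population(clean_sim_config(n = 300, seed = 27))
  sel <- build_cohort_from(pop)
  pers <- cohort_persistence(sel$cohort, pop$dispensings)
  sub <- select_switching_subcohort(sel$cohort, pop$dispensings)
  out <- cohort_switch_outcomes(sub, pers, pop$dispensings, pop$device_map)
  gt <- pop$ground_truth[match(out$patient_id, pop$ground_truth$patient_id), ]
  expect_gt(nrow(out), 30)
  expect_equal(out$category, gt$true_switch_category)
  ev <- !is.na(out$event_day)
  expect_equal(out$event_day[ev], gt$true_event_day[ev])
})

test_that("switching fractions partition each device cohort", {
  pop <- generate_population(clean_sim_config(n = 300, seed = 28))
  sel <- build_cohort_from(pop)
  pers <- cohort_persistence(sel$cohort, pop$dispensings)
  sub <- select_switching_subcohort(sel$cohort, pop$dispensings)
  out <- cohort_switch_outcomes(sub, pers, pop$dispensings, pop$device_map)
  frac <- summarize_switching(out, sel$cohort)
  sums <- tapply(frac$fraction, frac$device_cohort, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # single patient: one category takes fraction 1
  frac1 <- summarize_switching(out[1, ], sel$cohort)
  one <- frac1[frac1$device_cohort == "overall", ]
  expect_equal(sum(one$fraction == 1), 1)
  expect_equal(sum(one$fraction), 1)
})
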