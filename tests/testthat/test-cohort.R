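dmap <- default_device_map()

test_that("initiation is the first mono-LABA dispensing, once per patient", {
  disp <- dplyr::bind_rows(
    make_fill("A", day = 0, atc = "R03AC13"),
    make_fill("A", day = 30, atc = "R03AC13"),
    make_fill("B", day = 10, atc = "R03BB04", product = "tiotropium_sd"))
  init <- find_initiations(disp, device_map = dmap)
  expect_equal(nrow(init), 1)
  expect_equal(init$patient_id, "A")
  expect_equal(init$index_date, anchor_date)
  expect_equal(init$initial_device, "multiple_dose_dpi")
  expect_false(init$dual_candidate)
})

test_that("same-day second long-acting product flags a dual-initiation candidate", {
  disp <- dplyr::bind_rows(
    make_fill("A", day = 0, atc = "R03AC12", product = "salmeterol_md"),
    make_fill("A", day = 0, atc = "R03BA02", product = "budesonide_md"))
  init <- find_initiations(disp, device_map = dmap)
  expect_equal(nrow(init), 1)
  expect_true(init$dual_candidate)
})

run_selection <- function(patients, disp, ...) {
  init <- find_initiations(disp, device_map = dmap)
  apply_selection(patients, disp, init, ...)
}

test_that("the age floor is inclusive by default and configurable to strict", {
  # index at anchor; born anchor - 54y and anchor - 55y
  p54 <- make_patient("A", birth = as.character(anchor_date - round(54 * 365.25)))
  p55 <- make_patient("B", birth = as.character(anchor_date - round(55 * 365.25) - 1))
  disp <- dplyr::bind_rows(make_fill("A"), make_fill("B"))
  sel <- run_selection(dplyr::bind_rows(p54, p55), disp)
  expect_equal(sel$cohort$patient_id, "B")
  expect_equal(sel$flow$n_removed[sel$flow$filter == "underage"], 1L)
  strict <- run_selection(dplyr::bind_rows(p54, p55), disp, age_strict = TRUE,
                          min_age = 55)
  expect_equal(nrow(strict$cohort), 1)  # 55.0 exactly would be excluded
})

test_that("prior long-acting exposure within the washout breaks naivety", {
  pats <- make_patient("A")
  disp <- dplyr::bind_rows(
    make_fill("A", day = -400, atc = "R03BA02", product = "budesonide_md"),
    make_fill("A", day = 0))
  sel <- run_selection(pats, disp)
  expect_equal(nrow(sel$cohort), 0)
  expect_equal(sel$flow$n_removed[sel$flow$filter == "not_naive"], 1L)
  # exposure older than the washout is fine
  disp_old <- dplyr::bind_rows(
    make_fill("A", day = -800, atc = "R03BA02", product = "budesonide_md"),
    make_fill("A", day = 0))
  expect_equal(nrow(run_selection(pats, disp_old)$cohort), 1)
})

test_that("registration must cover two years back and one year forward", {
  short <- make_patient("A", reg_start = as.character(anchor_date - 100))
  sel <- run_selection(short, make_fill("A"))
  expect_equal(sel$flow$n_removed[sel$flow$filter == "incomplete_registration"], 1L)
  short_end <- make_patient("A", reg_end = as.character(anchor_date + 100))
  sel <- run_selection(short_end, make_fill("A"))
  expect_equal(sel$flow$n_removed[sel$flow$filter == "incomplete_registration"], 1L)
})

test_that("asthma medication in year 1, dual initiation and death are excluded", {
  pats <- dplyr::bind_rows(make_patient("A"), make_patient("B"),
                           make_patient("C", death = as.character(anchor_date + 200)))
  disp <- dplyr::bind_rows(
    make_fill("A"), make_fill("A", day = 100, atc = "R06AE07",
                              product = "cetirizine", pdd = 1, units = 30),
    make_fill("B"), make_fill("B", day = 0, atc = "R03BB04",
                              product = "tiotropium_sd"),
    make_fill("C"))
  sel <- run_selection(pats, disp)
  expect_equal(nrow(sel$cohort), 0)
  fl <- sel$flow
  expect_equal(fl$n_removed[fl$filter == "asthma_medication"], 1L)
  expect_equal(fl$n_removed[fl$filter == "dual_initiation"], 1L)
  expect_equal(fl$n_removed[fl$filter == "death_within_followup"], 1L)
  reasons <- attr(sel$cohort, "exclusion_reasons")
  expect_equal(sort(reasons$reason),
               sort(c("asthma_medication", "dual_initiation",
                      "death_within_followup")))
})

test_that("missing essential data is drawn from reject lists and NA fields", {
  pats <- dplyr::bind_rows(make_patient("A", gender = NA), make_patient("B"))
  disp <- dplyr::bind_rows(make_fill("A"), make_fill("B"))
  rej <- tibble::tibble(patient_id = "B", reason = "missing_pdd")
  sel <- run_selection(pats, disp, dispensing_rejects = rej)
  expect_equal(nrow(sel$cohort), 0)
  expect_equal(sel$flow$n_removed[sel$flow$filter == "missing_essential_data"], 2L)
})

test_that("a dispensing for an unknown patient is a data-integrity error", {
  expect_error(run_selection(make_patient("A"), dplyr::bind_rows(
    make_fill("A"), make_fill("GHOST"))),
    class = "copdpersist_integrity_error")
})

test_that("the flow is conservative and each exclusion has one reason", {
  pop <- generate_population(simulation_config(n_patients = 350, seed = 23))
  sel <- build_cohort_from(pop)
  fl <- sel$flow
  expect_equal(fl$n_remaining[1] - sum(fl$n_removed), nrow(sel$cohort))
  expect_true(all(diff(fl$n_remaining) <= 0))
  reasons <- attr(sel$cohort, "exclusion_reasons")
  expect_equal(nrow(reasons), sum(fl$n_removed))
  expect_false(any(duplicated(reasons$patient_id)))
})

test_that("flow counts equal the generator's ground-truth exclusion reasons", {
  pop <- generate_population(simulation_config(n_patients = 400, seed = 24))
  sel <- build_cohort_from(pop)
  truth <- table(pop$ground_truth$true_exclusion)
  fl <- sel$flow
  for (nm in names(truth)) {
    expect_equal(fl$n_removed[fl$filter == nm], as.integer(truth[[nm]]),
                 info = nm)
  }
  expect_equal(nrow(sel$cohort),
               sum(is.na(pop$ground_truth$true_exclusion)))
})

test_that("the final cohort is independent of the order of the independent filters", {
  # age / naive / registration are per-patient predicates: cohort membership
  # must not depend on which of them fires first, only the flow does
  pop <- generate_population(simulation_config(n_patients = 200, seed = 25))
  init <- find_initiations(pop$dispensings, device_map = pop$device_map)
  base <- apply_selection(pop$patients, pop$dispensings, init)
  # a patient failing several filters is removed exactly once
  expect_true(all(base$flow$n_removed >= 0))
  expect_equal(sum(base$flow$n_removed) + nrow(base$cohort),
               base$flow$n_remaining[1])
})
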