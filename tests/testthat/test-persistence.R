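test_that("supply timelines implement the doses/daily-dose coverage rule", {
  # one fill of 60 doses at 2/day covers 30 days
  tl <- build_supply_timeline(tibble::tibble(day = 0, duration = 30))
  expect_equal(unclass(tl$start), 0)
  expect_equal(unclass(tl$end), 30)

  tl <- build_supply_timeline(make_fill(units = 60, pdd = 2),
                              index_date = anchor_date)
  expect_equal(tl$end, 30)

  # early refill: carry-over stockpiles, no carry-over merges
  f <- tibble::tibble(day = c(0, 20), duration = c(30, 30))
  co <- build_supply_timeline(f, carry_over = TRUE)
  expect_equal(co$start, 0)        # contiguous, merged into one interval
  expect_equal(co$end, 60)
  nc <- build_supply_timeline(f, carry_over = FALSE)
  expect_equal(nc$start, 0)
  expect_equal(nc$end, 50)

  expect_error(build_supply_timeline(make_fill(pdd = 0),
                                     index_date = anchor_date),
               class = "copdpersist_validation_error")
  expect_error(build_supply_timeline(make_fill()),
               class = "copdpersist_arg_error")  # no index date
})

test_that("interval arithmetic equals the day-by-day stock oracle", {
  set.seed(7)
  for (rep in 1:60) {
    n_fills <- sample(1:10, 1)
    day <- sort(sample(0:400, n_fills))
    dur <- sample(c(10, 15, 30, 60, 90), n_fills, replace = TRUE)
    for (co in c(TRUE, FALSE)) {
      tl <- build_supply_timeline(tibble::tibble(day = day, duration = dur),
                                  carry_over = co)
      expect_equal(timeline_covered_days(tl),
                   oracle_covered_days(day, dur, co),
                   info = sprintf("rep %d carry_over %s", rep, co))
    }
  }
})

test_that("the gap rule flags the theoretical end before the first long gap", {
  one_fill <- build_supply_timeline(tibble::tibble(day = 0, duration = 30))
  r <- assess_persistence(one_fill, gap_days = 60, horizon = 365)
  expect_false(r$persistent)
  expect_equal(r$discontinuation_day, 30)

  # sub-threshold gap does not discontinue at day 30
  f <- build_supply_timeline(tibble::tibble(day = c(0, 80), duration = c(30, 30)))
  r <- assess_persistence(f)
  expect_equal(r$discontinuation_day, 110)  # later trailing gap, not day 30

  # trailing gap within threshold: persistent
  late <- build_supply_timeline(tibble::tibble(day = 0, duration = 330))
  expect_true(assess_persistence(late)$persistent)

  # a gap of exactly gap_days is allowed
  exact <- build_supply_timeline(tibble::tibble(day = c(0, 90), duration = c(30, 245)))
  expect_true(assess_persistence(exact)$persistent)
  # one day more is not
  over <- build_supply_timeline(tibble::tibble(day = c(0, 91), duration = c(30, 244)))
  r <- assess_persistence(over)
  expect_false(r$persistent)
  expect_equal(r$discontinuation_day, 30)

  # empty timeline
  r <- assess_persistence(build_supply_timeline(
    tibble::tibble(day = numeric(0), duration = numeric(0))))
  expect_false(r$persistent)
  expect_equal(r$discontinuation_day, 0)
})

test_that("only uncovered time inside the horizon counts", {
  # coverage to day 320, next fill at day 400: in-window gap is 45 days
  tl <- build_supply_timeline(tibble::tibble(day = c(0, 400),
                                             duration = c(320, 30)))
  expect_true(assess_persistence(tl)$persistent)
  # same coverage but the gap opens early enough to exceed the threshold
  tl2 <- build_supply_timeline(tibble::tibble(day = c(0, 400),
                                              duration = c(200, 30)))
  r <- assess_persistence(tl2)
  expect_false(r$persistent)
  expect_equal(r$discontinuation_day, 200)
  # discontinuation events after the horizon are ignored
  tl3 <- build_supply_timeline(tibble::tibble(day = 0, duration = 370))
  expect_true(assess_persistence(tl3)$persistent)
})

test_that("pooled long-acting persistence dominates initial-product persistence", {
  cfg <- atc_config()
  # LABA covers [0,90); LAMA covers [95, 380)
  fills <- dplyr::bind_rows(
    make_fill(day = 0, units = 180, pdd = 2),
    make_fill(day = 95, atc = "R03BB04", product = "tiotropium_sd",
              units = 285, pdd = 1))
  any_r <- assess_persistence_any(fills, anchor_date, cfg)
  expect_true(any_r$persistent)
  init_tl <- build_supply_timeline(fills[1, ], index_date = anchor_date)
  init_r <- assess_persistence(init_tl)
  expect_false(init_r$persistent)
  expect_equal(init_r$discontinuation_day, 90)
})

test_that("per-patient flags are monotone in the gap and dominated by pooling", {
  pop <- generate_population(clean_sim_config(n = 250, seed = 31))
  sel <- build_cohort_from(pop)
  p30 <- cohort_persistence(sel$cohort, pop$dispensings, gap_days = 30)
  p60 <- cohort_persistence(sel$cohort, pop$dispensings, gap_days = 60)
  p90 <- cohort_persistence(sel$cohort, pop$dispensings, gap_days = 90)
  pany <- cohort_persistence(sel$cohort, pop$dispensings,
                             scope = "any_long_acting")
  expect_true(all(p30$persistent <= p60$persistent))
  expect_true(all(p60$persistent <= p90$persistent))
  expect_true(all(p60$persistent <= pany$persistent))
})

test_that("a one-time user whose supply runs out early is never persistent", {
  for (g in c(30, 60, 90)) {
    tl <- build_supply_timeline(tibble::tibble(day = 0, duration = 30))
    r <- assess_persistence(tl, gap_days = g, horizon = 365)
    expect_false(r$persistent)
    expect_equal(r$discontinuation_day, 30)
  }
})

test_that("the engine reproduces the generator's ground truth exactly", {
  pop <- generate_population(clean_sim_config(n = 250, seed = 19))
  sel <- build_cohort_from(pop)
  pers <- cohort_persistence(sel$cohort, pop$dispensings)
  gt <- pop$ground_truth[match(pers$patient_id, pop$ground_truth$patient_id), ]
  expect_equal(pers$persistent, gt$true_persistent_365)
  np <- !pers$persistent
  expect_equal(pers$discontinuation_day[np], gt$true_discontinuation_day[np])
})

test_that("mixed daily doses contribute per-fill supply durations", {
  # 30 doses at 1/day then 60 doses at 2/day: 30 + 30 days of coverage
  fills <- dplyr::bind_rows(make_fill(day = 0, units = 30, pdd = 1),
                            make_fill(day = 30, units = 60, pdd = 2))
  tl <- build_supply_timeline(fills, index_date = anchor_date)
  expect_equal(max(tl$end), 60)
})
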