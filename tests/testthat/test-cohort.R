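t0 <- as.POSIXct("2020-01-01 08:00", tz = "UTC")

trig_at <- function(scores, admission_hour = length(scores) + 1) {
  detect_sustained_trigger(scores, t0 + 3600 * seq_along(scores),
                           t0 + 3600 * (admission_hour + 0.5))
}

test_that("sustained-trigger detection follows the inclusion rule", {
  tr <- trig_at(c(4, 7, 6, 8))
  expect_identical(tr$index, 2L)
  expect_identical(tr$score, 7)

  tr <- trig_at(c(8, 4, 9, 7))  # the 8 is disqualified by the later 4
  expect_identical(tr$index, 3L)
  expect_identical(tr$score, 9)

  tr <- trig_at(7)              # vacuously sustained
  expect_identical(tr$index, 1L)

  expect_null(trig_at(c(6, 6, 6)))
  expect_null(trig_at(c(8, 8, 4)))
  expect_null(detect_sustained_trigger(numeric(0), as.POSIXct(character()),
                                       t0))
  # observations at or after admission are outside the window
  tr <- detect_sustained_trigger(c(7, 3), t0 + c(3600, 7200), t0 + 7200)
  expect_identical(tr$index, 1L)
})

test_that("unsorted or malformed timelines are rejected", {
  expect_error(detect_sustained_trigger(c(7, 8), t0 + c(7200, 3600),
                                        t0 + 86400),
               "strictly increasing")
  expect_error(detect_sustained_trigger(c(7, 8), t0 + 3600, t0 + 86400),
               "equal length")
})

test_that("detector matches the quadratic brute-force scan on random input", {
  set.seed(99)
  for (rep in 1:300) {
    n <- sample(0:12, 1)
    scores <- sample(0:14, n, replace = TRUE)
    got <- trig_at(scores)
    want <- oracle_trigger_index(scores)
    if (is.null(want)) expect_null(got) else {
      expect_identical(got$index, want)
      expect_identical(got$score, scores[want])
    }
  }
})

test_that("inserting a sub-floor observation never advances the trigger", {
  set.seed(5)
  n_checked <- 0
  for (rep in 1:200) {
    n <- sample(1:10, 1)
    scores <- sample(0:14, n, replace = TRUE)
    before <- trig_at(scores)
    k <- sample(0:n, 1)  # insertion point (0 = before everything)
    scores2 <- append(scores, sample(0:4, 1), after = k)
    after <- trig_at(scores2)
    if (is.null(before)) {
      # a sub-floor reading can never create a trigger
      expect_null(after)
    } else if (!is.null(after)) {
      orig_index <- after$index - as.integer(after$index > k)
      expect_gte(orig_index, before$index)
      n_checked <- n_checked + 1
    }
  }
  expect_gt(n_checked, 20)
})

test_that("Score-to-Door time is the trigger-to-first-heart-rate interval", {
  trig <- as.POSIXct("2020-03-02 10:00", tz = "UTC")
  expect_equal(compute_score_to_door(trig, trig + 6.3 * 3600), 6.3)
  expect_equal(compute_score_to_door(trig, trig + 169 * 3600), 169)
  expect_error(compute_score_to_door(trig, trig), "non-positive")
  expect_error(compute_score_to_door(trig, trig - 60), "precedes")
  expect_error(compute_score_to_door(trig, as.POSIXct(NA)), "missing")
})

test_that("out-of-hours covers weekends and weekday nights, half-open", {
  oh <- function(s) is_out_of_hours(as.POSIXct(s, tz = "UTC"))
  expect_true(oh("2021-02-06 12:00"))   # Saturday noon
  expect_false(oh("2021-02-02 19:59"))  # Tuesday evening, in hours
  expect_true(oh("2021-02-02 20:00"))
  expect_false(oh("2021-02-01 08:00"))  # Monday morning boundary
  expect_true(oh("2021-02-01 03:00"))
  expect_true(oh("2021-02-08 00:00"))   # Monday 00:00 is weekday night
  expect_true(oh("2021-02-06 00:00"))   # Saturday 00:00 starts the weekend
  expect_false(oh("2021-02-05 19:59"))  # Friday just before the night window
})

test_that("derivation reproduces a hand-computed ledger", {
  pts <- list(
    make_patient("A1", c(5, 10, 12), c(3, 8, 7), door_hour = 14),
    make_patient("A2", c(5, 10), c(4, 9), door_hour = 13),
    make_patient("A3", c(5, 8, 11), c(2, 7, 5), door_hour = 12),
    make_patient("E1", numeric(0), integer(0), door_hour = 6,
                 pathway = "ed"),
    make_patient("E2", numeric(0), integer(0), door_hour = 4,
                 pathway = "ed"),
    make_patient("E3", numeric(0), integer(0), door_hour = 8,
                 pathway = "ed"),
    make_patient("N1", c(5, 10), c(6, 6), door_hour = 12),
    make_patient("N2", c(5, 8, 10), c(9, 4, 6), door_hour = 12),
    make_patient("L1", c(5, 6), c(8, 8), door_hour = 6 + 200),
    make_patient("M1", c(5, 9), c(3, 8), door_hour = 12))
  study <- bind_patients(pts)
  cov <- complete_covariates(c("A1", "A2", "A3", "E1", "E2", "E3", "N1",
                               "N2", "L1", "M1"))
  cov$sofa_day1[cov$patient_id == "M1"] <- NA
  res <- derive_cohort(study$observations, study$events, cov)
  expect_identical(res$ledger$n, c(10L, 3L, 2L, 1L, 1L, 3L))
  expect_setequal(res$cohort$patient_id, c("A1", "A2", "A3"))
  # trigger of A1 is the 8 at hour 10; door at hour 14
  a1 <- res$cohort[res$cohort$patient_id == "A1", ]
  expect_equal(a1$std_hours, 4)
  expect_identical(a1$trigger_news, 8L)
  expect_equal(a1$time_to_trigger_days, 10 / 24)
  # the missing-data patient is retained for imputation, flagged
  expect_identical(sum(!res$cohort_imputable$complete_case), 1L)
  expect_true("M1" %in% res$cohort_imputable$patient_id)
})

test_that("a theatre visit between ward and critical care excludes", {
  p <- make_patient("T1", c(5, 10), c(3, 9), door_hour = 14,
                    pathway = "theatre")
  res <- derive_cohort(p$observations, p$events,
                       complete_covariates("T1"))
  expect_identical(res$ledger$n[res$ledger$step == "excluded_direct_ed"], 1L)
  expect_identical(nrow(res$cohort), 0L)
})

test_that("empty input yields an empty cohort and an all-zero ledger", {
  p <- make_patient("X", numeric(0), integer(0), door_hour = 5)
  res <- derive_cohort(p$observations, p$events[0, ],
                       complete_covariates(character(0)))
  expect_identical(nrow(res$cohort), 0L)
  expect_true(all(res$ledger$n == 0L))
})

test_that("duplicate timestamps and duplicate covariate rows are data errors", {
  p <- make_patient("D1", c(5, 5), c(8, 8), door_hour = 10)
  expect_error(derive_cohort(p$observations, p$events,
                             complete_covariates("D1")),
               "duplicate observation timestamps")
  p2 <- make_patient("D2", c(5, 6), c(8, 8), door_hour = 10)
  expect_error(derive_cohort(p2$observations, p2$events,
                             complete_covariates(c("D2", "D2"))),
               "duplicate covariate rows")
})

test_that("ledger conservation holds for any generated study", {
  for (seed in c(11, 12)) {
    cfg <- generator_config(n_patients = 150, seed = seed,
                            fraction_theatre = 0.05)
    study <- simulate_study(cfg)
    res <- derive_cohort(study$observations, study$events, study$covariates)
    expect_identical(res$ledger$n[1],
                     sum(res$ledger$n[2:6]))
    expect_identical(res$ledger$n[6], nrow(res$cohort))
  }
})
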