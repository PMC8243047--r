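test_that("generation is deterministic given the seed", {
  cfg <- generator_config(n_patients = 60, seed = 50)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a, b)
  c2 <- simulate_study(generator_config(n_patients = 60, seed = 51))
  expect_false(identical(a$observations, c2$observations))
})

test_that("a pure-sustained configuration is included in full", {
  cfg <- generator_config(n_patients = 100, seed = 52,
                          fraction_ed_direct = 0, fraction_not_sustained = 0,
                          fraction_over_cap = 0, fraction_missing = 0)
  study <- simulate_study(cfg)
  res <- derive_cohort(study$observations, study$events, study$covariates)
  expect_identical(res$ledger$n,
                   c(100L, 0L, 0L, 0L, 0L, 100L))
  # construction-vs-detection round trip: trigger score and exposure agree
  m <- match(res$cohort$patient_id, study$truth$patient_id)
  expect_identical(res$cohort$trigger_news, study$truth$trigger_news[m])
  expect_equal(res$cohort$std_hours, study$truth$std_hours[m])
})

test_that("every generated violator is excluded at its intended step", {
  cfg <- generator_config(n_patients = 400, seed = 53,
                          fraction_theatre = 0.05)
  study <- simulate_study(cfg)
  res <- derive_cohort(study$observations, study$events, study$covariates)
  tr <- study$truth
  expect_identical(
    res$ledger$n[res$ledger$step == "excluded_direct_ed"],
    sum(tr$category %in% c("ed_direct", "theatre")))
  expect_identical(
    res$ledger$n[res$ledger$step == "excluded_not_sustained"],
    sum(tr$category == "not_sustained"))
  expect_identical(
    res$ledger$n[res$ledger$step == "excluded_over_7_days"],
    sum(tr$category == "over_cap"))
  expect_identical(
    res$ledger$n[res$ledger$step == "excluded_missing_data"],
    sum(tr$missing_flag))
  expect_setequal(res$cohort$patient_id,
                  tr$patient_id[tr$category == "included" & !tr$missing_flag])
})

test_that("violation fractions are honoured within binomial error", {
  cfg <- generator_config(n_patients = 1000, seed = 54,
                          fraction_ed_direct = 0.3,
                          fraction_not_sustained = 0.2)
  study <- simulate_study(cfg)
  n_ed <- sum(study$truth$category == "ed_direct")
  expect_lt(abs(n_ed - 300), 4 * sqrt(1000 * 0.3 * 0.7))
})

test_that("admission latency matches its lognormal target", {
  cfg <- generator_config(n_patients = 4000, seed = 55,
                          fraction_ed_direct = 0, fraction_not_sustained = 0,
                          fraction_over_cap = 0, fraction_missing = 0)
  study <- simulate_study(cfg)
  q <- quantile(study$truth$std_hours, c(0.25, 0.5, 0.75))
  expect_equal(unname(q[2]), 6.3, tolerance = 0.1)
  expect_equal(unname(q[1]), 3.85, tolerance = 0.15)
  expect_equal(unname(q[3]), 10.32, tolerance = 0.15)
})

test_that("triggering NEWS values follow the configured distribution", {
  probs <- c("7" = 0.5, "8" = 0.3, "9" = 0.2)
  cfg <- generator_config(n_patients = 10000, seed = 56,
                          fraction_ed_direct = 0, fraction_not_sustained = 0,
                          fraction_over_cap = 0, fraction_missing = 0,
                          trigger_news_probs = probs)
  study <- simulate_trajectories(cfg)
  obs_counts <- table(factor(study$truth$trigger_news, levels = 7:9))
  gof <- chisq.test(as.vector(obs_counts), p = probs)
  expect_gt(gof$p.value, 0.001)
})

test_that("outcome assignment reproduces its generating models", {
  # intercept-only mortality at the baseline rate
  cfg <- generator_config(
    n_patients = 2, seed = 57,
    beta_cc_death = c(intercept = qlogis(0.163)),
    gamma_cc_los = c(intercept = log(3), std_hours = 0),
    sigma_cc_los = 0)
  truth <- data.frame(std_hours = rlnorm(20000, 1.84, 0.73))
  set.seed(57)
  out <- assign_outcomes(truth, cfg)
  expect_lt(abs(mean(out$cc_death) - 0.163),
            4 * sqrt(0.163 * 0.837 / 20000))
  # noise-free log-linear model: exposure multiplies LOS exactly
  cfg2 <- generator_config(
    n_patients = 2, seed = 58,
    beta_cc_death = c(intercept = -2),
    gamma_cc_los = c(intercept = 1, std_hours = 0.012), sigma_cc_los = 0)
  out2 <- assign_outcomes(data.frame(std_hours = c(0, 10)), cfg2)
  expect_equal(out2$cc_los_days[2] / out2$cc_los_days[1], exp(0.12),
               tolerance = 1e-12)
  # per-hour odds compound multiplicatively: 50 extra hours = 1.02^50
  cfg3 <- generator_config(
    n_patients = 2, seed = 59,
    beta_cc_death = c(intercept = -3, std_hours = log(1.02)),
    gamma_cc_los = c(intercept = 1))
  big <- data.frame(std_hours = rep(c(5, 55), each = 40000))
  set.seed(59)
  out3 <- assign_outcomes(big, cfg3)
  p <- tapply(out3$cc_death, out3$std_hours, mean)
  odds <- p / (1 - p)
  expect_equal(unname(odds[["55"]] / odds[["5"]]), 1.02^50,
               tolerance = 0.15)
})

test_that("degenerate and infeasible configurations are handled", {
  expect_error(generator_config(n_patients = 10, seed = 1,
                                fraction_ed_direct = 0.8,
                                fraction_not_sustained = 0.5),
               "sum to at most 1")
  expect_error(generator_config(n_patients = 10), "seed")
  empty <- simulate_study(generator_config(n_patients = 0, seed = 1))
  expect_identical(nrow(empty$observations), 0L)
  expect_identical(nrow(empty$events), 0L)
  res <- derive_cohort(empty$observations, empty$events, empty$covariates)
  expect_true(all(res$ledger$n == 0L))
  expect_error(assign_outcomes(
    data.frame(std_hours = Inf),
    generator_config(n_patients = 1, seed = 2)), "coefficient|non-finite")
})
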