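test_that("cohort table has the promised structure", {
  cs <- syntheticCohortSpec(n_patients = 202L, followup_horizon = 60, seed = 3)
  d <- simulateCohort(cs)
  expect_equal(nrow(d), 202L)
  expect_true(all(d$time > 0 & d$time <= 60))
  expect_true(all(d$event %in% c(0L, 1L)))
  expect_true(all(d$score1 == d$grade_number + d$grade_circularity +
                    d$grade_total_perimeter))
  expect_true(all(d$score1 %in% 3:9) && all(d$score2 %in% 4:12))
  expect_identical(simulateCohort(cs), d)  # determinism
  expect_error(syntheticCohortSpec(n_patients = 0L), "positive")
})

test_that("overwhelming censoring removes every event", {
  cs <- syntheticCohortSpec(n_patients = 150L, censoring_rate = 1e6, seed = 8)
  d <- simulateCohort(cs)
  expect_true(all(d$event == 0L))
})

test_that("a null cohort yields a Cox hazard ratio near 1", {
  cs <- syntheticCohortSpec(n_patients = 3000L, log_hr_per_score_unit = 0,
                            baseline_hazard = 0.02, seed = 21)
  d <- simulateCohort(cs)
  fit <- coxMultivariate(d, "score1")
  expect_gt(fit$table$lo[1], 0.9)
  expect_lt(fit$table$hi[1], 1.1)
  expect_true(fit$table$lo[1] < 1 && fit$table$hi[1] > 1)
})

test_that("Kaplan-Meier on a null cohort matches the exponential survivor", {
  h0 <- 0.02
  cs <- syntheticCohortSpec(n_patients = 2000L, log_hr_per_score_unit = 0,
                            baseline_hazard = h0, censoring_rate = 0.005,
                            seed = 14)
  d <- simulateCohort(cs)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = d)
  tMed <- median(d$time)
  i <- max(which(sf$time <= tMed))
  est <- sf$surv[i]
  se <- sf$std.err[i] * sf$surv[i]  # Greenwood, survfit stores se of log S
  expect_lt(abs(est - exp(-h0 * tMed)), 3 * se)
})

test_that("cohort specs round-trip through JSON", {
  cs <- syntheticCohortSpec(n_patients = 77L, covariate_effects =
                              c(t_stage = 0.3, her2 = -0.1), seed = 4)
  path <- tempfile(fileext = ".json")
  writeSpecJson(cs, path)
  rt <- readSpecJson(path)
  expect_equal(rt, cs)
})
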