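# Interval construction, percentage falls, the 21-day filter and the
# per-dose median dose-response lines.

test_that("consecutive visits pair into intervals with correct phases", {
  ch <- toy_cohort()
  iv <- build_intervals(ch)
  p1 <- iv[iv$patient_id == "P1", ]
  expect_equal(nrow(p1), 2L)
  expect_equal(p1$phase, c("initial", "followup"))
  expect_equal(p1$start_day, c(0L, 30L))
  expect_equal(p1$dose_mg, c(20, 20))  # dose at the starting visit

  solo <- cohort(ch$patients[1, ], ch$visits[1, ])
  expect_equal(nrow(build_intervals(solo)), 0L)
})

test_that("interval count equals visits minus patients on a generated cohort", {
  ch <- default_cohort(seed = 1)
  iv <- build_intervals(ch)
  expect_equal(nrow(iv), nrow(ch$visits) - nrow(ch$patients))
})

test_that("pct_fall_per_day does the stated arithmetic", {
  iv <- data.frame(patient_id = "A", start_day = c(0L, 0L, 0L),
                   end_day = c(25L, 10L, 30L), dose_mg = 20,
                   ft4_start = c(40, 18, 20), ft4_end = c(30, 18, 26),
                   ft3_start = NA_real_, ft3_end = NA_real_,
                   phase = "initial", stringsAsFactors = FALSE)
  expect_equal(pct_fall_per_day(iv, "ft4"), c(1.0, 0, -1.0))
})

test_that("pct_fall_per_day is scale invariant", {
  set.seed(5)
  iv <- data.frame(patient_id = "A", start_day = 0L,
                   end_day = sample(21:60, 20, TRUE), dose_mg = 20,
                   ft4_start = runif(20, 10, 60),
                   ft4_end = runif(20, 8, 55),
                   ft3_start = NA_real_, ft3_end = NA_real_,
                   phase = "initial", stringsAsFactors = FALSE)
  base <- pct_fall_per_day(iv, "ft4")
  k <- 3.17
  iv$ft4_start <- iv$ft4_start * k; iv$ft4_end <- iv$ft4_end * k
  expect_equal(pct_fall_per_day(iv, "ft4"), base, tolerance = 1e-12)
})

test_that("the 21-day filter is boundary-inclusive, order-preserving and idempotent", {
  iv <- data.frame(patient_id = letters[1:5], start_day = 0L,
                   end_day = c(20L, 21L, 22L, 5L, 60L), dose_mg = 20,
                   ft4_start = 40, ft4_end = 30,
                   ft3_start = NA_real_, ft3_end = NA_real_,
                   phase = "initial", stringsAsFactors = FALSE)
  kept <- filter_intervals(iv)
  expect_equal(kept$patient_id, c("b", "c", "e"))   # 21 kept, 20 dropped
  expect_identical(filter_intervals(kept), kept)    # idempotent
  expect_identical(filter_intervals(iv, min_days = 0), iv)
  # retained set is a subset satisfying the bound
  expect_true(all(kept$end_day - kept$start_day >= 21))
})

test_that("fit_dose_response recovers an exact line through medians", {
  iv <- line_intervals(0.04, 0.09)
  f <- fit_dose_response(iv, "ft4", "initial")
  expect_equal(f$slope, 0.04, tolerance = 1e-12)
  expect_equal(f$intercept, 0.09, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)
  expect_error(fit_dose_response(iv[iv$dose_mg == 20, ], "ft4", "initial"),
               "dose groups")
})

test_that("noise-free generator output recovers all four configured lines", {
  iv <- build_intervals(noise_free_cohort())
  expect_equal(fit_dose_response(iv, "ft4", "initial")$slope, 0.04,
               tolerance = 1e-8)
  expect_equal(fit_dose_response(iv, "ft4", "initial")$intercept, 0.09,
               tolerance = 1e-8)
  expect_equal(fit_dose_response(iv, "ft4", "followup")$slope, 0.03,
               tolerance = 1e-8)
  expect_equal(fit_dose_response(iv, "ft4", "followup")$intercept, -0.17,
               tolerance = 1e-8)
  expect_equal(fit_dose_response(iv, "ft3", "initial")$slope, 0.05,
               tolerance = 1e-8)
  expect_equal(fit_dose_response(iv, "ft3", "followup")$intercept, -0.23,
               tolerance = 1e-8)
})

test_that("measured fall rate declines with interval length only under the early boost", {
  # curvilinear early response: longer initiation intervals dilute the
  # boosted first weeks, so %/day falls with interval length
  cfg <- generator_config(n_patients = 250, seed = 13,
                          measurement_noise_sd = 0, fall_shock_sd = 0,
                          patient_rate_sd = 0)
  tt <- time_interval_trend(build_intervals(generate_cohort(cfg)))
  expect_lt(tt$slope, 0)
  # ablating the boost leaves only compounding curvature, much weaker
  cfg1 <- generator_config(n_patients = 250, seed = 13,
                           measurement_noise_sd = 0, fall_shock_sd = 0,
                           patient_rate_sd = 0, early_factor = 1)
  tt1 <- time_interval_trend(build_intervals(generate_cohort(cfg1)))
  expect_lt(abs(tt1$slope), abs(tt$slope) / 2)
})

test_that("constant %/day regardless of length gives a zero time trend", {
  iv <- data.frame(patient_id = paste0("p", 1:6), start_day = 0L,
                   end_day = c(10L, 20L, 30L, 40L, 50L, 60L), dose_mg = 20,
                   ft4_start = 40, ft4_end = 40 * (1 - 0.01 * c(10, 20, 30, 40, 50, 60)),
                   ft3_start = NA_real_, ft3_end = NA_real_,
                   phase = "initial", stringsAsFactors = FALSE)
  expect_equal(time_interval_trend(iv)$slope, 0, tolerance = 1e-12)
})
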