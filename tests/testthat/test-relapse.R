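# Odds ratios, subgroup rates, the relapse rate score and overtreatment.

test_that("odds_ratio reproduces the worked proportions and basic symmetries", {
  # 80% vs 10% relapse (16/4 exposed, 2/18 unexposed)
  or <- odds_ratio(16, 4, 2, 18)
  expect_equal(or$or_value, 36.0, tolerance = 1e-12)
  expect_false(or$corrected)
  expect_equal(odds_ratio(10, 10, 10, 10)$or_value, 1.0)
})

test_that("odds_ratio matches direct arithmetic and inverts under label swap", {
  set.seed(31)
  for (i in 1:30) {
    tb <- sample(1:50, 4, replace = TRUE)
    or <- odds_ratio(tb[1], tb[2], tb[3], tb[4])
    expect_equal(or$or_value, (tb[1] * tb[4]) / (tb[2] * tb[3]),
                 tolerance = 1e-12)
    swap <- odds_ratio(tb[3], tb[4], tb[1], tb[2])
    expect_equal(or$or_value * swap$or_value, 1, tolerance = 1e-12)
    # Woolf interval recomputed by hand
    se <- sqrt(sum(1 / tb))
    expect_equal(or$ci_low, exp(log(or$or_value) - qnorm(0.975) * se),
                 tolerance = 1e-12)
    expect_true(or$ci_low <= or$or_value && or$or_value <= or$ci_high)
  }
})

test_that("zero cells trigger the Haldane-Anscombe correction", {
  or <- odds_ratio(5, 0, 3, 7)
  expect_true(or$corrected)
  expect_equal(or$or_value, (5.5 * 7.5) / (0.5 * 3.5), tolerance = 1e-12)
})

test_that("subgroup rates use the printed bins with lower-inclusive edges", {
  expect_equal(bin_ft4_initial(c(27.9, 28, 44.9, 45, 60)),
               c("<28", "28-44.9", "28-44.9", ">45", ">45"))
  expect_equal(bin_tshrab(c(2.9, 3, 5.9, 6, 9, 9.1)),
               c("<3", "3-5.9", "3-5.9", "6-9", "6-9", ">9"))
  expect_equal(bin_ft4_final(c(11.9, 12, 15, 15.1)),
               c("<12", "12-15", "12-15", ">15"))

  ch <- toy_cohort()
  ch$patients$relapsed <- c(TRUE, TRUE)
  ch$patients$relapse_day <- c(90L, 60L)
  ch <- cohort(ch$patients, ch$visits)
  sr <- subgroup_rates(ch, "sex")
  expect_equal(sr$relapse_pct[sr$n > 0], c(100, 100))
  expect_error(subgroup_rates(ch, "shoe_size"), "unknown factor")
})

test_that("compute_rrs is additive with configured points and strata", {
  zero <- rrs_default_config()
  zero$category_points <- lapply(zero$category_points, function(x) x * 0)
  p <- list(sex = "M", ethnicity = "White", smoking = "current",
            tshrab_u_ml = 12, ft4_init = 50)
  z <- compute_rrs(p, zero)
  expect_equal(z$score, 0)
  expect_equal(z$stratum, "<15")

  cfg <- rrs_default_config()
  high <- compute_rrs(p, cfg)
  expect_equal(high$stratum, ">20")
  # worst combination maps onto the top stratum by construction
  expect_equal(high$score,
               sum(cfg$category_points$sex["M"],
                   cfg$category_points$ethnicity["White"],
                   cfg$category_points$smoking["current"],
                   cfg$category_points$ft4_init[">45"],
                   cfg$category_points$tshrab[">9"]))
  expect_error(compute_rrs(list(sex = "M"), cfg), "ethnicity.*ft4_init")
  expect_error(compute_rrs(modifyList(p, list(ethnicity = "Martian")), cfg),
               "unknown level")
})

test_that("score strata reproduce the calibrated relapse gradient", {
  ch <- big_cohort()
  rs <- rrs_strata_rates(ch)
  tab <- rs$strata
  expect_lt(abs(tab$relapse_pct[tab$stratum == ">20"] - 80), 5)
  expect_lt(abs(tab$relapse_pct[tab$stratum == "<15"] - 10), 5)
  expect_lt(abs(log(rs$or_top_vs_bottom$or_value / 36)), log(1.6))
})

test_that("uniform-random outcomes show no stratum gradient", {
  ch <- default_cohort(seed = 2)
  set.seed(99)
  ch$patients$relapse_day <- NA_integer_
  ch$patients$relapsed <- runif(nrow(ch$patients)) < 0.35
  rs <- rrs_strata_rates(ch)
  spread <- diff(range(rs$strata$relapse_pct, na.rm = TRUE))
  expect_lt(spread, 20)  # sampling noise only, no 10-vs-80 separation
})

test_that("a single binary covariate reproduces the 2x2 odds ratio", {
  ch <- default_cohort(seed = 1)
  fit <- fit_multivariable_logistic(ch, "sex")
  d <- ch$patients[!is.na(ch$patients$relapsed), ]
  a <- sum(d$sex == "M" & d$relapsed); b <- sum(d$sex == "M" & !d$relapsed)
  c_ <- sum(d$sex == "F" & d$relapsed); dd <- sum(d$sex == "F" & !d$relapsed)
  or <- odds_ratio(a, b, c_, dd)
  expect_equal(fit$table$or_value[fit$table$term == "sexM"], or$or_value,
               tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("a null outcome yields adjusted odds ratios near one", {
  ch <- cached_cohort("null4k", function()
    generate_cohort(generator_config(n_patients = 3000, seed = 23)))
  set.seed(51)
  ch$patients$relapse_day <- NA_integer_
  ch$patients$relapsed <- runif(nrow(ch$patients)) < 0.35
  fit <- fit_multivariable_logistic(ch, c("sex", "smoking", "ft4_init"))
  expect_true(all(fit$table$ci_low < 1 + 0.25 & fit$table$ci_high > 1 - 0.25))
})

test_that("with only an initial-fT4 effect, only initial fT4 predicts relapse", {
  flat <- generator_config()$relapse_rates
  flat$sex[] <- 0.35; flat$ethnicity[] <- 0.35; flat$smoking[] <- 0.35
  flat$tshrab[] <- 0.35
  cfg <- generator_config(n_patients = 2500, seed = 29, relapse_rates = flat)
  ch <- generate_cohort(cfg)
  fit <- fit_multivariable_logistic(ch, c("sex", "smoking", "ft4_init"))
  p_ft4 <- min(fit$table$p_value[grepl("ft4_init", fit$table$term)])
  p_rest <- fit$table$p_value[!grepl("ft4_init", fit$table$term)]
  expect_lt(p_ft4, 1e-4)
  expect_true(all(p_rest > 0.01))
})

test_that("perfect separation is flagged rather than silently reported", {
  ch <- default_cohort(seed = 1)
  d <- ch$patients
  d$relapsed <- d$sex == "M"   # outcome fully determined by sex
  d$relapse_day <- NA_integer_
  ch2 <- cohort(d, ch$visits)
  fit <- fit_multivariable_logistic(ch2, "sex")
  expect_true(fit$separation)
})

test_that("overtreatment summary counts patients with any overtreated visit", {
  ch <- toy_cohort()  # no visit breaches bounds
  ot <- overtreatment_summary(ch, min_followup_days = 30)
  expect_equal(ot$overtreated_pct, 0)

  # inject dose-dependent overshoot: high-dose patients end hypothyroid
  set.seed(8)
  n <- 60
  pats <- data.frame(
    id = sprintf("Q%02d", 1:n), sex = "F", ethnicity = "White",
    smoking = "never", age = 45L, weight_kg = 70,
    tshrab_u_ml = 5, tpoab_u_ml = NA_real_,
    relapsed = NA, relapse_day = NA_integer_, stringsAsFactors = FALSE)
  dose0 <- rep(c(40, 10), each = n / 2)
  over <- dose0 == 40 & runif(n) < 0.8 | dose0 == 10 & runif(n) < 0.1
  visits <- do.call(rbind, lapply(1:n, function(i) data.frame(
    patient_id = pats$id[i], day = c(0L, 70L),
    ft4_pmol_l = c(45, if (over[i]) 7 else 15),
    ft3_pmol_l = c(30, 4), tsh_mu_l = c(0.02, if (over[i]) 6 else 1.5),
    dose_mg = c(dose0[i], 10), split_dose = FALSE,
    stringsAsFactors = FALSE)))
  ch3 <- cohort(pats, visits)
  ot3 <- suppressWarnings(overtreatment_summary(ch3))
  expect_equal(ot3$overtreated_pct, 100 * mean(over))
  expect_gt(ot3$predictors$dose_init$or_value[1], 1)

  ch4 <- default_cohort(seed = 1)
  v <- ch4$visits
  st <- suppressWarnings(
    classify_status(v$tsh_mu_l, v$ft4_pmol_l, v$ft3_pmol_l))
  manual <- sum(tapply(st == "overtreated", v$patient_id, any))
  ot4 <- suppressWarnings(overtreatment_summary(ch4))
  expect_equal(round(ot4$n * ot4$overtreated_pct / 100), manual)
})
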