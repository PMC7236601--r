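# The recursive daily pharmacodynamic model: stepping, simulation,
# fitting (linear, exponent, weight adjustment), RMSE and inverse dosing.

params_frac <- function(m = 4e-4, c = 9e-4, mf = 3e-4, cf = -1.7e-3, p = 1)
  pd_parameters("ft4", m_initial = m, c_initial = c,
                m_followup = mf, c_followup = cf, p = p)

test_that("pd_step handles the degenerate and hand-computed cases", {
  id <- pd_parameters("ft4", 0, 0, 0, 0)
  expect_equal(pd_step(37.3, 25, id, "initial"), 37.3)
  # zero dose with zero intercept is the identity
  p <- params_frac(c = 0)
  expect_equal(pd_step(40, 0, p, "initial"), 40)
  # hand arithmetic: m = 0.00089 per mg per day, c = 0
  p2 <- pd_parameters("ft4", 8.9e-4, 0, 8.9e-4, 0)
  expect_equal(pd_step(40, 20, p2, "initial"), 40 * (1 - 0.0178))
  # floored at the assay limit
  expect_equal(pd_step(5.2, 40, params_frac(m = 0.05), "initial"),
               assay_floors()$ft4)
})

test_that("pd_simulate matches the closed form under constant dose", {
  p <- params_frac(c = 0)
  traj <- pd_simulate(40, 20, 28, p, phase_boundary_day = 100)
  expect_equal(traj$levels[29], 40 * (1 - 4e-4 * 20)^28, tolerance = 1e-12)
  expect_equal(traj$levels, 40 * (1 - 4e-4 * 20)^(0:28), tolerance = 1e-12)
  # horizon 0: a single point
  t0 <- pd_simulate(40, 20, 0, p)
  expect_equal(t0$levels, 40)
  # strictly decreasing until the floor when the daily fall is positive
  tl <- pd_simulate(8, 40, 400, params_frac(m = 2e-3), 100)
  dec <- diff(tl$levels)
  expect_true(all(dec <= 0))
  expect_equal(min(tl$levels), assay_floors()$ft4)
  expect_error(pd_simulate(40, data.frame(day = 5, dose_mg = 20), 10, p),
               "schedule gap")
})

test_that("phase boundary switches the coefficients", {
  p <- pd_parameters("ft4", 1e-3, 0, 0, 0)  # falls only during initiation
  traj <- pd_simulate(40, 20, 20, p, phase_boundary_day = 10)
  expect_equal(traj$levels[11], 40 * (1 - 0.02)^10, tolerance = 1e-12)
  expect_equal(traj$levels[21], traj$levels[11], tolerance = 1e-12)
})

test_that("rmse does the stated arithmetic and is permutation invariant", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(3, 4), c(0, 0)), sqrt(25 / 2))
  expect_equal(rmse(-2, 0), 2)
  set.seed(3)
  o <- rnorm(20); pr <- rnorm(20)
  i <- sample(20)
  expect_equal(rmse(o, pr), rmse(o[i], pr[i]), tolerance = 1e-15)
  expect_error(rmse(1:3, 1:2), "length")
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("fit_linear_params recovers generator coefficients and is self-consistent", {
  iv <- build_intervals(noise_free_cohort())
  prm <- fit_linear_params(iv, "ft4")
  expect_equal(prm$m_initial * 100, 0.04, tolerance = 1e-7)
  expect_equal(prm$c_initial * 100, 0.09, tolerance = 1e-7)
  expect_equal(prm$m_followup * 100, 0.03, tolerance = 1e-7)
  expect_equal(prm$c_followup * 100, -0.17, tolerance = 1e-7)
  # simulating the training intervals reproduces their end levels
  expect_lt(pd_one_step_rmse(iv, prm), 1e-9)
})

test_that("fit_linear_params names the phase when a phase lacks dose groups", {
  iv <- line_intervals(0.04, 0.09)  # initiation only
  expect_error(fit_linear_params(iv, "ft4"), "followup")
  one <- rbind(iv, within(iv[1:2, ], {
    phase <- "followup"; start_day <- 50L; end_day <- 80L
  }))
  expect_error(fit_linear_params(one, "ft4"), "followup")
})

test_that("the dose exponent is recovered exactly from model-generated intervals", {
  gen_ivs <- function(p) {
    set.seed(17)
    n <- 300
    d <- sample(c(5, 10, 20, 40), n, TRUE)
    len <- sample(21:30, n, TRUE)
    ph <- sample(c("initial", "followup"), n, TRUE)
    s <- runif(n, 25, 60)
    m <- ifelse(ph == "initial", 3e-4, 2e-4)
    cc <- ifelse(ph == "initial", 9e-4, -1e-3)
    e <- s * (1 - (m * d^p + cc) * len)
    data.frame(patient_id = "X", start_day = ifelse(ph == "initial", 0L, 50L),
               end_day = ifelse(ph == "initial", 0L, 50L) + len, dose_mg = d,
               ft4_start = s, ft4_end = e, ft3_start = NA_real_,
               ft3_end = NA_real_, phase = ph, stringsAsFactors = FALSE)
  }
  f1 <- fit_exponent(gen_ivs(1.0), "ft4")
  expect_equal(f1$p, 1.0)
  f12 <- fit_exponent(gen_ivs(1.2), "ft4")
  expect_equal(f12$p, 1.2)
  expect_equal(f12$m_initial, 3e-4, tolerance = 1e-9)
  # argmin property: the chosen exponent never beats itself
  grid <- attr(f12, "rmse_grid")
  expect_lte(min(grid$rmse), grid$rmse[grid$p == 1.0])
})

test_that("weight adjustment is the identity at the reference weight", {
  prm <- params_frac()
  prm$weight_slope_adj <- 1e-6; prm$weight_intercept_adj <- -2e-6
  at_ref <- weight_adjust(prm, 70)
  expect_equal(at_ref$m_initial, prm$m_initial)
  expect_equal(at_ref$c_followup, prm$c_followup)
  none <- params_frac()
  expect_equal(weight_adjust(none, 95)$m_initial, none$m_initial)
  expect_error(weight_adjust(prm, 0), "weight")
})

test_that("fitting the weight adjustment lowers one-step RMSE on a weight-affected cohort", {
  cfg <- generator_config(n_patients = 441, seed = 21,
                          weight_rate_effect = 0.006)
  ch <- generate_cohort(cfg)
  iv <- build_intervals(ch)
  base <- fit_linear_params(iv, "ft4")
  adj <- fit_weight_adjustment(iv, ch$patients, base)
  r0 <- pd_one_step_rmse(iv, base, ch$patients)
  r1 <- pd_one_step_rmse(iv, adj, ch$patients)
  expect_lt(r1, r0)
  expect_true(abs(adj$weight_slope_adj) > 0)
})

test_that("recommend_dose is consistent with simulation and monotone", {
  prm <- params_frac(m = 5e-4, c = 5e-4)
  # target at or above the current level needs no drug
  expect_equal(recommend_dose(30, 30, 28, prm)$dose_mg, 0)
  rec <- recommend_dose(45, 20, 42, prm, phase = "initial")
  if (rec$reachable) {
    traj <- pd_simulate(45, rec$dose_mg, 42, prm, 43)
    expect_true(any(traj$levels <= 20))
    if (rec$dose_mg > 0) {
      lower <- max(allowed_doses()[allowed_doses() < rec$dose_mg])
      expect_false(any(pd_simulate(45, lower, 42, prm, 43)$levels <= 20))
    }
  }
  # monotone: easier targets never demand more drug
  targets <- seq(10, 45, by = 2.5)
  doses <- vapply(targets, function(tg)
    recommend_dose(45, tg, 42, prm, phase = "initial")$dose_mg, numeric(1))
  expect_true(all(diff(doses) <= 0))
  # unreachable targets return the maximum dose, flagged
  hard <- recommend_dose(60, 6, 3, prm)
  expect_false(hard$reachable)
  expect_equal(hard$dose_mg, max(allowed_doses()))
})
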