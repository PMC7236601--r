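# Synthetic cohort generator.
#
# The generator embeds the study's printed summary statistics as ground
# truth: the baseline antibody/hormone distributions, the phase- and
# dose-dependent percentage daily falls, the fall coupling between fT3 and
# fT4, and the subgroup relapse frequencies. Doses, visit spacing and
# monitoring mirror dose-titration care (review every 4-6 weeks, at least 18
# months of treatment before a trial off medication).

#' Configuration for the synthetic cohort generator
#'
#' Defaults encode the cohort conditions the analyses assume. The
#' percentage-fall lines are interval-level observables (median percentage
#' fall per day over inter-visit intervals of at least 21 days); the
#' generator converts them to daily base rates by inverting the interval
#' aggregation at the reference gap (\code{gap_ref_days}), including the
#' early-response boost for the initiation interval. Baseline fT3 carries an
#' fT4-dependent location term calibrated so the generated cohort reproduces
#' the target means while the error-free relation remains
#' \code{ft3_slope * fT4 + ft3_intercept}.
#'
#' @param n_patients Number of patients (default 441).
#' @param seed Integer root seed; per-patient substreams are derived from it
#'   by a fixed counter scheme, so cohorts are reproducible under reordering.
#' @param tshrab_median,tshrab_iqr Median and interquartile range of the
#'   TSH-receptor antibody titre (U/mL); sampled log-normal.
#' @param tshrab_cap Assay ceiling for the titre (U/mL); draws are
#'   winsorised here, as third-generation binding assays saturate.
#' @param ft4_vs_tshrab_slope Baseline fT4 change per unit titre (pmol/L per
#'   U/mL).
#' @param ft4_vs_tshrab_r2 Target population r-squared of baseline fT4 on
#'   titre.
#' @param ft3_slope,ft3_intercept Error-free baseline relation of fT3 on fT4.
#' @param ft3_baseline_r2 Target population r-squared of baseline fT3 on fT4.
#' @param target_mean_ft4,target_mean_ft3 Target baseline means (pmol/L).
#' @param fall_coupling_slope Absolute daily fT3 fall per unit fT4 fall, used
#'   when \code{ft3_mode = "coupled"}.
#' @param initial_line,followup_line Named vectors \code{c(slope, intercept)}
#'   of the fT4 percentage-fall-per-day lines (\%/day per mg, \%/day).
#' @param initial_line_ft3,followup_line_ft3 Same for fT3.
#' @param ft3_mode \code{"lines"} drives fT3 by its own dose-response lines
#'   (default); \code{"coupled"} ties daily fT3 falls to fT4 falls through
#'   \code{fall_coupling_slope}.
#' @param early_factor Multiplier on the daily fall rate during the first
#'   \code{early_days} days of the initiation interval (captures the
#'   curvilinear early fall).
#' @param early_days Length of the boosted early-response window (days).
#' @param gap_ref_days Reference inter-visit gap at which the configured
#'   lines are reproduced exactly (days).
#' @param measurement_noise_sd Standard deviation of the shared per-visit
#'   log-normal factor applied to both observed hormones (0 disables).
#' @param fall_shock_sd SD (as a fraction of the interval-start fT4 level)
#'   of a mean-zero per-interval response shock — within-patient variation
#'   in realised drug effect (compliance, intercurrent illness) — applied
#'   to the true fT4 fall and, scaled by \code{fall_coupling_slope}, to the
#'   true fT3 fall. Median-preserving, so the dose-response medians are
#'   unaffected; it houses the observed coupling of daily falls between the
#'   two hormones. 0 disables.
#' @param patient_rate_sd Log-scale SD of the per-patient fall-rate
#'   multiplier (median 1; 0 disables).
#' @param baseline_noise If FALSE, baseline errors are zeroed so fT4 and fT3
#'   are exact functions of the titre and of fT4 respectively.
#' @param visit_gap_days Integer range of early inter-visit gaps (days).
#' @param stable_gap_days Integer range of gaps once fT4 has normalised.
#' @param treatment_days Treatment duration before a trial off drug (days).
#' @param max_followups Maximum number of follow-up visits.
#' @param female_prob Probability a patient is female.
#' @param ethnicity_probs,smoking_probs Named category probabilities.
#' @param age_mean,age_sd Age distribution (years; truncated to 16-100).
#' @param weight_mean,weight_sd Weight distribution (kg; truncated 40-140).
#' @param weight_rate_effect Fractional change in the daily fall rate per kg
#'   away from 70 kg (0 = weight has no effect, as observed).
#' @param dose_policy Function \code{(ft4, visit_index, prev_dose)} returning
#'   the prescribed daily dose; NULL uses \code{\link{default_dose_policy}}.
#' @param relapse_rates Named list of per-factor subgroup relapse
#'   probabilities (see defaults).
#' @param relapse_day_median,relapse_day_range,relapse_day_sdlog Distribution
#'   of the day of relapse after drug cessation.
#' @return A list of class \code{"thyro_genconfig"} including derived
#'   calibration constants.
#' @export
generator_config <- function(
    n_patients = 441,
    seed = 42,
    tshrab_median = 4.1,
    tshrab_iqr = c(1.95, 8.0),
    tshrab_cap = 40,
    ft4_vs_tshrab_slope = 0.35,
    ft4_vs_tshrab_r2 = 0.11,
    ft3_slope = 0.97,
    ft3_intercept = -11,
    ft3_baseline_r2 = 0.68,
    target_mean_ft4 = 33.4,
    target_mean_ft3 = 19.3,
    fall_coupling_slope = 0.9541,
    initial_line = c(slope = 0.04, intercept = 0.09),
    followup_line = c(slope = 0.03, intercept = -0.17),
    initial_line_ft3 = c(slope = 0.05, intercept = 0.16),
    followup_line_ft3 = c(slope = 0.03, intercept = -0.23),
    ft3_mode = c("lines", "coupled"),
    early_factor = 1.8,
    early_days = 21,
    gap_ref_days = 35,
    measurement_noise_sd = 0.15,
    fall_shock_sd = 0.06,
    patient_rate_sd = 0.15,
    baseline_noise = TRUE,
    visit_gap_days = c(28, 42),
    stable_gap_days = c(56, 112),
    treatment_days = 540,
    max_followups = 12,
    female_prob = 0.814,
    ethnicity_probs = c(Asian = 47, Black = 50, White = 159, Mixed = 10,
                        Other = 87, Unknown = 87) / 440,
    smoking_probs = c(never = 0.6, ex = 0.2, current = 0.2),
    age_mean = 44, age_sd = 15,
    weight_mean = 75, weight_sd = 15,
    weight_rate_effect = 0,
    dose_policy = NULL,
    relapse_rates = list(
      sex = c(M = 0.52, F = 0.33),
      ethnicity = c(Asian = 0.21, Black = 0.28, White = 0.52, Mixed = 0.35,
                    Other = 0.35, Unknown = 0.35),
      smoking = c(never = 0.32, ex = 0.44, current = 0.47),
      ft4_init = c("<28" = 0.17, "28-44.9" = 0.39, ">45" = 0.60),
      tshrab = c("<3" = 0.27, "3-5.9" = 0.31, "6-9" = 0.38, ">9" = 0.57)),
    relapse_day_median = 85,
    relapse_day_range = c(25, 335),
    relapse_day_sdlog = 0.55) {

  ft3_mode <- match.arg(ft3_mode)
  stopifnot(n_patients >= 1, length(seed) == 1, is.finite(seed),
            tshrab_median > 0, tshrab_iqr[1] < tshrab_iqr[2],
            is.finite(ft3_slope), is.finite(ft4_vs_tshrab_slope),
            ft4_vs_tshrab_r2 > 0, ft4_vs_tshrab_r2 < 1,
            ft3_baseline_r2 > 0, ft3_baseline_r2 < 1,
            early_factor > 0, early_days >= 0,
            measurement_noise_sd >= 0, patient_rate_sd >= 0,
            visit_gap_days[1] <= visit_gap_days[2], visit_gap_days[1] >= 1,
            treatment_days > 0, max_followups >= 4,
            female_prob >= 0, female_prob <= 1,
            all(unlist(relapse_rates) >= 0), all(unlist(relapse_rates) <= 1))

  cfg <- list(
    n_patients = as.integer(n_patients), seed = as.integer(seed),
    tshrab_median = tshrab_median, tshrab_iqr = tshrab_iqr,
    tshrab_cap = tshrab_cap,
    ft4_vs_tshrab_slope = ft4_vs_tshrab_slope,
    ft4_vs_tshrab_r2 = ft4_vs_tshrab_r2,
    ft3_slope = ft3_slope, ft3_intercept = ft3_intercept,
    ft3_baseline_r2 = ft3_baseline_r2,
    target_mean_ft4 = target_mean_ft4, target_mean_ft3 = target_mean_ft3,
    fall_coupling_slope = fall_coupling_slope,
    initial_line = initial_line, followup_line = followup_line,
    initial_line_ft3 = initial_line_ft3,
    followup_line_ft3 = followup_line_ft3,
    ft3_mode = ft3_mode,
    early_factor = early_factor, early_days = early_days,
    gap_ref_days = gap_ref_days,
    measurement_noise_sd = measurement_noise_sd,
    fall_shock_sd = fall_shock_sd,
    patient_rate_sd = patient_rate_sd,
    baseline_noise = baseline_noise,
    visit_gap_days = as.integer(visit_gap_days),
    stable_gap_days = as.integer(stable_gap_days),
    treatment_days = as.integer(treatment_days),
    max_followups = as.integer(max_followups),
    female_prob = female_prob,
    ethnicity_probs = ethnicity_probs / sum(ethnicity_probs),
    smoking_probs = smoking_probs / sum(smoking_probs),
    age_mean = age_mean, age_sd = age_sd,
    weight_mean = weight_mean, weight_sd = weight_sd,
    weight_rate_effect = weight_rate_effect,
    dose_policy = if (is.null(dose_policy)) default_dose_policy else dose_policy,
    relapse_rates = relapse_rates,
    relapse_day_median = relapse_day_median,
    relapse_day_range = relapse_day_range,
    relapse_day_sdlog = relapse_day_sdlog)

  # --- derived baseline calibration -------------------------------------
  sdlog <- (log(tshrab_iqr[2]) - log(tshrab_iqr[1])) / (2 * stats::qnorm(0.75))
  meanlog <- log(tshrab_median)
  # titres are winsorised at the assay ceiling; use the winsorised moments
  # (keeps the median/IQR and bounds the tail so sample r2 is stable)
  zc <- (log(tshrab_cap) - meanlog) / sdlog
  p_over <- stats::pnorm(zc, lower.tail = FALSE)
  mean_ab <- exp(meanlog + sdlog^2 / 2) * stats::pnorm(zc - sdlog) +
    tshrab_cap * p_over
  e2_ab <- exp(2 * meanlog + 2 * sdlog^2) * stats::pnorm(zc - 2 * sdlog) +
    tshrab_cap^2 * p_over
  var_ab <- e2_ab - mean_ab^2
  b4 <- ft4_vs_tshrab_slope
  explained4 <- b4^2 * var_ab
  var_ft4 <- explained4 / ft4_vs_tshrab_r2
  cfg$tshrab_meanlog <- meanlog
  cfg$tshrab_sdlog <- sdlog
  cfg$ft4_intercept <- target_mean_ft4 - b4 * mean_ab
  cfg$ft4_resid_sd <- sqrt(var_ft4 - explained4)
  cfg$ft4_sd <- sqrt(var_ft4)
  # location term reconciling the printed relation with the printed means
  delta0 <- target_mean_ft3 - (ft3_slope * target_mean_ft4 + ft3_intercept)
  cfg$ft3_delta0 <- delta0
  cfg$ft3_delta1 <- delta0 / target_mean_ft4
  # fT3 baseline scatter is multiplicative (level-proportional), mean 1:
  # an additive error of the size the target r-squared requires would be
  # censored by the assay floor at low fT4 and attenuate the recovered
  # slope. Solve for the log-sd giving the target population r-squared.
  slope_eff <- ft3_slope + cfg$ft3_delta1
  explained3 <- slope_eff^2 * var_ft4
  pred2 <- target_mean_ft3^2 + explained3
  v3 <- explained3 * (1 - ft3_baseline_r2) / ft3_baseline_r2 / pred2
  cfg$ft3_resid_sdlog <- sqrt(log(1 + v3))

  # --- daily base rates per dose/phase/hormone --------------------------
  cfg$rates <- build_rate_table(cfg)

  # --- relapse model calibration (marginal matching) --------------------
  cfg$relapse_model <- build_relapse_model(cfg)

  class(cfg) <- "thyro_genconfig"
  cfg
}

#' @export
print.thyro_genconfig <- function(x, ...) {
  cat(sprintf("<thyro_genconfig> n=%d seed=%d ft3_mode=%s noise_sd=%.3g\n",
              x$n_patients, x$seed, x$ft3_mode, x$measurement_noise_sd))
  invisible(x)
}

#' Default dose-titration policy
#'
#' Mirrors dose-titration practice: 40 mg/day if fT4 exceeds 40 pmol/L,
#' 20 mg/day if fT4 is between 23 and 40 pmol/L, otherwise 10 mg/day at the
#' initiation visit; at follow-up the dose is halved (snapped down to the
#' allowed set, minimum 5 mg) once fT4 is at or below 23 pmol/L.
#'
#' @param ft4 Current (observed) fT4 in pmol/L.
#' @param visit_index 0 for the initiation visit.
#' @param prev_dose Dose prescribed at the previous visit (mg/day).
#' @return Daily dose in mg from \code{\link{allowed_doses}}.
#' @export
default_dose_policy <- function(ft4, visit_index, prev_dose = NA_real_) {
  if (ft4 > 40) return(40)
  if (ft4 > 23) return(20)
  if (visit_index == 0) return(10)
  half <- prev_dose / 2
  cand <- allowed_doses()
  cand <- cand[cand >= 5 & cand <= half]
  if (length(cand) == 0) 5 else max(cand)
}

# Daily base fractional fall reproducing an interval-level %/day line value
# over the reference gap. Closed form without the early boost; root-finding
# with it.
interval_base_rate <- function(pct_per_day, gap, early_factor = 1,
                               early_days = 0) {
  target_surv <- 1 - gap * pct_per_day / 100
  if (target_surv <= 0)
    stop("configured fall exceeds 100% over the reference gap")
  ed <- min(early_days, gap)
  if (early_factor == 1 || ed == 0)
    return(1 - target_surv^(1 / gap))
  f <- function(r) (1 - early_factor * r)^ed * (1 - r)^(gap - ed) - target_surv
  stats::uniroot(f, lower = -0.2, upper = 0.95 / early_factor,
                 tol = 1e-14)$root
}

line_value <- function(line, dose) unname(line["slope"] * dose + line["intercept"])

build_rate_table <- function(cfg) {
  doses <- allowed_doses()
  mk <- function(line, phase) {
    ef <- if (phase == "initial") cfg$early_factor else 1
    ed <- if (phase == "initial") cfg$early_days else 0
    vapply(doses, function(d)
      interval_base_rate(line_value(line, d), cfg$gap_ref_days, ef, ed),
      numeric(1))
  }
  out <- list(
    ft4 = list(initial = mk(cfg$initial_line, "initial"),
               followup = mk(cfg$followup_line, "followup")),
    ft3 = list(initial = mk(cfg$initial_line_ft3, "initial"),
               followup = mk(cfg$followup_line_ft3, "followup")))
  for (h in names(out)) for (p in names(out[[h]]))
    names(out[[h]][[p]]) <- as.character(doses)
  out
}

#' Calibrated daily base fall rate
#'
#' The daily fractional fall applied by the generator for a given dose,
#' phase and hormone (before patient-level multipliers). Inverts the
#' interval aggregation so that the measured percentage fall per day over a
#' reference-gap interval equals the configured line exactly.
#'
#' @param config A \code{\link{generator_config}}.
#' @param dose_mg Dose in the allowed set.
#' @param phase \code{"initial"} or \code{"followup"}.
#' @param hormone \code{"ft4"} or \code{"ft3"}.
#' @return Daily fractional fall (may be negative: levels rise).
#' @export
daily_base_rate <- function(config, dose_mg, phase = c("initial", "followup"),
                            hormone = c("ft4", "ft3")) {
  phase <- match.arg(phase); hormone <- match.arg(hormone)
  r <- config$rates[[hormone]][[phase]][as.character(dose_mg)]
  if (anyNA(r)) stop("dose not in allowed set: ", dose_mg)
  unname(r)
}

# survival fraction of a level over an interval of `days` at daily rate r
interval_survival <- function(r, days, phase, early_factor, early_days) {
  if (phase == "initial" && early_days > 0) {
    d1 <- min(early_days, days)
    s <- max(1 - early_factor * r, 0)^d1 * max(1 - r, 0)^(max(0, days - d1))
  } else {
    s <- max(1 - r, 0)^days
  }
  s
}

clamp_logit <- function(p) stats::qlogis(pmin(pmax(p, 1e-16), 1 - 1e-16))

# Marginal-matching calibration of the additive logistic relapse model.
# Factor offsets start from centred log-odds and are then raked
# (iterative proportional fitting on the logit scale) against a sampled
# baseline population, so that each factor's marginal subgroup relapse
# frequency matches the configured rate even though the factors are
# correlated (initial fT4 and antibody titre share the baseline model).
# Joint behaviour beyond the marginals remains under-determined.
build_relapse_model <- function(cfg, n_cal = 40000, sweeps = 30) {
  rr <- cfg$relapse_rates
  # deterministic private stream; caller RNG state is preserved
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(20230442L)

  tshrab <- pmin(stats::rlnorm(n_cal, cfg$tshrab_meanlog, cfg$tshrab_sdlog),
                 cfg$tshrab_cap)
  ft4 <- pmax(cfg$ft4_intercept + cfg$ft4_vs_tshrab_slope * tshrab +
                stats::rnorm(n_cal, 0, cfg$ft4_resid_sd), assay_floors()$ft4)
  lev <- list(
    sex = ifelse(stats::runif(n_cal) < cfg$female_prob, "F", "M"),
    ethnicity = sample(names(cfg$ethnicity_probs), n_cal, TRUE,
                       prob = cfg$ethnicity_probs),
    smoking = sample(names(cfg$smoking_probs), n_cal, TRUE,
                     prob = cfg$smoking_probs),
    ft4_init = bin_ft4_initial(ft4),
    tshrab = bin_tshrab(tshrab))

  offsets <- lapply(rr, function(r) {
    lo <- clamp_logit(r)
    lo - mean(lo)
  })
  target <- lapply(rr, clamp_logit)
  idx <- lapply(names(rr), function(f)
    lapply(names(rr[[f]]), function(l) which(lev[[f]] == l)))
  names(idx) <- names(rr)
  eta <- rep(0, n_cal)
  for (f in names(rr)) eta <- eta + offsets[[f]][lev[[f]]]
  for (s in seq_len(sweeps)) {
    for (f in names(rr)) {
      for (j in seq_along(rr[[f]])) {
        sel <- idx[[f]][[j]]
        if (length(sel) == 0) next
        adj <- target[[f]][j] - clamp_logit(mean(stats::plogis(eta[sel])))
        offsets[[f]][j] <- offsets[[f]][j] + adj
        eta[sel] <- eta[sel] + adj
      }
    }
  }
  list(offsets = offsets, lambda = 1, b0 = 0)
}

tsh_from_ft4 <- function(ft4, noise_sd = 0.45, z = NULL) {
  x <- c(5, 9, 11, 14, 18, 23, 30, 45, 100)
  y <- c(1.3, 0.75, 0.4, 0, -0.6, -1.1, -1.7, -2.1, -2.5)
  base <- stats::approx(x, y, xout = ft4, rule = 2)$y
  if (is.null(z)) z <- stats::rnorm(length(ft4))
  pmax(10^(base + noise_sd * z), 0.0025)
}

#' Sample patient baselines
#'
#' Draws antibody titres, baseline hormones and demographics from the
#' calibrated baseline model, using the current RNG stream. The titre is
#' log-normal matched to the configured median and IQR; baseline fT4 is
#' linear in the titre with residual scale set by the target r-squared and
#' mean; baseline fT3 follows the configured relation on fT4 with a residual
#' whose scale matches the target r-squared and whose location reconciles
#' the configured relation with the target means. Hormones are floored at
#' the assay detection limits.
#'
#' @param config A \code{\link{generator_config}}.
#' @param n Number of patients to draw.
#' @return data.frame with one row per patient (no ids assigned).
#' @export
sample_baseline <- function(config, n = 1) {
  floors <- assay_floors()
  tshrab <- pmin(stats::rlnorm(n, config$tshrab_meanlog, config$tshrab_sdlog),
                 config$tshrab_cap)
  eps4 <- if (config$baseline_noise) stats::rnorm(n, 0, config$ft4_resid_sd) else 0
  ft4 <- pmax(config$ft4_intercept + config$ft4_vs_tshrab_slope * tshrab + eps4,
              floors$ft4)
  if (config$baseline_noise) {
    loc <- config$ft3_delta0 +
      config$ft3_delta1 * (ft4 - config$target_mean_ft4)
    sdl <- config$ft3_resid_sdlog
    zeta <- exp(stats::rnorm(n, -sdl^2 / 2, sdl))  # mean-one multiplicative
  } else {
    loc <- 0; zeta <- 1
  }
  ft3 <- pmax((config$ft3_slope * ft4 + config$ft3_intercept + loc) * zeta,
              floors$ft3)
  sex <- ifelse(stats::runif(n) < config$female_prob, "F", "M")
  age <- pmin(pmax(round(stats::rnorm(n, config$age_mean, config$age_sd)), 16), 100)
  ethnicity <- sample(names(config$ethnicity_probs), n, replace = TRUE,
                      prob = config$ethnicity_probs)
  smoking <- sample(names(config$smoking_probs), n, replace = TRUE,
                    prob = config$smoking_probs)
  weight <- round(pmin(pmax(stats::rnorm(n, config$weight_mean, config$weight_sd),
                            40), 140), 1)
  have_tpo <- stats::runif(n) < 0.59
  tpo_zero <- stats::runif(n) < 0.35
  tpo_val <- round(stats::rlnorm(n, 5.74, 1.1))
  tpoab <- ifelse(have_tpo, ifelse(tpo_zero, 0, tpo_val), NA_real_)
  # symmetric about 1 so group medians of measured falls stay anchored on
  # the configured lines (a skewed multiplier would shift them under the
  # smoothing of measurement noise)
  rate_mult <- if (config$patient_rate_sd > 0)
    pmax(1 + stats::rnorm(n, 0, config$patient_rate_sd), 0.05) else rep(1, n)
  data.frame(sex = sex, ethnicity = ethnicity, smoking = smoking,
             age = as.integer(age), weight_kg = weight,
             tshrab_u_ml = tshrab, tpoab_u_ml = tpoab,
             ft4_0 = ft4, ft3_0 = ft3, rate_mult = rate_mult,
             stringsAsFactors = FALSE)
}

#' Simulate the visit trajectory of one patient
#'
#' Evolves the true hormone levels by the daily fall recursion (dose- and
#' phase-dependent rates, early-response boost during the first
#' \code{early_days} days of the initiation interval, assay-limit floors)
#' and records observed levels at each visit with shared multiplicative
#' measurement noise. Doses are chosen by the configured dose policy from
#' the observed fT4. Uses the current RNG stream.
#'
#' @param baseline One row of \code{\link{sample_baseline}} output.
#' @param config A \code{\link{generator_config}}.
#' @return data.frame of visits (without \code{patient_id}).
#' @export
simulate_visits <- function(baseline, config) {
  stopifnot(baseline$ft4_0 > 0)
  floors <- assay_floors()
  wmult <- 1 + config$weight_rate_effect * (baseline$weight_kg - 70)
  mult <- baseline$rate_mult * wmult
  policy <- config$dose_policy

  true4 <- baseline$ft4_0; true3 <- baseline$ft3_0
  obs4 <- true4; obs3 <- true3
  day <- 0L
  tsh <- tsh_from_ft4(true4)
  # Dosing decisions act on the error-free level: the prescriber integrates
  # the clinical picture, and conditioning dose groups on a noisy reading
  # would couple measurement error to dose selection and distort the
  # embedded dose-response ground truth.
  dose <- policy(true4, 0L, NA_real_)
  split <- stats::runif(1) < 0.2

  n_max <- config$max_followups + 1L
  days <- integer(n_max); ft4s <- ft3s <- tshs <- doses <- numeric(n_max)
  splits <- logical(n_max)
  days[1] <- 0L; ft4s[1] <- obs4; ft3s[1] <- obs3; tshs[1] <- tsh
  doses[1] <- dose; splits[1] <- split
  nv <- 1L

  sample_gap <- function(rng) {
    if (rng[1] >= rng[2]) rng[1] else sample(rng[1]:rng[2], 1L)
  }
  k <- 0L
  while (k < config$max_followups && day < config$treatment_days) {
    gap <- if (k < 4L || true4 > 23)
      sample_gap(config$visit_gap_days)
    else
      sample_gap(config$stable_gap_days)
    next_day <- min(day + gap, config$treatment_days)
    len <- next_day - day
    phase <- if (k == 0L) "initial" else "followup"
    ef <- config$early_factor; ed <- config$early_days

    r4 <- daily_base_rate(config, dose, phase, "ft4") * mult
    s4 <- interval_survival(r4, len, phase, ef, ed)
    new4 <- max(true4 * s4, floors$ft4)
    if (config$ft3_mode == "coupled") {
      new3 <- max(true3 - config$fall_coupling_slope * (true4 - new4),
                  floors$ft3)
    } else {
      r3 <- daily_base_rate(config, dose, phase, "ft3") * mult
      new3 <- max(true3 * interval_survival(r3, len, phase, ef, ed),
                  floors$ft3)
    }
    if (config$fall_shock_sd > 0) {
      e <- true4 * config$fall_shock_sd * stats::rnorm(1)
      new4 <- max(true4 - ((true4 - new4) + e), floors$ft4)
      new3 <- max(true3 - ((true3 - new3) + config$fall_coupling_slope * e),
                  floors$ft3)
    }
    true4 <- new4; true3 <- new3
    day <- next_day; k <- k + 1L

    z <- stats::rnorm(1)
    noise <- exp(config$measurement_noise_sd * z)
    obs4 <- max(true4 * noise, floors$ft4)
    obs3 <- max(true3 * noise, floors$ft3)
    tsh <- tsh_from_ft4(true4)
    dose <- policy(true4, k, dose)
    split <- stats::runif(1) < 0.2

    nv <- nv + 1L
    days[nv] <- day; ft4s[nv] <- obs4; ft3s[nv] <- obs3; tshs[nv] <- tsh
    doses[nv] <- dose; splits[nv] <- split
  }

  data.frame(day = days[1:nv], ft4_pmol_l = ft4s[1:nv],
             ft3_pmol_l = ft3s[1:nv], tsh_mu_l = tshs[1:nv],
             dose_mg = doses[1:nv], split_dose = splits[1:nv],
             stringsAsFactors = FALSE)
}

#' Assign a relapse outcome after completed treatment
#'
#' Draws relapse from an additive logistic combination of the patient's
#' baseline categories (sex, ethnicity, smoking, initial fT4 bin, antibody
#' titre bin), calibrated so marginal subgroup frequencies approximate the
#' configured rates; joint calibration across correlated factors is
#' under-determined, so only marginals are matched. The day of relapse is
#' log-normal around the configured median, truncated to the configured
#' range. Uses the current RNG stream.
#'
#' @param baseline One row of \code{\link{sample_baseline}} output.
#' @param config A \code{\link{generator_config}}.
#' @return list(relapsed, relapse_day) — \code{relapse_day} is NA unless
#'   relapsed.
#' @export
assign_relapse <- function(baseline, config) {
  rm_ <- config$relapse_model
  off <- rm_$offsets
  eta <- rm_$b0 + rm_$lambda *
    (off$sex[[baseline$sex]] +
       off$ethnicity[[baseline$ethnicity]] +
       off$smoking[[baseline$smoking]] +
       off$ft4_init[[bin_ft4_initial(baseline$ft4_0)]] +
       off$tshrab[[bin_tshrab(baseline$tshrab_u_ml)]])
  p <- stats::plogis(eta)
  relapsed <- stats::runif(1) < p
  if (relapsed) {
    d <- stats::rlnorm(1, log(config$relapse_day_median),
                       config$relapse_day_sdlog)
    d <- round(min(max(d, config$relapse_day_range[1]),
                   config$relapse_day_range[2]))
    list(relapsed = TRUE, relapse_day = as.integer(d))
  } else {
    stats::runif(1)  # keep the per-patient draw count fixed
    list(relapsed = FALSE, relapse_day = NA_integer_)
  }
}

#' Generate a synthetic cohort
#'
#' Deterministic for a fixed config and seed: each patient is generated
#' from an independent substream whose seed is derived from the root seed
#' and the patient counter, so the cohort is reproducible under reordering
#' and subsetting of patient indices. Patients who complete the configured
#' treatment duration receive a relapse outcome.
#'
#' @param config A \code{\link{generator_config}}.
#' @return A validated \code{\link{cohort}}.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "thyro_genconfig"))
  n <- config$n_patients
  pat_list <- vector("list", n)
  vis_list <- vector("list", n)
  for (i in seq_len(n)) {
    seed_i <- (as.numeric(config$seed) * 279470273 + i * 4294957) %% 2147483629
    set.seed(as.integer(seed_i))
    b <- sample_baseline(config, 1)
    v <- simulate_visits(b, config)
    completed <- v$day[nrow(v)] >= config$treatment_days
    if (completed) {
      rl <- assign_relapse(b, config)
    } else {
      rl <- list(relapsed = NA, relapse_day = NA_integer_)
    }
    id <- sprintf("P%05d", i)
    pat_list[[i]] <- data.frame(
      id = id, sex = b$sex, ethnicity = b$ethnicity, smoking = b$smoking,
      age = b$age, weight_kg = b$weight_kg, tshrab_u_ml = b$tshrab_u_ml,
      tpoab_u_ml = b$tpoab_u_ml, relapsed = rl$relapsed,
      relapse_day = rl$relapse_day, stringsAsFactors = FALSE)
    v$patient_id <- id
    vis_list[[i]] <- v[c("patient_id", "day", "ft4_pmol_l", "ft3_pmol_l",
                         "tsh_mu_l", "dose_mg", "split_dose")]
  }
  cohort(do.call(rbind, pat_list), do.call(rbind, vis_list))
}

# --- shared binning rules (lower-inclusive, upper-exclusive) -------------

bin_ft4_initial <- function(x) {
  as.character(cut(x, breaks = c(-Inf, 28, 45, Inf),
                   labels = c("<28", "28-44.9", ">45"), right = FALSE))
}
bin_tshrab <- function(x) {
  as.character(cut(x, breaks = c(-Inf, 3, 6, 9 + 1e-9, Inf),
                   labels = c("<3", "3-5.9", "6-9", ">9"), right = FALSE))
}
bin_ft4_final <- function(x) {
  as.character(cut(x, breaks = c(-Inf, 12, 15 + 1e-9, Inf),
                   labels = c("<12", "12-15", ">15"), right = FALSE))
}
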