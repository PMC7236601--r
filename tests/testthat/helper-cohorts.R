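# Shared fixtures, all generated in code. Heavy cohorts are cached so the
# expensive ones (the 10,000-patient reference cohort) are built once per
# test run and shared across files.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(key, maker) {
  if (is.null(.cohort_cache[[key]])) .cohort_cache[[key]] <- maker()
  .cohort_cache[[key]]
}

default_cohort <- function(seed = 1, n = 441) {
  cached_cohort(sprintf("default_%d_%d", seed, n), function()
    generate_cohort(generator_config(n_patients = n, seed = seed)))
}

big_cohort <- function() {
  cached_cohort("big", function()
    generate_cohort(generator_config(n_patients = 10000, seed = 42)))
}

# fully deterministic generator settings: no measurement noise, no
# per-patient heterogeneity, fixed reference-length gaps
noise_free_config <- function(n = 200, seed = 2, ...) {
  generator_config(n_patients = n, seed = seed, measurement_noise_sd = 0,
                   fall_shock_sd = 0, patient_rate_sd = 0,
                   visit_gap_days = c(35, 35), stable_gap_days = c(35, 35),
                   ...)
}

noise_free_cohort <- function() {
  cached_cohort("noisefree", function() generate_cohort(noise_free_config()))
}

# a tiny hand-written cohort: 2 patients, 5 visits
toy_cohort <- function() {
  patients <- data.frame(
    id = c("P1", "P2"), sex = c("F", "M"),
    ethnicity = c("White", "Asian"), smoking = c("never", "current"),
    age = c(40L, 55L), weight_kg = c(62, 80),
    tshrab_u_ml = c(5.2, 12.0), tpoab_u_ml = c(140, NA),
    relapsed = c(TRUE, FALSE), relapse_day = c(90L, NA_integer_),
    stringsAsFactors = FALSE)
  visits <- data.frame(
    patient_id = c("P1", "P1", "P1", "P2", "P2"),
    day = c(0L, 30L, 65L, 0L, 35L),
    ft4_pmol_l = c(40, 30, 22, 55, 35),
    ft3_pmol_l = c(27.8, 20, 14, 42, 25),
    tsh_mu_l = c(0.02, 0.05, 0.6, 0.01, 0.03),
    dose_mg = c(20, 20, 10, 40, 20),
    split_dose = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  cohort(patients, visits)
}

# intervals lying exactly on a %/day line, for exact-recovery checks
line_intervals <- function(slope, intercept, doses = c(5, 10, 20, 30, 40),
                           len = 30, start = 40, phase = "initial") {
  fall <- (slope * doses + intercept) * len / 100
  data.frame(patient_id = paste0("L", seq_along(doses)),
             start_day = if (phase == "initial") 0L else 50L,
             end_day = (if (phase == "initial") 0L else 50L) + len,
             dose_mg = doses,
             ft4_start = start, ft4_end = start * (1 - fall),
             ft3_start = start, ft3_end = start * (1 - fall),
             phase = phase, stringsAsFactors = FALSE)
}
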