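#!/usr/bin/env Rscript
# Stage 1 — generate the reference synthetic cohort.
#
# Produces a 441-patient dose-titration cohort with the calibrated baseline
# distributions, visit dynamics and relapse outcomes, and writes it as the
# two flat CSV tables every later stage reads.

suppressPackageStartupMessages(library(thyropd))
args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[1]) else 42L

dir.create("results", showWarnings = FALSE)
cfg <- generator_config(n_patients = 441, seed = seed)
ch <- generate_cohort(cfg)
write_cohort(ch, "results/patients.csv", "results/visits.csv")

v0 <- ch$visits[ch$visits$day == 0, ]
cat(sprintf("cohort: %d patients, %d visits (seed %d)\n",
            nrow(ch$patients), nrow(ch$visits), seed))
cat(sprintf("baseline: mean fT4 %.1f pmol/L, mean fT3 %.1f pmol/L, median TSHRab %.2f U/mL\n",
            mean(v0$ft4_pmol_l), mean(v0$ft3_pmol_l),
            median(ch$patients$tshrab_u_ml)))
cat(sprintf("%.0f%% female; %.0f%% completed treatment; %.0f%% of completers relapsed\n",
            100 * mean(ch$patients$sex == "F"),
            100 * mean(!is.na(ch$patients$relapsed)),
            100 * mean(ch$patients$relapsed, na.rm = TRUE)))
cat("wrote results/patients.csv, results/visits.csv\n")
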