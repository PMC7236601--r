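#!/usr/bin/env Rscript
# Stage 2 — pre-treatment relationships.
#
# Day-0 regressions of hormones on antibody titre and of fT3 on fT4, plus
# the coupling of per-day absolute falls between the two hormones over the
# initiation interval. Writes results/baseline.csv.

suppressPackageStartupMessages(library(thyropd))

ch <- read_cohort("results/patients.csv", "results/visits.csv")
br <- baseline_relationships(ch)
fc <- fall_coupling(build_intervals(ch))

rows <- lapply(c(br, list(fall_coupling = fc)), function(f)
  if (is.null(f)) rep(NA_real_, 5)
  else c(f$slope, f$intercept, f$r_squared, f$n, f$p_value))
tab <- data.frame(relation = names(rows), do.call(rbind, rows))
names(tab)[-1] <- c("slope", "intercept", "r_squared", "n", "p_value")
write.csv(tab, "results/baseline.csv", row.names = FALSE)

cat("baseline relationships (day-0 visits):\n")
cat(sprintf("  fT3 ~ fT4:       slope %.3f, intercept %.2f, r2 %.2f\n",
            br$ft3_ft4$slope, br$ft3_ft4$intercept, br$ft3_ft4$r_squared))
cat(sprintf("  fT4 ~ TSHRab:    slope %.3f, r2 %.2f\n",
            br$ft4_tshrab$slope, br$ft4_tshrab$r_squared))
cat(sprintf("  fT3 ~ TSHRab:    slope %.3f, r2 %.2f\n",
            br$ft3_tshrab$slope, br$ft3_tshrab$r_squared))
cat(sprintf("  fall coupling:   %.3f pmol/L fT3 per pmol/L fT4 (r2 %.2f)\n",
            fc$slope, fc$r_squared))
cat("wrote results/baseline.csv\n")
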