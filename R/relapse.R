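# Relapse outcome analysis: subgroup rates with the printed bins, odds
# ratios with Woolf confidence intervals and the Haldane-Anscombe zero-cell
# correction, multivariable logistic adjustment, the additive Relapse Rate
# Score with its <15 / 15-20 / >20 strata, and overtreatment frequency.

#' Odds ratio of a 2x2 table
#'
#' OR = (a*d)/(b*c) for counts (exposed-relapsed, exposed-not,
#' unexposed-relapsed, unexposed-not). If any cell is zero, 0.5 is added to
#' every cell (Haldane-Anscombe). The 95\% CI uses the log-OR normal
#' (Woolf) method and the two-sided p comes from the log-OR z statistic.
#'
#' @param a,b,c,d Non-negative integer counts; total must be positive.
#' @param conf_level Confidence level (default 0.95).
#' @return list of class \code{"thyro_or"}: or_value, ci_low, ci_high,
#'   p_value, corrected (whether the zero-cell correction was applied).
#' @export
odds_ratio <- function(a, b, c, d, conf_level = 0.95) {
  counts <- c(a, b, c, d)
  stopifnot(all(counts >= 0), sum(counts) > 0)
  corrected <- any(counts == 0)
  if (corrected) counts <- counts + 0.5
  or <- (counts[1] * counts[4]) / (counts[2] * counts[3])
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  lo <- exp(log(or) - z * se)
  hi <- exp(log(or) + z * se)
  p <- 2 * stats::pnorm(-abs(log(or) / se))
  structure(list(or_value = or, ci_low = lo, ci_high = hi, p_value = p,
                 corrected = corrected),
            class = "thyro_or")
}

#' @export
print.thyro_or <- function(x, ...) {
  cat(sprintf("OR %.3g (95%% CI %.3g-%.3g, p = %.3g)%s\n",
              x$or_value, x$ci_low, x$ci_high, x$p_value,
              if (x$corrected) " [zero-cell corrected]" else ""))
  invisible(x)
}

# Patient-level analysis table: baseline fields plus initial/final fT4 and
# the printed bins. Restricted (optionally) to patients with a relapse
# outcome, i.e. those who completed treatment and had a trial off drug.
relapse_table <- function(x, outcome_required = TRUE) {
  stopifnot(inherits(x, "thyro_cohort"))
  v <- x$visits[order(x$visits$patient_id, x$visits$day), ]
  first <- v[!duplicated(v$patient_id), c("patient_id", "ft4_pmol_l", "dose_mg")]
  names(first) <- c("id", "ft4_init", "dose_init")
  lastix <- rev(!duplicated(rev(v$patient_id)))
  last <- v[lastix, c("patient_id", "ft4_pmol_l")]
  names(last) <- c("id", "ft4_final")
  d <- merge(merge(x$patients, first, by = "id"), last, by = "id")
  d$ft4_init_bin <- bin_ft4_initial(d$ft4_init)
  d$ft4_final_bin <- bin_ft4_final(d$ft4_final)
  d$tshrab_bin <- bin_tshrab(d$tshrab_u_ml)
  if (outcome_required) d <- d[!is.na(d$relapsed), ]
  d
}

#' Relapse rates by patient subgroup
#'
#' Relapse frequency per level of a baseline (or final-visit) factor, using
#' the printed bins: initial fT4 \{<28, 28-44.9, >45\}, antibody titre
#' \{<3, 3-5.9, 6-9, >9\}, final fT4 \{<12, 12-15, >15\}. Continuous bins
#' are lower-inclusive, upper-exclusive. Only patients with a relapse
#' outcome (completed treatment) are counted.
#'
#' @param x A \code{\link{cohort}}.
#' @param factor One of \code{"sex", "ethnicity", "smoking", "ft4_init",
#'   "tshrab", "ft4_final"}.
#' @return data.frame with \code{level, n, relapse_pct}.
#' @export
subgroup_rates <- function(x, factor) {
  d <- relapse_table(x)
  col <- switch(factor,
                sex = d$sex, ethnicity = d$ethnicity, smoking = d$smoking,
                ft4_init = d$ft4_init_bin, tshrab = d$tshrab_bin,
                ft4_final = d$ft4_final_bin,
                stop("unknown factor: ", factor))
  lev <- switch(factor,
                sex = c("M", "F"),
                ethnicity = ETHNICITY_LEVELS,
                smoking = SMOKING_LEVELS,
                ft4_init = c("<28", "28-44.9", ">45"),
                tshrab = c("<3", "3-5.9", "6-9", ">9"),
                ft4_final = c("<12", "12-15", ">15"))
  col <- factor(col, levels = lev)
  n <- tapply(d$relapsed, col, length)
  r <- tapply(d$relapsed, col, function(z) 100 * mean(z))
  out <- data.frame(level = lev, n = as.integer(ifelse(is.na(n), 0, n)),
                    relapse_pct = as.numeric(r), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Default Relapse Rate Score configuration
#'
#' Point values per factor level are the subgroup relapse percentages
#' divided by ten (one decimal), then jointly affinely rescaled so that the
#' fixed strata (<15, 15-20, >20) isolate a low-risk and a high-risk tail
#' on the reference synthetic cohort (about 10\% and 80\% relapse). The
#' rescale constants were calibrated once on a large reference cohort (see
#' the repository's relapse analysis script) and apply per factor as
#' \code{a * points + b / 5} so the total score maps to \code{a * S + b}.
#'
#' @param rescale_a,rescale_b Affine rescale of the total score.
#' @param strata Stratum thresholds (score < strata[1]; between, inclusive;
#'   > strata[2]).
#' @return list of class \code{"rrs_config"}: category_points, strata.
#' @export
rrs_default_config <- function(rescale_a = 0.926, rescale_b = -0.28,
                               strata = c(15, 20)) {
  stopifnot(strata[1] < strata[2])
  base <- list(
    sex = c(M = 5.2, F = 3.3),
    ethnicity = c(Asian = 2.1, Black = 2.8, White = 5.2, Mixed = 3.5,
                  Other = 3.5, Unknown = 3.5),
    smoking = c(never = 3.2, ex = 4.4, current = 4.7),
    ft4_init = c("<28" = 1.7, "28-44.9" = 3.9, ">45" = 6.0),
    tshrab = c("<3" = 2.7, "3-5.9" = 3.1, "6-9" = 3.8, ">9" = 5.7))
  pts <- lapply(base, function(p) rescale_a * p + rescale_b / length(base))
  structure(list(category_points = pts, strata = strata,
                 base_points = base,
                 rescale = c(a = rescale_a, b = rescale_b)),
            class = "rrs_config")
}

#' Compute the Relapse Rate Score for one patient
#'
#' Additive score over the five baseline factors (initial fT4 bin, antibody
#' titre bin, sex, smoking status, ethnicity); the stratum is determined by
#' the configured thresholds (middle stratum inclusive at both ends).
#'
#' @param patient A list or one-row data.frame with \code{sex, ethnicity,
#'   smoking, tshrab_u_ml} and \code{ft4_init} (pmol/L).
#' @param config A \code{\link{rrs_default_config}}-style configuration.
#' @return list(score, stratum) with stratum in \code{c("<15", "15-20",
#'   ">20")}-style labels derived from the thresholds.
#' @export
compute_rrs <- function(patient, config = rrs_default_config()) {
  need <- c("sex", "ethnicity", "smoking", "tshrab_u_ml", "ft4_init")
  present <- vapply(need, function(f)
    !is.null(patient[[f]]) && !is.na(patient[[f]]), logical(1))
  if (!all(present))
    stop("missing factor(s) for RRS: ", paste(need[!present], collapse = ", "))
  pts <- config$category_points
  lookup <- function(tab, level) {
    if (!level %in% names(tab)) stop("unknown level '", level, "'")
    unname(tab[[level]])
  }
  score <- lookup(pts$sex, patient$sex) +
    lookup(pts$ethnicity, patient$ethnicity) +
    lookup(pts$smoking, patient$smoking) +
    lookup(pts$ft4_init, bin_ft4_initial(patient$ft4_init)) +
    lookup(pts$tshrab, bin_tshrab(patient$tshrab_u_ml))
  th <- config$strata
  stratum <- if (score < th[1]) sprintf("<%g", th[1])
  else if (score > th[2]) sprintf(">%g", th[2])
  else sprintf("%g-%g", th[1], th[2])
  list(score = score, stratum = stratum)
}

#' Score a whole cohort
#'
#' @param x A \code{\link{cohort}}.
#' @param config RRS configuration.
#' @param outcome_required Restrict to patients with a relapse outcome.
#' @return Patient-level data.frame with \code{score} and \code{stratum}.
#' @export
score_cohort <- function(x, config = rrs_default_config(),
                         outcome_required = TRUE) {
  d <- relapse_table(x, outcome_required)
  pts <- config$category_points
  score <- unname(pts$sex[d$sex]) + unname(pts$ethnicity[d$ethnicity]) +
    unname(pts$smoking[d$smoking]) + unname(pts$ft4_init[d$ft4_init_bin]) +
    unname(pts$tshrab[d$tshrab_bin])
  th <- config$strata
  d$score <- score
  d$stratum <- ifelse(score < th[1], sprintf("<%g", th[1]),
                      ifelse(score > th[2], sprintf(">%g", th[2]),
                             sprintf("%g-%g", th[1], th[2])))
  d
}

#' Relapse rates by score stratum
#'
#' Relapse frequency per RRS stratum plus the odds ratio of the top versus
#' bottom stratum. An empty stratum yields a zero-cell-corrected OR flagged
#' by \code{or$corrected}.
#'
#' @param x A \code{\link{cohort}}.
#' @param config RRS configuration.
#' @return list(strata = data.frame(stratum, n, relapse_pct),
#'   or_top_vs_bottom).
#' @export
rrs_strata_rates <- function(x, config = rrs_default_config()) {
  d <- score_cohort(x, config)
  th <- config$strata
  labs <- c(sprintf("<%g", th[1]), sprintf("%g-%g", th[1], th[2]),
            sprintf(">%g", th[2]))
  s <- factor(d$stratum, levels = labs)
  n <- as.integer(tapply(d$relapsed, s, length))
  n[is.na(n)] <- 0L
  rel <- as.integer(tapply(d$relapsed, s, sum))
  rel[is.na(rel)] <- 0L
  pct <- ifelse(n > 0, 100 * rel / n, NA_real_)
  or <- odds_ratio(rel[3], n[3] - rel[3], rel[1], n[1] - rel[1])
  list(strata = data.frame(stratum = labs, n = n, relapse_pct = pct,
                           stringsAsFactors = FALSE),
       or_top_vs_bottom = or)
}

#' Multivariable logistic model of relapse
#'
#' Maximum-likelihood logistic regression of the relapse outcome on the
#' requested baseline covariates (complete cases), with Wald confidence
#' intervals on the adjusted odds ratios and convergence/separation
#' diagnostics. Perfect separation is flagged rather than silently
#' reported.
#'
#' @param x A \code{\link{cohort}}.
#' @param covariates Character vector from \code{"sex", "ethnicity",
#'   "smoking", "age", "tpoab_u_ml", "tshrab_u_ml", "ft4_init",
#'   "ft4_final"} (continuous variables stay continuous).
#' @param min_events_per_param Complete-case sample-size guard (default 10
#'   per parameter).
#' @return list: table (term, or_value, ci_low, ci_high, p_value), n,
#'   converged, separation.
#' @export
fit_multivariable_logistic <- function(x, covariates,
                                       min_events_per_param = 10) {
  d <- relapse_table(x)
  allowed <- c("sex", "ethnicity", "smoking", "age", "tpoab_u_ml",
               "tshrab_u_ml", "ft4_init", "ft4_final")
  bad <- setdiff(covariates, allowed)
  if (length(bad)) stop("unknown covariate(s): ", paste(bad, collapse = ", "))
  dat <- d[, c("relapsed", covariates), drop = FALSE]
  dat <- dat[stats::complete.cases(dat), , drop = FALSE]
  for (v in intersect(covariates, c("sex", "ethnicity", "smoking")))
    dat[[v]] <- factor(dat[[v]])
  n_par <- 1 + sum(vapply(covariates, function(v)
    if (is.factor(dat[[v]])) nlevels(droplevels(dat[[v]])) - 1L else 1L,
    integer(1)))
  if (nrow(dat) < min_events_per_param * n_par)
    stop(sprintf("complete-case n = %d below %d per parameter (%d params)",
                 nrow(dat), min_events_per_param, n_par))
  form <- stats::as.formula(paste("relapsed ~", paste(covariates, collapse = " + ")))
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(form, family = stats::binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- summary(fit)$coefficients
  sep <- sep_warn || any(abs(cf[, 1]) > 15)
  terms <- rownames(cf)[-1]
  tab <- data.frame(
    term = terms,
    or_value = exp(cf[-1, 1]),
    ci_low = exp(cf[-1, 1] - 1.96 * cf[-1, 2]),
    ci_high = exp(cf[-1, 1] + 1.96 * cf[-1, 2]),
    p_value = cf[-1, 4],
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, n = nrow(dat), converged = fit$converged,
       separation = sep)
}

#' Overtreatment frequency and its univariate predictors
#'
#' Fraction of patients (with at least \code{min_followup_days} of
#' follow-up) who were over-treated — any visit classified
#' \code{"overtreated"} (TSH above range or fT4 below range) — plus
#' univariate logistic odds ratios of overtreatment for the stated
#' predictors.
#'
#' @param x A \code{\link{cohort}}.
#' @param ranges \code{\link{reference_ranges}}.
#' @param min_followup_days Minimum last-visit day (default 60).
#' @return list: overtreated_pct, n, predictors (list of per-predictor OR
#'   tables).
#' @export
overtreatment_summary <- function(x, ranges = reference_ranges(),
                                  min_followup_days = 60) {
  stopifnot(inherits(x, "thyro_cohort"))
  v <- x$visits
  status <- classify_status(v$tsh_mu_l, v$ft4_pmol_l, v$ft3_pmol_l, ranges)
  over_any <- tapply(status == "overtreated", v$patient_id, any)
  last_day <- tapply(v$day, v$patient_id, max)
  ids <- names(over_any)[last_day >= min_followup_days]
  if (length(ids) == 0) stop("no patients with sufficient follow-up")
  d <- relapse_table(x, outcome_required = FALSE)
  d <- d[d$id %in% ids, ]
  d$overtreated <- as.logical(over_any[d$id])
  preds <- c("dose_init", "ft4_init", "tpoab_u_ml", "tshrab_u_ml", "sex",
             "ethnicity", "age", "smoking")
  fits <- list()
  for (p in preds) {
    dat <- d[stats::complete.cases(d[[p]]), c("overtreated", p)]
    if (p %in% c("sex", "ethnicity", "smoking")) dat[[p]] <- factor(dat[[p]])
    fit <- tryCatch(
      suppressWarnings(stats::glm(stats::reformulate(p, "overtreated"),
                                  stats::binomial(), data = dat)),
      error = function(e) NULL)
    if (is.null(fit)) next
    cf <- summary(fit)$coefficients
    fits[[p]] <- data.frame(term = rownames(cf)[-1],
                            or_value = exp(cf[-1, 1]),
                            p_value = cf[-1, 4],
                            stringsAsFactors = FALSE)
    rownames(fits[[p]]) <- NULL
  }
  list(overtreated_pct = 100 * mean(d$overtreated), n = nrow(d),
       predictors = fits)
}
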