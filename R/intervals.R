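# Treatment intervals and the dose-response lines: consecutive-visit
# pairing, percentage fall per day, the >=21-day interval filter, and the
# per-dose median regression of percentage fall on dose by phase.

#' Build treatment intervals from consecutive visit pairs
#'
#' One interval per consecutive pair of visits of the same patient. The
#' dose attributed to an interval is the dose recorded at its starting
#' visit (mid-interval changes are assumed absent). Phase is
#' \code{"initial"} for intervals starting at day 0 and \code{"followup"}
#' otherwise. Patients with a single visit contribute no intervals.
#'
#' @param x A \code{\link{cohort}}.
#' @return data.frame with columns \code{patient_id, start_day, end_day,
#'   dose_mg, ft4_start, ft4_end, ft3_start, ft3_end, phase}.
#' @export
build_intervals <- function(x) {
  stopifnot(inherits(x, "thyro_cohort"))
  v <- x$visits[order(x$visits$patient_id, x$visits$day), ]
  n <- nrow(v)
  if (n < 2)
    return(data.frame(patient_id = character(0), start_day = integer(0),
                      end_day = integer(0), dose_mg = numeric(0),
                      ft4_start = numeric(0), ft4_end = numeric(0),
                      ft3_start = numeric(0), ft3_end = numeric(0),
                      phase = character(0), stringsAsFactors = FALSE))
  i <- seq_len(n - 1)
  same <- v$patient_id[i] == v$patient_id[i + 1]
  s <- i[same]
  out <- data.frame(
    patient_id = v$patient_id[s],
    start_day = v$day[s],
    end_day = v$day[s + 1],
    dose_mg = v$dose_mg[s],
    ft4_start = v$ft4_pmol_l[s],
    ft4_end = v$ft4_pmol_l[s + 1],
    ft3_start = v$ft3_pmol_l[s],
    ft3_end = v$ft3_pmol_l[s + 1],
    phase = ifelse(v$day[s] == 0, "initial", "followup"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Percentage fall per day over an interval
#'
#' \code{100 * (start - end) / start / (end_day - start_day)}: the simple
#' (non-compounded) average daily percentage fall, negative when the level
#' rose. The compounded alternative (the equivalent constant daily
#' fractional fall) is available via \code{compounded = TRUE} but is not
#' the default, matching the linear treatment of the dose-response figures.
#'
#' @param intervals Interval table from \code{\link{build_intervals}}.
#' @param hormone \code{"ft4"} or \code{"ft3"}.
#' @param compounded Use the compounded per-day rate instead.
#' @return Numeric vector, \%/day.
#' @export
pct_fall_per_day <- function(intervals, hormone = c("ft4", "ft3"),
                             compounded = FALSE) {
  hormone <- match.arg(hormone)
  s <- intervals[[paste0(hormone, "_start")]]
  e <- intervals[[paste0(hormone, "_end")]]
  len <- intervals$end_day - intervals$start_day
  if (any(len <= 0)) stop("zero-length interval")
  if (any(!is.na(s) & s <= 0)) stop("non-positive start level")
  if (compounded) 100 * (1 - (e / s)^(1 / len)) else 100 * (s - e) / s / len
}

#' Filter intervals by minimum length
#'
#' Keeps intervals whose length is at least \code{min_days} (boundary
#' inclusive: a 21-day interval is kept under the default). Order is
#' preserved and the operation is idempotent.
#'
#' @param intervals Interval table.
#' @param min_days Minimum interval length in days (default 21).
#' @return The retained subset of \code{intervals}.
#' @export
filter_intervals <- function(intervals, min_days = 21) {
  intervals[(intervals$end_day - intervals$start_day) >= min_days, ,
            drop = FALSE]
}

#' Fit a dose-response line through per-dose median falls
#'
#' For each dose group, takes the median percentage fall per day across
#' intervals (each interval counts once, pooling multiple intervals per
#' patient), then fits OLS of the medians on dose. Dose groups are weighted
#' equally regardless of size, as a fit through medians implies. Intervals
#' shorter than \code{min_days} are excluded first.
#'
#' @param intervals Interval table.
#' @param hormone \code{"ft4"} or \code{"ft3"}.
#' @param phase \code{"initial"} or \code{"followup"}.
#' @param min_days Minimum interval length (default 21).
#' @param compounded Passed to \code{\link{pct_fall_per_day}}.
#' @return list of class \code{"thyro_doseline"}: phase, hormone, slope
#'   (\%/day per mg), intercept (\%/day), r_squared, points (per-dose
#'   medians with group sizes), n_intervals.
#' @export
fit_dose_response <- function(intervals, hormone = c("ft4", "ft3"),
                              phase = c("initial", "followup"),
                              min_days = 21, compounded = FALSE) {
  hormone <- match.arg(hormone); phase <- match.arg(phase)
  keep <- filter_intervals(intervals[intervals$phase == phase, , drop = FALSE],
                           min_days)
  keep <- keep[!is.na(keep[[paste0(hormone, "_start")]]) &
                 !is.na(keep[[paste0(hormone, "_end")]]), , drop = FALSE]
  if (nrow(keep) == 0) stop("no usable intervals for phase ", phase)
  fall <- pct_fall_per_day(keep, hormone, compounded)
  med <- tapply(fall, keep$dose_mg, stats::median)
  sizes <- tapply(fall, keep$dose_mg, length)
  doses <- as.numeric(names(med))
  if (length(doses) < 3)
    stop("fewer than 3 dose groups for phase ", phase)
  fit <- fit_ols(doses, as.numeric(med))
  structure(list(phase = phase, hormone = hormone,
                 slope = fit$slope, intercept = fit$intercept,
                 r_squared = fit$r_squared,
                 points = data.frame(dose_mg = doses,
                                     median_pct_per_day = as.numeric(med),
                                     n = as.integer(sizes)),
                 n_intervals = nrow(keep)),
            class = "thyro_doseline")
}

#' @export
print.thyro_doseline <- function(x, ...) {
  cat(sprintf("%s %s: %%fall/day = %.4g * dose %+.4g  (r2 = %.3f, %d intervals)\n",
              x$phase, x$hormone, x$slope, x$intercept, x$r_squared,
              x$n_intervals))
  invisible(x)
}

#' Dependence of the measured fall rate on interval length
#'
#' OLS of the percentage fall in fT4 per day on the interval length in
#' days, across initiation intervals at a fixed dose, with no minimum-length
#' filter. A negative slope reflects the rapid early response: short
#' intervals are dominated by the boosted first weeks.
#'
#' @param intervals Interval table.
#' @param dose_mg Dose defining the group (default 20).
#' @return A \code{\link{fit_ols}} result.
#' @export
time_interval_trend <- function(intervals, dose_mg = 20) {
  sel <- intervals[intervals$phase == "initial" &
                     intervals$dose_mg == dose_mg, , drop = FALSE]
  if (nrow(sel) < 3) stop("fewer than 3 initiation intervals at dose ", dose_mg)
  fit_ols(sel$end_day - sel$start_day, pct_fall_per_day(sel, "ft4"))
}
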