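# Pre-treatment relationships: hormones vs antibody titre, fT3 vs fT4, and
# the coupling between per-day absolute falls of the two hormones.

#' Simple linear regression
#'
#' Ordinary least squares of y on x with the summaries used throughout the
#' pipeline: slope, intercept, r-squared (squared sample correlation) and
#' the two-sided p-value for slope != 0. p-values are reported but never
#' used for gating, and no multiplicity correction is applied.
#'
#' @param x,y Numeric vectors of equal length (>= 3 complete cases).
#' @return list of class \code{"thyro_ols"}: slope, intercept, r_squared, n,
#'   p_value.
#' @export
fit_ols <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete cases")
  if (stats::sd(x) == 0) stop("degenerate design: x is constant")
  fit <- stats::lm(y ~ x)
  cf <- stats::coef(fit)
  # exact-fit fixtures trip the "essentially perfect fit" warning; the
  # summaries themselves are still well-defined
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(slope = unname(cf[2]), intercept = unname(cf[1]),
                 r_squared = sm$r.squared, n = n,
                 p_value = unname(sm$coefficients[2, 4])),
            class = "thyro_ols")
}

#' @export
print.thyro_ols <- function(x, ...) {
  cat(sprintf("OLS: y = %.4g x + %.4g  (r2 = %.3f, n = %d, p = %.3g)\n",
              x$slope, x$intercept, x$r_squared, x$n, x$p_value))
  invisible(x)
}

#' Baseline regressions across patients
#'
#' Fits the pre-treatment relationships on day-0 visits only: fT4 on
#' TSH-receptor antibody titre, fT3 on titre, and fT3 on fT4. Relations
#' whose analyte is absent (or with fewer than 3 complete cases) are
#' reported as NULL rather than failing the others.
#'
#' @param x A \code{\link{cohort}}.
#' @return Named list of \code{\link{fit_ols}} results:
#'   \code{ft4_tshrab}, \code{ft3_tshrab}, \code{ft3_ft4}.
#' @export
baseline_relationships <- function(x) {
  stopifnot(inherits(x, "thyro_cohort"))
  v0 <- x$visits[x$visits$day == 0, ]
  d <- merge(v0, x$patients, by.x = "patient_id", by.y = "id")
  if (nrow(d) < 3) stop("insufficient complete cases at day 0")
  safe_fit <- function(xv, yv) {
    if (sum(stats::complete.cases(xv, yv)) < 3) return(NULL)
    fit_ols(xv, yv)
  }
  list(ft4_tshrab = safe_fit(d$tshrab_u_ml, d$ft4_pmol_l),
       ft3_tshrab = safe_fit(d$tshrab_u_ml, d$ft3_pmol_l),
       ft3_ft4 = safe_fit(d$ft4_pmol_l, d$ft3_pmol_l))
}

#' Coupling between daily falls of fT3 and fT4
#'
#' OLS of the per-day absolute fall in fT3 on the per-day absolute fall in
#' fT4 across treatment intervals with both analytes at both ends. The
#' default restricts to initiation-phase intervals — the falls observed
#' after the first weeks of treatment — because later intervals cluster
#' near zero fall and contribute mostly measurement noise.
#'
#' @param intervals Interval table from \code{\link{build_intervals}}.
#' @param phase Intervals to use: \code{"initial"} (default), or
#'   \code{"all"}/\code{"followup"}.
#' @return A \code{\link{fit_ols}} result.
#' @export
fall_coupling <- function(intervals, phase = c("initial", "all", "followup")) {
  phase <- match.arg(phase)
  if (phase != "all") intervals <- intervals[intervals$phase == phase, ]
  ok <- stats::complete.cases(intervals$ft3_start, intervals$ft3_end)
  intervals <- intervals[ok, ]
  if (nrow(intervals) < 3) stop("fewer than 3 usable intervals")
  len <- intervals$end_day - intervals$start_day
  fall4 <- (intervals$ft4_start - intervals$ft4_end) / len
  fall3 <- (intervals$ft3_start - intervals$ft3_end) / len
  fit_ols(fall4, fall3)
}
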