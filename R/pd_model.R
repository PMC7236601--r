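# Recursive daily pharmacodynamic model:
#   level(n+1) = level(n) - (m * Dose^p * level(n) + c_term)
# with phase-specific (m, c), an optional dose exponent p, and levels
# floored at the assay detection limit. The intercept c is interpreted by
# default as a fraction of the current level (so percentage-fall lines
# convert exactly); an absolute pmol/L-per-day mode is provided for
# sensitivity analysis.

#' Pharmacodynamic recursion parameters
#'
#' @param hormone \code{"ft4"} or \code{"ft3"}.
#' @param m_initial,m_followup Daily fractional fall per mg of dose (the
#'   model's m), by phase.
#' @param c_initial,c_followup The model's intercept c, by phase: a
#'   fraction of the current level per day under \code{c_mode =
#'   "fractional"}, pmol/L per day under \code{"absolute"}.
#' @param p Dose exponent, in [0.5, 1.5]; 1 gives the linear model.
#' @param weight_slope_adj,weight_intercept_adj Linear per-kg adjustments of
#'   m and c about \code{ref_weight}.
#' @param ref_weight Reference body weight (kg).
#' @param c_mode Interpretation of c (see above).
#' @return list of class \code{"pd_parameters"}.
#' @export
pd_parameters <- function(hormone = c("ft4", "ft3"),
                          m_initial, c_initial, m_followup, c_followup,
                          p = 1,
                          weight_slope_adj = 0, weight_intercept_adj = 0,
                          ref_weight = 70,
                          c_mode = c("fractional", "absolute")) {
  hormone <- match.arg(hormone); c_mode <- match.arg(c_mode)
  m_initial <- as.numeric(m_initial); c_initial <- as.numeric(c_initial)
  m_followup <- as.numeric(m_followup); c_followup <- as.numeric(c_followup)
  p <- as.numeric(p)
  stopifnot(p >= 0.5, p <= 1.5, is.finite(m_initial), is.finite(m_followup),
            is.finite(c_initial), is.finite(c_followup), ref_weight > 0)
  structure(list(hormone = hormone,
                 m_initial = m_initial, c_initial = c_initial,
                 m_followup = m_followup, c_followup = c_followup,
                 p = p,
                 weight_slope_adj = weight_slope_adj,
                 weight_intercept_adj = weight_intercept_adj,
                 ref_weight = ref_weight, c_mode = c_mode),
            class = "pd_parameters")
}

#' @export
print.pd_parameters <- function(x, ...) {
  cat(sprintf(paste0("<pd_parameters %s> p = %.2f, c_mode = %s\n",
                     "  initial:  m = %.6g, c = %.6g\n",
                     "  followup: m = %.6g, c = %.6g\n"),
              x$hormone, x$p, x$c_mode, x$m_initial, x$c_initial,
              x$m_followup, x$c_followup))
  if (x$weight_slope_adj != 0 || x$weight_intercept_adj != 0)
    cat(sprintf("  weight adj: dm/dkg = %.3g, dc/dkg = %.3g (ref %.0f kg)\n",
                x$weight_slope_adj, x$weight_intercept_adj, x$ref_weight))
  invisible(x)
}

phase_mc <- function(params, phase) {
  if (phase == "initial")
    c(m = params$m_initial, c = params$c_initial)
  else
    c(m = params$m_followup, c = params$c_followup)
}

#' One day of the recursion
#'
#' Applies \code{level - (m * dose^p * level + c_term)} with the
#' phase-selected coefficients, flooring at the assay detection limit.
#' Vectorised over \code{level}.
#'
#' @param level Current level (pmol/L, > 0).
#' @param dose Daily dose (mg, >= 0).
#' @param params \code{\link{pd_parameters}}.
#' @param phase \code{"initial"} or \code{"followup"}.
#' @return Next-day level (pmol/L).
#' @export
pd_step <- function(level, dose, params, phase = c("initial", "followup")) {
  phase <- match.arg(phase)
  stopifnot(all(level > 0), all(dose >= 0))
  mc <- phase_mc(params, phase)
  m <- unname(mc["m"]); cc <- unname(mc["c"])
  c_term <- if (params$c_mode == "fractional") cc * level else cc
  floor <- assay_floors()[[params$hormone]]
  pmax(level - (m * dose^params$p * level + c_term), floor)
}

#' Simulate a trajectory under a dose schedule
#'
#' Applies \code{\link{pd_step}} once per day from day 0 to
#' \code{horizon_days}. The phase is \code{"initial"} for days before
#' \code{phase_boundary_day} and \code{"followup"} after, mirroring the
#' distinction between the first inter-visit interval and later ones.
#' Deterministic.
#'
#' @param level0 Starting level (pmol/L, > 0).
#' @param schedule Either a single dose (mg/day, constant) or a data.frame
#'   with columns \code{day, dose_mg}: the dose applying from each \code{day}
#'   onward. Must cover day 0.
#' @param horizon_days Number of days to simulate (>= 0).
#' @param params \code{\link{pd_parameters}}.
#' @param phase_boundary_day Day at which follow-up coefficients take over
#'   (default 35, a typical first follow-up).
#' @return list of class \code{"pd_trajectory"}: days (0..horizon), levels,
#'   dose_schedule.
#' @export
pd_simulate <- function(level0, schedule, horizon_days, params,
                        phase_boundary_day = 35) {
  stopifnot(level0 > 0, horizon_days >= 0)
  if (is.numeric(schedule) && length(schedule) == 1)
    schedule <- data.frame(day = 0, dose_mg = schedule)
  schedule <- schedule[order(schedule$day), , drop = FALSE]
  if (schedule$day[1] > 0) stop("schedule gap: no dose defined for day 0")
  dose_at <- function(d) schedule$dose_mg[findInterval(d, schedule$day)]
  levels <- numeric(horizon_days + 1)
  levels[1] <- level0
  lv <- level0
  for (d in seq_len(horizon_days)) {
    ph <- if ((d - 1) < phase_boundary_day) "initial" else "followup"
    lv <- pd_step(lv, dose_at(d - 1), params, ph)
    levels[d + 1] <- lv
  }
  structure(list(days = 0:horizon_days, levels = levels,
                 dose_schedule = schedule,
                 phase_boundary_day = phase_boundary_day),
            class = "pd_trajectory")
}

#' @export
print.pd_trajectory <- function(x, ...) {
  cat(sprintf("<pd_trajectory> %d days: %.2f -> %.2f pmol/L\n",
              max(x$days), x$levels[1], x$levels[length(x$levels)]))
  invisible(x)
}

#' Root mean square error
#'
#' Square root of the mean squared residual between observed and predicted
#' levels, in pmol/L; zero indicates a perfect fit.
#'
#' @param observed,predicted Equal-length non-empty numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(observed, predicted) {
  if (length(observed) != length(predicted)) stop("length mismatch")
  if (length(observed) == 0) stop("empty vectors")
  sqrt(mean((observed - predicted)^2))
}

#' Convert fitted dose-response lines to recursion parameters
#'
#' Fits the phase dose-response lines (median percentage fall per day on
#' dose, intervals of at least \code{min_days} days) and converts them to
#' recursion coefficients: m = slope/100 per mg, and the line intercept as
#' a fractional per-day term c = intercept/100 of the current level, per
#' phase. The fitted lines are attached as provenance.
#'
#' @param intervals Interval table from \code{\link{build_intervals}}.
#' @param hormone \code{"ft4"} or \code{"ft3"}.
#' @param min_days Interval filter (default 21).
#' @return \code{\link{pd_parameters}} with attribute \code{"lines"}.
#' @export
fit_linear_params <- function(intervals, hormone = c("ft4", "ft3"),
                              min_days = 21) {
  hormone <- match.arg(hormone)
  li <- fit_dose_response(intervals, hormone, "initial", min_days)
  lf <- fit_dose_response(intervals, hormone, "followup", min_days)
  out <- pd_parameters(hormone,
                       m_initial = li$slope / 100,
                       c_initial = li$intercept / 100,
                       m_followup = lf$slope / 100,
                       c_followup = lf$intercept / 100)
  attr(out, "lines") <- list(initial = li, followup = lf)
  out
}

# Simple (non-compounded) daily fractional fall of each interval: the
# design used by the exponent / weight refits, 1 - e/s over len days, so
# that (fall per day) = m * dose^p + c (fractional c). This matches the
# percentage-fall-per-day observable the dose-response lines are fitted
# on, making line-derived parameters exactly self-consistent with the
# intervals they were fitted to.
interval_daily_fall <- function(intervals, hormone) {
  s <- intervals[[paste0(hormone, "_start")]]
  e <- intervals[[paste0(hormone, "_end")]]
  len <- intervals$end_day - intervals$start_day
  (1 - e / s) / len
}

# weighted by (start * len)^2 so the minimised loss is the end-level SSE
# that the one-step RMSE measures
refit_mc <- function(y, dose_p, w) {
  if (length(unique(dose_p)) < 2) stop("need at least 2 dose groups to refit")
  f <- stats::lm.wfit(cbind(1, dose_p), y, w = w)
  c(m = unname(f$coefficients[2]), c = unname(f$coefficients[1]))
}

predict_interval_end <- function(intervals, params, weights = NULL) {
  len <- intervals$end_day - intervals$start_day
  s <- intervals[[paste0(params$hormone, "_start")]]
  m <- ifelse(intervals$phase == "initial", params$m_initial, params$m_followup)
  cc <- ifelse(intervals$phase == "initial", params$c_initial, params$c_followup)
  if (!is.null(weights)) {
    dw <- weights - params$ref_weight
    m <- m + params$weight_slope_adj * dw
    cc <- cc + params$weight_intercept_adj * dw
  }
  daily <- m * intervals$dose_mg^params$p + cc
  if (params$c_mode != "fractional")
    stop("interval prediction implemented for fractional c only")
  # simple aggregation over the interval, matching the %/day observable
  pmax(s * pmax(1 - daily * len, 1e-12), assay_floors()[[params$hormone]])
}

#' One-interval-ahead prediction RMSE
#'
#' Predicts each interval's end level from its start level, dose and length
#' under the recursion parameters, and returns the RMSE against the
#' observed end levels. Supplying \code{patients} applies the per-patient
#' weight adjustment.
#'
#' @param intervals Interval table.
#' @param params \code{\link{pd_parameters}}.
#' @param patients Optional patient table (for \code{weight_kg}).
#' @param min_days Interval filter (default 21).
#' @return RMSE in pmol/L.
#' @export
pd_one_step_rmse <- function(intervals, params, patients = NULL,
                             min_days = 21) {
  keep <- filter_intervals(intervals, min_days)
  keep <- keep[!is.na(keep[[paste0(params$hormone, "_start")]]) &
                 !is.na(keep[[paste0(params$hormone, "_end")]]), ,
               drop = FALSE]
  w <- NULL
  if (!is.null(patients))
    w <- patients$weight_kg[match(keep$patient_id, patients$id)]
  rmse(keep[[paste0(params$hormone, "_end")]],
       predict_interval_end(keep, params, w))
}

#' Fit the dose exponent by grid search
#'
#' Selects the exponent p in the refined recursion by minimising the
#' one-interval-ahead RMSE over all intervals, refitting (m, c) for both
#' phases at every candidate p (1-D bounded grid search, reproducible; no
#' gradient descent). Ties are broken toward p = 1.
#'
#' @param intervals Interval table.
#' @param hormone \code{"ft4"} or \code{"ft3"}.
#' @param p_grid Candidate exponents (default 0.5 to 1.5, step 0.01).
#' @param min_days Interval filter (default 21).
#' @return \code{\link{pd_parameters}} with the selected p and refitted
#'   (m, c); attribute \code{"rmse_grid"} holds the RMSE profile.
#' @export
fit_exponent <- function(intervals, hormone = c("ft4", "ft3"),
                         p_grid = round(seq(0.5, 1.5, by = 0.01), 2),
                         min_days = 21) {
  hormone <- match.arg(hormone)
  if (length(p_grid) == 0) stop("empty exponent grid")
  keep <- filter_intervals(intervals, min_days)
  keep <- keep[!is.na(keep[[paste0(hormone, "_start")]]) &
                 !is.na(keep[[paste0(hormone, "_end")]]), , drop = FALSE]
  if (nrow(keep) < 3) stop("fewer than 3 usable intervals")
  y <- interval_daily_fall(keep, hormone)
  ends <- keep[[paste0(hormone, "_end")]]
  wts <- (keep[[paste0(hormone, "_start")]] *
            (keep$end_day - keep$start_day))^2

  eval_p <- function(p) {
    prm <- list()
    for (ph in c("initial", "followup")) {
      sel <- keep$phase == ph
      if (sum(sel) < 2) stop("too few intervals in phase ", ph)
      prm[[ph]] <- refit_mc(y[sel], keep$dose_mg[sel]^p, wts[sel])
    }
    pars <- pd_parameters(hormone,
                          m_initial = prm$initial["m"],
                          c_initial = prm$initial["c"],
                          m_followup = prm$followup["m"],
                          c_followup = prm$followup["c"],
                          p = p)
    list(pars = pars, rmse = rmse(ends, predict_interval_end(keep, pars)))
  }

  fits <- lapply(p_grid, eval_p)
  rmses <- vapply(fits, `[[`, numeric(1), "rmse")
  best <- min(rmses)
  cand <- which(rmses <= best + 1e-12)
  pick <- cand[which.min(abs(p_grid[cand] - 1))]
  out <- fits[[pick]]$pars
  attr(out, "rmse_grid") <- data.frame(p = p_grid, rmse = rmses)
  out
}

#' Apply the linear weight adjustment
#'
#' Shifts m and c of both phases linearly in body weight about the
#' reference weight: at \code{ref_weight} (or with zero adjustment terms)
#' the parameters are returned unchanged.
#'
#' @param params \code{\link{pd_parameters}}.
#' @param weight_kg Body weight (> 0).
#' @return Adjusted \code{\link{pd_parameters}} (adjustment terms reset to
#'   zero, already folded in).
#' @export
weight_adjust <- function(params, weight_kg) {
  stopifnot(weight_kg > 0)
  dw <- weight_kg - params$ref_weight
  out <- params
  out$m_initial <- params$m_initial + params$weight_slope_adj * dw
  out$m_followup <- params$m_followup + params$weight_slope_adj * dw
  out$c_initial <- params$c_initial + params$weight_intercept_adj * dw
  out$c_followup <- params$c_followup + params$weight_intercept_adj * dw
  out$weight_slope_adj <- 0
  out$weight_intercept_adj <- 0
  out
}

#' Estimate the weight-adjustment terms from intervals
#'
#' Regresses the residual daily fall (observed equivalent daily fall minus
#' the phase model) on the weight-centred dose term and on centred weight,
#' giving the per-kg slope and intercept adjustments.
#'
#' @param intervals Interval table.
#' @param patients Patient table (for \code{weight_kg}).
#' @param params Baseline \code{\link{pd_parameters}}.
#' @param min_days Interval filter (default 21).
#' @return \code{params} with the adjustment terms filled in.
#' @export
fit_weight_adjustment <- function(intervals, patients, params,
                                  min_days = 21) {
  keep <- filter_intervals(intervals, min_days)
  keep <- keep[!is.na(keep[[paste0(params$hormone, "_start")]]) &
                 !is.na(keep[[paste0(params$hormone, "_end")]]), ,
               drop = FALSE]
  w <- patients$weight_kg[match(keep$patient_id, patients$id)]
  ok <- !is.na(w)
  keep <- keep[ok, ]; w <- w[ok]
  # least squares on the end-level residuals (the loss the one-step RMSE
  # measures), so the fitted adjustment can only improve the in-sample fit
  resid <- keep[[paste0(params$hormone, "_end")]] -
    predict_interval_end(keep, params)
  dw <- w - params$ref_weight
  sl <- keep[[paste0(params$hormone, "_start")]] *
    (keep$end_day - keep$start_day)
  f <- stats::lm.fit(cbind(sl * dw * keep$dose_mg^params$p, sl * dw), resid)
  out <- params
  out$weight_slope_adj <- -unname(f$coefficients[1])
  out$weight_intercept_adj <- -unname(f$coefficients[2])
  out
}

#' Recommend the lowest sufficient dose
#'
#' Returns the smallest dose in the allowed set whose simulated trajectory
#' reaches the target level within the horizon; if none does, the maximum
#' dose with \code{reachable = FALSE}.
#'
#' @param level_now Current level (pmol/L, > 0).
#' @param target Target level (pmol/L).
#' @param horizon_days Days available (>= 1).
#' @param params \code{\link{pd_parameters}}.
#' @param phase Phase for the whole horizon (default "initial").
#' @param doses Candidate doses (default \code{\link{allowed_doses}}).
#' @return list(dose_mg, reachable, days_to_target).
#' @export
recommend_dose <- function(level_now, target, horizon_days, params,
                           phase = c("initial", "followup"),
                           doses = allowed_doses()) {
  phase <- match.arg(phase)
  stopifnot(level_now > 0, horizon_days >= 1)
  if (length(doses) == 0) stop("empty allowed dose set")
  boundary <- if (phase == "initial") horizon_days + 1 else 0
  for (d in sort(doses)) {
    traj <- pd_simulate(level_now, d, horizon_days, params, boundary)
    hit <- which(traj$levels <= target)
    if (length(hit))
      return(list(dose_mg = d, reachable = TRUE,
                  days_to_target = traj$days[hit[1]]))
  }
  list(dose_mg = max(doses), reachable = FALSE, days_to_target = NA_integer_)
}
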