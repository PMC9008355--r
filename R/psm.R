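#' Model settings for the partitioned survival model
#'
#' @param cycle_length_days cycle length in days (default 28, the 4-week
#'   medication cycle).
#' @param horizon_years model horizon in years (default 15; overall survival
#'   under the base-case models is below 1% by then).
#' @param annual_discount_rate annual discount rate for costs and QALYs,
#'   in `[0, 0.08]` (default 0.05).
#' @param half_cycle_correction when `TRUE`, all accruals use the trapezoid
#'   (mid-cycle) occupancy; default `FALSE` = start-of-cycle occupancy,
#'   which reproduces the published base case (see the methods vignette).
#' @param days_per_month days per model month on the survival time axis.
#'   Default 28: the survival parameters were estimated on a grid of 4-week
#'   cycle nodes, so one cycle advances the survival clock by one unit.
#'   Set 30.4375 for the exact calendar-month conversion.
#' @param drug_stop_midcycle when `TRUE` (default) drug acquisition accrues
#'   on mid-cycle (trapezoid) progression-free occupancy: treatment stops at
#'   progression, which on average occurs half-way through a cycle.
#' @return object of class `model_settings`.
#' @export
model_settings <- function(cycle_length_days = 28,
                           horizon_years = 15,
                           annual_discount_rate = 0.05,
                           half_cycle_correction = FALSE,
                           days_per_month = 28,
                           drug_stop_midcycle = TRUE) {
  stopifnot(cycle_length_days > 0, horizon_years > 0, days_per_month > 0)
  if (annual_discount_rate < 0 || annual_discount_rate > 0.08)
    stop("annual discount rate must lie in [0, 0.08]")
  structure(list(cycle_length_days = cycle_length_days,
                 horizon_years = horizon_years,
                 annual_discount_rate = annual_discount_rate,
                 half_cycle_correction = isTRUE(half_cycle_correction),
                 days_per_month = days_per_month,
                 drug_stop_midcycle = isTRUE(drug_stop_midcycle)),
            class = "model_settings")
}

.n_cycles <- function(settings) {
  floor(settings$horizon_years * 365.25 / settings$cycle_length_days)
}

#' Per-cycle discount factors at cycle midpoints
#' @keywords internal
.discount_factors <- function(settings, n = .n_cycles(settings)) {
  r <- settings$annual_discount_rate
  t_years <- (seq_len(n) - 0.5) * settings$cycle_length_days / 365.25
  (1 + r)^(-t_years)
}

#' Build the three-state occupancy trace from OS and PFS models
#'
#' At each cycle boundary t: `PF(t) = min(S_PFS(t), S_OS(t))` (the standard
#' cap for independently modelled curves — a crossing never produces
#' negative occupancy), `dead(t) = 1 - S_OS(t)`,
#' `PD(t) = S_OS(t) - PF(t) >= 0`. All patients start progression-free.
#'
#' @param os,pfs [surv_model()] objects for overall and progression-free
#'   survival (parametric or empirical `"km"` step functions).
#' @param settings a [model_settings()].
#' @param max_time_months optional truncation of the survival input (used by
#'   the KM-only scenario): occupancy is only accrued up to this time.
#' @return object of class `psm_trace` with boundary occupancies `pf`,
#'   `pd`, `dead` (length cycles + 1), per-cycle `new_deaths`, boundary
#'   times in model months, and the settings used.
#' @export
build_trace <- function(os, pfs, settings = model_settings(),
                        max_time_months = NULL) {
  stopifnot(inherits(os, "surv_model"), inherits(pfs, "surv_model"),
            inherits(settings, "model_settings"))
  n <- .n_cycles(settings)
  cycle_months <- settings$cycle_length_days / settings$days_per_month
  t_m <- (0:n) * cycle_months
  if (!is.null(max_time_months)) {
    n <- max(1L, min(n, floor(max_time_months / cycle_months)))
    t_m <- (0:n) * cycle_months
  }
  s_os <- survival_at(os, t_m)
  s_pfs <- survival_at(pfs, t_m)
  pf <- pmin(s_pfs, s_os)
  dead <- 1 - s_os
  pd <- s_os - pf
  stopifnot(all(abs(pf + pd + dead - 1) < 1e-12))
  structure(list(time_months = t_m, n_cycles = n,
                 pf = pf, pd = pd, dead = dead,
                 new_deaths = diff(dead),
                 settings = settings),
            class = "psm_trace")
}

#' @export
print.psm_trace <- function(x, ...) {
  cat(sprintf("<psm_trace> %d cycles of %g days (%.1f years); final state (pf, pd, dead) = (%.4f, %.4f, %.4f)\n",
              x$n_cycles, x$settings$cycle_length_days,
              x$n_cycles * x$settings$cycle_length_days / 365.25,
              utils::tail(x$pf, 1), utils::tail(x$pd, 1), utils::tail(x$dead, 1)))
  invisible(x)
}

# per-cycle occupancy used for accrual: start-of-cycle boundaries, or the
# trapezoid average when the half-cycle correction is on / forced
.occupancy <- function(x, half_cycle) {
  n <- length(x) - 1L
  if (half_cycle) (x[-1] + x[-(n + 1)]) / 2 else x[seq_len(n)]
}

#' Discounted life years by state
#'
#' Per-cycle person-time is occupancy times the cycle length in years
#' (365.25-day years), discounted at the cycle midpoint with
#' `(1 + r)^(-t)`.
#'
#' @param trace a [psm_trace()].
#' @param settings settings; defaults to those stored in the trace.
#' @return list with discounted years `total`, `pf`, `pd`.
#' @export
life_years <- function(trace, settings = trace$settings) {
  n <- trace$n_cycles
  cyc_y <- settings$cycle_length_days / 365.25
  disc <- .discount_factors(settings, n)
  hc <- settings$half_cycle_correction
  ly_pf <- sum(.occupancy(trace$pf, hc) * cyc_y * disc)
  ly_pd <- sum(.occupancy(trace$pd, hc) * cyc_y * disc)
  list(total = ly_pf + ly_pd, pf = ly_pf, pd = ly_pd)
}
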