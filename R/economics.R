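#' Patient assistance program (PAP) schemes
#'
#' `pap_none()` — full price every cycle. `pap_pay_first_k(k)` — full price
#' for the first `k` cycles, free afterwards (the typical
#' pay-some-boxes-then-donation design). `pap_price_multiplier(f)` — the
#' effective price is `f` times list price every cycle.
#'
#' @param k number of paid cycles, `>= 0`.
#' @param f price multiplier in `[0, 1]` (values above 1 rejected).
#' @return a `pap_scheme` list.
#' @export
pap_none <- function() structure(list(scheme = "none"), class = "pap_scheme")

#' @rdname pap_none
#' @export
pap_pay_first_k <- function(k) {
  if (k < 0) stop("k must be >= 0")
  structure(list(scheme = "pay_first_k", value = as.integer(k)),
            class = "pap_scheme")
}

#' @rdname pap_none
#' @export
pap_price_multiplier <- function(f) {
  if (f < 0 || f > 1) stop("price multiplier must lie in [0, 1]")
  structure(list(scheme = "price_multiplier", value = f), class = "pap_scheme")
}

#' Per-arm strategy: drug price, assistance scheme and adverse-event profile
#'
#' @param name strategy label.
#' @param drug_cost_per_cycle USD list price per 28-day cycle.
#' @param pap a `pap_scheme` (default none).
#' @param ae_profile data frame with columns `name`, `risk` (proportion of
#'   patients with the grade >= 3 event), `cost` (USD one-off management
#'   cost) and `disutility` (utility decrement while the event lasts).
#' @return object of class `strategy_spec`.
#' @export
strategy_spec <- function(name, drug_cost_per_cycle, pap = pap_none(),
                          ae_profile = data.frame(name = character(),
                                                  risk = numeric(),
                                                  cost = numeric(),
                                                  disutility = numeric())) {
  stopifnot(drug_cost_per_cycle >= 0, inherits(pap, "pap_scheme"))
  stopifnot(all(ae_profile$risk >= 0 & ae_profile$risk <= 1),
            all(ae_profile$cost >= 0),
            all(ae_profile$disutility >= 0 & ae_profile$disutility <= 1))
  structure(list(name = name, drug_cost_per_cycle = drug_cost_per_cycle,
                 pap = pap, ae_profile = ae_profile),
            class = "strategy_spec")
}

#' Shared economic parameters
#'
#' @param u_pf,u_pd health-state utilities, `0 <= u_pd <= u_pf <= 1`.
#' @param lab_panel_per_visit USD for the laboratory/consult panel of one
#'   follow-up visit (sum of the itemized tests).
#' @param ct_cost USD per CT imaging evaluation.
#' @param admin_cost USD diagnosis/examination charge at model entry.
#' @param subsequent_per_cycle USD subsequent-treatment cost per 4-week
#'   cycle in the progressed state.
#' @param end_of_life USD one-off cost at death.
#' @param wtp willingness-to-pay threshold, USD per QALY.
#' @return object of class `econ_params`.
#' @export
econ_params <- function(u_pf = 0.745, u_pd = 0.678,
                        lab_panel_per_visit = 57.83, ct_cost = 21.74,
                        admin_cost = 1.45, subsequent_per_cycle = 959.16,
                        end_of_life = 1870, wtp = 31499.23) {
  stopifnot(u_pd >= 0, u_pd <= u_pf, u_pf <= 1,
            lab_panel_per_visit >= 0, ct_cost >= 0, admin_cost >= 0,
            subsequent_per_cycle >= 0, end_of_life >= 0, wtp >= 0)
  structure(as.list(environment()), class = "econ_params")
}

# effective per-cycle drug price vector under the PAP scheme
.pap_price <- function(strategy, n_cycles) {
  p <- rep(strategy$drug_cost_per_cycle, n_cycles)
  pap <- strategy$pap
  switch(pap$scheme,
         none = p,
         pay_first_k = ifelse(seq_len(n_cycles) <= pap$value, p, 0),
         price_multiplier = p * pap$value,
         stop("unknown PAP scheme: ", pap$scheme))
}

#' Discounted drug acquisition cost
#'
#' Drug cost accrues only on progression-free occupancy, on the mid-cycle
#' (trapezoid) average when `settings$drug_stop_midcycle` is on (treatment
#' stops at progression), and is reduced by the strategy's PAP scheme.
#'
#' @param trace a [psm_trace()].
#' @param strategy a [strategy_spec()].
#' @param settings settings (default: stored in the trace).
#' @return discounted USD.
#' @export
drug_cost <- function(trace, strategy, settings = trace$settings) {
  n <- trace$n_cycles
  occ <- .occupancy(trace$pf,
                    settings$drug_stop_midcycle || settings$half_cycle_correction)
  sum(occ * .pap_price(strategy, n) * .discount_factors(settings, n))
}

#' Discounted follow-up and administration cost
#'
#' Progression-free: lab panel every 4-week cycle plus CT every second
#' cycle. Progressed: full visit (labs + CT) every second cycle. Diagnosis
#' and examination charged once at entry.
#'
#' @inheritParams drug_cost
#' @param econ an [econ_params()].
#' @return discounted USD.
#' @export
followup_cost <- function(trace, econ, settings = trace$settings) {
  n <- trace$n_cycles
  disc <- .discount_factors(settings, n)
  hc <- settings$half_cycle_correction
  opf <- .occupancy(trace$pf, hc); opd <- .occupancy(trace$pd, hc)
  every2 <- as.numeric(seq_len(n) %% 2 == 0)
  sum(opf * econ$lab_panel_per_visit * disc) +
    sum(opf * econ$ct_cost * every2 * disc) +
    sum(opd * (econ$lab_panel_per_visit + econ$ct_cost) * every2 * disc) +
    econ$admin_cost
}

#' Discounted subsequent-treatment and end-of-life costs
#'
#' Subsequent treatment accrues per 4-week cycle of progressed-state
#' occupancy; the end-of-life cost falls on each cycle's incident deaths.
#'
#' @inheritParams followup_cost
#' @return list with discounted USD `subsequent` and `eol`.
#' @export
downstream_costs <- function(trace, econ, settings = trace$settings) {
  n <- trace$n_cycles
  disc <- .discount_factors(settings, n)
  opd <- .occupancy(trace$pd, settings$half_cycle_correction)
  list(subsequent = sum(opd * econ$subsequent_per_cycle * disc),
       eol = sum(trace$new_deaths * econ$end_of_life * disc))
}

#' One-off adverse-event burden at model entry
#'
#' Expected management cost and QALY loss of the grade >= 3 adverse-event
#' profile, applied once (undiscounted, cycle 0). Each event is assumed to
#' last one cycle.
#'
#' @param strategy a [strategy_spec()].
#' @param settings a [model_settings()] (for the cycle length in years).
#' @return list with `cost` (USD) and `qaly_loss` (QALYs).
#' @export
ae_burden <- function(strategy, settings = model_settings()) {
  ae <- strategy$ae_profile
  cyc_y <- settings$cycle_length_days / 365.25
  list(cost = sum(ae$risk * ae$cost),
       qaly_loss = sum(ae$risk * ae$disutility) * cyc_y)
}

#' Discounted quality-adjusted life years
#'
#' State person-time weighted by the state utilities, minus the one-off
#' adverse-event QALY loss.
#'
#' @inheritParams followup_cost
#' @param strategy a [strategy_spec()] (for the AE profile).
#' @return discounted QALYs.
#' @export
qalys <- function(trace, econ, strategy, settings = trace$settings) {
  n <- trace$n_cycles
  cyc_y <- settings$cycle_length_days / 365.25
  disc <- .discount_factors(settings, n)
  hc <- settings$half_cycle_correction
  q <- sum((.occupancy(trace$pf, hc) * econ$u_pf +
            .occupancy(trace$pd, hc) * econ$u_pd) * cyc_y * disc)
  q - ae_burden(strategy, settings)$qaly_loss
}

#' Full discounted cost/QALY breakdown for one strategy arm
#'
#' @inheritParams qalys
#' @return object of class `econ_result`: cost components (`cost_drug`,
#'   `cost_followup`, `cost_subsequent`, `cost_ae`, `cost_eol`),
#'   `cost_total`, `qaly_total`, `ly_total`, `ly_pf`, `ly_pd`.
#' @export
arm_result <- function(trace, strategy, econ, settings = trace$settings) {
  ds <- downstream_costs(trace, econ, settings)
  ae <- ae_burden(strategy, settings)
  ly <- life_years(trace, settings)
  out <- list(
    strategy = strategy$name,
    cost_drug = drug_cost(trace, strategy, settings),
    cost_followup = followup_cost(trace, econ, settings),
    cost_subsequent = ds$subsequent,
    cost_ae = ae$cost,
    cost_eol = ds$eol,
    qaly_total = qalys(trace, econ, strategy, settings),
    ly_total = ly$total, ly_pf = ly$pf, ly_pd = ly$pd
  )
  out$cost_total <- out$cost_drug + out$cost_followup + out$cost_subsequent +
    out$cost_ae + out$cost_eol
  stopifnot(out$qaly_total <= out$ly_total * econ$u_pf + 1e-9)
  structure(out, class = "econ_result")
}

#' @export
print.econ_result <- function(x, ...) {
  cat(sprintf("<econ_result> %s: cost US$%.2f (drug %.2f, follow-up %.2f, subsequent %.2f, AE %.2f, end-of-life %.2f)\n",
              x$strategy, x$cost_total, x$cost_drug, x$cost_followup,
              x$cost_subsequent, x$cost_ae, x$cost_eol))
  cat(sprintf("  QALYs %.3f, LYs %.3f (PF %.3f, PD %.3f)\n",
              x$qaly_total, x$ly_total, x$ly_pf, x$ly_pd))
  invisible(x)
}

#' Incremental comparison of two strategy arms
#'
#' @param a,b [arm_result()] objects (intervention `a` vs comparator `b`).
#' @param wtp willingness-to-pay threshold, USD/QALY.
#' @return object of class `ce_comparison`: `delta_cost`, `delta_qaly`,
#'   `icer` (USD/QALY; `NA` when `delta_qaly = 0`), `dominance`
#'   (`"dominant"`, `"dominated"` or `""`), and `nmb` at `wtp`.
#' @export
compare_strategies <- function(a, b, wtp = 31499.23) {
  dc <- a$cost_total - b$cost_total
  dq <- a$qaly_total - b$qaly_total
  dominance <- if (dq > 0 && dc <= 0) "dominant"
               else if (dq < 0 && dc >= 0) "dominated" else ""
  icer <- if (dq != 0) dc / dq else NA_real_
  structure(list(a = a$strategy, b = b$strategy,
                 delta_cost = dc, delta_qaly = dq,
                 icer = icer, dominance = dominance,
                 wtp = wtp, nmb = wtp * dq - dc),
            class = "ce_comparison")
}

#' @export
print.ce_comparison <- function(x, ...) {
  lab <- if (nzchar(x$dominance)) sprintf(" (%s)", x$dominance) else ""
  cat(sprintf("<ce_comparison> %s vs %s: dCost US$%.2f, dQALY %.4f, ICER %s%s, NMB at US$%.0f/QALY = US$%.2f\n",
              x$a, x$b, x$delta_cost, x$delta_qaly,
              if (is.na(x$icer)) "undefined" else sprintf("US$%.2f/QALY", x$icer),
              lab, x$wtp, x$nmb))
  invisible(x)
}
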