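base_eval <- function() evaluate_model(base_config())

test_that("per-cycle drug prices rebuild from unit prices", {
  # donafenib: 0.2 g twice daily = 4 x 100 mg/day at US$29.95
  expect_lt(abs(per_cycle_price(29.95, 4) - 3354.38), 0.05)
  # sorafenib: 0.4 g twice daily = 4 x 200 mg/day at the VBP price US$3.31
  expect_lt(abs(per_cycle_price(3.31, 4) - 370.36), 0.40)
  # branded sorafenib
  expect_equal(per_cycle_price(13.77, 4), 1542.24)
})

test_that("the follow-up lab panel is the sum of the itemized tests", {
  cfg <- base_config()
  lab <- sum(param_values(cfg)[cfg$followup$lab_items])
  expect_equal(lab, 57.83, tolerance = 1e-9)
})

test_that("PAP schemes behave as documented", {
  cfg <- base_config()
  tr <- cfg$survival$donafenib
  st <- cfg$settings
  trace <- build_trace(tr$os, tr$pfs, st)
  mk <- function(pap) strategy_spec("don", 3354.38, pap)
  expect_equal(drug_cost(trace, mk(pap_pay_first_k(0))), 0)
  expect_equal(drug_cost(trace, mk(pap_price_multiplier(1))),
               drug_cost(trace, mk(pap_none())))
  expect_equal(drug_cost(trace, mk(pap_price_multiplier(0.5))),
               0.5 * drug_cost(trace, mk(pap_none())))
  # paying k+1 cycles always costs more than k
  costs <- vapply(0:5, function(k) drug_cost(trace, mk(pap_pay_first_k(k))),
                  numeric(1))
  expect_true(all(diff(costs) > 0))
  expect_error(pap_pay_first_k(-1))
  expect_error(pap_price_multiplier(1.2))
})

test_that("cost accrual is linear in unit costs and blind to utilities", {
  cfg <- base_config()
  ev <- base_eval()
  # doubling the CT price raises follow-up cost by exactly the CT mass
  ct <- param_values(cfg)[["fu_ct"]]
  ev2 <- evaluate_model(cfg, overrides = c(fu_ct = 2 * ct))
  for (arm in names(ev$arms)) {
    d1 <- ev$arms[[arm]]; d2 <- ev2$arms[[arm]]
    ct_mass <- d2$cost_followup - d1$cost_followup
    expect_gt(ct_mass, 0)
    ev3 <- evaluate_model(cfg, overrides = c(fu_ct = 3 * ct))
    expect_equal(ev3$arms[[arm]]$cost_followup - d2$cost_followup, ct_mass,
                 tolerance = 1e-9)
    expect_equal(d1$qaly_total, d2$qaly_total)  # QALYs untouched by costs
  }
  # utilities leave costs untouched
  ev4 <- evaluate_model(cfg, overrides = c(u_pf = 0.76, u_pd = 0.70))
  expect_equal(ev4$arms[[1]]$cost_total, ev$arms[[1]]$cost_total)
  expect_false(ev4$arms[[1]]$qaly_total == ev$arms[[1]]$qaly_total)
  # every unit cost moves total cost in the same direction
  for (nm in c("subsequent_tx", "end_of_life", "admin", "fu_liver")) {
    up <- evaluate_model(cfg, overrides = stats::setNames(
      param_values(cfg)[[nm]] * 1.5, nm))
    expect_gt(up$arms[[2]]$cost_total, ev$arms[[2]]$cost_total)
  }
})

test_that("end-of-life cost follows incident deaths", {
  econ <- econ_params()
  st <- model_settings()
  immortal <- build_trace(surv_model("km", list(time = 200, surv = 1)),
                          surv_model("km", list(time = 200, surv = 1)), st)
  expect_equal(downstream_costs(immortal, econ, st)$eol, 0)
  # everyone dies within the first cycle
  dead1 <- build_trace(surv_model("km", list(time = 0.5, surv = 0)),
                       surv_model("km", list(time = 0.5, surv = 0)), st)
  disc1 <- (1 + 0.05)^(-(0.5 * 28 / 365.25))
  expect_equal(downstream_costs(dead1, econ, st)$eol, 1870 * disc1)
})

test_that("adverse-event burden is the risk-weighted one-off sum", {
  st <- model_settings()
  don_ae <- data.frame(name = c("hfsr", "htn"),
                       risk = c(0.057, 0.090),
                       cost = c(12.97, 35.46),
                       disutility = c(0.116, 0.012))
  b <- ae_burden(strategy_spec("don", 3354.38, ae_profile = don_ae), st)
  expect_equal(b$cost, 0.057 * 12.97 + 0.090 * 35.46)  # ~ 3.93 USD
  expect_equal(b$cost, 3.93, tolerance = 1e-2)
  expect_equal(b$qaly_loss,
               (0.057 * 0.116 + 0.090 * 0.012) * 28 / 365.25)
  empty <- ae_burden(strategy_spec("x", 0), st)
  expect_equal(unlist(empty), c(cost = 0, qaly_loss = 0))
  # zero-disutility events (elevated AST) contribute cost only
  ast <- data.frame(name = "ast", risk = 0.048, cost = 56.54, disutility = 0)
  b2 <- ae_burden(strategy_spec("sor", 370.36, ae_profile = ast), st)
  expect_gt(b2$cost, 0)
  expect_equal(b2$qaly_loss, 0)
})

test_that("QALYs collapse to life years under unit utilities and no adverse events", {
  cfg <- base_config()
  st <- cfg$settings
  tr <- build_trace(cfg$survival$sorafenib$os, cfg$survival$sorafenib$pfs, st)
  econ1 <- econ_params(u_pf = 1, u_pd = 1)
  q <- qalys(tr, econ1, strategy_spec("s", 370.36), st)
  expect_equal(q, life_years(tr, st)$total, tolerance = 1e-12)
})

test_that("arm results are internally consistent", {
  ev <- base_eval()
  for (a in ev$arms) {
    expect_equal(a$cost_total,
                 a$cost_drug + a$cost_followup + a$cost_subsequent +
                   a$cost_ae + a$cost_eol, tolerance = 1e-9)
    expect_lte(a$qaly_total, a$ly_total * 0.745 + 1e-9)
    expect_equal(a$ly_total, a$ly_pf + a$ly_pd, tolerance = 1e-12)
  }
})

test_that("incremental comparison computes ICER, dominance and NMB", {
  mk <- function(cost, qaly)
    structure(list(strategy = "x", cost_total = cost, qaly_total = qaly),
              class = "econ_result")
  cmp <- compare_strategies(mk(22330.23, 1.045), mk(14775.92, 0.861),
                            wtp = 31499.23)
  expect_equal(cmp$icer, (22330.23 - 14775.92) / (1.045 - 0.861))
  expect_equal(cmp$icer, 41056, tolerance = 1e-4)  # 3-dp-rounded QALY inputs
  expect_equal(cmp$nmb, 31499.23 * cmp$delta_qaly - cmp$delta_cost)
  expect_equal(compare_strategies(mk(100, 2), mk(100, 1))$dominance, "dominant")
  expect_equal(compare_strategies(mk(200, 1), mk(100, 2))$dominance, "dominated")
  tie <- compare_strategies(mk(150, 1), mk(100, 1))
  expect_true(is.na(tie$icer))
  expect_equal(tie$nmb, -50)
  self <- compare_strategies(mk(100, 1), mk(100, 1))
  expect_true(is.na(self$icer))
  expect_equal(self$delta_cost, 0)
})

test_that("doubling the discount rate weakly decreases cost and QALY totals", {
  cfg <- base_config()
  ev5 <- evaluate_model(cfg)
  ev8 <- evaluate_model(cfg, overrides = c(discount_rate = 0.08))
  for (arm in names(ev5$arms)) {
    expect_lte(ev8$arms[[arm]]$cost_total, ev5$arms[[arm]]$cost_total)
    expect_lte(ev8$arms[[arm]]$qaly_total, ev5$arms[[arm]]$qaly_total)
  }
})

test_that("the packaged configuration validates and rejects unknown overrides", {
  cfg <- base_config()
  expect_s3_class(validate_config(cfg), "psm_config")
  vals <- param_values(cfg)
  expect_equal(vals[["drug_sorafenib"]], 370.36)
  expect_equal(vals[["u_pd"]], 0.678)
  expect_error(evaluate_model(cfg, overrides = c(nonsense = 1)), "unknown")
  # results table carries both arms and the comparison
  tab <- results_table(evaluate_model(cfg))
  expect_equal(nrow(tab), 2)
  expect_false(is.na(tab$icer[1]))
})
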