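test_that("distributional sampling reproduces the configured means", {
  cfg <- base_config()
  set.seed(41)
  # moment-matched beta for the PF utility keeps its published mean
  u <- sample_param(cfg$parameters["u_pf", ], 10000)
  expect_lt(abs(mean(u) - 0.745), 0.001)
  # end-of-life gamma: moment-matched shape x scale = 1870
  eol <- sample_param(cfg$parameters["end_of_life", ], 10000)
  expect_lt(abs(mean(eol) - 1870), 3 * 190.82 / sqrt(10000) + 2)
  # constants pass through untouched
  expect_equal(sample_param(cfg$parameters["discount_rate", ], 5), rep(0.05, 5))
  expect_error(sample_param(list(value = 1, se = 0.1, dist = "cauchy")),
               "unsupported")
})

test_that("every sampled parameter's mean lands within 3 Monte Carlo SEs of its base value", {
  cfg <- base_config()
  p <- cfg$parameters
  set.seed(42)
  for (nm in p$name[p$dist != "constant" & !is.na(p$se)]) {
    x <- sample_param(p[nm, ], 10000)
    mc_se <- sd(x) / sqrt(length(x))
    expect_lt(abs(mean(x) - p[nm, "value"]), 3 * mc_se + 1e-9,
              label = paste("mean of", nm))
  }
})

test_that("Cholesky survival sampling honours the covariance", {
  est <- c(meanlog = 2.5, sdlog = log(1.0))
  mk_fit <- function(V) structure(list(family = "lognormal", est_t = est,
                                       covariance = V), class = "surv_fit")
  # zero covariance: always the point estimate
  m <- sample_survival_params(mk_fit(diag(0, 2)), 1)
  expect_equal(unlist(m$params), c(meanlog = 2.5, sdlog = 1.0))
  # diagonal covariance: empirical SDs match within 3%
  set.seed(43)
  V <- diag(c(0.02^2, 0.05^2))
  draws <- sample_survival_params(mk_fit(V), 10000)
  mls <- vapply(draws, function(d) d$params$meanlog, numeric(1))
  sds <- vapply(draws, function(d) log(d$params$sdlog), numeric(1))
  expect_lt(abs(sd(mls) / 0.02 - 1), 0.03)
  expect_lt(abs(sd(sds) / 0.05 - 1), 0.03)
  # correlated draws: empirical correlation tracks rho = 0.8
  rho <- 0.8
  V <- matrix(c(0.03^2, rho * 0.03 * 0.04, rho * 0.03 * 0.04, 0.04^2), 2)
  draws <- sample_survival_params(mk_fit(V), 10000)
  mls <- vapply(draws, function(d) d$params$meanlog, numeric(1))
  sds <- vapply(draws, function(d) log(d$params$sdlog), numeric(1))
  expect_lt(abs(cor(mls, sds) - rho), 0.03)
  # a non-PSD covariance is repaired with a warning
  bad <- matrix(c(1, 2, 2, 1), 2)
  expect_warning(sample_survival_params(mk_fit(bad), 1), "positive")
})

test_that("a fully degenerate PSA reproduces the base case bit for bit", {
  cfg <- base_config()
  base <- evaluate_model(cfg)
  psa <- run_psa(constant_config(cfg), n_iter = 3, seed = 7,
                 survival_fits = degenerate_fits(cfg))
  expect_equal(psa$n_failed, 0)
  expect_identical(unique(psa$draws$delta_cost), base$comparison$delta_cost)
  expect_identical(unique(psa$draws$delta_qaly), base$comparison$delta_qaly)
})

test_that("the PSA is reproducible per seed and failures are counted, not hidden", {
  cfg <- base_config()
  fits <- cached_psa_fits(cfg)
  p1 <- run_psa(cfg, n_iter = 40, seed = 5, survival_fits = fits)
  p2 <- run_psa(cfg, n_iter = 40, seed = 5, survival_fits = fits)
  expect_identical(p1$draws, p2$draws)
  p3 <- run_psa(cfg, n_iter = 40, seed = 6, survival_fits = fits)
  expect_false(identical(p1$draws$delta_cost, p3$draws$delta_cost))
  expect_equal(nrow(p1$draws) + p1$n_failed, 40)
})

test_that("the CEAC is a proper probability curve with the right limits", {
  cfg <- base_config()
  psa <- run_psa(cfg, n_iter = 200, seed = 11,
                 survival_fits = cached_psa_fits(cfg))
  cc <- ceac(psa, wtp_grid = c(0, 1e4, 3e4, 1e7))
  expect_true(all(cc$prob_cost_effective >= 0 & cc$prob_cost_effective <= 1))
  expect_equal(cc$prob_cost_effective[1], mean(psa$draws$delta_cost < 0))
  expect_equal(cc$prob_cost_effective[4], mean(psa$draws$delta_qaly > 0),
               tolerance = 0.01)
  # restricted to draws that gain QALYs, the curve is nondecreasing
  pos <- psa$draws[psa$draws$delta_qaly > 0, ]
  cc2 <- ceac(pos, wtp_grid = seq(0, 6e4, by = 500))
  expect_true(all(diff(cc2$prob_cost_effective) >= 0))
})

test_that("the tornado ranks parameter influence and is order-invariant", {
  cfg <- base_config()
  tor <- dsa_oneway(cfg)
  # drug acquisition costs of both arms among the widest bars
  expect_true(all(c("drug_sorafenib", "drug_donafenib") %in% tor$param[1:3]))
  expect_true(all(diff(tor$span) <= 1e-9))
  # order of the input list does not change the result
  p <- cfg$parameters
  nm <- p$name[!is.na(p$min) & !is.na(p$max)]
  tor2 <- dsa_oneway(cfg, params = rev(nm))
  expect_equal(tor2[order(tor2$param), c("param", "span")],
               tor[order(tor$param), c("param", "span")],
               ignore_attr = TRUE)
  # a pinned parameter has zero span and ranks last
  cfg2 <- cfg
  cfg2$parameters["fu_ecg", c("min", "max")] <- 3.19
  tor3 <- dsa_oneway(cfg2)
  expect_equal(tor3$span[tor3$param == "fu_ecg"], 0)
  expect_equal(tor3$param[nrow(tor3)], "fu_ecg")
  # the discount rate swept over its full printed range stays finite
  dr <- tor[tor$param == "discount_rate", ]
  expect_true(is.finite(dr$icer_low) && is.finite(dr$icer_high))
})

test_that("scenario analyses swap exactly one assumption", {
  cfg <- base_config()
  base <- evaluate_model(cfg)
  # branded sorafenib: only the sorafenib drug cost moves
  sb <- run_scenario(cfg, "branded_sorafenib")
  expect_equal(sb$arms$sorafenib$cost_total - base$arms$sorafenib$cost_total,
               sb$arms$sorafenib$cost_drug - base$arms$sorafenib$cost_drug,
               tolerance = 1e-9)
  expect_identical(sb$arms$donafenib$cost_total, base$arms$donafenib$cost_total)
  expect_identical(sb$arms$sorafenib$qaly_total, base$arms$sorafenib$qaly_total)
  # KM-only: truncation at last follow-up strictly reduces QALYs
  km_models <- lapply(cfg$survival, function(arm) lapply(arm, function(m) {
    tt <- seq(0.5, 18, by = 0.5)
    surv_model("km", list(time = tt, surv = survival_at(m, tt)))
  }))
  ka <- run_scenario(cfg, "km_only", km_models = km_models)
  for (arm in names(ka$arms)) {
    expect_lt(ka$arms[[arm]]$qaly_total, base$arms[[arm]]$qaly_total)
    expect_lt(ka$arms[[arm]]$ly_total, base$arms[[arm]]$ly_total)
  }
  expect_error(run_scenario(cfg, "km_only"), "step-function")
})
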