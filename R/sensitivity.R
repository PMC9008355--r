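#' Sample one model parameter from its assigned distribution
#'
#' Cost parameters follow a gamma distribution, utilities and adverse-event
#' risks a beta distribution, the rest are constants. Gamma parameters are
#' re-derived by moment matching from the base value and SE
#' (`shape = (value/se)^2`, `scale = se^2/value`), and beta parameters
#' likewise (`nu = value(1-value)/se^2 - 1`, `alpha = value nu`,
#' `beta = (1-value) nu`): the printed shape pairs are rounded to two
#' decimals, which distorts the implied means of small-valued items by up
#' to several percent (see [validate_config()]); moment matching keeps
#' every sampling mean exactly on its base value. The printed pairs are
#' retained in the configuration and cross-checked at load time. A row
#' whose SE is missing is treated as constant.
#'
#' @param spec one row of `config$parameters` (data frame row or list).
#' @param n number of draws.
#' @return numeric vector of `n` draws; uses the current RNG stream, so
#'   seed with [set.seed()] for reproducibility.
#' @export
sample_param <- function(spec, n = 1) {
  spec <- as.list(spec)
  v <- spec$value; se <- spec$se
  if (is.null(se) || is.na(se) || se == 0 || spec$dist == "constant")
    return(rep(v, n))
  switch(spec$dist,
    gamma = {
      shape <- (v / se)^2
      stats::rgamma(n, shape = shape, scale = se^2 / v)
    },
    beta = {
      nu <- v * (1 - v) / se^2 - 1
      stats::rbeta(n, v * nu, (1 - v) * nu)
    },
    stop("unsupported distribution: ", spec$dist)
  )
}

# transform natural-scale parameters to the estimation scale used by the fits
.to_est_scale <- function(family, params) {
  vapply(names(params), function(p)
    if (.is_log_par(family, p)) log(params[[p]]) else params[[p]],
    numeric(1))
}

.from_est_scale <- function(family, est) {
  out <- lapply(names(est), function(p)
    if (.is_log_par(family, p)) exp(est[[p]]) else est[[p]])
  stats::setNames(out, names(est))
}

#' Draw correlated survival parameters via Cholesky decomposition
#'
#' Draws `theta = theta_hat + L z` on the estimation scale, where `L` is
#' the Cholesky factor of the fit's covariance matrix and `z` standard
#' normal, then back-transforms; log-scale estimation enforces positivity.
#' `L` is the symmetric square root from the eigendecomposition, so a
#' singular (even all-zero) covariance degenerates cleanly to the point
#' estimate; a covariance that is not positive semidefinite is repaired by
#' clipping negative eigenvalues at zero (with a warning).
#'
#' @param fit a `surv_fit` (only `family`, `est_t`, `covariance` are used).
#' @param n number of draws.
#' @return for `n = 1` a [surv_model()]; otherwise a list of them.
#' @export
sample_survival_params <- function(fit, n = 1) {
  fam <- fit$family
  est <- fit$est_t
  V <- fit$covariance
  k <- length(est)
  eg <- eigen(V, symmetric = TRUE)
  if (any(eg$values < -1e-8 * max(abs(eg$values), 1)))
    warning("covariance not positive semidefinite; clipping eigenvalues at zero")
  L <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), k) %*% t(eg$vectors)
  z <- matrix(stats::rnorm(n * k), n, k)
  draws <- sweep(z %*% L, 2, est, "+")
  colnames(draws) <- names(est)
  models <- lapply(seq_len(n), function(i) {
    p <- .from_est_scale(fam, as.list(draws[i, ]))
    suppressWarnings(surv_model(fam, p))
  })
  if (n == 1) models[[1]] else models
}

#' Survival-parameter uncertainty inputs for the PSA
#'
#' The trial publication reports point estimates but no covariance for the
#' fitted survival parameters. The default PSA input therefore refits each
#' configured family to synthetic individual-patient data simulated from
#' the configured model itself (arm sizes and administrative censoring from
#' `config$psa`), keeps that fit's covariance, and re-centres the estimate
#' on the configured parameters. Seeded and deterministic.
#'
#' @param config a `psm_config`.
#' @param seed integer seed.
#' @return nested list `fits[[arm]][[endpoint]]` of `surv_fit` objects.
#' @export
psa_survival_fits <- function(config, seed = 1) {
  set.seed(seed)
  cen <- config$psa$censor
  lapply(stats::setNames(nm = names(config$survival)), function(arm) {
    n <- config$psa$arm_n[[arm]]
    lapply(config$survival[[arm]], function(model) {
      ipd <- simulate_ipd(n, model,
                          censoring = list(type = cen$type, min = cen$min,
                                           max = cen$max, rate = cen$rate))
      fit <- fit_parametric(ipd, model$family)
      if (!isTRUE(fit$converged))
        stop("covariance refit failed for the PSA: ", fit$message)
      fit$est_t <- .to_est_scale(model$family, model$params)
      fit$model <- model
      fit
    })
  })
}

#' Probabilistic sensitivity analysis
#'
#' Samples every distributional parameter ([sample_param()]) and all
#' survival parameters (Cholesky, [sample_survival_params()]; per-curve
#' blocks — OS and PFS are fitted independently), rebuilds both arms per
#' iteration, and records incremental cost and QALYs. Failed iterations
#' (e.g. sampled utilities out of order) are excluded with a reported
#' count, never silently dropped.
#'
#' @param config a `psm_config`.
#' @param n_iter Monte Carlo iterations (default 1000).
#' @param seed integer seed; the draw sequence is reproducible per
#'   `(seed, n_iter)`.
#' @param survival_fits optional override of [psa_survival_fits()] output
#'   (e.g. fits to real reconstructed IPD).
#' @return object of class `psa_result`: `draws` (data frame with per-arm
#'   cost/QALY and deltas per iteration), `param_draws` matrix,
#'   `n_failed`, `seed`.
#' @export
run_psa <- function(config, n_iter = 1000, seed = 1, survival_fits = NULL) {
  if (is.null(survival_fits)) survival_fits <- psa_survival_fits(config, seed)
  set.seed(seed + 1L)
  pars <- config$parameters
  sampled <- pars$name[pars$dist != "constant" & !is.na(pars$se)]
  pmat <- vapply(sampled, function(nm) sample_param(pars[nm, ], n_iter),
                 numeric(n_iter))
  surv_draws <- lapply(survival_fits, function(arm)
    lapply(arm, function(fit) sample_survival_params(fit, n_iter)))
  arm_names <- names(config$survival)
  rows <- vector("list", n_iter)
  n_failed <- 0L
  for (i in seq_len(n_iter)) {
    surv_i <- lapply(surv_draws, function(arm)
      list(os = arm$os[[i]], pfs = arm$pfs[[i]]))
    res <- tryCatch(
      evaluate_model(config, overrides = pmat[i, ], survival = surv_i),
      error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    a <- res$arms[[1]]; b <- res$arms[[2]]
    rows[[i]] <- data.frame(iter = i,
                            cost_a = a$cost_total, qaly_a = a$qaly_total,
                            cost_b = b$cost_total, qaly_b = b$qaly_total,
                            delta_cost = a$cost_total - b$cost_total,
                            delta_qaly = a$qaly_total - b$qaly_total)
  }
  draws <- do.call(rbind, rows)
  if (n_failed > 0)
    message(sprintf("PSA: %d of %d iterations failed and were excluded",
                    n_failed, n_iter))
  structure(list(draws = draws, param_draws = pmat, n_failed = n_failed,
                 seed = seed, arms = arm_names),
            class = "psa_result")
}

#' @export
print.psa_result <- function(x, ...) {
  q <- mean(x$draws$delta_qaly > 0 & x$draws$delta_cost > 0)
  cat(sprintf("<psa_result> %d draws (%d failed); %.1f%% in the costlier-and-more-effective quadrant\n",
              nrow(x$draws), x$n_failed, 100 * q))
  invisible(x)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the intervention
#' is cost-effective: the fraction of PSA draws with positive net monetary
#' benefit, `lambda * dQALY - dCost > 0`.
#'
#' @param psa a `psa_result` (or its `draws` data frame).
#' @param wtp_grid increasing USD/QALY grid (default 0 to 60,000 in steps
#'   of 500, covering 1-3x per-capita GDP).
#' @return data frame `(wtp, prob_cost_effective)`.
#' @export
ceac <- function(psa, wtp_grid = seq(0, 60000, by = 500)) {
  draws <- if (inherits(psa, "psa_result")) psa$draws else psa
  stopifnot(nrow(draws) > 0, !is.unsorted(wtp_grid))
  prob <- vapply(wtp_grid, function(l)
    mean(l * draws$delta_qaly - draws$delta_cost > 0), numeric(1))
  data.frame(wtp = wtp_grid, prob_cost_effective = prob)
}

#' One-way deterministic sensitivity analysis (tornado)
#'
#' Reruns the full deterministic model with each parameter set to its lower
#' and upper bound (95% CI where reported, otherwise +-20% of base), all
#' others at base. Distribution shapes are re-derived from the perturbed
#' value with the SE held fixed (moment matching happens at sampling time,
#' so this is automatic).
#'
#' @param config a `psm_config`.
#' @param params parameter names to vary; default all rows with bounds.
#' @return data frame `(param, label, low, high, icer_base, icer_low,
#'   icer_high, span)` sorted by `span` descending (ties keep input order).
#' @export
dsa_oneway <- function(config, params = NULL) {
  p <- config$parameters
  if (is.null(params)) params <- p$name[!is.na(p$min) & !is.na(p$max)]
  if (any(p[params, "min"] > p[params, "max"])) stop("dsa_min > dsa_max")
  base_icer <- evaluate_model(config)$comparison$icer
  rows <- lapply(params, function(nm) {
    lo <- p[nm, "min"]; hi <- p[nm, "max"]
    icer_lo <- evaluate_model(config, overrides = stats::setNames(lo, nm))$comparison$icer
    icer_hi <- evaluate_model(config, overrides = stats::setNames(hi, nm))$comparison$icer
    data.frame(param = nm, label = p[nm, "label"], low = lo, high = hi,
               icer_base = base_icer, icer_low = icer_lo, icer_high = icer_hi,
               span = abs(icer_hi - icer_lo))
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$span), ]
  rownames(out) <- NULL
  out
}

#' Scenario analyses
#'
#' `"km_only"` replaces the parametric survival inputs with empirical KM
#' step functions truncated at last follow-up (no extrapolation); requires
#' `km_models`. `"branded_sorafenib"` rebuilds the sorafenib per-cycle
#' price from the branded unit price (US$13.77 per 200 mg at 0.4 g twice
#' daily), everything else unchanged.
#'
#' @param config a `psm_config`.
#' @param scenario `"km_only"` or `"branded_sorafenib"`.
#' @param km_models for `"km_only"`: nested list `[[arm]][[endpoint]]` of
#'   `"km"`-family [surv_model()] objects.
#' @return an [evaluate_model()] result.
#' @export
run_scenario <- function(config, scenario = c("km_only", "branded_sorafenib"),
                         km_models = NULL) {
  scenario <- match.arg(scenario)
  if (scenario == "branded_sorafenib") {
    sc <- config$strategies$sorafenib
    price <- per_cycle_price(sc$branded_unit_price,
                             sc$unit_price$units_per_day,
                             config$settings$cycle_length_days)
    evaluate_model(config, overrides = c(drug_sorafenib = price))
  } else {
    if (is.null(km_models))
      stop("the KM-only scenario needs empirical step-function survival inputs")
    tmax <- min(vapply(km_models, function(arm)
      min(vapply(arm, function(m) max(m$params$time), numeric(1))), numeric(1)))
    evaluate_model(config, survival = km_models, max_time_months = tmax)
  }
}
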