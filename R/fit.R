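#' Fit a parametric survival family to right-censored data by maximum likelihood
#'
#' Maximizes the right-censored log-likelihood
#' \eqn{\sum_{events} \log f(t_i) + \sum_{censored} \log S(t_i)} via
#' [flexsurv::flexsurvreg()], whose data-driven initial values make the fit
#' deterministic. The covariance matrix is the inverse observed information
#' at the optimum, on the estimation scale (log scale for positive
#' parameters, identity for `meanlog` and the Gompertz shape).
#'
#' @param ipd data frame with columns `time` (months, >= 0) and `event`
#'   (1 = event observed, 0 = right-censored).
#' @param family one of [SURV_FAMILIES].
#' @return object of class `surv_fit`: fields `model` ([surv_model()]),
#'   `loglik`, `aic` (`2k - 2 loglik`), `bic` (`k log n - 2 loglik`), `n`,
#'   `n_events`, `est_t` (estimation-scale estimates), `covariance`
#'   (estimation scale), `converged`, and `message` on failure.
#' @export
fit_parametric <- function(ipd, family) {
  family <- match.arg(family, SURV_FAMILIES)
  stopifnot(is.data.frame(ipd), all(c("time", "event") %in% names(ipd)))
  if (any(!is.finite(ipd$time)) || any(ipd$time < 0))
    stop("times must be finite and nonnegative")
  if (!all(ipd$event %in% c(0, 1))) stop("event must be 0/1")
  if (nrow(ipd) < 10) stop("need at least 10 observations")
  if (sum(ipd$event) < 2)
    stop("need at least 2 observed events (all-censored data cannot identify a survival model)")
  dist <- c(exponential = "exp", weibull = "weibull", gompertz = "gompertz",
            loglogistic = "llogis", lognormal = "lnorm", gamma = "gamma")[[family]]
  # flexsurv rejects t = 0 event times; nudge to the smallest positive step
  dat <- ipd
  dat$time <- pmax(dat$time, 1e-6)
  fit <- tryCatch(
    flexsurv::flexsurvreg(survival::Surv(time, event) ~ 1, data = dat,
                          dist = dist),
    error = function(e) e, warning = function(w) w
  )
  if (inherits(fit, "condition")) {
    return(structure(list(family = family, converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "surv_fit"))
  }
  pars <- .family_pars[[family]]
  est <- as.list(fit$res[pars, "est"])
  names(est) <- pars
  k <- length(pars)
  n <- fit$N
  ll <- fit$loglik
  model <- suppressWarnings(surv_model(family, est))
  structure(list(
    model = model, family = family,
    loglik = ll, aic = 2 * k - 2 * ll, bic = k * log(n) - 2 * ll,
    n = n, n_events = fit$events, k = k,
    est_t = stats::setNames(fit$res.t[pars, "est"], pars),
    covariance = fit$cov,
    converged = TRUE, message = NULL
  ), class = "surv_fit")
}

#' Fit all six parametric families
#'
#' @inheritParams fit_parametric
#' @param families subset of [SURV_FAMILIES] (default: all six).
#' @return named list of `surv_fit` objects (non-converged fits included,
#'   flagged with `converged = FALSE`).
#' @export
fit_all_families <- function(ipd, families = SURV_FAMILIES) {
  stats::setNames(lapply(families, function(f) fit_parametric(ipd, f)), families)
}

#' Select the best fit by information criteria
#'
#' Minimum AIC wins; ties broken by minimum BIC, then by the fixed order of
#' [SURV_FAMILIES].
#'
#' @param fits list of `surv_fit` objects.
#' @return the selected `surv_fit`.
#' @export
select_best <- function(fits) {
  if (inherits(fits, "surv_fit")) fits <- list(fits)
  ok <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(ok)) stop("no converged fits to select from")
  aic <- vapply(ok, `[[`, numeric(1), "aic")
  bic <- vapply(ok, `[[`, numeric(1), "bic")
  fam <- vapply(ok, `[[`, character(1), "family")
  ord <- order(aic, bic, match(fam, SURV_FAMILIES))
  ok[[ord[1]]]
}

#' @export
print.surv_fit <- function(x, ...) {
  if (!isTRUE(x$converged)) {
    cat(sprintf("<surv_fit> %s: DID NOT CONVERGE (%s)\n", x$family, x$message))
    return(invisible(x))
  }
  cat(sprintf("<surv_fit> %s  n = %d (%d events)  loglik = %.2f  AIC = %.2f  BIC = %.2f\n",
              x$family, x$n, x$n_events, x$loglik, x$aic, x$bic))
  print(x$model)
  invisible(x)
}

#' Serialize a fitted (or constructed) model to the configuration layout
#'
#' @param x a `surv_fit` or `surv_model`.
#' @return plain list `list(family=, params=)` as stored under the
#'   `survival:` block of the model configuration.
#' @export
as_config_survival <- function(x) {
  if (inherits(x, "surv_fit")) x <- x$model
  stopifnot(inherits(x, "surv_model"))
  list(family = x$family, params = lapply(x$params, as.numeric))
}
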