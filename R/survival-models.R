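#' Parametric survival families supported by the model
#'
#' The fixed family order also breaks AIC/BIC ties in [select_best()].
#' @export
SURV_FAMILIES <- c("exponential", "weibull", "gompertz", "loglogistic",
                   "lognormal", "gamma")

# natural-scale parameter names per family (flexsurv's naming)
.family_pars <- list(
  exponential = "rate",
  weibull     = c("shape", "scale"),
  gompertz    = c("shape", "rate"),
  loglogistic = c("shape", "scale"),
  lognormal   = c("meanlog", "sdlog"),
  gamma       = c("shape", "rate")
)

# parameters estimated on the log scale (positivity); all others on identity
.log_pars <- c("rate", "scale", "sdlog",
               "shape_weibull", "shape_loglogistic", "shape_gamma")

.is_log_par <- function(family, par) {
  if (par %in% c("rate", "scale", "sdlog")) return(TRUE)
  if (par == "shape") return(family %in% c("weibull", "loglogistic", "gamma"))
  FALSE
}

#' Construct a parametric (or empirical step) survival model
#'
#' Time is measured in model months: one month equals one 28-day treatment
#' cycle on the scale the survival parameters were estimated on (see the
#' methods vignette for why this, and not a 30.4375-day calendar month, is
#' the default time axis).
#'
#' @param family one of `SURV_FAMILIES`, or `"km"` for an empirical
#'   step-function model with `params = list(time=, surv=)`.
#' @param params named list of natural-scale parameters. Naming follows
#'   flexsurv: `exponential(rate)`, `weibull(shape, scale)`,
#'   `gompertz(shape, rate)`, `loglogistic(shape, scale)` with
#'   `S(t) = 1/(1 + (t/scale)^shape)`, `lognormal(meanlog, sdlog)` with
#'   `S(t) = 1 - pnorm((log t - meanlog)/sdlog)`, `gamma(shape, rate)`.
#' @return an object of class `surv_model`.
#' @examples
#' m <- surv_model("lognormal", list(meanlog = 2.5312, sdlog = 1.0034))
#' survival_at(m, c(0, 12, 24))
#' @export
surv_model <- function(family, params) {
  family <- match.arg(family, c(SURV_FAMILIES, "km"))
  params <- as.list(params)
  if (family == "km") {
    stopifnot(is.numeric(params$time), is.numeric(params$surv),
              length(params$time) == length(params$surv))
    if (is.unsorted(params$time)) stop("km model times must be sorted")
    if (any(params$surv < 0 | params$surv > 1)) stop("km survival outside [0,1]")
  } else {
    need <- .family_pars[[family]]
    if (!all(need %in% names(params)))
      stop(sprintf("family '%s' needs parameters: %s", family,
                   paste(need, collapse = ", ")))
    for (p in need) {
      v <- params[[p]]
      if (!is.finite(v)) stop(sprintf("parameter '%s' not finite", p))
      # meanlog may be any real; Gompertz shape may be negative (flagged)
      if (!(p == "meanlog" || (family == "gompertz" && p == "shape")) && v <= 0)
        stop(sprintf("parameter '%s' must be > 0 (got %g)", p, v))
    }
    params <- params[need]
  }
  out <- structure(list(family = family, params = params), class = "surv_model")
  out$improper <- (family == "gompertz" && params$shape < 0)
  if (isTRUE(out$improper))
    warning("Gompertz model with negative shape: S(Inf) > 0 (improper); ",
            "the model horizon bounds its effect")
  out
}

#' @export
print.surv_model <- function(x, ...) {
  if (x$family == "km") {
    cat(sprintf("<surv_model> empirical KM step function, %d steps, last t = %g months\n",
                length(x$params$time), max(x$params$time)))
  } else {
    cat(sprintf("<surv_model> %s(%s)\n", x$family,
                paste(sprintf("%s = %.4f", names(x$params), unlist(x$params)),
                      collapse = ", ")))
    cat(sprintf("  median survival: %.3f months\n", median_survival(x)))
  }
  invisible(x)
}

#' Survival function S(t)
#'
#' @param model a [surv_model()].
#' @param t nonnegative times in model months; vectorized.
#' @return S(t) in `[0, 1]`.
#' @export
survival_at <- function(model, t) {
  stopifnot(inherits(model, "surv_model"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  p <- model$params
  s <- switch(model$family,
    exponential = stats::pexp(t, rate = p$rate, lower.tail = FALSE),
    weibull     = stats::pweibull(t, shape = p$shape, scale = p$scale,
                                  lower.tail = FALSE),
    gompertz    = flexsurv::pgompertz(t, shape = p$shape, rate = p$rate,
                                      lower.tail = FALSE),
    loglogistic = flexsurv::pllogis(t, shape = p$shape, scale = p$scale,
                                    lower.tail = FALSE),
    lognormal   = stats::plnorm(t, meanlog = p$meanlog, sdlog = p$sdlog,
                                lower.tail = FALSE),
    gamma       = stats::pgamma(t, shape = p$shape, rate = p$rate,
                                lower.tail = FALSE),
    km          = stats::approx(x = c(0, p$time), y = c(1, p$surv), xout = t,
                                method = "constant", f = 0, rule = 2,
                                ties = "ordered")$y
  )
  pmin(pmax(s, 0), 1)
}

#' Median survival time
#'
#' Closed forms where available (`exp(meanlog)` for the lognormal, `scale`
#' for the log-logistic, `log(2)/rate` for the exponential, ...); bisection
#' to relative tolerance 1e-8 for the Gompertz. Returns `Inf` for an
#' improper model whose survival plateau exceeds 0.5.
#'
#' @param model a [surv_model()].
#' @return smallest t (months) with `S(t) <= 0.5`.
#' @export
median_survival <- function(model) {
  p <- model$params
  switch(model$family,
    exponential = log(2) / p$rate,
    weibull     = p$scale * log(2)^(1 / p$shape),
    lognormal   = exp(p$meanlog),
    loglogistic = p$scale,
    gamma       = stats::qgamma(0.5, shape = p$shape, rate = p$rate),
    gompertz    = .median_bisect(model),
    km          = {
      idx <- which(p$surv <= 0.5)
      if (!length(idx)) Inf else p$time[min(idx)]
    }
  )
}

.median_bisect <- function(model) {
  f <- function(t) survival_at(model, t) - 0.5
  hi <- 1
  while (f(hi) > 0 && hi < 1e8) hi <- hi * 2
  if (f(hi) > 0) return(Inf)  # improper plateau above 0.5
  stats::uniroot(f, c(0, hi), tol = 1e-10)$root
}
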