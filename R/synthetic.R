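#' Simulate individual-patient data from a known survival model
#'
#' Event times are drawn from the generating model; an independent
#' censoring time is drawn from the censoring mechanism; the observed time
#' is the minimum, with the event flag set accordingly.
#'
#' @param n cohort size (`>= 2`); the trial randomized about 334 patients
#'   per arm, the package default elsewhere.
#' @param model a parametric [surv_model()] (the truth).
#' @param censoring list: `list(type = "none")`,
#'   `list(type = "uniform", min =, max =)` (administrative censoring in
#'   months), or `list(type = "exponential", rate =)` (per-month dropout
#'   hazard).
#' @param seed optional integer; when given, the cohort is bit-reproducible.
#' @return data frame `(time, event)`.
#' @export
simulate_ipd <- function(n, model, censoring = list(type = "none"),
                         seed = NULL) {
  stopifnot(n >= 2, inherits(model, "surv_model"), model$family != "km")
  if (!is.null(seed)) set.seed(seed)
  p <- model$params
  ev <- switch(model$family,
    exponential = stats::rexp(n, rate = p$rate),
    weibull     = stats::rweibull(n, shape = p$shape, scale = p$scale),
    gompertz    = flexsurv::rgompertz(n, shape = p$shape, rate = p$rate),
    loglogistic = flexsurv::rllogis(n, shape = p$shape, scale = p$scale),
    lognormal   = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    gamma       = stats::rgamma(n, shape = p$shape, rate = p$rate)
  )
  cn <- switch(censoring$type,
    none        = rep(Inf, n),
    uniform     = stats::runif(n, censoring$min, censoring$max),
    exponential = stats::rexp(n, rate = censoring$rate),
    stop("unknown censoring type: ", censoring$type)
  )
  data.frame(time = pmin(ev, cn), event = as.integer(ev <= cn))
}

#' Emulate curve digitization of a KM figure
#'
#' Computes the exact product-limit curve of the cohort, samples it at a
#' regular grid plus every drop location, perturbs the sampled survival by
#' uniform jitter mimicking digitizer error, and tabulates numbers at risk
#' at the requested figure times. Output feeds straight into
#' [guyot_reconstruct()].
#'
#' @param ipd data frame `(time, event)`.
#' @param grid_step grid spacing in months (default 1).
#' @param at_risk_times times of the at-risk row (default every 3 months,
#'   the typical trial-figure cadence).
#' @param jitter half-width of the uniform digitization error on survival
#'   probabilities (default 0.002; 0 gives lossless digitization).
#' @param include_total_events attach the cohort's true event count to the
#'   output (as a figure caption would report it)?
#' @param seed optional integer seed for the jitter.
#' @return a [digitized_km()].
#' @export
digitize_km <- function(ipd, grid_step = 1, at_risk_times = NULL,
                        jitter = 0.002, include_total_events = FALSE,
                        seed = NULL) {
  stopifnot(nrow(ipd) > 0, grid_step > 0)
  if (!is.null(seed)) set.seed(seed)
  km <- km_estimate(ipd)
  tmax <- max(ipd$time)
  tt <- sort(unique(c(seq(0, tmax, by = grid_step), km$time[km$time <= tmax])))
  ss <- km_at(km, tt)
  if (jitter > 0) {
    ss <- ss + stats::runif(length(ss), -jitter, jitter)
    ss[tt == 0] <- 1
  }
  if (is.null(at_risk_times)) at_risk_times <- seq(0, tmax, by = 3)
  nar <- vapply(at_risk_times, function(a) sum(ipd$time >= a), integer(1))
  keep <- nar > 0
  digitized_km(data.frame(time = tt, survival = ss),
               data.frame(time = at_risk_times[keep], n_at_risk = nar[keep]),
               total_events = if (include_total_events) sum(ipd$event) else NULL)
}
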