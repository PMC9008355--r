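# Hand-written densities used as independent quadrature oracles for the
# survival functions (deliberately not the library p/d functions).
oracle_density <- function(family, p) {
  switch(family,
    exponential = function(t) p$rate * exp(-p$rate * t),
    weibull = function(t)
      (p$shape / p$scale) * (t / p$scale)^(p$shape - 1) *
        exp(-(t / p$scale)^p$shape),
    gompertz = function(t)
      p$rate * exp(p$shape * t) *
        exp(-(p$rate / p$shape) * (exp(p$shape * t) - 1)),
    loglogistic = function(t)
      (p$shape / p$scale) * (t / p$scale)^(p$shape - 1) /
        (1 + (t / p$scale)^p$shape)^2,
    lognormal = function(t)
      stats::dnorm((log(t) - p$meanlog) / p$sdlog) / (p$sdlog * t),
    gamma = function(t)
      p$rate^p$shape * t^(p$shape - 1) * exp(-p$rate * t) / gamma(p$shape)
  )
}

oracle_survival <- function(family, p, t) {
  if (t == 0) return(1)
  1 - stats::integrate(oracle_density(family, p), 0, t,
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# random admissible parameter sets per family (moderate scales, months)
random_params <- function(family) {
  switch(family,
    exponential = list(rate = runif(1, 0.02, 0.5)),
    weibull     = list(shape = runif(1, 0.6, 3), scale = runif(1, 3, 30)),
    gompertz    = list(shape = runif(1, 0.01, 0.2), rate = runif(1, 0.01, 0.2)),
    loglogistic = list(shape = runif(1, 0.8, 3), scale = runif(1, 3, 20)),
    lognormal   = list(meanlog = runif(1, 0.5, 3), sdlog = runif(1, 0.4, 1.5)),
    gamma       = list(shape = runif(1, 0.6, 3), rate = runif(1, 0.05, 0.5))
  )
}

# cached PSA survival-parameter fits for the packaged config (refit once)
.psa_fit_cache <- new.env(parent = emptyenv())
cached_psa_fits <- function(config) {
  if (is.null(.psa_fit_cache$fits))
    .psa_fit_cache$fits <- psa_survival_fits(config, seed = 99)
  .psa_fit_cache$fits
}

# survival fits with degenerate (zero) covariance at the configured estimates
degenerate_fits <- function(config) {
  lapply(config$survival, function(arm)
    lapply(arm, function(model) {
      est <- psmcea:::.to_est_scale(model$family, model$params)
      structure(list(family = model$family, model = model, est_t = est,
                     covariance = diag(0, length(est)), converged = TRUE),
                class = "surv_fit")
    }))
}

# a config where every sampled parameter is degenerate (SE dropped)
constant_config <- function(config) {
  config$parameters$se <- NA_real_
  config
}
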