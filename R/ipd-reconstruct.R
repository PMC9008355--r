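#' Clean raw digitizer output into a monotone survival curve
#'
#' Sorts by time, clamps survival into `[0, 1]`, enforces a nonincreasing
#' curve by isotonic clipping (each value capped at its predecessor — drop
#' locations, which carry the event signal, are preserved; no smoothing),
#' collapses duplicate times to their lowest survival, and prepends the
#' origin `(0, 1)` if absent.
#'
#' @param coords data frame with columns `time` (months) and `survival`.
#' @return cleaned data frame `(time, survival)` starting at `(0, 1)`.
#' @export
preprocess_km <- function(coords) {
  stopifnot(is.data.frame(coords), all(c("time", "survival") %in% names(coords)))
  if (!nrow(coords)) stop("empty coordinate list")
  if (any(coords$survival < -0.05 | coords$survival > 1.05))
    stop("survival values outside [-0.05, 1.05]: beyond digitizer noise")
  if (any(coords$time < 0)) stop("negative times")
  coords <- coords[order(coords$time), c("time", "survival")]
  coords$survival <- pmin(pmax(coords$survival, 0), 1)
  coords <- stats::aggregate(survival ~ time, data = coords, FUN = min)
  if (coords$time[1] > 0)
    coords <- rbind(data.frame(time = 0, survival = 1), coords)
  coords$survival[1] <- 1
  coords$survival <- cummin(coords$survival)
  rownames(coords) <- NULL
  coords
}

#' Bundle digitized KM coordinates with a numbers-at-risk table
#'
#' @param coords data frame `(time, survival)`; run through
#'   [preprocess_km()] unless `preprocess = FALSE`.
#' @param at_risk data frame `(time, n_at_risk)`, counts nonincreasing.
#' @param total_events optional total event count reported alongside the
#'   curve; when given, the reconstruction's final interval is reallocated
#'   to match it.
#' @param preprocess run [preprocess_km()] on `coords` first.
#' @return object of class `digitized_km`.
#' @export
digitized_km <- function(coords, at_risk, total_events = NULL,
                         preprocess = TRUE) {
  if (preprocess) coords <- preprocess_km(coords)
  stopifnot(is.data.frame(at_risk), all(c("time", "n_at_risk") %in% names(at_risk)))
  at_risk <- at_risk[order(at_risk$time), c("time", "n_at_risk")]
  if (any(diff(at_risk$n_at_risk) > 0))
    stop("numbers at risk must be nonincreasing over time")
  if (nrow(at_risk) < 2) stop("need at least 2 at-risk intervals")
  keep <- at_risk$time <= max(coords$time)
  if (!all(keep)) {
    warning("dropping at-risk entries beyond the last digitized coordinate")
    at_risk <- at_risk[keep, ]
  }
  if (nrow(at_risk) < 2) stop("coordinates must span the at-risk times")
  structure(list(coords = coords, at_risk = at_risk,
                 total_events = total_events),
            class = "digitized_km")
}

#' @export
print.digitized_km <- function(x, ...) {
  cat(sprintf("<digitized_km> %d coordinates to %g months; n at risk %d -> %d over %d intervals\n",
              nrow(x$coords), max(x$coords$time),
              x$at_risk$n_at_risk[1], utils::tail(x$at_risk$n_at_risk, 1),
              nrow(x$at_risk)))
  invisible(x)
}

#' Reconstruct pseudo individual-patient data from a digitized KM curve
#'
#' The iterative algorithm of Guyot and colleagues: within each
#' numbers-at-risk interval, censorings are assumed uniformly spread and
#' their count is adjusted until the implied number still at risk matches
#' the published count at the start of the next interval; event counts at
#' each digitized drop follow from the product-limit relation. Events are
#' placed at the coordinate (left edge of the drop); patients still at risk
#' after the last coordinate are administratively censored there. Fully
#' deterministic.
#'
#' @param km a [digitized_km()].
#' @return object of class `reconstructed_ipd`: `ipd` (data frame
#'   `time`/`event`), `n_events`, `n_censored`, and the implied KM fit
#'   diagnostics.
#' @export
guyot_reconstruct <- function(km) {
  stopifnot(inherits(km, "digitized_km"))
  tS <- km$coords$time
  S  <- km$coords$survival
  trisk <- km$at_risk$time
  nrisk <- km$at_risk$n_at_risk
  K <- length(tS); I <- length(trisk)
  lower <- vapply(trisk, function(tt) min(which(tS >= tt)), integer(1))
  nhat <- numeric(K + 1)
  cen <- integer(K); d <- integer(K)
  KM.hat <- rep(1, K)
  cen_times <- vector("list", I)
  last_surv <- 1; last_n <- nrisk[1]

  recompute <- function(from, to, n_start, cenv, last0, KMlast0) {
    # product-limit pass over coordinates from..to given censor placement
    nh <- numeric(K + 1); nh[from] <- n_start
    dd <- integer(K); KMh <- KM.hat
    last <- last0; KMlast <- KMlast0
    for (k in from:to) {
      if (k == 1) {
        dd[k] <- 0; KMh[k] <- 1
      } else {
        dd[k] <- round(nh[k] * (1 - S[k] / KMlast))
        dd[k] <- max(0L, min(dd[k], nh[k]))
        KMh[k] <- KMlast * (1 - dd[k] / max(nh[k], 1))
      }
      nh[k + 1] <- nh[k] - dd[k] - cenv[k]
      if (nh[k + 1] < 0) { cenv[k] <- cenv[k] + nh[k + 1]; nh[k + 1] <- 0 }
      if (dd[k] > 0) { last <- k; KMlast <- KMh[k] }
    }
    list(nh = nh, d = dd, KMh = KMh, cen = cenv, last = last, KMlast = KMlast)
  }

  last_idx <- 1; KMlast <- 1
  for (i in seq_len(I)) {
    from <- lower[i]
    to   <- if (i < I) lower[i + 1] - 1 else K
    if (to < from) { nhat[if (i < I) lower[i + 1] else K + 1] <- last_n; next }
    span_end_t <- if (i < I) tS[lower[i + 1]] else tS[K]
    if (i < I) {
      ncensor <- round(last_n * S[lower[i + 1]] / max(S[from], 1e-12)) - nrisk[i + 1]
    } else {
      prev_cen <- sum(vapply(cen_times, length, integer(1)))
      prev_span <- max(tS[from] - tS[1], 1e-12)
      ncensor <- if (prev_cen > 0)
        min(round(prev_cen * (tS[K] - tS[from]) / prev_span), last_n) else 0
    }
    iter <- 0
    repeat {
      iter <- iter + 1
      ncensor <- max(0L, as.integer(ncensor))
      cenv <- integer(K)
      ct <- numeric(0)
      if (ncensor > 0) {
        ct <- tS[from] + seq_len(ncensor) * (span_end_t - tS[from]) / (ncensor + 1)
        # bin censor times into coordinate gaps [tS[k], tS[k+1])
        brks <- c(tS[from:to], span_end_t)
        if (length(brks) >= 2) {
          idx <- findInterval(ct, brks, rightmost.closed = TRUE)
          idx <- pmin(pmax(idx, 1L), to - from + 1L)
          tab <- tabulate(idx, nbins = to - from + 1L)
          cenv[from:to] <- tab
        } else cenv[from] <- ncensor
      }
      res <- recompute(from, to, last_n, cenv, last_idx, KMlast)
      if (i == I) break
      gap <- res$nh[lower[i + 1]] - nrisk[i + 1]
      if (gap == 0 || (gap < 0 && ncensor == 0) || iter > 100) break
      ncensor <- ncensor + gap
    }
    d[from:to] <- res$d[from:to]
    cen[from:to] <- res$cen[from:to]
    KM.hat[from:to] <- res$KMh[from:to]
    cen_times[[i]] <- ct[seq_len(sum(res$cen[from:to]))]
    last_idx <- res$last; KMlast <- res$KMlast
    last_n <- res$nh[if (i < I) lower[i + 1] else K + 1]
    if (i < I && last_n < nrisk[i + 1]) nrisk[i + 1] <- last_n
  }

  # final-interval reallocation toward a reported total event count
  if (!is.null(km$total_events)) {
    diff <- km$total_events - sum(d)
    k <- K
    while (diff != 0 && k > 1) {
      if (diff > 0) {
        room <- max(0, cen[k])  # convert censorings to events at same coordinate
        take <- min(diff, room)
        d[k] <- d[k] + take; cen[k] <- cen[k] - take; diff <- diff - take
      } else {
        take <- min(-diff, d[k])
        d[k] <- d[k] - take; cen[k] <- cen[k] + take; diff <- diff + take
      }
      k <- k - 1
    }
  }

  ev_times <- rep(tS, times = d)
  cn_times <- unlist(cen_times, use.names = FALSE)
  n_used <- length(ev_times) + length(cn_times)
  n_left <- nrisk[1] - n_used
  admin <- rep(tS[K], max(0, n_left))  # still at risk at last follow-up
  ipd <- data.frame(
    time = c(ev_times, cn_times, admin),
    event = c(rep(1L, length(ev_times)), rep(0L, length(cn_times) + length(admin)))
  )
  ipd <- ipd[order(ipd$time, -ipd$event), ]
  rownames(ipd) <- NULL
  structure(list(ipd = ipd,
                 n = nrow(ipd),
                 n_events = sum(ipd$event),
                 n_censored = sum(ipd$event == 0)),
            class = "reconstructed_ipd")
}

#' @export
print.reconstructed_ipd <- function(x, ...) {
  cat(sprintf("<reconstructed_ipd> %d patients: %d events, %d censored\n",
              x$n, x$n_events, x$n_censored))
  invisible(x)
}

#' Kaplan-Meier (product-limit) estimate of an IPD sample
#'
#' Thin wrapper over [survival::survfit()].
#'
#' @param ipd data frame `time`/`event`, or a `reconstructed_ipd`.
#' @return data frame `(time, survival)`: the step function evaluated at
#'   and after each event/censoring time, starting from `S(0) = 1`.
#' @export
km_estimate <- function(ipd) {
  if (inherits(ipd, "reconstructed_ipd")) ipd <- ipd$ipd
  stopifnot(nrow(ipd) >= 1)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  data.frame(time = c(0, sf$time), survival = c(1, sf$surv))
}

#' Evaluate a KM step function at arbitrary times
#' @param km data frame `(time, survival)` from [km_estimate()].
#' @param t times (months).
#' @return survival probabilities.
#' @export
km_at <- function(km, t) {
  stats::approx(km$time, km$survival, xout = t, method = "constant",
                f = 0, rule = 2, ties = "ordered")$y
}

#' Read / write digitized curves and IPD as delimited text
#'
#' `read_digitized_km` expects two CSV files: coordinates with header
#' `time,survival` and an at-risk table with header `time,n_at_risk`.
#' `write_ipd`/`read_ipd` use header `time,event` (months, 0/1).
#'
#' @param coords_path,at_risk_path CSV paths for the digitized curve.
#' @param ... passed to [digitized_km()].
#' @return `read_digitized_km`: a [digitized_km()] object.
#' @export
read_digitized_km <- function(coords_path, at_risk_path, ...) {
  digitized_km(utils::read.csv(coords_path), utils::read.csv(at_risk_path), ...)
}

#' @rdname read_digitized_km
#' @param ipd IPD data frame (or `reconstructed_ipd`).
#' @param path output CSV path.
#' @export
write_ipd <- function(ipd, path) {
  if (inherits(ipd, "reconstructed_ipd")) ipd <- ipd$ipd
  utils::write.csv(ipd[, c("time", "event")], path, row.names = FALSE)
}

#' @rdname read_digitized_km
#' @export
read_ipd <- function(path) {
  ipd <- utils::read.csv(path)
  stopifnot(all(c("time", "event") %in% names(ipd)))
  ipd
}
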