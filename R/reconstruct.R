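# Pseudo-IPD reconstruction from a digitized KM curve plus number-at-risk
# table: the iterative interval-allocation scheme of Guyot-type algorithms,
# with an event-first tie convention and midpoint censoring times.

#' Step-function evaluator for a digitized curve
#'
#' @param curve a `cua_curve`.
#' @return function of time (months) returning the right-continuous
#'   product-limit step value.
#' @export
curve_survival <- function(curve) {
  stopifnot(inherits(curve, "cua_curve"))
  tt <- curve$time; ss <- curve$survival
  function(t) {
    if (any(t < 0)) stop_input("time must be non-negative")
    if (length(tt) == 1) return(rep(1, length(t)))
    stats::approx(tt, ss, xout = t, method = "constant", f = 0, rule = 2)$y
  }
}

#' Kaplan-Meier estimate of individual patient data
#'
#' Product-limit step function sampled at the observed event times (validation
#' refit for the reconstruction round trip). Computed with
#' [survival::survfit()].
#'
#' @param ipd a single-arm `cua_ipd`.
#' @return a [digitized_curve()] ((0, 1) anchor plus one point per distinct
#'   event time).
#' @export
kaplan_meier <- function(ipd) {
  ipd <- as_cua_ipd(ipd)
  if (length(unique(ipd$arm)) > 1)
    stop_input("kaplan_meier expects a single arm; subset first")
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = ipd)
  keep <- sf$n.event > 0
  if (!any(keep)) return(digitized_curve(0, 1))
  digitized_curve(sf$time[keep], pmax(sf$surv[keep], 0))
}

# Allocate events/censorings over the coordinates of one risk interval.
# Returns local d/cen vectors, the KM value carried out of the interval and
# the implied number at risk entering the next interval.
.alloc_interval <- function(ncen, lo, up, t_end, t.S, S, n_start, km_in,
                            final = FALSE) {
  ks <- lo:up
  cen_bins <- integer(length(ks))
  n_bins <- if (final) up - lo else up - lo + 1  # final: no bin after last coord
  if (ncen > 0 && n_bins > 0) {
    cen.t <- t.S[lo] + seq_len(ncen) * (t_end - t.S[lo]) / (ncen + 1)
    edges <- c(t.S[lo:(lo + n_bins - 1)], t_end)
    idx <- findInterval(cen.t, edges, rightmost.closed = TRUE,
                        all.inside = TRUE)
    for (j in idx) cen_bins[j] <- cen_bins[j] + 1L
  }
  d_loc <- cen_loc <- integer(length(ks))
  nh <- n_start
  kmp <- km_in
  for (m in seq_along(ks)) {
    k <- ks[m]
    dd <- 0L
    if (k > 1 && nh > 0 && kmp > 0) {
      dd <- as.integer(round(nh * (1 - S[k] / kmp)))
      dd <- max(0L, min(dd, nh))
      if (dd > 0) kmp <- kmp * (1 - dd / nh)
    }
    cc <- if (m <= n_bins) min(cen_bins[m], nh - dd) else 0L
    d_loc[m] <- dd
    cen_loc[m] <- as.integer(cc)
    nh <- nh - dd - cc
  }
  list(d = d_loc, cen = cen_loc, km_out = kmp, nh_next = nh)
}

#' Reconstruct pseudo individual patient data from a digitized curve
#'
#' Iteratively allocates event and censoring counts within each inter-risk-time
#' interval so that (i) the product-limit estimate of the output tracks the
#' input coordinates and (ii) the implied number at risk matches the table.
#' Censoring is assumed uniform within each interval; ties between an event
#' and a risk-table time count the event first. The algorithm is deterministic.
#'
#' @param curve a [digitized_curve()].
#' @param risk a [risk_table()]; its time-0 entry fixes the sample size.
#' @param total_events optional reported arm-level event total; when supplied,
#'   censoring in the final interval is rebalanced until the reconstructed
#'   event count matches it as closely as the integer allocation permits.
#' @param arm arm label attached to the output records.
#' @return a `cua_ipd` with attribute `qc`: a per-interval data.frame of
#'   allocated events/censorings and implied vs tabulated at-risk counts.
#' @export
reconstruct_ipd <- function(curve, risk, total_events = NULL, arm = "arm") {
  stopifnot(inherits(curve, "cua_curve"), inherits(risk, "cua_risktable"))
  trisk <- risk$time
  nrisk <- as.integer(risk$n_risk)
  if (max(trisk) > max(curve$time) + 1e-9) {
    keep <- trisk <= max(curve$time) + 1e-9
    if (sum(keep) < 2)
      stop_input("curve does not span the risk-table interval")
    trisk <- trisk[keep]; nrisk <- nrisk[keep]
  }
  if (length(trisk) < 2) stop_input("risk table needs at least 2 usable entries")

  sfun <- curve_survival(curve)
  t.S <- sort(unique(c(curve$time, trisk)))  # step-exact augmentation
  S <- sfun(t.S)
  n.t <- length(t.S)
  nint <- length(trisk)
  lower <- vapply(trisk, function(x) which(t.S >= x - 1e-9)[1], integer(1))
  upper <- c(lower[-1] - 1L, n.t)

  d <- cen <- integer(n.t)
  ncensor <- integer(nint)
  implied <- integer(nint)
  implied[1] <- nrisk[1]
  km_in <- 1
  nh_carry <- nrisk[1]

  commit <- function(res, lo, up) {
    d[lo:up] <<- res$d
    cen[lo:up] <<- res$cen
  }

  for (i in seq_len(nint - 1)) {
    lo <- lower[i]; up <- upper[i]
    t_end <- t.S[lower[i + 1]]
    s_lo <- S[lo]; s_next <- S[lower[i + 1]]
    ncen <- if (s_lo > 0) round(nh_carry * s_next / s_lo - nrisk[i + 1]) else 0
    tried <- integer(0)
    best <- NULL; best_gap <- Inf
    for (iter in 1:60) {
      ncen <- max(0L, as.integer(ncen))
      res <- .alloc_interval(ncen, lo, up, t_end, t.S, S, nh_carry, km_in)
      gap <- res$nh_next - nrisk[i + 1]
      if (abs(gap) < best_gap) { best <- res; best_gap <- abs(gap); ncensor[i] <- ncen }
      if (gap == 0 || (gap < 0 && ncen == 0) || (ncen + gap) %in% tried) break
      tried <- c(tried, ncen)
      ncen <- ncen + gap
    }
    res <- best
    shortfall <- nrisk[i + 1] - res$nh_next
    if (shortfall > 2)
      stop_input("risk table inconsistent with curve at interval ", i,
                 ": implied at-risk ", res$nh_next, " vs table ", nrisk[i + 1],
                 " (reconstruction infeasible)")
    commit(res, lo, up)
    km_in <- res$km_out
    nh_carry <- res$nh_next          # continue from implied count
    implied[i + 1] <- res$nh_next
  }

  # final interval: extrapolate the earlier censoring rate (Guyot convention)
  lo <- lower[nint]; up <- upper[nint]
  t_end <- t.S[n.t]
  run_last <- function(ncen_last) {
    .alloc_interval(ncen_last, lo, up, t_end, t.S, S, nh_carry, km_in,
                    final = TRUE)
  }
  ncen_last <- if (nint > 1 && t.S[lo] > t.S[1] && t_end > t.S[lo]) {
    min(round(sum(ncensor[seq_len(nint - 1)]) *
                (t_end - t.S[lo]) / (t.S[lo] - t.S[1])), nh_carry)
  } else 0
  ncen_last <- max(0L, as.integer(ncen_last))
  res <- run_last(ncen_last)
  if (!is.null(total_events)) {
    total_events <- as.integer(total_events)
    events_now <- function(r) sum(d[seq_len(lo - 1)]) + sum(r$d)
    for (iter in 1:500) {
      cur <- events_now(res)
      if (cur > total_events && ncen_last < nh_carry) {
        ncen_last <- ncen_last + 1L
      } else if (cur < total_events && ncen_last > 0) {
        ncen_last <- ncen_last - 1L
      } else break
      res <- run_last(ncen_last)
    }
  }
  commit(res, lo, up)
  leftover <- res$nh_next  # still at risk past the last coordinate

  # assemble records: events at coordinates, censorings at bin midpoints
  times <- events <- numeric(0)
  for (k in seq_len(n.t)) {
    if (d[k] > 0) {
      times <- c(times, rep(t.S[k], d[k]))
      events <- c(events, rep(1, d[k]))
    }
    if (cen[k] > 0) {
      tc <- if (k < n.t) (t.S[k] + t.S[k + 1]) / 2 else t.S[n.t]
      times <- c(times, rep(tc, cen[k]))
      events <- c(events, rep(0, cen[k]))
    }
  }
  if (leftover > 0) {
    times <- c(times, rep(t.S[n.t], leftover))
    events <- c(events, rep(0, leftover))
  }
  ipd <- as_cua_ipd(data.frame(time = times, event = as.integer(events),
                               arm = arm, stringsAsFactors = FALSE))
  qc <- data.frame(
    interval = seq_len(nint),
    t_start = trisk,
    events = vapply(seq_len(nint), function(i) sum(d[lower[i]:upper[i]]), integer(1)),
    censorings = vapply(seq_len(nint), function(i) sum(cen[lower[i]:upper[i]]), integer(1)),
    implied_risk = c(implied[1], implied[-1]),
    table_risk = nrisk)
  qc$censorings[nint] <- qc$censorings[nint] + leftover
  attr(ipd, "qc") <- qc
  ipd
}

#' Write the reconstruction QC report
#'
#' @param ipd output of [reconstruct_ipd()].
#' @param path CSV destination.
#' @return invisibly `path`.
#' @export
write_reconstruction_qc <- function(ipd, path) {
  qc <- attr(ipd, "qc")
  if (is.null(qc)) stop_input("no QC attribute; was this reconstructed?")
  utils::write.csv(qc, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
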