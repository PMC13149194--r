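# Discounted cost and QALY accounting over a cohort trace, incremental
# comparison (ICER, dominance) and price-threshold search.
#
# Accrual conventions: payoffs for cycle k (k = 1..K) accrue on start-of-cycle
# occupancy (row k-1 of the trace) and are discounted continuously at the
# cycle-start time, (1 + r)^(-t/365.25) with t in days. Adverse events occur
# once, in cycle 1. An optional half-cycle (trapezoid) correction averages
# start- and end-of-cycle occupancy instead.

#' Continuous-time discount factor
#'
#' @param t_days time in days from model start.
#' @param rate annual discount rate (>= 0).
#' @return `(1 + rate)^(-t_days/365.25)`.
#' @export
discount_factor <- function(t_days, rate) {
  if (rate < 0) stop_input("discount rate must be non-negative")
  (1 + rate)^(-t_days / DAYS_PER_YEAR)
}

#' Patient-assistance-program payment indicator
#'
#' The "2 cycles paid, 2 cycles free" scheme: a repeating paid, paid, free,
#' free pattern starting paid at cycle 1.
#'
#' @param k cycle index (1-based).
#' @param scheme_on if `FALSE` every cycle is paid.
#' @return 0/1 vector.
#' @export
pap_pay <- function(k, scheme_on = TRUE) {
  if (any(k < 1)) stop_input("cycle index must be >= 1")
  if (!scheme_on) return(rep(1, length(k)))
  as.numeric((k - 1) %% 4 < 2)
}

# Occupancy used for cycle payoffs: start-of-cycle rows, or the start/end
# average under the half-cycle correction.
.cycle_occ <- function(trace, half_cycle) {
  K <- nrow(trace$occupancy) - 1
  occ0 <- trace$occupancy[1:K, , drop = FALSE]
  if (!half_cycle) return(occ0)
  (occ0 + trace$occupancy[2:(K + 1), , drop = FALSE]) / 2
}

#' Discounted costs for one arm
#'
#' Components: drug acquisition while progression-free (price factor and the
#' assistance-program pattern apply to the experimental arm only), one-off
#' adverse-event management in cycle 1, routine monitoring in both alive
#' states, post-progression therapy / best supportive care while in PD
#' (mixed by the post-progression treatment probability; per-cycle by
#' default, one-off at PD entry if `posttx_mode = "at_entry"`), and
#' end-of-life care on each cycle's new deaths.
#'
#' @param trace a `cua_trace`.
#' @param inputs a `cua_inputs`.
#' @param arm `"experimental"` or `"control"`.
#' @return total discounted cost (USD) with a `breakdown` attribute; the
#'   components are checked to sum to the total.
#' @export
arm_costs <- function(trace, inputs, arm = c("experimental", "control")) {
  arm <- match.arg(arm)
  stopifnot(inherits(trace, "cua_trace"), inherits(inputs, "cua_inputs"))
  K <- nrow(trace$occupancy) - 1
  k <- seq_len(K)
  occ <- .cycle_occ(trace, inputs$half_cycle)
  disc <- discount_factor(trace$t_days[k], inputs$discount_annual)

  f <- if (arm == "experimental") inputs$price_factor else 1
  pay <- if (arm == "experimental") pap_pay(k, inputs$pap) else rep(1, K)
  drug <- sum(f * inputs$drug_cost_cycle[[arm]] * pay * occ[, "pfs"] * disc)

  risks <- inputs$ae[[paste0("risk_", arm)]]
  ae <- sum(risks * inputs$ae$cost) * trace$occupancy[1, "pfs"] * disc[1]

  mon_cycle <- vapply(k, function(kk)
    sum(inputs$monitor_costs * (kk %% inputs$monitor_every == 0)), numeric(1))
  monitoring <- sum(mon_cycle * (occ[, "pfs"] + occ[, "pd"]) * disc)

  pd_unit <- inputs$posttx_prob[[arm]] * inputs$posttx_cost[[arm]] +
    (1 - inputs$posttx_prob[[arm]]) * inputs$bsc_cost
  pd_state <- if (identical(inputs$posttx_mode, "at_entry"))
    sum(pd_unit * trace$new_pd * disc)
  else
    sum(pd_unit * occ[, "pd"] * disc)

  eol <- sum(inputs$eol_cost * trace$new_deaths * disc)

  breakdown <- c(drug = unname(drug), adverse_events = unname(ae),
                 monitoring = unname(monitoring),
                 post_progression = unname(pd_state),
                 end_of_life = unname(eol))
  structure(sum(breakdown), breakdown = breakdown)
}

#' Discounted QALYs for one arm
#'
#' Per cycle, `(u_pfs*PFS + u_pd*PD) * 28/365.25` on start-of-cycle occupancy
#' (dead contributes zero), discounted at the cycle-start time, minus a
#' one-time first-cycle adverse-event disutility of one cycle's duration.
#'
#' @inheritParams arm_costs
#' @return total discounted QALYs.
#' @export
arm_qalys <- function(trace, inputs, arm = c("experimental", "control")) {
  arm <- match.arg(arm)
  stopifnot(inherits(trace, "cua_trace"), inherits(inputs, "cua_inputs"))
  K <- nrow(trace$occupancy) - 1
  k <- seq_len(K)
  occ <- .cycle_occ(trace, inputs$half_cycle)
  disc <- discount_factor(trace$t_days[k], inputs$discount_annual)
  cycle_years <- diff(trace$t_days)[1] / DAYS_PER_YEAR
  q <- sum((inputs$u_pfs * occ[, "pfs"] + inputs$u_pd * occ[, "pd"]) *
             cycle_years * disc)
  risks <- inputs$ae[[paste0("risk_", arm)]]
  ae_dec <- sum(risks * inputs$ae$disutility) * cycle_years *
    trace$occupancy[1, "pfs"] * disc[1]
  unname(q - ae_dec)
}

#' Incremental cost-effectiveness comparison
#'
#' @param exp_arm,ctrl_arm either numeric `c(cost, qaly)` vectors or lists
#'   with elements `cost` and `qaly` for the experimental and control
#'   strategies, computed under an identical horizon and discount rate.
#' @param labels strategy labels.
#' @return object of class `cua_cea`: per-arm totals, `delta_cost`,
#'   `delta_qaly`, `icer` (USD/QALY, `NA` when dominance applies) and a
#'   dominance label among `icer`, `dominant`, `dominated`, `equivalent`.
#' @export
cea_compare <- function(exp_arm, ctrl_arm,
                        labels = c("experimental", "control")) {
  as_ce <- function(x) {
    if (is.numeric(x) && length(x) == 2)
      return(list(cost = unname(x[1]), qaly = unname(x[2])))
    if (is.list(x) && all(c("cost", "qaly") %in% names(x)))
      return(list(cost = unname(as.numeric(x$cost)),
                  qaly = unname(as.numeric(x$qaly))))
    stop_input("arm results must be c(cost, qaly) or list(cost=, qaly=)")
  }
  e <- as_ce(exp_arm); c0 <- as_ce(ctrl_arm)
  dc <- e$cost - c0$cost
  dq <- e$qaly - c0$qaly
  status <- if (dq == 0 && dc == 0) "equivalent"
  else if (dq > 0 && dc <= 0) "dominant"
  else if (dq < 0 && dc >= 0) "dominated"
  else if (dq == 0) { if (dc > 0) "dominated" else "dominant" }
  else "icer"
  icer <- if (status == "icer") dc / dq else NA_real_
  structure(list(labels = labels,
                 cost = c(e$cost, c0$cost), qaly = c(e$qaly, c0$qaly),
                 delta_cost = dc, delta_qaly = dq, icer = icer,
                 status = status),
            class = "cua_cea")
}

#' @export
print.cua_cea <- function(x, ...) {
  df <- data.frame(strategy = x$labels,
                   total_cost = round_half_up(x$cost, 2),
                   incr_cost = c(round_half_up(x$delta_cost, 2), NA),
                   qalys = round_half_up(x$qaly, 2),
                   incr_qalys = c(round_half_up(x$delta_qaly, 2), NA),
                   icer = c(round_half_up(x$icer, 2), NA))
  print(df, row.names = FALSE, na.print = "-")
  if (x$status != "icer")
    cat("Status:", x$labels[1], "is", x$status, "\n")
  invisible(x)
}

#' Full cost-utility comparison from two arm traces
#'
#' @param trace_exp,trace_ctrl `cua_trace` objects for the two arms.
#' @param inputs a `cua_inputs`.
#' @param labels strategy labels.
#' @return a `cua_cea` with per-arm cost breakdowns in attribute
#'   `breakdowns`.
#' @export
run_cea <- function(trace_exp, trace_ctrl, inputs,
                    labels = c("experimental", "control")) {
  ce <- arm_costs(trace_exp, inputs, "experimental")
  cc <- arm_costs(trace_ctrl, inputs, "control")
  qe <- arm_qalys(trace_exp, inputs, "experimental")
  qc <- arm_qalys(trace_ctrl, inputs, "control")
  out <- cea_compare(c(as.numeric(ce), qe), c(as.numeric(cc), qc), labels)
  attr(out, "breakdowns") <- list(experimental = attr(ce, "breakdown"),
                                  control = attr(cc, "breakdown"))
  out
}

#' Price-threshold analysis
#'
#' Finds the drug price factor `f*` (fraction of list price) at which the
#' ICER equals the willingness-to-pay threshold, by bisection on a model
#' closure. Assumes the ICER is continuous and increasing in `f`.
#'
#' @param model_fn function of the price factor returning a `cua_cea`.
#' @param wtp willingness-to-pay (USD/QALY).
#' @param f_range search interval for the factor (default (1e-6, 1\]).
#' @param tol_icer stop when `|ICER(f*) - wtp| <= tol_icer` (USD/QALY).
#' @param tol_f or when the bracketing interval is narrower than `tol_f`.
#' @return list of class `cua_threshold`: `f_star`, `icer`, `wtp`,
#'   `status` (`"ok"`, `"infeasible"` when even a near-zero price exceeds
#'   the WTP, `"above_range"` when the list price is already
#'   cost-effective) and the evaluation `grid`.
#' @export
threshold_price <- function(model_fn, wtp, f_range = c(1e-6, 1),
                            tol_icer = 0.01, tol_f = 1e-12) {
  icer_at <- function(f) {
    r <- model_fn(f)
    stopifnot(inherits(r, "cua_cea"))
    if (is.na(r$icer)) {
      if (r$status == "dominant") return(-Inf)
      stop_input("ICER undefined at price factor ", f)
    }
    r$icer
  }
  lo <- f_range[1]; hi <- f_range[2]
  grid <- data.frame(f = numeric(0), icer = numeric(0))
  note <- function(f, v) grid <<- rbind(grid, data.frame(f = f, icer = v))
  v_lo <- icer_at(lo); note(lo, v_lo)
  v_hi <- icer_at(hi); note(hi, v_hi)
  if (v_lo > wtp)
    return(structure(list(f_star = NA_real_, icer = v_lo, wtp = wtp,
                          status = "infeasible", grid = grid),
                     class = "cua_threshold"))
  if (v_hi <= wtp)
    return(structure(list(f_star = hi, icer = v_hi, wtp = wtp,
                          status = "above_range", grid = grid),
                     class = "cua_threshold"))
  repeat {
    mid <- (lo + hi) / 2
    v <- icer_at(mid); note(mid, v)
    if (abs(v - wtp) <= tol_icer || (hi - lo) / 2 <= tol_f) {
      return(structure(list(f_star = mid, icer = v, wtp = wtp,
                            status = "ok", grid = grid),
                       class = "cua_threshold"))
    }
    if (v > wtp) hi <- mid else lo <- mid
  }
}

#' @export
print.cua_threshold <- function(x, ...) {
  cat("Price-threshold analysis (WTP", format(x$wtp, big.mark = ","),
      "USD/QALY)\n")
  if (x$status == "infeasible") {
    cat("  Not cost-effective at any positive price factor",
        sprintf("(ICER %.2f at f -> 0)\n", x$icer))
  } else {
    cat(sprintf("  f* = %.4f (%.1f%% of list price), ICER(f*) = %.2f [%s]\n",
                x$f_star, 100 * x$f_star, x$icer, x$status))
  }
  invisible(x)
}

#' Write a results CSV in the published table layout
#'
#' Columns: strategy, total_cost, incr_cost, qalys, incr_qalys, icer
#' (2-decimal half-up rounding; internal arithmetic is full precision).
#'
#' @param cea a `cua_cea`.
#' @param path CSV destination.
#' @return invisibly `path`.
#' @export
write_cea_table <- function(cea, path) {
  df <- data.frame(strategy = cea$labels,
                   total_cost = round_half_up(cea$cost, 2),
                   incr_cost = c(round_half_up(cea$delta_cost, 2), NA),
                   qalys = round_half_up(cea$qaly, 2),
                   incr_qalys = c(round_half_up(cea$delta_qaly, 2), NA),
                   icer = c(round_half_up(cea$icer, 2), NA))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
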