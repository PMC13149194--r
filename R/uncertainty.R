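# One-way deterministic sensitivity analysis (tornado ordering) and
# probabilistic sensitivity analysis with moment-matched gamma/beta sampling,
# cost-effectiveness plane samples and acceptability curves.
#
# Parameter uncertainty covers the economic parameters only (costs, risks,
# utilities, probabilities, discount rate); survival-curve parameters are
# held fixed, matching the scope of the input table.

#' One-way deterministic sensitivity analysis
#'
#' Re-evaluates the model at each parameter's lower and upper bound with all
#' other parameters at base, and orders the entries by tornado bar width
#' `|ICER_high - ICER_low|` (descending).
#'
#' @param inputs a `cua_inputs` (the base case).
#' @param model_fn function of a `cua_inputs` returning a `cua_cea`.
#' @param ranges parameter ranges, default [param_ranges()].
#' @return data.frame of class `cua_dsa`: name, base, low, high, icer_low,
#'   icer_high, width, sorted by width; evaluation failures are flagged in
#'   the `failed` column, never dropped.
#' @export
one_way_dsa <- function(inputs, model_fn, ranges = param_ranges(inputs)) {
  stopifnot(inherits(inputs, "cua_inputs"))
  base_res <- model_fn(inputs)
  eval_at <- function(name, value) {
    tryCatch(model_fn(set_param(inputs, name, value))$icer,
             error = function(e) NA_real_)
  }
  icer_low <- icer_high <- numeric(nrow(ranges))
  failed <- logical(nrow(ranges))
  for (i in seq_len(nrow(ranges))) {
    icer_low[i] <- eval_at(ranges$name[i], ranges$low[i])
    icer_high[i] <- eval_at(ranges$name[i], ranges$high[i])
    failed[i] <- is.na(icer_low[i]) || is.na(icer_high[i])
  }
  width <- abs(icer_high - icer_low)
  out <- data.frame(ranges[c("name", "base", "low", "high")],
                    icer_low = icer_low, icer_high = icer_high,
                    width = width, failed = failed)
  out <- out[order(-out$width), ]
  rownames(out) <- NULL
  structure(out, base_icer = base_res$icer,
            class = c("cua_dsa", "data.frame"))
}

#' @export
plot.cua_dsa <- function(x, n_top = 12, ...) {
  d <- utils::head(x[!x$failed, ], n_top)
  d <- d[rev(seq_len(nrow(d))), ]
  base <- attr(x, "base_icer")
  graphics::par(mar = c(4, 12, 2, 1))
  graphics::plot(NULL, xlim = range(c(d$icer_low, d$icer_high, base)),
                 ylim = c(0.5, nrow(d) + 0.5), yaxt = "n",
                 xlab = "ICER (USD/QALY)", ylab = "", main = "Tornado diagram")
  graphics::axis(2, at = seq_len(nrow(d)), labels = d$name, las = 1, cex.axis = 0.7)
  for (i in seq_len(nrow(d)))
    graphics::rect(min(d$icer_low[i], d$icer_high[i]), i - 0.35,
                   max(d$icer_low[i], d$icer_high[i]), i + 0.35, col = "grey70")
  graphics::abline(v = base, lty = 2)
  invisible(x)
}

# Moment-matched distribution parameters: mean = base, sd = (high-low)/3.92.
.psa_dist <- function(base, low, high, dist) {
  sd <- (high - low) / (2 * 1.96)
  if (sd <= 0 || base <= 0 || (dist == "beta" && base >= 1))
    return(list(kind = "fixed", value = base))
  if (dist == "gamma") {
    return(list(kind = "gamma", shape = (base / sd)^2, rate = base / sd^2))
  }
  cap <- sqrt(base * (1 - base))
  warn <- FALSE
  if (sd >= cap) { sd <- 0.95 * cap; warn <- TRUE }  # infeasible beta moments
  nu <- base * (1 - base) / sd^2 - 1
  list(kind = "beta", shape1 = base * nu, shape2 = (1 - base) * nu,
       clamped = warn)
}

#' Sample parameter draws for probabilistic sensitivity analysis
#'
#' Gamma for costs, beta for probabilities and utilities, parameterized by
#' moment matching with mean = base and sd = (high - low)/3.92. Degenerate
#' ranges (sd = 0, or base on the support boundary) yield the base value in
#' every draw; infeasible beta moments are shrunk to 95% of the feasible
#' bound with a warning recorded in the `clamped` attribute.
#'
#' @param ranges data.frame as from [param_ranges()].
#' @param n number of draws.
#' @param seed integer seed (explicit; no global RNG state is consumed).
#' @return n x nrow(ranges) matrix of draws, columns named by parameter.
#' @export
sample_parameters <- function(ranges, n, seed = 1L) {
  draws <- matrix(NA_real_, n, nrow(ranges),
                  dimnames = list(NULL, ranges$name))
  clamped <- character(0)
  with_seed(seed, {
    for (i in seq_len(nrow(ranges))) {
      d <- .psa_dist(ranges$base[i], ranges$low[i], ranges$high[i],
                     ranges$dist[i])
      draws[, i] <- switch(d$kind,
        fixed = rep(d$value, n),
        gamma = stats::rgamma(n, shape = d$shape, rate = d$rate),
        # guard float underflow to the closed endpoints of the support
        beta = pmin(1 - 1e-12,
                    pmax(1e-12, stats::rbeta(n, d$shape1, d$shape2))))
      if (isTRUE(d$clamped)) clamped <- c(clamped, ranges$name[i])
    }
  })
  attr(draws, "clamped") <- clamped
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Second-order Monte Carlo: jointly redraws all economic parameters and
#' re-evaluates the model for each iteration. A failing iteration is
#' resampled once from the tail of the random stream, then flagged.
#'
#' @param inputs a `cua_inputs`.
#' @param model_fn function of a `cua_inputs` returning a `cua_cea`.
#' @param n iterations (1,000 in the reference analysis).
#' @param seed integer seed.
#' @param ranges parameter ranges, default [param_ranges()].
#' @return data.frame of class `cua_psa`: iteration, delta_cost, delta_qaly,
#'   cost/qaly per arm, failed flag; parameter draws kept in attribute
#'   `draws` for audit.
#' @export
run_psa <- function(inputs, model_fn, n = 1000, seed = 1L,
                    ranges = param_ranges(inputs)) {
  draws <- sample_parameters(ranges, n, seed = seed)
  spare <- sample_parameters(ranges, n, seed = seed + 104729L)
  eval_draw <- function(row) {
    ip <- inputs
    for (j in seq_along(row)) ip <- set_param(ip, colnames(draws)[j], row[j])
    model_fn(ip)
  }
  out <- data.frame(iteration = seq_len(n), delta_cost = NA_real_,
                    delta_qaly = NA_real_, cost_exp = NA_real_,
                    cost_ctrl = NA_real_, qaly_exp = NA_real_,
                    qaly_ctrl = NA_real_, failed = FALSE)
  for (i in seq_len(n)) {
    r <- tryCatch(eval_draw(draws[i, ]), error = function(e) NULL)
    if (is.null(r)) {
      r <- tryCatch(eval_draw(spare[i, ]), error = function(e) NULL)
      if (is.null(r)) { out$failed[i] <- TRUE; next }
      draws[i, ] <- spare[i, ]
    }
    out$delta_cost[i] <- r$delta_cost
    out$delta_qaly[i] <- r$delta_qaly
    out$cost_exp[i] <- r$cost[1]; out$cost_ctrl[i] <- r$cost[2]
    out$qaly_exp[i] <- r$qaly[1]; out$qaly_ctrl[i] <- r$qaly[2]
  }
  structure(out, draws = draws, seed = seed,
            class = c("cua_psa", "data.frame"))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay level, the fraction of PSA samples with
#' positive net monetary benefit `wtp*delta_qaly - delta_cost > 0` (ties
#' count as not cost-effective).
#'
#' @param psa a `cua_psa` (or data.frame with delta_cost/delta_qaly).
#' @param wtp_grid willingness-to-pay levels (USD/QALY).
#' @return data.frame (wtp, prob_cost_effective) of class `cua_ceac`.
#' @export
ceac <- function(psa, wtp_grid) {
  if (length(wtp_grid) == 0) stop_input("wtp_grid must be non-empty")
  ok <- !psa$failed %||% rep(FALSE, nrow(psa))
  dc <- psa$delta_cost[ok]; dq <- psa$delta_qaly[ok]
  if (length(dc) == 0) stop_input("no successful PSA samples")
  p <- vapply(wtp_grid, function(l) mean(l * dq - dc > 0), numeric(1))
  structure(data.frame(wtp = wtp_grid, prob_cost_effective = p),
            class = c("cua_ceac", "data.frame"))
}

#' @export
plot.cua_psa <- function(x, wtp = NULL, ...) {
  graphics::plot(x$delta_qaly, x$delta_cost, pch = 16, cex = 0.5,
                 col = "grey40", xlab = "Incremental QALYs",
                 ylab = "Incremental cost (USD)",
                 main = "Cost-effectiveness plane")
  graphics::abline(h = 0, v = 0, col = "grey70")
  if (!is.null(wtp)) graphics::abline(0, wtp, lty = 2)
  invisible(x)
}

#' @export
plot.cua_ceac <- function(x, ...) {
  graphics::plot(x$wtp, x$prob_cost_effective, type = "l", ylim = c(0, 1),
                 xlab = "Willingness-to-pay (USD/QALY)",
                 ylab = "P(cost-effective)",
                 main = "Cost-effectiveness acceptability curve")
  invisible(x)
}
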