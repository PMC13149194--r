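# Fractional-polynomial survival models on the log-hazard scale:
# log h(t) = b0 + b1*g_p1(t) [+ b2*g_p2(t)], with g_p(t) = t^p for p != 0 and
# g_0(t) = ln t; a repeated power uses t^p * ln t for the second term.
# Survival has no closed form for arbitrary powers, so S(t) = exp(-H(t)) with
# H obtained by trapezoid quadrature on a fixed one-day grid.

.fp_grid <- c(-2, -1, -0.5, 0, 0.5, 1, 2, 3)
.fp_default_step <- 12 / 365.25  # one day, in months

fp_basis <- function(t, powers) {
  g <- function(p) if (p == 0) log(t) else t^p
  if (length(powers) == 1) return(cbind(1, g(powers[1])))
  b2 <- if (powers[1] == powers[2]) g(powers[1]) * log(t) else g(powers[2])
  cbind(1, g(powers[1]), b2)
}

# Trapezoid quadrature nodes: a regular grid of width `step`, with the first
# step subdivided geometrically because power/log bases are singular at t = 0
# (the first node sits at step*1e-3; the mass below it is ignored).
fp_quad_nodes <- function(tmax, step) {
  first <- step * 10^seq(-3, 0, length.out = 16)
  rest <- seq(step, tmax + step, by = step)
  unique(c(first, rest))
}

fp_cumhaz_at <- function(beta, powers, times, step) {
  nodes <- fp_quad_nodes(max(times, step), step)
  hq <- exp(pmin(drop(fp_basis(nodes, powers) %*% beta), 700))
  Hq <- c(0, cumsum((hq[-1] + hq[-length(hq)]) / 2 * diff(nodes)))
  stats::approx(nodes, Hq, xout = pmax(times, nodes[1]), rule = 2)$y *
    (times > 0)
}

fp_functions <- function(object, step = NULL) {
  step <- step %||% .fp_default_step
  beta <- object$params[grep("^beta", names(object$params))]
  powers <- object$powers
  list(
    S = function(t) exp(-fp_cumhaz_at(beta, powers, t, step)),
    h = function(t) exp(pmin(drop(fp_basis(pmax(t, step * 1e-3), powers) %*%
                                    beta), 700)))
}

fp_fit_one <- function(ti, ev, powers, step, restarts) {
  nodes <- fp_quad_nodes(max(ti, step), step)
  Xq <- fp_basis(nodes, powers)
  dn <- diff(nodes)
  te <- pmax(ti, nodes[1])
  Xe <- fp_basis(te, powers)
  negll <- function(beta) {
    eta_q <- drop(Xq %*% beta)
    if (any(!is.finite(eta_q))) return(1e10)
    hq <- exp(pmin(eta_q, 700))
    Hq <- c(0, cumsum((hq[-1] + hq[-length(hq)]) / 2 * dn))
    Hi <- stats::approx(nodes, Hq, xout = te, rule = 2)$y * (ti > 0)
    ll <- sum(ev * drop(Xe %*% beta)) - sum(Hi)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  init <- c(log(max(sum(ev), 1) / sum(ti)), rep(0, length(powers)))
  best <- NULL
  for (r in seq_len(max(1, restarts))) {
    start <- if (r == 1) init else
      init + with_seed(1000 + r, stats::rnorm(length(init), sd = 0.5))
    o1 <- tryCatch(stats::optim(start, negll, method = "Nelder-Mead",
                                control = list(maxit = 2000, reltol = 1e-10)),
                   error = function(e) NULL)
    if (is.null(o1)) next
    o2 <- tryCatch(stats::optim(o1$par, negll, method = "BFGS",
                                control = list(maxit = 1000)),
                   error = function(e) o1)
    cand <- if (o2$value <= o1$value) o2 else o1
    if (is.null(best) || cand$value < best$value - 1e-12) best <- cand
  }
  if (is.null(best) || best$value >= 1e9) return(NULL)
  list(beta = best$par, loglik = -best$value,
       converged = (best$convergence %||% 1) == 0)
}

#' Fit a fractional-polynomial hazard model
#'
#' Searches the standard power grid \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}
#' (unordered pairs, repeats allowed, for order 2) and returns the grid-best
#' model by AIC. Powers are treated as selected, not as free parameters, so
#' `k` counts the regression coefficients only.
#'
#' @param ipd a `cua_ipd` with at least 3 events.
#' @param order 1 (one power term) or 2.
#' @param powers optional fixed power(s) to fit, bypassing the grid search.
#' @param grid candidate powers.
#' @param step quadrature step in months (default one day).
#' @param restarts jittered optimizer restarts for the final fit.
#' @return a `cua_survfit` with `family` `"fp1"`/`"fp2"`, coefficients
#'   `beta0, beta1[, beta2]` and the chosen `powers`; a `cua_fitfail` if
#'   every grid fit fails.
#' @export
fit_fracpoly <- function(ipd, order = 1, powers = NULL, grid = .fp_grid,
                         step = .fp_default_step, restarts = 5) {
  ipd <- as_cua_ipd(ipd)
  if (sum(ipd$event) < 3)
    stop_input("need at least 3 events to fit a fractional polynomial")
  if (!order %in% 1:2) stop_input("order must be 1 or 2")
  ti <- ipd$time
  ev <- ipd$event
  cands <- if (!is.null(powers)) {
    if (length(powers) != order) stop_input("powers must have length ", order)
    list(powers)
  } else if (order == 1) {
    as.list(grid)
  } else {
    out <- list()
    for (i in seq_along(grid)) for (j in i:length(grid))
      out[[length(out) + 1]] <- c(grid[i], grid[j])
    out
  }
  best <- NULL
  best_p <- NULL
  for (p in cands) {
    f <- fp_fit_one(ti, ev, p, step,
                    restarts = if (length(cands) == 1) restarts else 2)
    if (!is.null(f) && (is.null(best) || f$loglik > best$loglik)) {
      best <- f
      best_p <- p
    }
  }
  if (is.null(best))
    return(structure(list(family = paste0("fp", order),
                          message = "all power-grid fits failed"),
                     class = "cua_fitfail"))
  if (length(cands) > 1) {  # polish the winner with the full restart budget
    f <- fp_fit_one(ti, ev, best_p, step, restarts = restarts)
    if (!is.null(f) && f$loglik >= best$loglik) best <- f
  }
  params <- best$beta
  names(params) <- paste0("beta", seq_along(params) - 1)
  new_survfit(family = paste0("fp", order), params = params,
              loglik = best$loglik, k = order + 1, n_obs = nrow(ipd),
              n_events = sum(ev), converged = best$converged,
              powers = best_p)
}
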