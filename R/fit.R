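# Maximum-likelihood survival fitting: seven standard parametric families
# (via flexsurv) and the shared `cua_survfit` model class used for
# extrapolation. Fractional-polynomial hazard models live in fracpoly.R.

.std_families <- c(exponential = "exp", weibull = "weibull",
                   gompertz = "gompertz", lognormal = "lnorm",
                   loglogistic = "llogis", gamma = "gamma",
                   generalized_gamma = "gengamma")

#' Fit a survival model to individual patient data
#'
#' Fits one candidate extrapolation model to right-censored IPD by maximum
#' likelihood. Families: the seven standard parametric distributions
#' (exponential, weibull, gompertz, lognormal, loglogistic, gamma,
#' generalized_gamma) and the fractional-polynomial log-hazard models
#' (`fp1`, `fp2`, delegated to [fit_fracpoly()]).
#'
#' A failed fit is returned as an object of class `cua_fitfail` carrying the
#' diagnostic message rather than silently falling back to another family.
#'
#' @param ipd a `cua_ipd` (single arm) with at least 2 events.
#' @param family model family name.
#' @param ... passed on to [fit_fracpoly()] for the fp families.
#' @return object of class `cua_survfit`: family, natural-scale parameter
#'   vector, log-likelihood, AIC/BIC (`aic = 2k - 2*loglik`,
#'   `bic = k*log(n_obs) - 2*loglik`), number of observations/events and a
#'   convergence flag.
#' @export
fit_survival <- function(ipd, family, ...) {
  ipd <- as_cua_ipd(ipd)
  if (family %in% c("fp1", "fp2"))
    return(fit_fracpoly(ipd, order = if (family == "fp1") 1 else 2, ...))
  if (!family %in% names(.std_families))
    stop_input("unknown survival family: ", family)
  if (sum(ipd$event) < 2)
    stop_input("need at least 2 events to fit a survival model")
  dist <- .std_families[[family]]
  fit <- NULL
  msg <- NULL
  for (attempt in 1:5) {
    fit <- tryCatch(
      withCallingHandlers(
        flexsurv::flexsurvreg(
          survival::Surv(time, event) ~ 1, data = ipd, dist = dist,
          control = list(reltol = 1e-12, maxit = 5000)),
        warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) { msg <<- conditionMessage(e); NULL })
    if (!is.null(fit)) break
  }
  if (is.null(fit))
    return(structure(list(family = family, message = msg),
                     class = "cua_fitfail"))
  params <- fit$res[, "est"]
  names(params) <- rownames(fit$res)
  new_survfit(family = family, params = params, loglik = fit$loglik,
              k = fit$npars, n_obs = nrow(ipd), n_events = sum(ipd$event),
              converged = TRUE)
}

new_survfit <- function(family, params, loglik, k, n_obs, n_events,
                        converged, powers = NULL) {
  structure(list(family = family, params = params, loglik = loglik,
                 k = k, aic = 2 * k - 2 * loglik,
                 bic = k * log(n_obs) - 2 * loglik,
                 n_obs = n_obs, n_events = n_events,
                 converged = converged, powers = powers),
            class = "cua_survfit")
}

# Natural-scale survival and hazard closures for a fitted model.
survfit_functions <- function(object, fp_step = NULL) {
  if (object$family %in% c("fp1", "fp2"))
    return(fp_functions(object, step = fp_step))
  p <- object$params
  switch(object$family,
    exponential = list(
      S = function(t) stats::pexp(t, p[["rate"]], lower.tail = FALSE),
      h = function(t) rep(p[["rate"]], length(t))),
    weibull = list(
      S = function(t) stats::pweibull(t, p[["shape"]], p[["scale"]], lower.tail = FALSE),
      h = function(t) flexsurv::hweibull(t, p[["shape"]], p[["scale"]])),
    gompertz = list(
      S = function(t) flexsurv::pgompertz(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
      h = function(t) flexsurv::hgompertz(t, p[["shape"]], p[["rate"]])),
    lognormal = list(
      S = function(t) stats::plnorm(t, p[["meanlog"]], p[["sdlog"]], lower.tail = FALSE),
      h = function(t) flexsurv::hlnorm(t, p[["meanlog"]], p[["sdlog"]])),
    loglogistic = list(
      S = function(t) flexsurv::pllogis(t, shape = p[["shape"]], scale = p[["scale"]], lower.tail = FALSE),
      h = function(t) flexsurv::hllogis(t, shape = p[["shape"]], scale = p[["scale"]])),
    gamma = list(
      S = function(t) stats::pgamma(t, p[["shape"]], p[["rate"]], lower.tail = FALSE),
      h = function(t) flexsurv::hgamma(t, p[["shape"]], p[["rate"]])),
    generalized_gamma = list(
      S = function(t) flexsurv::pgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]], lower.tail = FALSE),
      h = function(t) flexsurv::hgengamma(t, p[["mu"]], p[["sigma"]], p[["Q"]])),
    stop_input("no evaluator for family ", object$family))
}

#' Evaluate fitted survival probabilities
#'
#' @param model a `cua_survfit`.
#' @param times months, non-negative.
#' @param fp_step quadrature step in months for fractional-polynomial models
#'   (default one day); ignored for closed-form families.
#' @return survival probabilities clamped to \[0, 1\], `S(0) = 1`.
#' @export
survival_at <- function(model, times, fp_step = NULL) {
  stopifnot(inherits(model, "cua_survfit"))
  if (any(times < 0)) stop_input("time must be non-negative")
  fns <- survfit_functions(model, fp_step = fp_step)
  s <- fns$S(times)
  s[times == 0] <- 1
  pmin(1, pmax(0, s))
}

#' Evaluate the fitted hazard
#'
#' @inheritParams survival_at
#' @return hazard values (per month).
#' @export
hazard_at <- function(model, times, fp_step = NULL) {
  stopifnot(inherits(model, "cua_survfit"))
  if (any(times < 0)) stop_input("time must be non-negative")
  survfit_functions(model, fp_step = fp_step)$h(times)
}

#' Proportional-hazards subgroup adjustment
#'
#' Under proportional hazards with hazard ratio HR against the reference
#' population, the subgroup survival curve is `S(t)^HR`.
#'
#' @param model a `cua_survfit` or a survival evaluator function.
#' @param hazard_ratio positive hazard ratio.
#' @param label optional subgroup label.
#' @return survival evaluator function of time (months) with attributes
#'   `hazard_ratio` and `label`.
#' @export
adjust_by_hazard_ratio <- function(model, hazard_ratio, label = NULL) {
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0)
    stop_input("hazard_ratio must be a positive number")
  base <- as_surv_fn(model)
  f <- function(t) pmin(1, pmax(0, base(t)^hazard_ratio))
  attr(f, "hazard_ratio") <- hazard_ratio
  attr(f, "label") <- label
  f
}

#' Coerce to a survival evaluator function
#'
#' @param x a `cua_survfit` or a function of time.
#' @return function mapping months to survival probabilities.
#' @export
as_surv_fn <- function(x) {
  if (is.function(x)) return(x)
  if (inherits(x, "cua_survfit")) return(function(t) survival_at(x, t))
  stop_input("cannot interpret object of class ", class(x)[1],
             " as a survival curve")
}

#' Rank candidate fits by information criteria
#'
#' Ascending AIC; ties broken by fewer free parameters, then family name.
#' Failed fits (`cua_fitfail`) are excluded from the ranking but listed in
#' the `failed` attribute.
#'
#' @param fits list of `cua_survfit` / `cua_fitfail` objects.
#' @return data.frame of class `cua_modelrank` (family, powers, k, loglik,
#'   aic, bic) sorted by rank, with the sorted fit objects in attribute
#'   `fits`.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "cua_survfit")) fits <- list(fits)
  if (length(fits) == 0) stop_input("no fits supplied")
  ok <- vapply(fits, inherits, logical(1), what = "cua_survfit")
  failed <- fits[!ok]
  fits <- fits[ok]
  if (length(fits) == 0) stop_input("no successful fits to rank")
  tab <- data.frame(
    family = vapply(fits, function(f) f$family, character(1)),
    powers = vapply(fits, function(f)
      if (is.null(f$powers)) "" else paste(f$powers, collapse = ","), character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    loglik = vapply(fits, function(f) f$loglik, numeric(1)),
    aic = vapply(fits, function(f) f$aic, numeric(1)),
    bic = vapply(fits, function(f) f$bic, numeric(1)),
    stringsAsFactors = FALSE)
  ord <- order(tab$aic, tab$k, tab$family)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(tab, fits = fits[ord], failed = failed,
            class = c("cua_modelrank", "data.frame"))
}

#' Best-ranked fit from a model ranking
#' @param ranking a `cua_modelrank`.
#' @return the top `cua_survfit`.
#' @export
best_fit <- function(ranking) {
  stopifnot(inherits(ranking, "cua_modelrank"))
  attr(ranking, "fits")[[1]]
}

#' Write a fit-comparison summary CSV
#'
#' One row per candidate: family, parameters, log-likelihood, AIC, BIC and
#' convergence flag, mirroring a supplementary model-fit table.
#'
#' @param fits list of fit objects (or a `cua_modelrank`).
#' @param path CSV destination.
#' @return invisibly `path`.
#' @export
write_fit_summary <- function(fits, path) {
  if (inherits(fits, "cua_modelrank")) fits <- attr(fits, "fits")
  rows <- lapply(fits, function(f) {
    if (inherits(f, "cua_fitfail"))
      return(data.frame(family = f$family, parameters = "", loglik = NA,
                        aic = NA, bic = NA, converged = FALSE))
    data.frame(
      family = f$family,
      parameters = paste(sprintf("%s=%.6g", names(f$params), f$params),
                         collapse = "; "),
      loglik = f$loglik, aic = f$aic, bic = f$bic, converged = f$converged)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

# ---- methods ---------------------------------------------------------------

#' @export
print.cua_survfit <- function(x, ...) {
  cat("Survival model:", x$family,
      if (!is.null(x$powers)) paste0("(powers ", paste(x$powers, collapse = ", "), ")"),
      "\n")
  cat("  n =", x$n_obs, " events =", x$n_events, "\n")
  cat("  parameters:", paste(sprintf("%s = %.4g", names(x$params), x$params),
                             collapse = ", "), "\n")
  cat(sprintf("  loglik = %.3f  AIC = %.3f  BIC = %.3f\n",
              x$loglik, x$aic, x$bic))
  if (!x$converged) cat("  WARNING: optimizer did not converge\n")
  invisible(x)
}

#' @export
coef.cua_survfit <- function(object, ...) object$params

#' @export
summary.cua_survfit <- function(object, times = seq(0, 120, by = 12), ...) {
  out <- data.frame(time = times,
                    survival = survival_at(object, times))
  structure(list(fit = object, table = out), class = "summary.cua_survfit")
}

#' @export
print.summary.cua_survfit <- function(x, ...) {
  print(x$fit)
  cat("Extrapolated survival:\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
predict.cua_survfit <- function(object, times,
                                type = c("survival", "hazard"), ...) {
  type <- match.arg(type)
  if (type == "survival") survival_at(object, times) else hazard_at(object, times)
}

#' @export
plot.cua_survfit <- function(x, tmax = 120, km = NULL, ...) {
  tt <- seq(0, tmax, length.out = 400)
  graphics::plot(tt, survival_at(x, tt), type = "l", ylim = c(0, 1),
                 xlab = "Months", ylab = "Survival",
                 main = paste("Fitted", x$family, "model"), ...)
  if (!is.null(km))
    graphics::lines(km$time, km$survival, type = "s", lty = 2)
  invisible(x)
}

#' @export
simulate.cua_survfit <- function(object, nsim = 1, seed = NULL, tmax = 1200, ...) {
  draw <- function(n) {
    u <- stats::runif(n)
    fns <- survfit_functions(object)
    vapply(u, function(ui) {
      if (fns$S(tmax) >= ui) return(tmax)
      stats::uniroot(function(t) fns$S(t) - ui, c(1e-9, tmax),
                     tol = 1e-8)$root
    }, numeric(1))
  }
  if (is.null(seed)) draw(nsim) else with_seed(seed, draw(nsim))
}

#' @export
print.cua_fitfail <- function(x, ...) {
  cat("Survival fit FAILED for family", x$family, "\n  ", x$message, "\n")
  invisible(x)
}

#' @export
print.cua_modelrank <- function(x, ...) {
  cat("Candidate survival models ranked by AIC:\n")
  print(as.data.frame(x), row.names = FALSE)
  nf <- length(attr(x, "failed"))
  if (nf) cat(nf, "fit(s) failed and were excluded.\n")
  invisible(x)
}
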