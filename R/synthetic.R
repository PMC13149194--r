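# Synthetic two-arm trial generator: event/censoring models, digitized-curve
# artifacts and the default study used throughout the tests and examples.

.sim_families <- c("exponential", "weibull", "lognormal", "loglogistic",
                   "gompertz", "gamma", "none")

#' Specify one simulated trial arm
#'
#' Defines the event-time model, random-dropout model, administrative cutoff
#' and number-at-risk grid for a single arm of a synthetic two-arm trial.
#' All times are in months.
#'
#' @param arm_label character label for the arm.
#' @param n_patients number of subjects (>= 2).
#' @param event_model list with `family` (one of exponential, weibull,
#'   lognormal, loglogistic, gompertz, gamma) and the family's parameters,
#'   e.g. `list(family = "weibull", shape = 1.3, scale = 8)`.
#' @param censor_model dropout model in the same form, or
#'   `list(family = "none")` for no random dropout.
#' @param admin_cutoff administrative censoring time in months (may be `Inf`).
#' @param risk_grid strictly increasing vector of months starting at 0 at
#'   which the number at risk is tabulated.
#' @param seed integer seed; every simulation is reproducible given the spec.
#' @return an object of class `cua_simspec`.
#' @export
simulation_spec <- function(arm_label, n_patients, event_model,
                            censor_model = list(family = "none"),
                            admin_cutoff = 24,
                            risk_grid = seq(0, 24, by = 2),
                            seed = 1L) {
  if (!is.numeric(n_patients) || n_patients < 2)
    stop_input("n_patients must be >= 2")
  if (!is.numeric(admin_cutoff) || admin_cutoff <= 0)
    stop_input("admin_cutoff must be positive")
  if (risk_grid[1] != 0 || any(diff(risk_grid) <= 0))
    stop_input("risk_grid must start at 0 and be strictly increasing")
  check_sim_model(event_model)
  check_sim_model(censor_model)
  if (identical(event_model$family, "none"))
    stop_input("event_model cannot have family 'none'")
  structure(list(arm_label = as.character(arm_label),
                 n_patients = as.integer(n_patients),
                 event_model = event_model, censor_model = censor_model,
                 admin_cutoff = admin_cutoff, risk_grid = risk_grid,
                 seed = as.integer(seed)),
            class = "cua_simspec")
}

check_sim_model <- function(m) {
  if (is.null(m$family) || !m$family %in% .sim_families)
    stop_input("unknown distribution family: ", m$family %||% "<missing>")
  pos <- function(name) {
    v <- m[[name]]
    if (is.null(v) || !is.numeric(v) || v <= 0)
      stop_input("parameter '", name, "' of ", m$family,
                 " model must be a positive number")
  }
  switch(m$family,
         exponential = pos("rate"),
         weibull = { pos("shape"); pos("scale") },
         lognormal = {
           if (is.null(m$meanlog) || !is.numeric(m$meanlog))
             stop_input("lognormal model needs numeric 'meanlog'")
           pos("sdlog")
         },
         loglogistic = { pos("shape"); pos("scale") },
         gompertz = {
           if (is.null(m$shape) || !is.numeric(m$shape))
             stop_input("gompertz model needs numeric 'shape'")
           pos("rate")
         },
         gamma = { pos("shape"); pos("rate") },
         none = invisible(NULL))
  invisible(m)
}

draw_times <- function(model, n) {
  switch(model$family,
         exponential = stats::rexp(n, rate = model$rate),
         weibull = stats::rweibull(n, shape = model$shape, scale = model$scale),
         lognormal = stats::rlnorm(n, meanlog = model$meanlog, sdlog = model$sdlog),
         loglogistic = flexsurv::rllogis(n, shape = model$shape, scale = model$scale),
         gompertz = flexsurv::rgompertz(n, shape = model$shape, rate = model$rate),
         gamma = stats::rgamma(n, shape = model$shape, rate = model$rate),
         none = rep(Inf, n))
}

# True survival function of a simulation event model (used by convergence tests).
model_survival <- function(model) {
  switch(model$family,
    exponential = function(t) stats::pexp(t, model$rate, lower.tail = FALSE),
    weibull = function(t) stats::pweibull(t, model$shape, model$scale, lower.tail = FALSE),
    lognormal = function(t) stats::plnorm(t, model$meanlog, model$sdlog, lower.tail = FALSE),
    loglogistic = function(t) flexsurv::pllogis(t, shape = model$shape, scale = model$scale, lower.tail = FALSE),
    gompertz = function(t) flexsurv::pgompertz(t, shape = model$shape, rate = model$rate, lower.tail = FALSE),
    gamma = function(t) stats::pgamma(t, shape = model$shape, rate = model$rate, lower.tail = FALSE),
    stop_input("no survival function for family ", model$family))
}

#' Simulate one trial arm
#'
#' Draws latent event and dropout times and applies administrative censoring:
#' the observed time is the minimum of the three, and the event indicator is 1
#' iff the event time is that minimum.
#'
#' @param spec a [simulation_spec()].
#' @return individual patient data: a `data.frame` with columns `time`
#'   (months), `event` (0/1) and `arm`, of class `cua_ipd`.
#' @export
simulate_arm <- function(spec) {
  stopifnot(inherits(spec, "cua_simspec"))
  n <- spec$n_patients
  with_seed(spec$seed, {
    t_event <- draw_times(spec$event_model, n)
    t_drop <- draw_times(spec$censor_model, n)
    time <- pmin(t_event, t_drop, spec$admin_cutoff)
    event <- as.integer(t_event <= pmin(t_drop, spec$admin_cutoff))
    as_cua_ipd(data.frame(time = time, event = event,
                          arm = spec$arm_label, stringsAsFactors = FALSE))
  })
}

#' Validate individual patient data
#'
#' @param x data.frame with columns `time`, `event`, `arm`.
#' @return the validated data.frame with class `cua_ipd`.
#' @export
as_cua_ipd <- function(x) {
  if (!is.data.frame(x) || !all(c("time", "event", "arm") %in% names(x)))
    stop_input("IPD must be a data.frame with columns time, event, arm")
  if (nrow(x) == 0) stop_input("IPD must contain at least one record")
  if (any(!is.finite(x$time)) || any(x$time < 0))
    stop_input("IPD times must be finite and non-negative")
  if (!all(x$event %in% c(0L, 1L)))
    stop_input("IPD event flag must be 0 or 1")
  x$event <- as.integer(x$event)
  class(x) <- unique(c("cua_ipd", class(x)))
  x
}

#' Digitized-curve and risk-table artifacts from IPD
#'
#' Emulates the product a curve-digitization step would yield for a published
#' trial figure: the product-limit (Kaplan-Meier) estimate evaluated at the
#' observed event times, plus a number-at-risk table on a regular grid
#' (subjects with observed time >= grid time).
#'
#' @param ipd a single-arm `cua_ipd`.
#' @param risk_grid months at which the number at risk is reported.
#' @return list with elements `curve` (a [digitized_curve()]) and `risk`
#'   (a [risk_table()]).
#' @export
make_km_artifacts <- function(ipd, risk_grid = seq(0, 24, by = 2)) {
  ipd <- as_cua_ipd(ipd)
  curve <- kaplan_meier(ipd)
  n_risk <- vapply(risk_grid, function(g) sum(ipd$time >= g), integer(1))
  # trailing grid rows beyond follow-up carry no information; keep only rows
  # with at least one subject still at risk (plus the first empty one, if any)
  keep <- n_risk > 0
  if (any(!keep)) keep[which(!keep)[1]] <- TRUE
  list(curve = curve,
       risk = risk_table(risk_grid[keep], n_risk[keep]))
}

#' Default synthetic two-arm study
#'
#' A trial-shaped fixture used by the examples, tests and the acceptance
#' pipeline: 132 vs 131 subjects, Weibull event times with the experimental
#' arm at longer median PFS and OS than control, exponential dropout at
#' 1%/month, administrative cutoff 24 months and a risk grid every 2 months.
#' PFS and OS share the Weibull shape within an arm so the latent curves
#' never cross.
#'
#' @param seed integer base seed; endpoint/arm streams are offsets of it.
#' @return nested list `spec[[arm]][[endpoint]]` of [simulation_spec()]s,
#'   arms `experimental`/`control`, endpoints `pfs`/`os`.
#' @export
synthetic_trial_default <- function(seed = 20260101L) {
  wb <- function(shape, median) list(family = "weibull", shape = shape,
                                     scale = median / log(2)^(1 / shape))
  drop <- list(family = "exponential", rate = 0.01)
  mk <- function(label, n, model, off)
    simulation_spec(label, n, model, drop, admin_cutoff = 24,
                    risk_grid = seq(0, 24, by = 2), seed = seed + off)
  list(experimental = list(pfs = mk("experimental", 132, wb(1.3, 5.7), 1L),
                           os = mk("experimental", 132, wb(1.3, 13.6), 2L)),
       control = list(pfs = mk("control", 131, wb(1.1, 2.8), 3L),
                      os = mk("control", 131, wb(1.1, 9.4), 4L)))
}
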