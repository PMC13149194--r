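# End-to-end orchestration: configuration schema, the reconstruct -> fit ->
# select -> trace -> economics -> (DSA, PSA, threshold) pipeline, and report
# writing.

.default_families <- c("exponential", "weibull", "gompertz", "lognormal",
                       "loglogistic", "gamma", "generalized_gamma",
                       "fp1", "fp2")

.config_schema <- list(
  input = c("type", "seed", "paths", "total_events"),
  horizon = c("cycle_length_days", "horizon_years"),
  economics = NULL,  # validated against the settable parameter names
  scenario = c("preset", "structure", "price_factor", "pap", "wtp",
               "subgroup_hr", "posttx_mode", "half_cycle",
               "pd_excess_mortality"),
  survival = c("families", "fp_restarts"),
  dsa = c("enabled"),
  psa = c("enabled", "n", "seed"),
  threshold = c("enabled", "wtp"),
  output_dir = NULL)

.econ_override_keys <- function() {
  c(param_ranges(make_reference_config())$name, "price_factor")
}

#' Pipeline run configuration
#'
#' Assembles and validates the nested configuration driving [run_cua()].
#' Unknown blocks or keys are rejected by name. An empty `economics` block
#' reproduces the full reference parameter set of the base case.
#'
#' @param input list: `type = "synthetic"` (default; uses
#'   [synthetic_trial_default()] with `seed`) or `type = "csv"` with `paths`,
#'   a nested list `paths[[arm]][[endpoint]] = list(curve=, risk=)` of CSV
#'   paths for arms experimental/control and endpoints pfs/os.
#' @param horizon list: `cycle_length_days`, `horizon_years`.
#' @param economics named list of parameter overrides (names as in
#'   [param_ranges()], plus `price_factor`).
#' @param scenario list: `preset` (see [make_reference_config()]) and
#'   optional explicit switches `structure` ("markov"/"psm"),
#'   `price_factor`, `pap`, `wtp` ("national"/"regional"), `subgroup_hr`
#'   (named vector with elements pfs/os), `posttx_mode`, `half_cycle`,
#'   `pd_excess_mortality`.
#' @param survival list: `families` (candidate model families),
#'   `fp_restarts`.
#' @param dsa,psa,threshold analysis toggles: `list(enabled = TRUE, ...)`;
#'   `psa` takes `n` and `seed`, `threshold` takes `wtp`.
#' @param output_dir directory for CSV reports (created), or `NULL` to skip
#'   writing.
#' @return validated config list of class `cua_config`.
#' @export
cua_config <- function(input = list(type = "synthetic", seed = 20260101L),
                       horizon = list(cycle_length_days = 28,
                                      horizon_years = 10),
                       economics = list(),
                       scenario = list(preset = "base_case"),
                       survival = list(families = .default_families),
                       dsa = list(enabled = FALSE),
                       psa = list(enabled = FALSE, n = 1000, seed = 1L),
                       threshold = list(enabled = FALSE, wtp = "national"),
                       output_dir = NULL) {
  cfg <- list(input = input, horizon = horizon, economics = economics,
              scenario = scenario, survival = survival, dsa = dsa,
              psa = psa, threshold = threshold, output_dir = output_dir)
  validate_config(cfg)
}

#' Validate a pipeline configuration
#'
#' @param cfg a config list.
#' @return the config, classed `cua_config`; errors name the offending key.
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown))
    stop_input("unknown config block(s): ", paste(unknown, collapse = ", "))
  for (block in names(.config_schema)) {
    keys <- .config_schema[[block]]
    if (is.null(keys) || is.null(cfg[[block]])) next
    bad <- setdiff(names(cfg[[block]]), keys)
    if (length(bad))
      stop_input("unknown key(s) in config block '", block, "': ",
                 paste(bad, collapse = ", "))
  }
  if (length(cfg$economics)) {
    bad <- setdiff(names(cfg$economics), .econ_override_keys())
    if (length(bad))
      stop_input("unknown economics parameter(s): ",
                 paste(bad, collapse = ", "))
  }
  type <- cfg$input$type %||% "synthetic"
  if (!type %in% c("synthetic", "csv"))
    stop_input("input$type must be 'synthetic' or 'csv'")
  if (type == "csv" && is.null(cfg$input$paths))
    stop_input("input$type 'csv' requires input$paths")
  structure(cfg, class = "cua_config")
}

# Build the economic inputs implied by a config.
config_inputs <- function(cfg) {
  inputs <- make_reference_config(cfg$scenario$preset %||% "base_case")
  for (nm in names(cfg$economics))
    inputs <- set_param(inputs, nm, cfg$economics[[nm]])
  sc <- cfg$scenario
  if (!is.null(sc$structure)) inputs$scenario$structure <- sc$structure
  if (!is.null(sc$price_factor)) inputs$price_factor <- sc$price_factor
  if (!is.null(sc$pap)) inputs$pap <- sc$pap
  if (!is.null(sc$wtp)) inputs$scenario$wtp <- sc$wtp
  if (!is.null(sc$subgroup_hr)) inputs$scenario$subgroup_hr <- sc$subgroup_hr
  if (!is.null(sc$posttx_mode)) inputs$posttx_mode <- sc$posttx_mode
  if (!is.null(sc$half_cycle)) inputs$half_cycle <- sc$half_cycle
  if (!is.null(sc$pd_excess_mortality))
    inputs$pd_excess_mortality <- sc$pd_excess_mortality
  inputs
}

# Reconstructed IPD per arm/endpoint, via the digitized-artifact route so the
# synthetic path exercises the same reconstruction code as CSV input.
gather_ipd <- function(cfg, log) {
  type <- cfg$input$type %||% "synthetic"
  out <- list()
  hashes <- character(0)
  if (type == "synthetic") {
    specs <- synthetic_trial_default(seed = cfg$input$seed %||% 20260101L)
    for (arm in names(specs)) {
      out[[arm]] <- list()
      for (ep in names(specs[[arm]])) {
        ipd0 <- simulate_arm(specs[[arm]][[ep]])
        art <- make_km_artifacts(ipd0, specs[[arm]][[ep]]$risk_grid)
        out[[arm]][[ep]] <- reconstruct_ipd(art$curve, art$risk, arm = arm)
      }
    }
  } else {
    for (arm in c("experimental", "control")) {
      out[[arm]] <- list()
      for (ep in c("pfs", "os")) {
        p <- cfg$input$paths[[arm]][[ep]]
        if (is.null(p$curve) || is.null(p$risk))
          stop_input("missing curve/risk path for ", arm, "/", ep)
        curve <- read_digitized_curve(p$curve)
        risk <- read_risk_table(p$risk)
        te <- cfg$input$total_events[[arm]][[ep]] %||% NULL
        out[[arm]][[ep]] <- reconstruct_ipd(curve, risk, total_events = te,
                                            arm = arm)
        hashes <- c(hashes, tools::md5sum(c(p$curve, p$risk)))
      }
    }
  }
  list(ipd = out, hashes = hashes)
}

#' Run the full cost-utility pipeline
#'
#' Executes reconstruct -> fit -> select -> trace -> economics and, as
#' enabled, one-way DSA, PSA and the price-threshold analysis, then writes
#' CSV reports to `output_dir`.
#'
#' @param cfg a [cua_config()].
#' @return result bundle of class `cua_result`: inputs, per-arm/endpoint
#'   model rankings and selected fits, traces, the `cua_cea` comparison,
#'   optional `dsa`/`psa`/`ceac`/`threshold` components, and a log of
#'   design-decision flags and clamp counters.
#' @export
run_cua <- function(cfg) {
  cfg <- validate_config(unclass(cfg))
  log <- list()
  t0 <- Sys.time()
  inputs <- config_inputs(cfg)
  horizon <- model_horizon(cfg$horizon$cycle_length_days %||% 28,
                           cfg$horizon$horizon_years %||% 10)

  gi <- gather_ipd(cfg, log)
  ipd <- gi$ipd
  log$stage_ipd <- sprintf("ipd: %s input, %d datasets",
                           cfg$input$type %||% "synthetic",
                           sum(lengths(ipd)))

  families <- cfg$survival$families %||% .default_families
  fits <- list()
  rankings <- list()
  selected <- list()
  for (arm in names(ipd)) for (ep in names(ipd[[arm]])) {
    key <- paste(arm, ep, sep = ".")
    fl <- lapply(families, function(fam)
      tryCatch(fit_survival(ipd[[arm]][[ep]], fam),
               error = function(e)
                 structure(list(family = fam, message = conditionMessage(e)),
                           class = "cua_fitfail")))
    rankings[[key]] <- select_model(fl)
    selected[[key]] <- best_fit(rankings[[key]])
    fits[[key]] <- fl
  }
  log$stage_fit <- sprintf("fit: %d families x %d datasets",
                           length(families), length(rankings))

  curve_of <- function(arm, ep) {
    f <- as_surv_fn(selected[[paste(arm, ep, sep = ".")]])
    hr <- inputs$scenario$subgroup_hr
    if (!is.null(hr) && !is.na(hr[ep]))
      f <- adjust_by_hazard_ratio(f, hr[[ep]])
    f
  }
  structure_used <- inputs$scenario$structure %||% "markov"
  make_trace <- function(arm) {
    sp <- curve_of(arm, "pfs"); so <- curve_of(arm, "os")
    if (structure_used == "psm") return(run_psm(sp, so, horizon))
    sch <- build_schedule(sp, so, horizon,
                          pd_excess_mortality = inputs$pd_excess_mortality)
    tr <- run_markov(sch, horizon)
    attr(tr, "n_clamped") <- attr(sch, "n_clamped")
    tr
  }
  traces <- list(experimental = make_trace("experimental"),
                 control = make_trace("control"))
  log$stage_trace <- sprintf(
    "trace: structure=%s cycles=%d clamped=(%d,%d)",
    structure_used, horizon$n_cycles,
    attr(traces$experimental, "n_clamped") %||% 0,
    attr(traces$control, "n_clamped") %||% 0)

  cea <- run_cea(traces$experimental, traces$control, inputs)
  log$stage_economics <- sprintf("economics: dC=%.2f dE=%.4f icer=%.2f",
                                 cea$delta_cost, cea$delta_qaly, cea$icer)

  model_fn_inputs <- function(ip) run_cea(traces$experimental,
                                          traces$control, ip)
  res <- list(config = cfg, inputs = inputs, horizon = horizon,
              rankings = rankings, selected = selected, traces = traces,
              cea = cea)

  if (isTRUE(cfg$dsa$enabled)) {
    res$dsa <- one_way_dsa(inputs, model_fn_inputs)
    log$stage_dsa <- sprintf("dsa: %d parameters", nrow(res$dsa))
  }
  if (isTRUE(cfg$psa$enabled)) {
    n <- cfg$psa$n %||% 1000
    res$psa <- run_psa(inputs, model_fn_inputs, n = n,
                       seed = cfg$psa$seed %||% 1L)
    wtp_max <- 6 * inputs$wtp_national
    res$ceac <- ceac(res$psa, seq(0, wtp_max, length.out = 121))
    log$stage_psa <- sprintf("psa: %d iterations, %d failed", n,
                             sum(res$psa$failed))
  }
  if (isTRUE(cfg$threshold$enabled)) {
    wtp <- if (identical(cfg$threshold$wtp, "regional"))
      inputs$wtp_regional else inputs$wtp_national
    res$threshold <- threshold_price(function(f) {
      model_fn_inputs(set_param(inputs, "price_factor", f))
    }, wtp = wtp)
    log$stage_threshold <- sprintf("threshold: f*=%.4f status=%s",
                                   res$threshold$f_star %||% NA,
                                   res$threshold$status)
  }
  log$flags <- list(posttx_mode = inputs$posttx_mode,
                    half_cycle = inputs$half_cycle,
                    pd_excess_mortality = inputs$pd_excess_mortality,
                    pap = inputs$pap, price_factor = inputs$price_factor,
                    structure = structure_used,
                    input_hashes = gi$hashes)
  log$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  res$log <- log
  res <- structure(res, class = "cua_result")
  if (!is.null(cfg$output_dir)) report_tables(res, cfg$output_dir)
  res
}

#' Write the result bundle's report tables
#'
#' One CSV per analysis in the published column layout, plus per-arm traces,
#' fit summaries and a manifest recording every design-decision flag in
#' effect.
#'
#' @param res a `cua_result`.
#' @param dir output directory (created if needed).
#' @return invisibly the vector of written paths.
#' @export
report_tables <- function(res, dir) {
  stopifnot(inherits(res, "cua_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  w <- function(fname, writer) {
    p <- file.path(dir, fname)
    writer(p)
    paths <<- c(paths, p)
  }
  w("cea_results.csv", function(p) write_cea_table(res$cea, p))
  for (arm in names(res$traces))
    w(paste0("trace_", arm, ".csv"),
      function(p) write_trace(res$traces[[arm]], p))
  for (key in names(res$rankings))
    w(paste0("fits_", key, ".csv"),
      function(p) write_fit_summary(res$rankings[[key]], p))
  if (!is.null(res$dsa))
    w("dsa_tornado.csv",
      function(p) utils::write.csv(as.data.frame(res$dsa), p, row.names = FALSE))
  if (!is.null(res$psa))
    w("psa_samples.csv",
      function(p) utils::write.csv(as.data.frame(res$psa), p, row.names = FALSE))
  if (!is.null(res$ceac))
    w("ceac.csv",
      function(p) utils::write.csv(as.data.frame(res$ceac), p, row.names = FALSE))
  if (!is.null(res$threshold))
    w("threshold_grid.csv", function(p) {
      g <- res$threshold$grid[order(res$threshold$grid$f), ]
      g$is_f_star <- !is.na(res$threshold$f_star) &
        abs(g$f - res$threshold$f_star) < 1e-12
      utils::write.csv(g, p, row.names = FALSE)
    })
  w("manifest.txt", function(p) {
    fl <- res$log$flags
    lines <- c(sprintf("structure=%s", fl$structure),
               sprintf("posttx_mode=%s", fl$posttx_mode),
               sprintf("half_cycle=%s", fl$half_cycle),
               sprintf("pd_excess_mortality=%s", fl$pd_excess_mortality),
               sprintf("pap=%s", fl$pap),
               sprintf("price_factor=%s", fl$price_factor),
               sprintf("components=%s",
                       paste(intersect(c("cea", "dsa", "psa", "ceac",
                                         "threshold"), names(res)),
                             collapse = ",")),
               if (length(fl$input_hashes))
                 paste0("input_md5=", names(fl$input_hashes), ":",
                        fl$input_hashes))
    writeLines(lines, p)
  })
  invisible(paths)
}

#' @export
print.cua_result <- function(x, ...) {
  cat("Cost-utility analysis result (",
      x$log$flags$structure, " structure)\n", sep = "")
  cat("Selected survival models:\n")
  for (key in names(x$selected)) {
    f <- x$selected[[key]]
    cat(sprintf("  %-20s %s%s\n", key, f$family,
                if (!is.null(f$powers))
                  paste0(" (p=", paste(f$powers, collapse = ","), ")") else ""))
  }
  print(x$cea)
  if (!is.null(x$threshold)) print(x$threshold)
  invisible(x)
}
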