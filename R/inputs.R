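# Reference economic inputs: per-cycle drug costs, post-progression mix,
# monitoring, adverse-event risks/costs/disutilities, utilities, discounting
# and willingness-to-pay thresholds for the two-arm comparison (all USD;
# experimental arm = the antibody-drug conjugate, control = single-agent
# chemotherapy), plus the scenario switches of the analysis presets.

.ae_table <- function() {
  data.frame(
    name = c("anemia", "neutropenia", "leukopenia", "thrombocytopenia",
             "rash", "stomatitis", "ast_elevation"),
    risk_experimental = c(0.29, 0.35, 0.28, 0.13, 0.038, 0.10, 0.02),
    risk_control      = c(0.06, 0.47, 0.36, 0.04, 0,     0.01, 0.01),
    cost       = c(924.89, 684.18, 452.17, 1484.53, 745.43, 30.94, 160.38),
    disutility = c(0.07, 0.09, 0.09, 0.11, 0.05, 0.15, 0.06),
    stringsAsFactors = FALSE)
}

# Printed lower/upper bounds for every parameter (95% CIs where reported,
# otherwise +/-25%); utilities later clamped to [0, 1] for beta support.
.ae_bounds <- function() {
  list(
    risk_experimental = list(anemia = c(0.22, 0.36), neutropenia = c(0.26, 0.44),
                             leukopenia = c(0.21, 0.35), thrombocytopenia = c(0.10, 0.16),
                             rash = c(0.03, 0.05), stomatitis = c(0.08, 0.13),
                             ast_elevation = c(0.02, 0.03)),
    risk_control = list(anemia = c(0.05, 0.08), neutropenia = c(0.35, 0.59),
                        leukopenia = c(0.27, 0.45), thrombocytopenia = c(0.03, 0.05),
                        rash = c(0, 0), stomatitis = c(0.01, 0.01),
                        ast_elevation = c(0.01, 0.01)),
    cost = list(anemia = c(693.67, 1156.11), neutropenia = c(513.14, 855.23),
                leukopenia = c(339.13, 565.21), thrombocytopenia = c(1113.40, 1855.66),
                rash = c(559.07, 931.79), stomatitis = c(23.21, 38.68),
                ast_elevation = c(120.29, 200.48)),
    disutility = list(anemia = c(0.05, 0.09), neutropenia = c(0.07, 0.11),
                      leukopenia = c(0.07, 0.11), thrombocytopenia = c(0.08, 0.14),
                      rash = c(0.04, 0.06), stomatitis = c(0.11, 0.19),
                      ast_elevation = c(0.05, 0.08)))
}

#' Reference economic configuration
#'
#' Returns the full base parameter set of the cost-utility model with scenario
#' switches set per preset:
#' \describe{
#'   \item{base_case}{Markov structure, list price, national WTP.}
#'   \item{pap}{patient-assistance program on ("2 cycles paid, 2 free").}
#'   \item{negotiated}{drug price factor 1800/9399 (post-negotiation vial
#'     price over list vial price).}
#'   \item{regional_wtp}{WTP of an economically underdeveloped region.}
#'   \item{psm}{partitioned-survival structure.}
#'   \item{subgroup}{hazard-ratio-adjusted subgroup curves (synthetic default
#'     HRs; real subgroup HRs are study inputs).}
#' }
#'
#' @param preset one of `base_case`, `pap`, `negotiated`, `regional_wtp`,
#'   `psm`, `subgroup`.
#' @return list of class `cua_inputs`.
#' @export
make_reference_config <- function(preset = "base_case") {
  presets <- c("base_case", "pap", "negotiated", "regional_wtp", "psm",
               "subgroup")
  if (!preset %in% presets)
    stop_input("unknown preset '", preset, "'; expected one of ",
               paste(presets, collapse = ", "))
  inputs <- structure(list(
    drug_cost_cycle = c(experimental = 3635.34, control = 402.23),
    posttx_cost = c(experimental = 585.62, control = 1332.77),
    posttx_prob = c(experimental = 0.51, control = 0.71),
    bsc_cost = 807.68,
    monitor_costs = c(blood = 36.79, imaging = 45.28, bone_scan = 39.62),
    monitor_every = c(blood = 1, imaging = 2, bone_scan = 3),
    ae = .ae_table(),
    eol_cost = 2330.28,
    u_pfs = 0.85,
    u_pd = 0.52,
    discount_annual = 0.045,
    wtp_national = 26933.61,
    wtp_regional = 14880.28,
    price_factor = 1,
    pap = FALSE,
    posttx_mode = "per_cycle",
    half_cycle = FALSE,
    pd_excess_mortality = 1,
    scenario = list(label = preset, structure = "markov", wtp = "national",
                    subgroup_hr = NULL)),
    class = "cua_inputs")
  switch(preset,
         pap = { inputs$pap <- TRUE },
         negotiated = { inputs$price_factor <- 1800 / 9399 },
         regional_wtp = { inputs$scenario$wtp <- "regional" },
         psm = { inputs$scenario$structure <- "psm" },
         subgroup = {
           inputs$scenario$subgroup_hr <- c(pfs = 0.8, os = 0.8)
         },
         base_case = NULL)
  inputs
}

#' Active willingness-to-pay threshold of a configuration
#' @param inputs a `cua_inputs`.
#' @return USD/QALY.
#' @export
active_wtp <- function(inputs) {
  if (identical(inputs$scenario$wtp, "regional")) inputs$wtp_regional
  else inputs$wtp_national
}

#' Sensitivity-analysis parameter ranges
#'
#' One row per varied parameter: base value, lower/upper bound and assigned
#' distribution (gamma for costs, beta for probabilities and utilities; the
#' discount rate spans 0.03-0.05). Utility bounds are clamped to \[0, 1\].
#'
#' @param inputs a `cua_inputs`.
#' @return data.frame (name, base, low, high, dist).
#' @export
param_ranges <- function(inputs) {
  stopifnot(inherits(inputs, "cua_inputs"))
  b <- .ae_bounds()
  rows <- list(
    c("drug_cost_experimental", 3635.34, 2726.51, 4544.18, "gamma"),
    c("drug_cost_control", 402.23, 301.67, 502.79, "gamma"),
    c("posttx_cost_experimental", 585.62, 439.22, 732.03, "gamma"),
    c("posttx_cost_control", 1332.77, 999.58, 1665.96, "gamma"),
    c("bsc_cost", 807.68, 605.76, 1009.60, "gamma"),
    c("monitor_blood", 36.79, 27.59, 45.99, "gamma"),
    c("monitor_imaging", 45.28, 33.96, 56.6, "gamma"),
    c("monitor_bone_scan", 39.62, 29.72, 49.53, "gamma"),
    c("eol_cost", 2330.28, 1747.71, 2912.85, "gamma"),
    c("u_pfs", 0.85, 0.64, 1, "beta"),
    c("u_pd", 0.52, 0.39, 0.65, "beta"),
    c("discount", 0.045, 0.03, 0.05, "beta"),
    c("posttx_prob_experimental", 0.51, 0.38, 0.64, "beta"),
    c("posttx_prob_control", 0.71, 0.53, 0.89, "beta"))
  ae <- inputs$ae
  for (i in seq_len(nrow(ae))) {
    nm <- ae$name[i]
    rows <- c(rows, list(
      c(paste0("ae_cost_", nm), ae$cost[i], b$cost[[nm]][1], b$cost[[nm]][2], "gamma"),
      c(paste0("ae_risk_", nm, "_experimental"), ae$risk_experimental[i],
        b$risk_experimental[[nm]][1], b$risk_experimental[[nm]][2], "beta"),
      c(paste0("ae_risk_", nm, "_control"), ae$risk_control[i],
        b$risk_control[[nm]][1], b$risk_control[[nm]][2], "beta"),
      c(paste0("ae_disutil_", nm), ae$disutility[i],
        b$disutility[[nm]][1], b$disutility[[nm]][2], "beta")))
  }
  out <- data.frame(name = vapply(rows, `[`, character(1), 1),
                    base = as.numeric(vapply(rows, `[`, character(1), 2)),
                    low = as.numeric(vapply(rows, `[`, character(1), 3)),
                    high = as.numeric(vapply(rows, `[`, character(1), 4)),
                    dist = vapply(rows, `[`, character(1), 5),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$low <= out$base & out$base <= out$high))
  out
}

#' Set one named parameter in an inputs object
#'
#' Writes a value addressed by its sensitivity-analysis name (see
#' [param_ranges()], plus `price_factor`) back into a `cua_inputs`; used by
#' the DSA/PSA machinery and scenario closures.
#'
#' @param inputs a `cua_inputs`.
#' @param name parameter name.
#' @param value new value.
#' @return the modified inputs.
#' @export
set_param <- function(inputs, name, value) {
  ae_m <- regmatches(name, regexec(
    "^ae_(cost|risk|disutil)_([a-z_]+?)(_(experimental|control))?$", name,
    perl = TRUE))[[1]]
  if (length(ae_m)) {
    what <- ae_m[2]; ae_name <- ae_m[3]; arm <- ae_m[5]
    i <- match(ae_name, inputs$ae$name)
    if (is.na(i)) stop_input("unknown adverse event: ", ae_name)
    col <- switch(what, cost = "cost", disutil = "disutility",
                  risk = paste0("risk_", arm))
    inputs$ae[i, col] <- value
    return(inputs)
  }
  switch(name,
         drug_cost_experimental = inputs$drug_cost_cycle[["experimental"]] <- value,
         drug_cost_control = inputs$drug_cost_cycle[["control"]] <- value,
         posttx_cost_experimental = inputs$posttx_cost[["experimental"]] <- value,
         posttx_cost_control = inputs$posttx_cost[["control"]] <- value,
         posttx_prob_experimental = inputs$posttx_prob[["experimental"]] <- value,
         posttx_prob_control = inputs$posttx_prob[["control"]] <- value,
         bsc_cost = inputs$bsc_cost <- value,
         monitor_blood = inputs$monitor_costs[["blood"]] <- value,
         monitor_imaging = inputs$monitor_costs[["imaging"]] <- value,
         monitor_bone_scan = inputs$monitor_costs[["bone_scan"]] <- value,
         eol_cost = inputs$eol_cost <- value,
         u_pfs = inputs$u_pfs <- value,
         u_pd = inputs$u_pd <- value,
         discount = inputs$discount_annual <- value,
         price_factor = inputs$price_factor <- value,
         stop_input("unknown parameter: ", name))
  inputs
}
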