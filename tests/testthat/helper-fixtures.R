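# Shared fixtures: small IPD generators, hand-built traces and horizons.

with_seed_test <- function(seed, code) survcua:::with_seed(seed, code)

# true survival function of a simulation event model
model_survival_true <- function(m) survcua:::model_survival(m)

exp_ipd <- function(n, rate, seed = 1L, arm = "a") {
  spec <- simulation_spec(arm, n, list(family = "exponential", rate = rate),
                          admin_cutoff = Inf, risk_grid = c(0, 1),
                          seed = seed)
  simulate_arm(spec)
}

# Horizon with exactly K cycles of 28 days.
horizon_k <- function(K) model_horizon(28, (K * 28 + 1) / 365.25)

# Manually specified trace; occupancy rows must sum to 1.
manual_trace <- function(pfs, pd, structure_name = "manual") {
  occ <- cbind(pfs, pd, 1 - pfs - pd)
  survcua:::new_trace(occ, diff(occ[, 3]),
                      pmax(0, diff(occ[, 2])),
                      horizon_k(length(pfs) - 1), structure_name)
}

# Schedule with given per-cycle probabilities.
manual_schedule <- function(p_death, q_leave, p_death_pd = p_death) {
  K <- length(p_death)
  structure(data.frame(cycle = seq_len(K), p_death = p_death,
                       p_death_pd = p_death_pd, q_leave = q_leave,
                       p_pfs_to_pd = pmax(0, q_leave - p_death),
                       clamped = FALSE, floor_bind = q_leave < p_death),
            n_clamped = 0L, n_floor = sum(q_leave < p_death),
            pd_excess_mortality = 1,
            class = c("cua_schedule", "data.frame"))
}

# Reference inputs with adverse events switched off (for hand arithmetic).
inputs_no_ae <- function(preset = "base_case") {
  inp <- make_reference_config(preset)
  inp$ae$risk_experimental <- 0
  inp$ae$risk_control <- 0
  inp
}

# Brute-force product-limit estimator, independent of the package's
# survfit-based implementation: direct loop over distinct event times.
brute_km <- function(time, event) {
  tu <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tu))
  for (i in seq_along(tu)) {
    n_at_risk <- sum(time >= tu[i])
    d <- sum(time == tu[i] & event == 1)
    s <- s * (1 - d / n_at_risk)
    out[i] <- s
  }
  data.frame(time = tu, survival = out)
}
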